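#' Estimate the plastid-derived read fraction
#'
#' Maps a sample of reads against a (possibly diverged) plastome bait and
#' reports the fraction of read bases that align, with a 95% binomial
#' interval computed on reads.
#'
#' @param reads a [read_pairs] object.
#' @param bait_reference plastome bait sequence (character) or named vector
#'   (first entry used).
#' @param sample_size number of pairs sampled (default 10000, or all).
#' @param max_mm_rate mapping mismatch tolerance (bait may be a relative).
#' @param seed sampling seed.
#' @return List: `fraction` (of bases), `ci` (95% interval over reads),
#'   `n_reads_sampled`, `n_reads_mapped`.
#' @export
estimate_cp_fraction <- function(reads, bait_reference, sample_size = 10000,
                                 max_mm_rate = 0.1, seed = 1) {
  bait <- as.character(bait_reference)[1]
  if (is.na(bait) || !nzchar(bait)) stop("empty bait reference")
  n <- length(reads)
  idx <- if (n > sample_size)
    with_seed(seed, sort(sample.int(n, sample_size))) else seq_len(n)
  sub <- reads[idx]
  pl <- map_reads(sub, bait, max_mm_rate = max_mm_rate, circular = TRUE)
  best <- pl[!duplicated(pl$qidx), , drop = FALSE]
  mapped_bases <- sum(best$qend - best$qstart)
  tot <- total_bases(sub)
  n_mates <- 2L * length(sub)
  n_mapped <- length(unique(pl$qidx))
  ci <- as.numeric(stats::binom.test(n_mapped, n_mates)$conf.int)
  list(fraction = mapped_bases / tot, ci = ci,
       n_reads_sampled = n_mates, n_reads_mapped = n_mapped)
}

#' Subsample a skim into a plastid-coverage window
#'
#' Draws a seed-deterministic uniform subset of pairs totalling
#' `target_cp_coverage * cp_size_estimate / cp_fraction` read bases.
#' A warning is emitted when the implied whole-genome coverage of the
#' selection exceeds 20x, the regime where nuclear/mitochondrial plastid
#' insertions start to corrupt high-copy assembly; another when the request
#' exceeds the available data (everything is returned).
#'
#' @param reads a [read_pairs] object.
#' @param plan a [coverage_plan].
#' @return A `read_pairs` subset; attribute `selected_bases` reports size.
#' @export
subsample <- function(reads, plan) {
  stopifnot(inherits(plan, "coverage_plan"))
  target <- plan$target_cp_coverage * plan$cp_size_estimate / plan$cp_fraction
  implied_wg <- target / plan$genome_size
  if (implied_wg > 20)
    warning(sprintf(paste0("selection implies %.1fx whole-genome coverage ",
                           "(>20x): NMPT co-assembly becomes likely"),
                    implied_wg))
  bases <- nchar(reads$seq1) + nchar(reads$seq2)
  if (target >= sum(bases)) {
    if (target > sum(bases))
      warning("requested bases exceed available reads: returning all pairs")
    out <- reads
    attr(out, "selected_bases") <- sum(bases)
    return(out)
  }
  ord <- with_seed(plan$seed, sample.int(length(reads)))
  cum <- cumsum(bases[ord])
  k <- findInterval(target, cum) + 1L   # allow overshoot by at most one pair
  k <- min(k, length(reads))
  sel <- sort(ord[seq_len(k)])
  out <- reads[sel]
  attr(out, "selected_bases") <- sum(bases[sel])
  out
}

panel_kmer_sets <- function(panel, k = 21) {
  lapply(panel, function(seqs)
    cpp_count_kmers(as.character(seqs), as.integer(k), 1L)$kmer)
}

#' Classify contigs against a labelled reference panel
#'
#' Screens each contig by the fraction of its canonical 21-mers shared with
#' each panel class; the best class wins, or `other` when the best fraction
#' falls below `min_fraction`. Invariant under contig reverse complement.
#'
#' @param contigs list of [contig] objects (or character vector).
#' @param panel named list of character vectors of reference sequences;
#'   names are the class labels (e.g. `cp`, `mt`, `nR`).
#' @param k screening k-mer size.
#' @param min_fraction minimum shared fraction for a confident label.
#' @return data.frame sorted by decreasing contig length: `id`, `length`,
#'   `label`, `fraction`, `best_class`.
#' @export
classify_contigs <- function(contigs, panel, k = 21, min_fraction = 0.3) {
  stopifnot(length(panel) >= 1, !is.null(names(panel)))
  if (!length(contigs))
    return(data.frame(id = character(), length = integer(),
                      label = character(), fraction = numeric(),
                      best_class = character(), stringsAsFactors = FALSE))
  seqs <- vapply(contigs, function(x)
    if (inherits(x, "contig")) x$seq else as.character(x), character(1))
  ids <- vapply(seq_along(contigs), function(i) {
    x <- contigs[[i]]
    if (inherits(x, "contig")) x$id else paste0("ctg", i)
  }, character(1))
  sets <- panel_kmer_sets(panel, k)
  res <- lapply(seqs, function(s) {
    km <- cpp_count_kmers(s, as.integer(k), 1L)$kmer
    if (!length(km)) return(c(frac = 0, best = NA_integer_))
    fr <- vapply(sets, function(ref) mean(km %in% ref), numeric(1))
    c(frac = max(fr), best = unname(which.max(fr)))
  })
  frac <- vapply(res, `[[`, numeric(1), "frac")
  best <- names(panel)[vapply(res, `[[`, numeric(1), "best")]
  label <- ifelse(frac >= min_fraction, best, "other")
  out <- data.frame(id = ids, length = nchar(seqs), label = label,
                    fraction = frac, best_class = best,
                    stringsAsFactors = FALSE)
  out[order(-out$length, out$id), , drop = FALSE]
}
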