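#' Complete a 45S ribosomal DNA unit by two-unit tandem gap closing
#'
#' Because 45S units are tandemly arrayed and highly homogeneous, a contig
#' carrying the cistron plus a partial intergenic spacer can be completed
#' by building `contig + (N)n + contig`, gap-closing with the raw reads,
#' and cutting one full unit between the two cistron start positions.
#' The intervening N length acts as the gap-size prior for the closer; when
#' a stage stalls (GC-rich IGS sub-repeats, badly under-estimated gaps) the
#' next length in `n_len_schedule` is tried.
#'
#' @param initial_contig a [contig] or sequence containing the full cistron.
#' @param reads the raw [read_pairs].
#' @param n_len_schedule N lengths tried in order (default 100, 300, 1000).
#' @param cistron_model sequence marking the cistron (18S) start; the unit
#'   is canonicalized to begin at its match.
#' @param sub_models optional named list of sub-region model sequences
#'   (`18S`, `5.8S`, `26S`) used to annotate the unit.
#' @return An object of class `rdna_unit` (`unit_class = "45S"`): `seq`,
#'   `sub_regions`, `cistron_length`, `igs_length`, `complete`,
#'   `n_used`; when every schedule entry stalls, the partial two-unit
#'   construct is returned with `complete = FALSE` and the remaining gap
#'   marked.
#' @export
complete_45s <- function(initial_contig, reads, n_len_schedule = c(100, 300, 1000),
                         cistron_model, sub_models = NULL) {
  s <- if (inherits(initial_contig, "contig")) initial_contig$seq
       else as.character(initial_contig)
  model <- as.character(cistron_model)[1]
  # orient the contig so the model reads forward
  hit <- locate_model(model, s)
  if (is.null(hit)) stop("initial contig does not match the cistron model")
  if (hit$strand == "-") {
    s <- cpp_revcomp(s)
    hit <- locate_model(model, s)
  }
  closed <- NULL
  n_used <- NA_integer_
  for (nl in n_len_schedule) {
    two <- paste0(s, strrep("N", nl), s)
    st <- tryCatch(close_gaps(two, reads), error = function(e) NULL)
    if (!is.null(st) && st$n_gaps == 0) { closed <- st$seq; n_used <- nl; break }
  }
  if (is.null(closed)) {
    return(structure(list(unit_class = "45S", seq = paste0(s, strrep("N", 100), s),
                          sub_regions = NULL, cistron_length = NA_integer_,
                          igs_length = NA_integer_, complete = FALSE,
                          n_used = NA_integer_,
                          copy_number_estimate = NA_real_),
                     class = "rdna_unit"))
  }
  # one full unit spans cistron start to cistron start
  h1 <- locate_model(model, closed)
  if (is.null(h1)) stop("cistron model lost during gap closing")
  rest <- substring(closed, h1$start + 1L)
  h2 <- locate_model(model, rest)
  if (is.null(h2)) stop("second cistron copy not found after closing")
  unit <- substr(closed, h1$start, h1$start + h2$start - 1L)
  annotate_45s_unit(unit, model, sub_models, n_used)
}

annotate_45s_unit <- function(unit, model, sub_models, n_used = NA_integer_) {
  ul <- nchar(unit)
  sub_regions <- NULL
  cis_len <- NA_integer_
  if (!is.null(sub_models)) {
    pos <- lapply(sub_models, function(m) locate_model(m, unit))
    if (!any(vapply(pos, is.null, logical(1)))) {
      s18 <- pos[["18S"]]; s58 <- pos[["5.8S"]]; s26 <- pos[["26S"]]
      ends <- c(`18S` = s18$end, `5.8S` = s58$end, `26S` = s26$end)
      sub_regions <- data.frame(
        region = c("18S", "ITS1", "5.8S", "ITS2", "26S", "IGS"),
        start = c(s18$start, s18$end + 1L, s58$start, s58$end + 1L,
                  s26$start, s26$end + 1L),
        end = c(s18$end, s58$start - 1L, s58$end, s26$start - 1L,
                s26$end, ul), stringsAsFactors = FALSE)
      cis_len <- s26$end
    }
  }
  structure(list(unit_class = "45S", seq = unit, sub_regions = sub_regions,
                 cistron_length = cis_len,
                 igs_length = if (is.na(cis_len)) NA_integer_ else ul - cis_len,
                 complete = TRUE, n_used = n_used,
                 copy_number_estimate = NA_real_),
            class = "rdna_unit")
}

# locate a model sequence in s (exact first, then mapped); returns 1-based
# start/end and strand, or NULL
locate_model <- function(model, s) {
  p <- regexpr(model, s, fixed = TRUE)
  if (p > 0) return(list(start = as.integer(p),
                         end = as.integer(p) + nchar(model) - 1L,
                         strand = "+"))
  p <- regexpr(cpp_revcomp(model), s, fixed = TRUE)
  if (p > 0) return(list(start = as.integer(p),
                         end = as.integer(p) + nchar(model) - 1L,
                         strand = "-"))
  pl <- map_reads(model, s, max_mm_rate = 0.1)
  if (!nrow(pl)) return(NULL)
  b <- pl[1, ]
  list(start = b$rstart + 1L, end = b$rend, strand = b$strand)
}

#' Extract a complete 5S unit from a tandem contig
#'
#' The unit is one full period of the tandem structure, found as the
#' minimal rotation period at >= 99% self-identity (a contig spanning more
#' than one unit); circular contigs (an assembled tandem collapsed into a
#' cycle) are taken as exactly one unit. The unit is canonicalized to start
#' at the 5S gene model match. Secondary period candidates are reported
#' rather than suppressed.
#'
#' @param contigs list of [contig]s (or a single contig/sequence).
#' @param gene_model the 5S gene sequence used to select and orient.
#' @return An `rdna_unit` (`unit_class = "5S"`) with attribute
#'   `secondary_periods`.
#' @export
extract_5s <- function(contigs, gene_model) {
  if (inherits(contigs, "contig") || is.character(contigs))
    contigs <- list(contigs)
  model <- as.character(gene_model)[1]
  for (ct in contigs) {
    s <- if (inherits(ct, "contig")) ct$seq else as.character(ct)
    circ <- if (inherits(ct, "contig")) isTRUE(ct$circular) else FALSE
    hit <- locate_model(model, s)
    if (is.null(hit)) next
    if (hit$strand == "-") {
      s <- cpp_revcomp(s)
      hit <- locate_model(model, s)
    }
    n <- nchar(s)
    if (circ) {
      unit <- paste0(substring(s, hit$start), substr(s, 1, hit$start - 1L))
      out <- structure(list(unit_class = "5S", seq = unit, sub_regions = NULL,
                            cistron_length = nchar(model),
                            igs_length = nchar(unit) - nchar(model),
                            complete = TRUE, n_used = NA_integer_,
                            copy_number_estimate = NA_real_),
                       class = "rdna_unit")
      attr(out, "secondary_periods") <- integer()
      return(out)
    }
    # minimal period with >= 99% identity between shifted copies
    periods <- integer()
    for (p in seq(20L, n %/% 2)) {
      a <- substr(s, 1, n - p); b <- substring(s, p + 1L)
      mm <- cpp_hamming(a, b)
      if (mm >= 0 && mm <= 0.01 * (n - p)) periods <- c(periods, p)
      if (length(periods) >= 4) break
    }
    if (!length(periods)) {
      if (n < 2 * nchar(model)) stop("incomplete unit: contig shorter than one period")
      # exactly-one-unit contig: treat the whole contig as the unit
      unit <- paste0(substring(s, hit$start), substr(s, 1, hit$start - 1L))
      out <- structure(list(unit_class = "5S", seq = unit, sub_regions = NULL,
                            cistron_length = nchar(model),
                            igs_length = nchar(unit) - nchar(model),
                            complete = TRUE, n_used = NA_integer_,
                            copy_number_estimate = NA_real_),
                       class = "rdna_unit")
      attr(out, "secondary_periods") <- integer()
      return(out)
    }
    p <- periods[1]
    if (hit$start + p - 1L > n) stop("incomplete unit: model match too close to contig end")
    unit <- substr(s, hit$start, hit$start + p - 1L)
    out <- structure(list(unit_class = "5S", seq = unit, sub_regions = NULL,
                          cistron_length = nchar(model),
                          igs_length = p - nchar(model), complete = TRUE,
                          n_used = NA_integer_,
                          copy_number_estimate = NA_real_),
                     class = "rdna_unit")
    attr(out, "secondary_periods") <- setdiff(periods, p)
    return(out)
  }
  stop("no contig matches the 5S gene model")
}

#' @export
print.rdna_unit <- function(x, ...) {
  cat(sprintf("rdna_unit %s: %d bp%s%s\n", x$unit_class, nchar(x$seq),
              if (isTRUE(x$complete)) "" else " (incomplete)",
              if (is.na(x$copy_number_estimate)) ""
              else sprintf(", ~%.0f copies per 1x genome equivalent",
                           x$copy_number_estimate)))
  invisible(x)
}

#' Estimate rDNA copy number from read depth
#'
#' Subsamples the reads to exactly one haploid genome equivalent
#' (`genome_size` read bases, seed-deterministic), maps them to the unit
#' treated as circular (tandem context), and reports the mean per-base
#' depth — under a 1x genome equivalent the mean mapped depth of a
#' sequence equals its copy number. Multi-mapping reads contribute
#' fractional weight.
#'
#' @param unit an `rdna_unit` (or sequence).
#' @param reads raw [read_pairs] (at least 1x genome equivalent).
#' @param genome_size haploid genome size in bp.
#' @param seed subsampling seed.
#' @param max_mm_rate mapping tolerance.
#' @return The unit with `copy_number_estimate` set; attributes `interval`
#'   (mean +/- 1.96 se over unit positions) and `mean_depth`.
#' @export
estimate_copy_number <- function(unit, reads, genome_size, seed = 1,
                                 max_mm_rate = 0.05) {
  useq <- if (inherits(unit, "rdna_unit")) unit$seq else as.character(unit)
  stopifnot(genome_size > 0)
  read_len <- max(nchar(reads$seq1), nchar(reads$seq2))
  if (nchar(useq) < read_len)
    stop("unit shorter than the read length")
  bases <- nchar(reads$seq1) + nchar(reads$seq2)
  if (sum(bases) < genome_size)
    warning("fewer than 1x genome-equivalent read bases available")
  ord <- with_seed(seed, sample.int(length(reads)))
  k <- findInterval(genome_size, cumsum(bases[ord])) + 1L
  k <- min(k, length(reads))
  sub <- reads[sort(ord[seq_len(k)])]
  pl <- map_reads(sub, useq, max_mm_rate = max_mm_rate, circular = TRUE)
  d <- placement_depth(pl, nchar(useq), TRUE, weight = "fractional")
  est <- mean(d)
  n_eff <- nchar(useq) / read_len
  se <- stats::sd(d) / sqrt(max(n_eff, 1))
  if (inherits(unit, "rdna_unit")) {
    unit$copy_number_estimate <- est
    out <- unit
  } else {
    out <- structure(list(unit_class = "unknown", seq = useq,
                          sub_regions = NULL, cistron_length = NA_integer_,
                          igs_length = NA_integer_, complete = TRUE,
                          n_used = NA_integer_, copy_number_estimate = est),
                     class = "rdna_unit")
  }
  attr(out, "interval") <- c(est - 1.96 * se, est + 1.96 * se)
  attr(out, "mean_depth") <- est
  out
}
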