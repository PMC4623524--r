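#' Build a canonical k-mer de Bruijn graph
#'
#' Counts canonical k-mers (lexicographic minimum of a k-mer and its reverse
#' complement) across all mates and keeps those occurring at least
#' `min_count` times. Counts are exact. Odd `k` is required unless
#' `allow_even_k = TRUE` (even k admits palindromic self-canonical k-mers;
#' it is permitted so that repeat-resolving values such as k = 64 can be
#' used).
#'
#' @param reads a [read_pairs] object or character vector of sequences.
#' @param k k-mer length (< read length).
#' @param min_count minimum k-mer multiplicity retained (default 3; use 1
#'   for error-free data).
#' @param allow_even_k permit even k.
#' @return An object of class `kmer_graph` (k, k-mer vector, count vector).
#' @export
build_graph <- function(reads, k = 31, min_count = 3, allow_even_k = FALSE) {
  seqs <- if (inherits(reads, "read_pairs")) c(reads$seq1, reads$seq2)
          else as.character(reads)
  stopifnot(min_count >= 1)
  if (k %% 2 == 0 && !allow_even_k)
    stop("even k admits palindromic k-mers; pass allow_even_k = TRUE to override")
  if (!any(nchar(seqs) >= k)) stop("no read is at least k bases long")
  tab <- cpp_count_kmers(seqs, k, as.integer(min_count))
  structure(list(k = k, kmer = tab$kmer, count = tab$count),
            class = "kmer_graph")
}

#' @export
print.kmer_graph <- function(x, ...) {
  cat(sprintf("kmer_graph: k=%d, %d nodes, counts %s\n", x$k, length(x$kmer),
              if (length(x$count)) paste0("[", min(x$count), ", ",
                                          max(x$count), "]") else "[]"))
  invisible(x)
}

#' Assemble unitigs from a k-mer graph
#'
#' Extracts maximal unambiguous paths after tip clipping, bubble popping and
#' relative-abundance edge cleanup. Contigs are reported longest first
#' (lexicographic tie-break); a path that closes on itself is flagged
#' circular and reported in canonical rotation with the duplicated overlap
#' removed. Traversal stops at every ambiguous branch: repeat resolution is
#' deferred to the finishing stage.
#'
#' @param graph a `kmer_graph` from [build_graph].
#' @param reads unused; retained so callers can thread the read set through
#'   a uniform interface.
#' @param cleanup_rounds graph-cleanup iterations (default 3).
#' @param tip_len_factor tips shorter than this multiple of k are clipping
#'   candidates.
#' @param tip_frac tip mean-count threshold relative to its neighbours.
#' @param rel_frac branches below this fraction of the strongest neighbour
#'   are removed.
#' @param bubble_mm maximal mismatches between popped bubble branches.
#' @return List of [contig] objects.
#' @export
assemble <- function(graph, reads = NULL, cleanup_rounds = 3,
                     tip_len_factor = 2, tip_frac = 0.25, rel_frac = 0.05,
                     bubble_mm = 2) {
  if (length(graph$kmer) == 0) return(list())
  u <- cpp_unitigs(graph$kmer, graph$count, graph$k,
                   as.integer(cleanup_rounds), tip_len_factor, tip_frac,
                   rel_frac, as.integer(bubble_mm))
  prov <- sprintf("k=%d", graph$k)
  lapply(seq_along(u$seq), function(i)
    contig(u$seq[i], id = sprintf("ctg%04d", i), circular = u$circular[i],
           mean_count = u$mean_count[i], provenance = prov))
}

# --- gap closing ------------------------------------------------------------

# Recruit partner reads anchored near a point, oriented into the gap.
# side = "left": anchors on '+' strand upstream of `edge`; returns partner
# sequences oriented 5'->3' along the reference with expected start.
recruit_side <- function(pl, rp, edge, max_ins, insert_mean, insert_sd,
                         side = c("left", "right")) {
  side <- match.arg(side)
  n <- length(rp)
  if (side == "left") {
    sel <- pl$strand == "+" & pl$rend <= edge & pl$rend >= edge - max_ins
  } else {
    sel <- pl$strand == "-" & pl$rstart >= edge & pl$rstart <= edge + max_ins
  }
  if (!any(sel)) return(data.frame(seq = character(), est = numeric()))
  p <- pl[sel, , drop = FALSE]
  mate <- ifelse(p$qidx > n, p$qidx - n, p$qidx + n)  # the partner mate index
  partner_raw <- c(rp$seq1, rp$seq2)[mate]
  if (side == "left") {
    seqs <- vapply(partner_raw, cpp_revcomp, character(1), USE.NAMES = FALSE)
    est <- p$rstart + insert_mean - nchar(seqs)
  } else {
    seqs <- partner_raw
    est <- p$rend - insert_mean
  }
  unique(data.frame(seq = seqs, est = est, stringsAsFactors = FALSE))
}

# Greedy consensus extension of `flank` using candidates gated by expected
# position. Returns the extension string (possibly "").
extend_edge <- function(flank, cand, edge_pos, budget, min_anchor,
                        read_len_max, tol) {
  ext <- ""
  if (!nrow(cand)) return(ext)
  o <- order(cand$est, cand$seq)
  cand <- cand[o, , drop = FALSE]
  repeat {
    if (nchar(ext) >= budget) break
    cur <- paste0(flank, ext)
    pos_now <- edge_pos + nchar(ext)
    use <- cand$est >= pos_now - read_len_max - tol & cand$est <= pos_now + tol
    if (!any(use)) break
    ov <- cpp_max_overlap_vec(cur, cand$seq[use], as.integer(min_anchor),
                              as.integer(read_len_max + 10L))
    overhang <- nchar(cand$seq[use]) - ov
    good <- ov >= min_anchor & overhang > 0
    if (!any(good)) break
    ovg <- ov[good]
    sq <- cand$seq[use][good]
    mx <- max(ovg)
    top <- sq[ovg == mx]
    pieces <- substring(top, mx + 1L)
    tb <- sort(table(pieces), decreasing = TRUE)
    # candidates vote on the continuation; deterministic tie-break
    piece <- names(tb)[1]
    if (length(tb) > 1 && tb[2] == tb[1]) {
      cands <- sort(names(tb)[tb == tb[1]])
      agree <- max(nchar(cands[1]), 0)
      # keep only the agreed prefix of the tied continuations
      pref <- cands[1]
      for (cc in cands[-1]) {
        m <- min(nchar(pref), nchar(cc))
        eq <- which(seq_chars(substr(pref, 1, m)) != seq_chars(substr(cc, 1, m)))
        if (length(eq)) pref <- substr(pref, 1, eq[1] - 1L)
        agree <- nchar(pref)
      }
      if (agree == 0) break  # genuine ambiguity: stall this edge
      piece <- pref
    }
    ext <- paste0(ext, piece)
  }
  substr(ext, 1, budget)
}

#' Iteratively close N gaps with paired-read support
#'
#' Per iteration each gap edge is extended by the consensus of reads whose
#' mates anchor within insert range of the edge and whose expected placement
#' overlaps it. A gap closes when the two extensions (or an extension and
#' the opposite flank) overlap by at least `min_merge_overlap` at >= 99%
#' identity. The annotated N-run length acts as the gap-size prior: total
#' extension is budgeted to the N length plus twice the insert standard
#' deviation, which is why closing a badly under-estimated gap requires
#' re-annotating it with a longer N run (see the 45S completion schedule).
#'
#' @param draft sequence containing at least one N run.
#' @param reads a [read_pairs] object.
#' @param max_iter maximum closing iterations.
#' @param min_anchor minimum exact overlap for a read to vote on an edge.
#' @param min_merge_overlap minimum overlap to merge the two gap edges.
#' @param circular is the draft circular?
#' @return An object of class `gap_close_state`: `seq`, `n_gaps_initial`,
#'   `n_gaps`, `iterations`, `stalled`.
#' @export
close_gaps <- function(draft, reads, max_iter = 20, min_anchor = 20,
                       min_merge_overlap = 20, circular = FALSE) {
  gaps0 <- n_runs(draft)
  if (!nrow(gaps0)) stop("nothing to close: draft contains no N run")
  insert_mean <- reads$insert_mean
  insert_sd <- reads$insert_sd
  rl <- max(nchar(reads$seq1), nchar(reads$seq2))
  max_ins <- insert_mean + 3 * insert_sd
  tol <- 3 * insert_sd
  iter <- 0L
  stalled <- FALSE
  repeat {
    iter <- iter + 1L
    gaps <- n_runs(draft)
    if (!nrow(gaps) || iter > max_iter) break
    pl <- map_reads(reads, draft, max_mm_rate = 0.05, circular = circular)
    progressed <- FALSE
    for (gi in rev(seq_len(nrow(gaps)))) {
      g <- gaps[gi, ]
      gs <- g$start; ge <- g$end
      glen <- ge - gs + 1L
      # total per-gap extension budget: the N run is the gap-size prior
      budget <- glen + 2L * insert_sd + min_merge_overlap
      flankL <- substr(draft, max(1L, gs - 300L), gs - 1L)
      flankR <- substr(draft, ge + 1L, min(nchar(draft), ge + 300L))
      candL <- recruit_side(pl, reads, gs - 1L, max_ins, insert_mean,
                            insert_sd, "left")
      candR <- recruit_side(pl, reads, ge, max_ins, insert_mean,
                            insert_sd, "right")
      extL <- extend_edge(flankL, candL, gs - 1L, budget, min_anchor, rl, tol)
      extR <- ""
      budgetR <- budget - nchar(extL)
      if (budgetR > 0 && nrow(candR)) {
        # right edge: extend in reverse-complement space
        candR_rc <- data.frame(
          seq = vapply(candR$seq, cpp_revcomp, character(1), USE.NAMES = FALSE),
          est = nchar(draft) - (candR$est + nchar(candR$seq)),
          stringsAsFactors = FALSE)
        extR_rc <- extend_edge(cpp_revcomp(flankR), candR_rc,
                               nchar(draft) - ge, budgetR, min_anchor, rl, tol)
        extR <- cpp_revcomp(extR_rc)
      }
      # merge test: (flankL + extL) against (extR + flankR), >= 99% identity
      left_full <- paste0(flankL, extL)
      right_full <- paste0(extR, flankR)
      ov <- cpp_max_overlap_mm(left_full, right_full,
                               as.integer(min_merge_overlap), 0.01,
                               as.integer(min(nchar(left_full),
                                              nchar(right_full))))
      if (ov >= min_merge_overlap) {
        repl <- paste0(extL, substr(right_full, ov + 1L, nchar(right_full)))
        draft <- paste0(substr(draft, 1, gs - 1L), repl,
                        substr(draft, ge + nchar(flankR) + 1L, nchar(draft)))
        progressed <- TRUE
      }
      # otherwise leave the gap untouched: the N annotation (and hence the
      # budget) is only ever changed by the caller's N-length schedule
    }
    if (!progressed) { stalled <- nrow(n_runs(draft)) > 0; break }
  }
  structure(list(seq = draft, n_gaps_initial = nrow(gaps0),
                 n_gaps = nrow(n_runs(draft)), iterations = iter,
                 stalled = stalled), class = "gap_close_state")
}
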