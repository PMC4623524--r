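#' Join plastid contigs and circularize
#'
#' Orders and orients contigs by maximal exact terminal overlaps: a greedy
#' walk starts from the longest contig and repeatedly appends the contig
#' (either strand) with the longest terminal overlap of at least
#' `min_overlap`; each contig may be used twice so a collapsed inverted
#' repeat can serve in both orientations. Once every contig has been
#' placed, closure requires a last-to-first terminal overlap. Junctions
#' without an admissible overlap are bridged by an N run of `placeholder`
#' bases and reported; a tie between distinct contigs with different
#' continuations is an error listing the ambiguous joins.
#'
#' When a related plastome `reference` is supplied, contigs are instead
#' ordered and oriented by their best placements on it (a collapsed
#' inverted repeat placing twice) before overlap joining; this resolves
#' layouts that terminal overlaps alone cannot (notably the two
#' equivalent single-copy-region isomers).
#'
#' @param cp_contigs list of [contig]s (cp-labelled) or character vector.
#' @param min_overlap minimal exact terminal overlap (default 15).
#' @param placeholder N-run length for unjoinable junctions.
#' @param min_len contigs shorter than this are dropped before joining
#'   (short periodic repeat cores are re-resolved during finishing).
#' @param reference optional related plastome used to order and orient the
#'   contigs before joining.
#' @return A circular draft [contig]; attribute `joins` logs the layout.
#' @export
join_and_circularize <- function(cp_contigs, min_overlap = 15,
                                 placeholder = 100, min_len = 100,
                                 reference = NULL) {
  stopifnot(length(cp_contigs) >= 1)
  seqs <- vapply(cp_contigs, function(x)
    if (inherits(x, "contig")) x$seq else as.character(x), character(1))
  circ <- vapply(cp_contigs, function(x)
    if (inherits(x, "contig")) isTRUE(x$circular) else FALSE, logical(1))
  cnt <- vapply(cp_contigs, function(x)
    if (inherits(x, "contig")) x$mean_count else NA_real_, numeric(1))
  ord <- order(-nchar(seqs), seqs)
  seqs <- seqs[ord]; circ <- circ[ord]; cnt <- cnt[ord]
  if (circ[1])  # a circular contig containing everything is the draft
    return(contig(seqs[1], id = "draft", circular = TRUE,
                  provenance = "already circular"))
  keep <- nchar(seqs) >= min_len
  if (!any(keep)) stop("no contig passes the length filter")
  seqs <- seqs[keep]; cnt <- cnt[keep]
  # drop contigs contained in a longer one (either strand)
  contained <- logical(length(seqs))
  if (length(seqs) > 1) {
    for (i in seq_along(seqs)[-1]) {
      for (j in seq_len(i - 1L)) {
        if (contained[j]) next
        if (grepl(seqs[i], seqs[j], fixed = TRUE) ||
            grepl(cpp_revcomp(seqs[i]), seqs[j], fixed = TRUE)) {
          contained[i] <- TRUE; break
        }
      }
    }
  }
  seqs <- seqs[!contained]; cnt <- cnt[!contained]

  if (!is.null(reference))
    return(join_with_reference(seqs, as.character(reference)[1], min_overlap,
                               placeholder))

  uses <- integer(length(seqs))
  uses[1] <- 1L
  cur <- seqs[1]
  joins <- list()
  circular <- FALSE
  try_closure <- function(cur) {
    head <- substr(cur, 1, min(nchar(cur) %/% 2, 2000L))
    cpp_max_overlap(cur, head, as.integer(min_overlap), 0L)
  }
  for (step in seq_len(2L * length(seqs) + 2L)) {
    if (all(uses >= 1L)) {
      ov <- try_closure(cur)
      if (ov >= min_overlap) {
        cur <- substr(cur, 1, nchar(cur) - ov)
        circular <- TRUE
        break
      }
    }
    avail <- which(uses < 2L)
    if (!length(avail)) break
    best_ov <- 0L; ties <- list()
    for (i in avail) {
      for (rc in c(FALSE, TRUE)) {
        cand <- if (rc) cpp_revcomp(seqs[i]) else seqs[i]
        ov <- cpp_max_overlap(cur, cand, as.integer(min_overlap),
                              as.integer(nchar(cand) - 1L))
        if (ov > best_ov) {
          best_ov <- ov
          ties <- list(list(i = i, rc = rc, ext = substring(cand, ov + 1L)))
        } else if (ov == best_ov && ov >= min_overlap) {
          ties <- c(ties, list(list(i = i, rc = rc,
                                    ext = substring(cand, ov + 1L))))
        }
      }
    }
    if (best_ov >= min_overlap) {
      exts <- vapply(ties, `[[`, character(1), "ext")
      pick <- 1L
      if (length(unique(exts)) > 1L) {
        idxs <- vapply(ties, `[[`, numeric(1), "i")
        if (length(unique(idxs)) == 1L) {
          # one contig, two orientations (inverted-repeat flank): take the
          # lexicographically smaller continuation; the single-copy-region
          # isomer is normalised by detect_quadripartite afterwards
          pick <- order(exts)[1]
        } else {
          # high-copy dominance breaks ties between distinct contigs (the
          # plastid path outweighs NMPT homologs several-fold)
          tc <- cnt[idxs]
          if (all(is.finite(tc)) && max(tc) > 5 * sort(tc, decreasing = TRUE)[2]) {
            pick <- which.max(tc)
          } else {
            stop(sprintf(
              "ambiguous joins: contigs {%s} overlap the walk end by %d bp with different continuations",
              paste(sort(unique(idxs)), collapse = ","), best_ov))
          }
        }
      }
      t <- ties[[pick]]
      cand <- if (t$rc) cpp_revcomp(seqs[t$i]) else seqs[t$i]
      joins[[length(joins) + 1L]] <-
        data.frame(contig = t$i, rc = t$rc, overlap = best_ov, gap = FALSE)
      cur <- paste0(cur, substring(cand, best_ov + 1L))
      uses[t$i] <- uses[t$i] + 1L
      next
    }
    unused <- which(uses == 0L)
    if (!length(unused)) break
    # bridge with Ns: prefer the unused contig with the best sub-threshold
    # overlap, then the longest
    score <- vapply(unused, function(i)
      max(cpp_max_overlap(cur, seqs[i], 5L, 400L),
          cpp_max_overlap(cur, cpp_revcomp(seqs[i]), 5L, 400L)), integer(1))
    nx <- unused[order(-score, -nchar(seqs[unused]))][1]
    use_rc <- cpp_max_overlap(cur, cpp_revcomp(seqs[nx]), 5L, 400L) >
      cpp_max_overlap(cur, seqs[nx], 5L, 400L)
    joins[[length(joins) + 1L]] <-
      data.frame(contig = nx, rc = use_rc, overlap = 0L, gap = TRUE)
    cur <- paste0(cur, strrep("N", placeholder),
                  if (use_rc) cpp_revcomp(seqs[nx]) else seqs[nx])
    uses[nx] <- uses[nx] + 1L
  }
  if (!circular) {
    ov <- try_closure(cur)
    if (ov >= min_overlap) {
      cur <- substr(cur, 1, nchar(cur) - ov)
    } else {
      joins[[length(joins) + 1L]] <-
        data.frame(contig = NA_integer_, rc = FALSE, overlap = 0L, gap = TRUE)
      cur <- paste0(cur, strrep("N", placeholder))
    }
    circular <- TRUE
  }
  cur <- rotate_off_terminal_n(cur)
  out <- contig(cur, id = "draft", circular = TRUE,
                provenance = sprintf("joined %d contigs", length(seqs)))
  attr(out, "joins") <- if (length(joins)) do.call(rbind, joins) else NULL
  out
}

# order/orient contigs along a related reference plastome, then join
# adjacent contigs by maximal exact terminal overlaps
join_with_reference <- function(seqs, reference, min_overlap, placeholder) {
  n <- nchar(reference)
  entries <- list()
  for (i in seq_along(seqs)) {
    pl <- map_reads(seqs[i], reference, max_mm_rate = 0.1, circular = TRUE,
                    min_aln = min(nchar(seqs[i]) %/% 2 + 1L, 200L))
    if (!nrow(pl)) {
      warning(sprintf("contig %d (%d bp) does not place on the reference: dropped",
                      i, nchar(seqs[i])))
      next
    }
    pl <- pl[seq_len(min(nrow(pl), 2L)), , drop = FALSE]  # IR places twice
    for (r in seq_len(nrow(pl)))
      entries[[length(entries) + 1L]] <- data.frame(
        contig = i, pos = pl$rstart[r], strand = pl$strand[r],
        alen = pl$qend[r] - pl$qstart[r])
  }
  if (!length(entries)) stop("no contig places on the reference")
  e <- do.call(rbind, entries)
  e <- e[order(e$pos, e$contig), , drop = FALSE]
  joins <- list()
  cur <- NULL
  for (r in seq_len(nrow(e))) {
    s <- if (e$strand[r] == "+") seqs[e$contig[r]]
         else cpp_revcomp(seqs[e$contig[r]])
    if (is.null(cur)) { cur <- s; next }
    ov <- cpp_max_overlap(cur, s, as.integer(min_overlap),
                          as.integer(nchar(s) - 1L))
    if (ov >= min_overlap) {
      if (ov >= nchar(s)) next  # contained in practice
      joins[[length(joins) + 1L]] <- data.frame(contig = e$contig[r],
                                                rc = e$strand[r] == "-",
                                                overlap = ov, gap = FALSE)
      cur <- paste0(cur, substring(s, ov + 1L))
    } else {
      joins[[length(joins) + 1L]] <- data.frame(contig = e$contig[r],
                                                rc = e$strand[r] == "-",
                                                overlap = 0L, gap = TRUE)
      cur <- paste0(cur, strrep("N", placeholder), s)
    }
  }
  head <- substr(cur, 1, min(nchar(cur) %/% 2, 2000L))
  ov <- cpp_max_overlap(cur, head, as.integer(min_overlap), 0L)
  if (ov >= min_overlap) {
    cur <- substr(cur, 1, nchar(cur) - ov)
  } else {
    cur <- paste0(cur, strrep("N", placeholder))
    joins[[length(joins) + 1L]] <- data.frame(contig = NA_integer_,
                                              rc = FALSE, overlap = 0L,
                                              gap = TRUE)
  }
  cur <- rotate_off_terminal_n(cur)
  out <- contig(cur, id = "draft", circular = TRUE,
                provenance = sprintf("joined %d contigs (reference-ordered)",
                                     length(seqs)))
  attr(out, "joins") <- do.call(rbind, joins)
  out
}

# rotate a circular sequence so neither terminus is N
rotate_off_terminal_n <- function(s) {
  if (!grepl("^N|N$", s)) return(s)
  v <- seq_chars(s)
  n <- length(v)
  ok <- v != "N"
  if (!any(ok)) stop("draft is all N")
  prev_ok <- c(ok[n], ok[-n])
  p <- which(ok & prev_ok)[1]
  if (is.na(p)) p <- which(ok)[1]
  paste0(substring(s, p), substr(s, 1, p - 1L))
}

# Longest inverted repeat of a circular sequence (exact): k-mer seeding,
# then maximal character-wise extension. Returns 1-based starts or NULL.
find_longest_inverted_repeat <- function(s, min_ir = 1000, k = 31) {
  n <- nchar(s)
  if (n < 2 * min_ir) return(NULL)
  v <- seq_chars(s)
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "x")
  starts <- seq_len(n - k + 1L)
  kms <- substring(s, starts, starts + k - 1L)
  ok <- !grepl("N", kms, fixed = TRUE)
  r <- cpp_revcomp(s)
  rkms <- substring(r, starts, starts + k - 1L)
  m <- match(kms, rkms)
  hit <- which(ok & !is.na(m))
  if (!length(hit)) return(NULL)
  i0 <- hit - 1L                       # 0-based forward start
  b0 <- (n - (m[hit] - 1L) - k)        # 0-based start of the mirrored copy
  keep <- b0 != i0
  i0 <- i0[keep]; b0 <- b0[keep]
  if (!length(i0)) return(NULL)
  e <- (i0 + b0) %% n                  # invariant along one IR pair
  # one representative seed per diagonal class
  rep_idx <- !duplicated(e)
  cat_best <- NULL
  at <- function(p) v[(p %% n) + 1L]
  for (t in which(rep_idx)) {
    a <- i0[t]; b <- b0[t]
    La <- a; Lb <- b + k - 1L          # extend left of a / right of b
    len <- k
    while (len < n %/% 2) {
      if (at(La - 1L) == "N") break
      if (at(La - 1L) != comp[[at(Lb + 1L)]]) break
      La <- La - 1L; Lb <- Lb + 1L; len <- len + 1L
    }
    Ra <- a + k - 1L; Rb <- b
    while (len < n %/% 2) {
      if (at(Ra + 1L) == "N") break
      if (at(Ra + 1L) != comp[[at(Rb - 1L)]]) break
      Ra <- Ra + 1L; Rb <- Rb - 1L; len <- len + 1L
    }
    if (len >= min_ir &&
        (is.null(cat_best) || len > cat_best$len)) {
      a_start0 <- La %% n
      b_start0 <- Rb %% n
      # copies must not overlap
      if (((b_start0 - a_start0) %% n) >= len &&
          ((a_start0 - b_start0) %% n) >= len)
        cat_best <- list(a_start = a_start0 + 1L, b_start = b_start0 + 1L,
                         len = len)
    }
  }
  cat_best
}

#' Detect the quadripartite plastome structure
#'
#' Finds the longest inverted-repeat pair (>= `min_ir`) by k-mer
#' self-comparison with exact boundary extension, then canonicalizes the
#' draft: rotated to the LSC start, with the SSC on its lexicographically
#' smaller strand (the two SSC isomers are molecularly equivalent and
#' indistinguishable from reads whenever the IR exceeds the insert size),
#' on the whole-molecule strand giving the lexicographically smaller
#' sequence. The IR copy following the LSC is labelled IRb.
#'
#' @param draft a circular [contig] or sequence.
#' @param min_ir minimal inverted-repeat length (default 1000).
#' @param k seeding k-mer size.
#' @return List: `seq` (canonicalized sequence), `regions` (data.frame
#'   name/start/end/strand, 1-based inclusive), or `regions = NULL` with a
#'   warning when no IR qualifies (then `seq` is returned unrotated).
#' @export
detect_quadripartite <- function(draft, min_ir = 1000, k = 31) {
  s <- if (inherits(draft, "contig")) draft$seq else as.character(draft)
  n <- nchar(s)
  ir <- find_longest_inverted_repeat(s, min_ir, k)
  if (is.null(ir)) {
    warning("no inverted repeat >= min_ir found: quadripartite regions unset")
    return(list(seq = s, regions = NULL))
  }
  circ_substr <- function(from0, len) {
    from <- (from0 %% n) + 1L
    if (from + len - 1L <= n) substr(s, from, from + len - 1L)
    else paste0(substring(s, from), substr(s, 1, len - (n - from + 1L)))
  }
  a0 <- ir$a_start - 1L; b0 <- ir$b_start - 1L; L <- ir$len
  arcAB <- (b0 - (a0 + L)) %% n        # gap after copy A, before copy B
  arcBA <- (a0 - (b0 + L)) %% n
  if (arcBA >= arcAB) {
    lsc <- circ_substr(b0 + L, arcBA)
    irX <- circ_substr(a0, L)          # IR copy following the LSC
    ssc <- circ_substr(a0 + L, arcAB)
  } else {
    lsc <- circ_substr(a0 + L, arcAB)
    irX <- circ_substr(b0, L)
    ssc <- circ_substr(b0 + L, arcBA)
  }
  ssc_c <- min(ssc, cpp_revcomp(ssc))
  cand1 <- paste0(lsc, irX, ssc_c, cpp_revcomp(irX))
  cand2 <- paste0(cpp_revcomp(lsc), irX, ssc_c, cpp_revcomp(irX))
  out <- min(cand1, cand2)
  L_l <- nchar(lsc); L_s <- nchar(ssc)
  regions <- data.frame(
    name = c("LSC", "IRb", "SSC", "IRa"),
    start = c(1L, L_l + 1L, L_l + L + 1L, L_l + L + L_s + 1L),
    end = c(L_l, L_l + L, L_l + L + L_s, L_l + 2L * L + L_s),
    strand = c("+", "+", "+", "-"), stringsAsFactors = FALSE)
  list(seq = out, regions = regions)
}

# --- issue detection --------------------------------------------------------

new_issue <- function(kind, start, end, evidence = list(), payload = list()) {
  structure(list(kind = kind, start = start, end = end,
                 evidence = evidence, payload = payload),
            class = "assembly_issue")
}

#' @export
print.assembly_issue <- function(x, ...) {
  cat(sprintf("assembly_issue %s at [%d, %d]\n", x$kind, x$start, x$end))
  invisible(x)
}

# smallest lag in [2, max_lag] with a periodic run (consecutive positions
# matching at that lag) whose total span (run + lag) covers at least two
# complete unit copies and at least 15 bp; the repeat unit must contain
# >= 2 distinct bases (monopolymers have their own detector). Returns lag
# and the 1-based run interval, or NULL.
best_period <- function(s, max_lag = 60) {
  v <- seq_chars(s)
  n <- length(v)
  best <- NULL
  for (lag in 2:max(2, min(max_lag, n %/% 2))) {
    m <- n - lag
    min_run <- max(lag, 15L - lag, 4L)   # span = run + lag >= max(2*lag, 15)
    if (m < min_run) break
    eq <- v[seq_len(m)] == v[seq_len(m) + lag]
    r <- rle(eq)
    hits <- which(r$values & r$lengths >= min_run)
    if (!length(hits)) next
    ends <- cumsum(r$lengths)
    for (i in hits) {
      run_start <- ends[i] - r$lengths[i] + 1L
      unit <- substr(s, run_start, run_start + lag - 1L)
      if (length(unique(seq_chars(unit))) < 2) next
      span <- r$lengths[i] + lag
      # the real tandem array is the widest periodic structure in the
      # window; short spurious micro-periodicities must not shadow it
      if (is.null(best) || span > best$span)
        best <- list(lag = lag, run_start = run_start,
                     run_end = ends[i] + lag, span = span)
    }
  }
  best
}

# maximal interval around [from, to] (1-based) where s is periodic with lag u
periodic_extent <- function(s, from, to, u) {
  v <- seq_chars(s)
  n <- length(v)
  a <- from; b <- to
  while (a - 1L >= 1L && a - 1L + u <= n && v[a - 1L] == v[a - 1L + u]) a <- a - 1L
  while (b + 1L <= n && b + 1L - u >= 1L && v[b + 1L] == v[b + 1L - u]) b <- b + 1L
  c(a, b)
}

#' Detect assembly issues on a circular draft
#'
#' Maps the reads and screens for the four mis-assembly classes:
#' \describe{
#'   \item{FALSE_GAP}{every N run.}
#'   \item{MONOPOLYMER}{homopolymer runs >= `mono_min_len` with a pile of
#'     soft-clipped read ends at their borders.}
#'   \item{TR_COLLAPSE}{depth windows with |z| >= `z_thresh` overlapping a
#'     tandem periodicity (autocorrelation peak at the unit length).}
#'   \item{FALSE_SNP}{clusters of linked variant columns where the majority
#'     haplotype disagrees with the draft (or a minor haplotype exceeds
#'     `min_var_frac`), outside the masks of the structural issues.}
#' }
#' Issues are returned sorted by position.
#'
#' @param draft a circular [contig] or character sequence.
#' @param reads a [read_pairs] object.
#' @param z_thresh depth z-score threshold (default 3).
#' @param min_var_frac minor-haplotype detection floor (default 0.05).
#' @param mono_min_len minimal homopolymer length screened (default 8).
#' @param placements optional precomputed [map_reads] result.
#' @return List of `assembly_issue` objects; attributes `placements`,
#'   `pileup` and `anomaly` carry the evidence tracks.
#' @export
detect_issues <- function(draft, reads, z_thresh = 3, min_var_frac = 0.05,
                          mono_min_len = 8, placements = NULL) {
  s <- if (inherits(draft, "contig")) draft$seq else as.character(draft)
  L <- nchar(s)
  read_len <- max(nchar(reads$seq1), nchar(reads$seq2))
  if (is.null(placements))
    placements <- map_reads(reads, s, max_mm_rate = 0.08, circular = TRUE)
  an <- suppressWarnings(anomaly_profile(placements, reads))
  issues <- list()
  masks <- list()  # intervals to exclude from SNP screening
  add_mask <- function(a, b) masks[[length(masks) + 1L]] <<- c(a, b)

  # FALSE_GAP: every N run
  gaps <- n_runs(s)
  for (i in seq_len(nrow(gaps))) {
    g <- gaps[i, ]
    issues[[length(issues) + 1L]] <- new_issue(
      "FALSE_GAP", g$start, g$end,
      evidence = list(discordant = sum(an$discordant[
        max(1, g$start - 2 * reads$insert_mean):min(L, g$end + 2 * reads$insert_mean)])))
    add_mask(g$start - reads$insert_mean - read_len,
             g$end + reads$insert_mean + read_len)
  }

  # MONOPOLYMER: long homopolymer runs with clipped ends piling at borders
  runs <- base_runs(s)
  runs <- runs[runs$length >= mono_min_len & runs$base %in% BASES, , drop = FALSE]
  for (i in seq_len(nrow(runs))) {
    r <- runs[i, ]
    win <- max(1, r$start - 5L):min(L, r$start + r$length - 1L + 5L)
    clip_n <- sum(an$clipped[win])
    flank <- c(max(1, r$start - 150L):max(1, r$start - 20L),
               min(L, r$start + r$length + 19L):min(L, r$start + r$length + 149L))
    base_depth <- stats::median(an$depth[flank])
    if (clip_n >= max(5, 0.2 * base_depth)) {
      issues[[length(issues) + 1L]] <- new_issue(
        "MONOPOLYMER", r$start, r$start + r$length - 1L,
        evidence = list(clipped = clip_n, flank_depth = base_depth),
        payload = list(base = r$base, draft_len = r$length))
      add_mask(r$start - read_len, r$start + r$length - 1L + read_len)
    }
  }

  # TR_COLLAPSE: anomalous windows with tandem periodicity. Candidates are
  # depth-z excursions (arrays longer than a read change depth) plus
  # clip pileups (short collapsed arrays concentrate soft-clipped read
  # ends at their borders while their surplus depth smears out)
  w <- an$windows
  flagged <- w[abs(w$z) >= z_thresh, , drop = FALSE]
  clip_cum <- cumsum(c(0, an$clipped))
  clip_win <- clip_cum[pmin(w$end, L) + 1L] - clip_cum[w$start]
  base_d <- an$baseline$mean
  flagged <- rbind(flagged,
                   w[clip_win >= max(6, 0.25 * base_d), , drop = FALSE])
  if (nrow(flagged)) {
    # merge overlapping flagged windows
    o <- order(flagged$start)
    fs <- flagged$start[o]; fe <- flagged$end[o]
    grp <- cumsum(c(1L, fs[-1] > cummax(fe)[-length(fe)] + 1L))
    for (g in unique(grp)) {
      a <- min(fs[grp == g]); b <- max(fe[grp == g])
      # skip anomalies explained by gaps or monopolymer issues
      skip <- FALSE
      for (m in masks) if (a <= m[2] && b >= m[1]) skip <- TRUE
      if (skip) next
      wa <- max(1, a - 50L); wb <- min(L, b + 50L)
      per <- best_period(substr(s, wa, wb))
      if (is.null(per)) next
      ext <- periodic_extent(s, wa + per$run_start - 1L,
                             wa + per$run_start - 1L + per$lag, per$lag)
      span <- ext[2] - ext[1] + 1L
      if (span < max(2L * per$lag, 15L)) next
      copies <- span %/% per$lag
      zmax <- max(abs(w$z[w$start >= a & w$start <= b]))
      issues[[length(issues) + 1L]] <- new_issue(
        "TR_COLLAPSE", ext[1], ext[2],
        evidence = list(z = zmax),
        payload = list(unit_len = per$lag, copies = max(copies, 1L)))
      add_mask(ext[1] - read_len, ext[2] + read_len)
    }
  }

  # FALSE_SNP: linked variant clusters outside masks
  pu <- pileup(placements, reads, s, min_var_frac = min_var_frac)
  for (lg in pu$link_groups) {
    p <- lg$positions
    masked <- FALSE
    for (m in masks) if (min(p) <= m[2] && max(p) >= m[1]) masked <- TRUE
    if (masked) next
    vr <- pu$variants[pu$variants$pos %in% p, , drop = FALSE]
    strong <- any(vr$disagrees) ||
      (length(lg$groups) >= 2 &&
       sum(lg$groups[-1]) / max(sum(lg$groups), 1) >= min_var_frac)
    if (!strong || !length(lg$groups)) next
    issues[[length(issues) + 1L]] <- new_issue(
      "FALSE_SNP", min(p), max(p),
      evidence = list(partition = lg$groups),
      payload = list(positions = p))
  }

  ord <- order(vapply(issues, `[[`, numeric(1), "start"))
  issues <- issues[ord]
  attr(issues, "placements") <- placements
  attr(issues, "anomaly") <- an
  attr(issues, "pileup") <- pu
  issues
}

# --- fixes ------------------------------------------------------------------

#' Repair a false gap by merging duplicated flanks
#'
#' Collapses the maximal exact duplication (suffix of the left flank equal
#' to a prefix of the right flank, >= `min_dup`) and removes the N run.
#' The edit is accepted only if spanning reads re-map cleanly across the
#' new junction; otherwise the draft is returned unchanged with the issue
#' marked unresolved (such gaps are handed to [close_gaps]).
#'
#' @param draft draft sequence (character).
#' @param issue a FALSE_GAP `assembly_issue`.
#' @param reads the read set.
#' @param min_dup minimal flank duplication (default 10).
#' @return List: `seq`, `resolved`, `note`.
#' @export
fix_false_gap <- function(draft, issue, reads, min_dup = 10) {
  stopifnot(issue$kind == "FALSE_GAP")
  L <- nchar(draft)
  gs <- issue$start; ge <- issue$end
  fl <- substr(draft, max(1, gs - 300L), gs - 1L)
  fr <- substr(draft, ge + 1L, min(L, ge + 300L))
  dup <- cpp_max_overlap(fl, fr, as.integer(min_dup), 0L)
  if (dup < min_dup)
    return(list(seq = draft, resolved = FALSE, note = "no flank duplication"))
  fixed <- paste0(substr(draft, 1, gs - 1L),
                  substring(fr, dup + 1L),
                  substr(draft, min(L, ge + 300L) + 1L, L))
  # validation: spanning reads must re-map across the junction
  junction <- gs - 1L
  lo <- max(1, junction - 300L); hi <- min(nchar(fixed), junction + 300L)
  local_ref <- substr(fixed, lo, hi)
  pl <- map_reads(reads, local_ref, max_mm_rate = 0.02, circular = FALSE)
  jpos <- junction - lo      # 0-based junction position in local ref
  spanning <- sum(pl$rstart <= jpos - 20L & pl$rend >= jpos + 20L &
                  pl$nm <= 1L)
  if (spanning < 3)
    return(list(seq = draft, resolved = FALSE,
                note = sprintf("only %d spanning reads after merge", spanning)))
  list(seq = fixed, resolved = TRUE,
       note = sprintf("collapsed %d bp duplication, %d spanning reads",
                      dup, spanning))
}

#' Repair a false SNP cluster from the haplotype partition
#'
#' All linked positions are jointly replaced by the allele vector of the
#' largest haplotype group (the plastid haplotype, present at 8-100-fold
#' excess over its nuclear/mitochondrial homologs). A tie between the two
#' largest groups leaves the draft unchanged; a largest group under 50% of
#' the covering reads triggers a contamination warning but is still
#' applied.
#'
#' @param draft draft sequence.
#' @param issue a FALSE_SNP `assembly_issue` (payload carries positions,
#'   evidence the partition).
#' @param pu optional `pileup_result` for the warning denominator.
#' @return List: `seq`, `resolved`, `note`.
#' @export
fix_false_snp <- function(draft, issue, pu = NULL) {
  stopifnot(issue$kind == "FALSE_SNP")
  groups <- issue$evidence$partition
  pos <- issue$payload$positions
  if (!length(groups))
    return(list(seq = draft, resolved = FALSE, note = "no haplotype groups"))
  if (length(groups) >= 2 && groups[1] == groups[2])
    return(list(seq = draft, resolved = FALSE, note = "tied major haplotypes"))
  alleles <- seq_chars(names(groups)[1])
  if (length(alleles) != length(pos))
    return(list(seq = draft, resolved = FALSE, note = "partition/position mismatch"))
  if (groups[1] < 0.5 * sum(groups))
    warning("largest haplotype group below 50% of depth: contamination suspected")
  changed <- FALSE
  for (j in seq_along(pos)) {
    if (substr(draft, pos[j], pos[j]) != alleles[j]) changed <- TRUE
    substr(draft, pos[j], pos[j]) <- alleles[j]
  }
  list(seq = draft, resolved = TRUE,
       note = sprintf("consensus %s assigned at %s (major group %d/%d)%s",
                      names(groups)[1], paste(pos, collapse = ","),
                      groups[1], sum(groups),
                      if (changed) "" else " (already consensus)"))
}

# local reassembly splice for tandem-repeat windows
local_reassembly_splice <- function(draft, win_a, win_b, reads, placements,
                                    read_len, anchor_len = 40) {
  L <- nchar(draft)
  # anchors just outside the window; widen until unique on both strands
  for (alen in c(anchor_len, 60L, 80L)) {
    aL <- substr(draft, max(1, win_a - alen), win_a - 1L)
    aR <- substr(draft, win_b + 1L, min(L, win_b + alen))
    d2 <- paste0(draft, "#", cpp_revcomp(draft))
    okL <- length(gregexpr(aL, d2, fixed = TRUE)[[1]]) == 1L
    okR <- length(gregexpr(aR, d2, fixed = TRUE)[[1]]) == 1L
    if (okL && okR) break
  }
  if (!okL || !okR) return(NULL)
  # recruit: placements overlapping the window plus unplaced reads sharing
  # a 21-mer with the neighbourhood
  am <- all_mates(reads)
  near <- placements$qidx[placements$rstart <= win_b + read_len &
                          placements$rend >= win_a - read_len]
  unplaced <- setdiff(seq_along(am$seq), unique(placements$qidx))
  hood <- substr(draft, max(1, win_a - 2L * read_len),
                 min(L, win_b + 2L * read_len))
  hood_k <- cpp_count_kmers(hood, 21L, 1L)$kmer
  if (length(unplaced)) {
    share <- vapply(unplaced, function(i) {
      km <- cpp_count_kmers(am$seq[i], 21L, 1L)$kmer
      any(km %in% hood_k)
    }, logical(1))
    near <- c(near, unplaced[share])
  }
  rs <- am$seq[sort(unique(near))]
  if (length(rs) < 5) return(NULL)
  k_local <- min(read_len - 1L, 99L)
  if (k_local %% 2L == 0L) k_local <- k_local - 1L
  g <- build_graph(rs, k = k_local, min_count = 2)
  ctgs <- tryCatch(assemble(g), error = function(e) list())
  for (ct in ctgs) {
    for (sq in c(ct$seq, cpp_revcomp(ct$seq))) {
      pa <- regexpr(aL, sq, fixed = TRUE)
      pb <- regexpr(aR, sq, fixed = TRUE)
      if (pa > 0 && pb > 0 && pb > pa) {
        inner <- substr(sq, pa + nchar(aL), pb - 1L)
        return(paste0(substr(draft, 1, win_a - 1L), inner,
                      substr(draft, win_b + 1L, L)))
      }
    }
  }
  NULL
}

#' Repair a tandem-repeat copy-number error
#'
#' Strategy A (preferred when the reads can span the corrected array):
#' local re-assembly of the recruited reads at a k-mer size exceeding the
#' array span, spliced between unique flanking anchors. Strategy B
#' (fallback): rewrite the array with `round(copies * depth_ratio)` unit
#' copies, the read-depth ratio between the array and its flanks being the
#' copy-number evidence. Acceptance requires the post-fix depth ratio at
#' the array to fall within [0.8, 1.25] of the flank baseline.
#'
#' @param draft draft sequence.
#' @param issue a TR_COLLAPSE `assembly_issue` (payload: unit_len, copies).
#' @param reads read set.
#' @param placements precomputed placements on `draft` (optional).
#' @return List: `seq`, `resolved`, `note`.
#' @export
fix_tr_copy <- function(draft, issue, reads, placements = NULL) {
  stopifnot(issue$kind == "TR_COLLAPSE")
  u <- issue$payload$unit_len
  read_len <- max(nchar(reads$seq1), nchar(reads$seq2))
  L <- nchar(draft)
  if (is.null(placements))
    placements <- map_reads(reads, draft, max_mm_rate = 0.08, circular = TRUE)
  win_a <- issue$start; win_b <- issue$end
  am_seq <- all_mates(reads)$seq
  # read mass smears across array borders, so measure the ratio on the
  # array interior whenever the array is long enough to have one
  depth <- placement_depth(placements, L, TRUE, weight = "fractional")
  arr_i <- if (win_b - win_a + 1L > 2L * read_len + u)
    (win_a + read_len):(win_b - read_len) else win_a:win_b
  flank_idx <- c(max(1, win_a - 200L):max(1, win_a - 30L),
                 min(L, win_b + 30L):min(L, win_b + 200L))
  flank_d <- stats::median(depth[flank_idx])
  ratio <- if (flank_d > 0) mean(depth[arr_i]) / flank_d else NA_real_

  accept <- function(seq2) {
    delta <- nchar(seq2) - L
    new_b <- win_b + delta
    lo <- max(1, win_a - 500L)
    hi <- min(nchar(seq2), new_b + 500L)
    local_ref <- substr(seq2, lo, hi)
    pl2 <- map_reads(reads, local_ref, max_mm_rate = 0.02, circular = FALSE)
    d2 <- placement_depth(pl2, nchar(local_ref), FALSE, weight = "fractional",
                          qlen = nchar(am_seq[pl2$qidx]))
    core <- (win_a - lo + 1L):(new_b - lo + 1L)
    # flanks measured clear of the local-reference edge ramp
    flk <- c(seq(read_len + 10L, max(win_a - lo - 10L, read_len + 11L)),
             seq(min(new_b - lo + 12L, length(d2) - read_len - 10L),
                 length(d2) - read_len - 10L))
    flk <- flk[flk >= 1 & flk <= length(d2)]
    core <- core[core >= 1 & core <= length(d2)]
    fl <- stats::median(d2[flk])
    if (!length(core) || !is.finite(fl) || fl <= 0) return(FALSE)
    r <- mean(d2[core]) / fl
    r >= 0.8 && r <= 1.25
  }

  # strategy A: local reassembly
  fixed <- local_reassembly_splice(draft, win_a, win_b, reads, placements,
                                   read_len)
  if (!is.null(fixed) && accept(fixed))
    return(list(seq = fixed, resolved = TRUE,
                note = sprintf("local reassembly spliced %d bp over the array",
                               nchar(fixed) - L + (win_b - win_a + 1L))))
  # strategy B: copy-number rewrite from the read-depth ratio between the
  # array and its flanks, measured in k-mer space where it is free of the
  # placement edge effects that bias mapped depth over a collapsed tandem:
  # an array of n copies carries (n*u - k + 1)/u occurrences of each of its
  # u phase k-mers, and a unique flank k-mer carries exactly one.
  span0 <- win_b - win_a + 1L
  copies0 <- max(span0 %/% u, 1L)
  unit <- substr(draft, win_a, win_a + u - 1L)
  k2 <- 21L
  tab <- cpp_count_kmers(am_seq, k2, 1L)
  phase_ref <- strrep(unit, max(2L, ceiling(k2 / u) + 1L))
  arr_k <- cpp_count_kmers(phase_ref, k2, 1L)$kmer
  fl_med <- function(sq) {
    kk <- cpp_count_kmers(sq, k2, 1L)$kmer
    stats::median(tab$count[match(kk, tab$kmer)], na.rm = TRUE)
  }
  med_arr <- stats::median(tab$count[match(arr_k, tab$kmer)], na.rm = TRUE)
  med_fl <- mean(c(fl_med(substr(draft, max(1, win_a - 1020L), win_a - 21L)),
                   fl_med(substr(draft, win_b + 21L,
                                 min(L, win_b + 1020L)))), na.rm = TRUE)
  if (is.finite(med_arr) && is.finite(med_fl) && med_fl > 0) {
    occ <- med_arr / med_fl               # occurrences per phase k-mer
    n_star <- max(round(occ + (k2 - 1) / u), 1L)
    if (n_star == copies0)
      return(list(seq = draft, resolved = TRUE,
                  note = sprintf("k-mer depth ratio %.1f consistent with %d copies",
                                 occ, copies0)))
    partial <- if (span0 %% u) substr(draft, win_a + copies0 * u, win_b) else ""
    fixed2 <- paste0(substr(draft, 1, win_a - 1L), strrep(unit, n_star),
                     partial, substring(draft, win_b + 1L))
    if (accept(fixed2))
      return(list(seq = fixed2, resolved = TRUE,
                  note = sprintf("k-mer depth ratio %.1f (mapped %.2f): %d -> %d unit copies",
                                 occ, ratio, copies0, n_star)))
  }
  list(seq = draft, resolved = FALSE, note = "no strategy passed acceptance")
}

#' Repair a monopolymer length error by candidate-depth selection
#'
#' For each candidate tract length the corresponding draft variant is
#' built and reads are re-mapped requiring perfect full-length matches
#' within the tract +/- one read length; the candidate with the highest
#' mean window depth wins, ties keeping the draft's current length.
#'
#' @param draft draft sequence.
#' @param issue a MONOPOLYMER `assembly_issue` (payload: base, draft_len).
#' @param reads read set.
#' @param candidate_lengths lengths to evaluate (default 5..25 plus the
#'   draft's current length).
#' @return List: `seq`, `resolved`, `note`, `depths` (per candidate).
#' @export
fix_monopolymer <- function(draft, issue, reads, candidate_lengths = NULL) {
  stopifnot(issue$kind == "MONOPOLYMER")
  cur_len <- issue$payload$draft_len
  base <- issue$payload$base
  if (is.null(candidate_lengths)) candidate_lengths <- 5:25
  candidate_lengths <- sort(unique(c(candidate_lengths, cur_len)))
  read_len <- max(nchar(reads$seq1), nchar(reads$seq2))
  L <- nchar(draft)
  gs <- issue$start; ge <- issue$end
  flank <- read_len
  lo <- max(1, gs - flank - 50L); hi <- min(L, ge + flank + 50L)
  left <- substr(draft, lo, gs - 1L)
  right <- substr(draft, ge + 1L, hi)
  depths <- vapply(candidate_lengths, function(cl) {
    ref <- paste0(left, strrep(base, cl), right)
    pl <- map_reads(reads, ref, max_mm_rate = 0, require_full = TRUE)
    if (!nrow(pl)) return(0)
    d <- placement_depth(pl, nchar(ref), FALSE, weight = "fractional")
    win <- max(1, gs - lo + 1L - flank):min(nchar(ref), gs - lo + cl + flank)
    mean(d[win])
  }, numeric(1))
  names(depths) <- candidate_lengths
  if (all(depths == 0))
    return(list(seq = draft, resolved = FALSE,
                note = "no candidate has perfect-match support",
                depths = depths))
  best <- max(depths)
  winners <- candidate_lengths[depths == best]
  pick <- if (cur_len %in% winners) cur_len else winners[1]
  if (pick == cur_len)
    return(list(seq = draft, resolved = TRUE,
                note = sprintf("(%s)%d retained (depth %.2f)", base, cur_len,
                               best), depths = depths))
  fixed <- paste0(substr(draft, 1, gs - 1L), strrep(base, pick),
                  substr(draft, ge + 1L, L))
  list(seq = fixed, resolved = TRUE,
       note = sprintf("(%s)%d -> (%s)%d (depth %.2f)", base, cur_len, base,
                      pick, best), depths = depths)
}

# --- the finishing loop -----------------------------------------------------

#' Finish a draft plastome
#'
#' Rounds of [detect_issues] followed by fixes until the draft is
#' evidence-clean or `max_rounds` is reached. Within a round only the
#' highest-priority issue class present is repaired (structural first:
#' FALSE_GAP, then MONOPOLYMER, FALSE_SNP, TR_COLLAPSE), right-to-left so
#' positions stay valid; re-detection then refreshes all coordinates.
#' False gaps without a flank duplication are handed to [close_gaps] under
#' an N-length schedule. The finished sequence is canonicalized via
#' [detect_quadripartite].
#'
#' @param draft a circular [contig] (or sequence) to finish.
#' @param reads the supporting [read_pairs].
#' @param max_rounds maximal detect/fix rounds (default 5).
#' @param gap_schedule N-length schedule for stubborn gaps.
#' @return An object of class `plastome_assembly`: `seq`, `regions`,
#'   `finishing_log` (data.frame), `residual_issues`.
#' @export
finish <- function(draft, reads, max_rounds = 5,
                   gap_schedule = c(100, 300, 1000)) {
  s <- if (inherits(draft, "contig")) draft$seq else as.character(draft)
  log <- list()
  note_log <- function(round, kind, start, end, action)
    log[[length(log) + 1L]] <<- data.frame(round = round, kind = kind,
                                           start = start, end = end,
                                           action = action,
                                           stringsAsFactors = FALSE)
  residual <- list()
  seen <- character()
  verified_sigs <- character()
  priority <- c(FALSE_GAP = 1, MONOPOLYMER = 2, FALSE_SNP = 3, TR_COLLAPSE = 4)
  for (round in seq_len(max_rounds)) {
    dig <- paste(nchar(s), substr(s, 1, 50), sum(utf8ToInt(substr(s, 1, 10000))))
    if (dig %in% seen) { residual <- c(residual, list("oscillation detected")); break }
    issues <- detect_issues(s, reads)
    sig <- function(i) sprintf("%s:%d:%d", i$kind, i$start, i$end)
    issues <- issues[!vapply(issues, function(i) sig(i) %in% verified_sigs,
                             logical(1))]
    if (!length(issues)) { residual <- list(); break }
    kinds <- vapply(issues, `[[`, character(1), "kind")
    k <- names(priority)[min(priority[kinds])]
    todo <- issues[kinds == k]
    ord <- order(-vapply(todo, `[[`, numeric(1), "start"))
    todo <- todo[ord]
    pl <- attr(issues, "placements")
    residual <- list()
    changed <- FALSE
    for (iss in todo) {
      res <- switch(iss$kind,
        FALSE_GAP = {
          r <- fix_false_gap(s, iss, reads)
          if (!r$resolved) {
            # re-annotate the gap along the schedule and gap-close
            for (nl in gap_schedule) {
              s_try <- paste0(substr(s, 1, iss$start - 1L), strrep("N", nl),
                              substr(s, iss$end + 1L, nchar(s)))
              gc <- tryCatch(close_gaps(s_try, reads, circular = TRUE),
                             error = function(e) NULL)
              if (!is.null(gc) && gc$n_gaps == 0) {
                r <- list(seq = gc$seq, resolved = TRUE,
                          note = sprintf("gap closed at N=%d", nl))
                break
              }
            }
          }
          r
        },
        MONOPOLYMER = fix_monopolymer(s, iss, reads),
        FALSE_SNP = fix_false_snp(s, iss),
        TR_COLLAPSE = fix_tr_copy(s, iss, reads, placements = pl))
      if (res$resolved) {
        if (!identical(res$seq, s)) {
          s <- res$seq
          changed <- TRUE
          note_log(round, iss$kind, iss$start, iss$end, res$note)
        } else {
          note_log(round, iss$kind, iss$start, iss$end,
                   paste0("verified: ", res$note))
          verified_sigs <- c(verified_sigs, sig(iss))
        }
      } else {
        residual <- c(residual, list(iss))
        note_log(round, iss$kind, iss$start, iss$end,
                 paste0("unresolved: ", res$note))
      }
    }
    if (changed) {
      seen <- c(seen, dig)         # record the state we just left
      verified_sigs <- character() # coordinates shifted
    } else if (length(todo) == length(issues)) {
      break  # converged: remaining issues verified or unresolved
    }
  }
  quad <- suppressWarnings(detect_quadripartite(s))
  finishing_log <- if (length(log)) do.call(rbind, log) else
    data.frame(round = integer(), kind = character(), start = integer(),
               end = integer(), action = character(), stringsAsFactors = FALSE)
  structure(list(seq = quad$seq, regions = quad$regions,
                 finishing_log = finishing_log,
                 residual_issues = residual),
            class = "plastome_assembly")
}

#' @export
print.plastome_assembly <- function(x, ...) {
  cat(sprintf("plastome_assembly: %d bp, %d fix(es), %d residual issue(s)\n",
              nchar(x$seq), sum(!grepl("^verified", x$finishing_log$action)),
              length(x$residual_issues)))
  if (!is.null(x$regions)) {
    for (i in seq_len(nrow(x$regions)))
      cat(sprintf("  %-3s %6d..%6d\n", x$regions$name[i], x$regions$start[i],
                  x$regions$end[i]))
  }
  invisible(x)
}
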