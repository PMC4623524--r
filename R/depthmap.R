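#' Map reads to a small reference
#'
#' Seed-and-extend mapping: exact 15-mer seeds, gapless extension with an
#' X-drop rule (match +1, mismatch -3) and soft clipping. Every best-scoring
#' placement is reported (up to `max_hits`); `unique` marks reads whose best
#' score is achieved at a single location. Circular references wrap.
#'
#' @param reads a [read_pairs] object or character vector; for pairs, both
#'   mates are mapped and `pair`/`mate` columns identify them.
#' @param reference a single reference sequence (character).
#' @param max_mm_rate maximal mismatch fraction of the aligned segment.
#' @param circular treat the reference as circular.
#' @param require_full only accept full-length, mismatch-free placements.
#' @param min_aln minimal aligned length.
#' @return A data.frame of placements: `qidx` (index into the flattened
#'   mate vector), `pair`, `mate`, `rstart`/`rend` (0-based half-open;
#'   `rend` may exceed the reference length when a placement wraps),
#'   `qstart`/`qend` (on the oriented read), `strand`, `nm`, `n_best`,
#'   `unique`. Attributes `reflen` and `circular` describe the target.
#' @export
map_reads <- function(reads, reference, max_mm_rate = 0.08, circular = FALSE,
                      require_full = FALSE, min_aln = 25) {
  stopifnot(is.character(reference), length(reference) == 1,
            nchar(reference) > 0, max_mm_rate >= 0, max_mm_rate <= 0.2)
  if (inherits(reads, "read_pairs")) {
    am <- all_mates(reads)
    seqs <- am$seq; pair <- am$pair; mate <- am$mate
  } else {
    seqs <- as.character(reads)
    pair <- seq_along(seqs); mate <- rep(1L, length(seqs))
  }
  df <- cpp_map_reads(seqs, reference, circular, max_mm_rate,
                      require_full = require_full, min_aln = as.integer(min_aln))
  df$pair <- pair[df$qidx]
  df$mate <- mate[df$qidx]
  df$unique <- df$n_best == 1L
  attr(df, "reflen") <- nchar(reference)
  attr(df, "circular") <- circular
  attr(df, "n_query") <- length(seqs)
  df
}

# oriented read sequences for a placement table
oriented_seqs <- function(pl, seqs) {
  out <- seqs[pl$qidx]
  neg <- pl$strand == "-"
  if (any(neg)) out[neg] <- vapply(out[neg], cpp_revcomp, character(1),
                                   USE.NAMES = FALSE)
  out
}

# per-base depth; weight = "unique" (unique placements, weight 1) or
# "fractional" (all best placements, weight 1/n_best). When `qlen` (full
# read lengths per placement row) is given, each read's whole extent is
# projected along its placement diagonal, soft-clipped tails included —
# the depth a local-alignment viewer shows, where a collapsed repeat
# doubles instead of shedding its clipped mass.
placement_depth <- function(pl, reflen = attr(pl, "reflen"),
                            circular = attr(pl, "circular"),
                            weight = c("fractional", "unique"),
                            qlen = NULL) {
  weight <- match.arg(weight)
  if (weight == "unique") {
    keep <- pl$unique
    pl <- pl[keep, , drop = FALSE]
    if (!is.null(qlen)) qlen <- qlen[keep]
    w <- rep(1, nrow(pl))
  } else {
    w <- 1 / pl$n_best
  }
  s <- pl$rstart; e <- pl$rend
  if (!is.null(qlen)) {
    s <- s - pl$qstart
    e <- e + (qlen - pl$qend)
    if (isTRUE(circular)) {
      neg <- s < 0
      s[neg] <- s[neg] + reflen
      e[neg] <- e[neg] + reflen
    }
  }
  depth_from_intervals(s, e, w, reflen, isTRUE(circular))
}

#' Pileup with linked-haplotype partition
#'
#' Accumulates per-position allele counts from the aligned (unclipped)
#' segments of unique placements, reports variant columns, and partitions
#' the reads covering each cluster of linked variant columns (columns
#' within `link_window` of each other) by their joint allele vector.
#'
#' @param placements output of [map_reads] against `reference`.
#' @param reads the read set that was mapped.
#' @param reference the mapped reference sequence.
#' @param link_window linkage window in bp (default: longest read).
#' @param min_var_frac minor-allele fraction needed to call a variant
#'   column when the majority agrees with the reference.
#' @param min_depth minimal column depth considered.
#' @return An object of class `pileup_result`: `counts` (5 x L matrix,
#'   rows A,C,G,T,N), `depth`, `variants` (data.frame), and `link_groups`
#'   (per linked cluster: 1-based `positions` and a named `groups` vector of
#'   read counts per allele vector, largest first).
#' @export
pileup <- function(placements, reads, reference, link_window = NULL,
                   min_var_frac = 0.05, min_depth = 5) {
  if (attr(placements, "reflen") != nchar(reference))
    stop("placements were computed against a different reference")
  circular <- isTRUE(attr(placements, "circular"))
  seqs <- if (inherits(reads, "read_pairs")) all_mates(reads)$seq
          else as.character(reads)
  if (is.null(link_window)) link_window <- max(nchar(seqs))
  pl <- placements[placements$unique, , drop = FALSE]
  ori <- oriented_seqs(pl, seqs)
  L <- nchar(reference)
  counts <- cpp_pileup(pl$rstart, pl$qstart, pl$qend, ori, L, circular)
  rownames(counts) <- c("A", "C", "G", "T", "N")
  depth <- colSums(counts)
  refv <- seq_chars(reference)

  variants <- data.frame(pos = integer(), ref = character(),
                         major = character(), major_n = integer(),
                         depth = integer(), minor_frac = numeric(),
                         disagrees = logical(), stringsAsFactors = FALSE)
  cand <- which(depth >= min_depth)
  if (length(cand)) {
    sub <- counts[1:4, cand, drop = FALSE]
    major_i <- max.col(t(sub), ties.method = "first")
    major_n <- sub[cbind(major_i, seq_along(cand))]
    minor_n <- colSums(sub) - major_n
    major <- c("A", "C", "G", "T")[major_i]
    keep <- (major != refv[cand] & major_n >= min_depth) |
      (minor_n / pmax(depth[cand], 1) >= min_var_frac & minor_n >= 2)
    if (any(keep)) {
      variants <- data.frame(
        pos = cand[keep], ref = refv[cand[keep]], major = major[keep],
        major_n = major_n[keep], depth = as.integer(depth[cand[keep]]),
        minor_frac = minor_n[keep] / pmax(depth[cand[keep]], 1),
        disagrees = major[keep] != refv[cand[keep]],
        stringsAsFactors = FALSE)
    }
  }

  link_groups <- list()
  if (nrow(variants)) {
    pos <- variants$pos
    cl <- cumsum(c(1L, diff(pos) > link_window))
    for (g in unique(cl)) {
      p <- pos[cl == g]
      link_groups[[length(link_groups) + 1L]] <-
        list(positions = p,
             groups = haplotype_partition(pl, ori, p, L, circular))
    }
  }
  structure(list(counts = counts, depth = depth, variants = variants,
                 link_groups = link_groups, reflen = L, circular = circular),
            class = "pileup_result")
}

# group reads covering all of `positions` (1-based) by joint allele vector
haplotype_partition <- function(pl, ori, positions, reflen, circular) {
  p0 <- positions - 1L
  alleles <- matrix(NA_character_, nrow(pl), length(positions))
  for (j in seq_along(p0)) {
    off <- p0[j] - pl$rstart
    if (circular) off <- ((off %% reflen) + reflen) %% reflen
    covered <- off >= 0 & off < (pl$rend - pl$rstart)
    qpos <- pl$qstart + off + 1L
    alleles[covered, j] <- substring(ori[covered], qpos[covered], qpos[covered])
  }
  full <- stats::complete.cases(alleles)
  if (!any(full)) return(stats::setNames(integer(), character()))
  key <- apply(alleles[full, , drop = FALSE], 1, paste, collapse = "")
  tab <- sort(table(key), decreasing = TRUE)
  stats::setNames(as.integer(tab), names(tab))
}

#' @export
print.pileup_result <- function(x, ...) {
  cat(sprintf("pileup over %d bp: mean depth %.1f, %d variant column(s), %d linked cluster(s)\n",
              x$reflen, mean(x$depth), nrow(x$variants), length(x$link_groups)))
  invisible(x)
}

#' Discordance / depth-anomaly profile
#'
#' A placed pair is discordant when its mates map to the same strand, in
#' the wrong order, or at an insert deviating more than 4 standard
#' deviations from the library model. Per-position tracks accumulate
#' discordant-pair coverage and soft-clip boundaries; window depth z-scores
#' are computed against a 10%-trimmed baseline.
#'
#' @param placements output of [map_reads] on a [read_pairs] object.
#' @param insert_mean,insert_sd insert model (defaults from the reads).
#' @param reads the mapped [read_pairs] (for the insert model default).
#' @param window,step depth-window geometry in bp.
#' @return An object of class `anomaly_track`: `discordant`, `clipped`,
#'   `depth` (per position), `windows` (start/end/mean/z), `baseline`,
#'   `n_pairs_used`, `unreliable`.
#' @export
anomaly_profile <- function(placements, reads = NULL, insert_mean = NULL,
                            insert_sd = NULL, window = 40, step = 20) {
  if (is.null(insert_mean)) insert_mean <- if (!is.null(reads)) reads$insert_mean else 500
  if (is.null(insert_sd)) insert_sd <- if (!is.null(reads)) reads$insert_sd else 50
  L <- attr(placements, "reflen")
  circular <- isTRUE(attr(placements, "circular"))
  pl <- placements[placements$unique, , drop = FALSE]

  discordant <- numeric(L)
  clipped <- numeric(L)
  m1 <- pl[pl$mate == 1L, , drop = FALSE]
  m2 <- pl[pl$mate == 2L, , drop = FALSE]
  common <- intersect(m1$pair, m2$pair)
  n_pairs <- length(common)
  if (n_pairs) {
    i1 <- match(common, m1$pair); i2 <- match(common, m2$pair)
    a <- m1[i1, ]; b <- m2[i2, ]
    lo <- pmin(a$rstart, b$rstart)
    hi <- pmax(a$rend, b$rend)
    ins <- hi - lo
    wrapped <- rep(FALSE, length(ins))
    if (circular) {
      # a pair may straddle the origin: its fragment then runs from the
      # right-hand mate through the origin to the left-hand mate
      ins2 <- L - pmax(a$rstart, b$rstart) + pmin(a$rend, b$rend)
      wrapped <- ins2 < ins
      ins <- pmin(ins, ins2)
    }
    left_plus <- ifelse(a$rstart <= b$rstart, a$strand == "+",
                        b$strand == "+")
    bad_orient <- a$strand == b$strand |
      ifelse(wrapped, left_plus, !left_plus)
    bad_insert <- abs(ins - insert_mean) > 4 * insert_sd
    disc <- bad_orient | bad_insert
    if (any(disc)) {
      dd <- rbind(a[disc, c("rstart", "rend")], b[disc, c("rstart", "rend")])
      discordant <- depth_from_intervals(dd$rstart, dd$rend,
                                         rep(1, nrow(dd)), L, circular)
    }
  }
  # clip boundaries
  if (nrow(pl) > 0) {
    seqs <- if (inherits(reads, "read_pairs")) all_mates(reads)$seq
            else as.character(reads)
    qlen <- nchar(seqs[pl$qidx])
    left_clip <- pl$qstart > 0
    right_clip <- (pl$qend < qlen)
    at <- c(pl$rstart[left_clip], pl$rend[right_clip])
    at <- ((at %% L) + L) %% L
    if (length(at)) {
      tb <- table(at)
      clipped[as.integer(names(tb)) + 1L] <- as.integer(tb)
    }
  }
  # depth uses every best placement at fractional weight with the full read
  # extent projected (collapsed repeats must register their whole read
  # mass); discordance/clip evidence above is restricted to unique
  # placements
  all_seqs <- if (inherits(reads, "read_pairs")) all_mates(reads)$seq
              else as.character(reads)
  depth <- placement_depth(placements, L, circular, weight = "fractional",
                           qlen = nchar(all_seqs[placements$qidx]))

  starts <- seq(1L, max(L - window + 1L, 1L), by = step)
  wmean <- vapply(starts, function(s) mean(depth[s:min(s + window - 1L, L)]),
                  numeric(1))
  tm <- mean(wmean, trim = 0.1)
  ts <- stats::sd(wmean[wmean >= stats::quantile(wmean, 0.1) &
                        wmean <= stats::quantile(wmean, 0.9)])
  if (!is.finite(ts) || ts == 0) ts <- max(sqrt(max(tm, 1)), 1e-8)
  # window means are autocorrelated over a read length, so the trimmed sd
  # can collapse; floor it at 15% of the baseline so z >= 3 means a
  # >= 45% depth excursion (a collapsed repeat doubles depth)
  ts <- max(ts, 0.15 * tm)
  windows <- data.frame(start = starts,
                        end = pmin(starts + window - 1L, L),
                        mean = wmean, z = (wmean - tm) / ts)
  unreliable <- n_pairs < 100
  if (unreliable) warning("fewer than 100 placed pairs: baseline unreliable")
  structure(list(discordant = discordant, clipped = clipped, depth = depth,
                 windows = windows, baseline = list(mean = tm, sd = ts),
                 n_pairs_used = n_pairs, unreliable = unreliable),
            class = "anomaly_track")
}

#' @export
print.anomaly_track <- function(x, ...) {
  cat(sprintf("anomaly_track: %d pairs, %d discordant positions, max |z| %.1f\n",
              x$n_pairs_used, sum(x$discordant > 0),
              max(abs(x$windows$z))))
  invisible(x)
}

# total anomaly mass: discordant coverage plus |z| of flagged windows
anomaly_mass <- function(track, z_thresh = 3) {
  sum(track$discordant) +
    sum(abs(track$windows$z[abs(track$windows$z) >= z_thresh]))
}
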