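# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(code)
}

# Derive a child seed; kept well below 2^31.
child_seed <- function(seed, offset) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 7919 + offset) %% 2147483587)
}

random_dna <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, n, replace = TRUE, prob = p), collapse = "")
}

revcomp <- function(s) cpp_revcomp(s)

#' @keywords internal
seq_chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

# Substitute bases at `rate` (per base); returns the mutated string.
mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  v <- seq_chars(s)
  idx <- which(stats::runif(length(v)) < rate & v %in% BASES)
  if (length(idx)) {
    for (i in idx) v[i] <- sample(setdiff(BASES, v[i]), 1L)
  }
  paste(v, collapse = "")
}

# Replace s[start..start+nchar(repl)-1] (1-based) with repl.
splice_at <- function(s, start, repl) {
  stopifnot(start >= 1, start + nchar(repl) - 1 <= nchar(s))
  paste0(substr(s, 1, start - 1), repl, substr(s, start + nchar(repl), nchar(s)))
}

# Circular sequence equality up to rotation and strand.
seq_equal_circular <- function(a, b) {
  if (nchar(a) != nchar(b)) return(FALSE)
  if (nchar(a) == 0) return(TRUE)
  aa <- paste0(a, a)
  grepl(b, aa, fixed = TRUE) || grepl(revcomp(b), aa, fixed = TRUE)
}

# Maximal single-base runs as a data frame (base, start, length), 1-based.
base_runs <- function(s) {
  v <- seq_chars(s)
  r <- rle(v)
  ends <- cumsum(r$lengths)
  data.frame(base = r$values, start = ends - r$lengths + 1L,
             length = r$lengths, stringsAsFactors = FALSE)
}

# N runs as (start, end) 1-based inclusive.
n_runs <- function(s) {
  m <- gregexpr("N+", s)[[1]]
  if (m[1] == -1) return(data.frame(start = integer(), end = integer()))
  data.frame(start = as.integer(m), end = as.integer(m) + attr(m, "match.length") - 1L)
}

# Per-base depth from placement intervals with weights; intervals 0-based
# half-open, wrapped when circular.
depth_from_intervals <- function(start0, end0, weight, reflen, circular = FALSE) {
  d <- numeric(reflen + 1L)
  add <- function(s, e, w) {
    agg_s <- rowsum(w, s + 1L)
    agg_e <- rowsum(w, pmin(e, reflen) + 1L)
    i_s <- as.integer(rownames(agg_s)); i_e <- as.integer(rownames(agg_e))
    d[i_s] <<- d[i_s] + agg_s[, 1]
    d[i_e] <<- d[i_e] - agg_e[, 1]
  }
  if (!length(start0)) return(numeric(reflen))
  if (circular) {
    wrap <- end0 > reflen
    if (any(!wrap)) add(start0[!wrap], end0[!wrap], weight[!wrap])
    if (any(wrap)) {
      add(start0[wrap], rep(reflen, sum(wrap)), weight[wrap])
      add(rep(0L, sum(wrap)), end0[wrap] - reflen, weight[wrap])
    }
  } else {
    add(pmax(start0, 0L), pmin(end0, reflen), weight)
  }
  cumsum(d)[seq_len(reflen)]
}

vlog <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(format(Sys.time(), "[%H:%M:%S] "), ...)
  invisible(NULL)
}
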