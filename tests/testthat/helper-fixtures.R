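# Shared fixtures (memoised: the mock genome and read sets are expensive)
# and independent brute-force oracles used across the suite.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_cache[[name]]))
    assign(name, force(expr), envir = .fixture_cache)
  .fixture_cache[[name]]
}

test_genome <- function() memo("genome", build_mock_genome(mock_genome_spec(seed = 3)))

test_fixture <- function(kind) {
  memo(paste0("fixture_", kind),
       make_misassembly_fixture(kind, test_genome(), seed = 5))
}

test_panel <- function() {
  g <- test_genome()
  list(cp = g$components$cp,
       mt = unname(unlist(g$components[c("mt1", "mt2")])),
       nR = c(g$unit_45s, g$unit_5s))
}

rnd_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

rc <- function(s) skim2organelle:::revcomp(s)

seq_eq_circ <- function(a, b) {
  nchar(a) == nchar(b) &&
    (grepl(a, paste0(b, b), fixed = TRUE) ||
     grepl(rc(a), paste0(b, b), fixed = TRUE))
}

# brute-force canonical k-mer counter (independent of the C++ path)
oracle_kmer_counts <- function(seqs, k) {
  tab <- list()
  for (s in seqs) {
    n <- nchar(s)
    if (n < k) next
    for (i in seq_len(n - k + 1L)) {
      km <- substr(s, i, i + k - 1L)
      if (grepl("[^ACGT]", km)) next
      canon <- min(km, rc(km))
      tab[[canon]] <- (tab[[canon]] %||% 0L) + 1L
    }
  }
  unlist(tab[order(names(tab))])
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force best Hamming placements of a read over a linear reference;
# returns data.frame(start0, strand, mm) of all equal-best placements
oracle_map <- function(read, ref) {
  L <- nchar(read); n <- nchar(ref)
  refv <- strsplit(ref, "")[[1]]
  out <- list()
  for (strand in c("+", "-")) {
    q <- if (strand == "+") read else rc(read)
    qv <- strsplit(q, "")[[1]]
    for (p in seq_len(n - L + 1L)) {
      mm <- sum(refv[p:(p + L - 1L)] != qv)
      out[[length(out) + 1L]] <- data.frame(start0 = p - 1L, strand = strand,
                                            mm = mm)
    }
  }
  d <- do.call(rbind, out)
  d[d$mm == min(d$mm), , drop = FALSE]
}

# regex-based monopolymer scan (strictly longer than `thr`)
oracle_monopolymers <- function(s, thr) {
  out <- list()
  for (b in c("A", "C", "G", "T")) {
    m <- gregexpr(sprintf("%s{%d,}", b, thr + 1L), s)[[1]]
    if (m[1] == -1) next
    out[[b]] <- data.frame(base = b, start = as.integer(m),
                           length = attr(m, "match.length"))
  }
  d <- do.call(rbind, out)
  if (is.null(d)) return(data.frame(base = character(), start = integer(),
                                    length = integer()))
  d <- d[order(d$start), , drop = FALSE]
  rownames(d) <- NULL
  d
}
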