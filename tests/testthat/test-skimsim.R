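test_that("mock genome generation is a pure function of (spec, seed)", {
  g1 <- build_mock_genome(mock_genome_spec(seed = 7))
  g2 <- build_mock_genome(mock_genome_spec(seed = 7))
  expect_identical(g1$components, g2$components)
  expect_identical(g1$truth, g2$truth)
  g3 <- build_mock_genome(mock_genome_spec(seed = 8))
  expect_false(identical(g1$components$cp, g3$components$cp))
})

test_that("NMPT tracts are exact plastome substrings at zero divergence", {
  g <- build_mock_genome(mock_genome_spec(seed = 11, nmpt_divergence = 0))
  nm <- g$truth[g$truth$feature == "nmpt", ]
  for (i in seq_len(nrow(nm))) {
    tract <- substr(g$components$nuclear, nm$start[i], nm$end[i])
    expect_true(grepl(tract, g$components$cp, fixed = TRUE))
  }
})

test_that("planted plastid monopolymers agree with an independent regex scan", {
  g <- test_genome()
  found <- oracle_monopolymers(g$components$cp, 8)
  planted <- g$truth[g$truth$feature == "monopolymer" &
                     g$truth$component == "cp", ]
  # every planted tract of length > 8 must be recovered by the regex scan
  expect_true(all(planted$start %in% found$start))
  pl_row <- found[found$start == planted$start[1], ]
  expect_equal(pl_row$length, planted$end[1] - planted$start[1] + 1L)
})

test_that("simulated coverage matches the request and reads are genome substrings", {
  g <- test_genome()
  reads <- simulate_reads(g, c(cp = 100), seed = 2)
  tot <- sum(nchar(reads$seq1)) + sum(nchar(reads$seq2))
  expect_lt(abs(tot - 100 * 30000) / (100 * 30000), 0.05)
  cp2 <- paste0(g$components$cp, g$components$cp)
  idx <- sample(length(reads), 200)
  for (i in idx) {
    r <- reads$seq1[i]
    expect_true(grepl(r, cp2, fixed = TRUE) || grepl(rc(r), cp2, fixed = TRUE))
  }
  # determinism
  reads2 <- simulate_reads(g, c(cp = 100), seed = 2)
  expect_identical(reads$seq1, reads2$seq1)
})

test_that("substitution errors appear at the binomial rate", {
  g <- test_genome()
  rate <- 0.01
  reads <- simulate_reads(g, c(cp = 20), error_rate = rate, seed = 6)
  cp2 <- paste0(g$components$cp, g$components$cp)
  tr <- attr(reads, "truth")
  nmm <- 0L; nb <- 0L
  for (i in seq_len(min(500, length(reads)))) {
    frag <- substr(cp2, tr$pos[i], tr$pos[i] + tr$insert[i] - 1L)
    L <- nchar(reads$seq1[i])
    head <- substr(frag, 1, L)
    tail_rc <- rc(substring(frag, nchar(frag) - L + 1L))
    truth1 <- if (tr$flip[i]) tail_rc else head
    truth2 <- if (tr$flip[i]) head else tail_rc
    nmm <- nmm +
      sum(strsplit(truth1, "")[[1]] != strsplit(reads$seq1[i], "")[[1]]) +
      sum(strsplit(truth2, "")[[1]] != strsplit(reads$seq2[i], "")[[1]])
    nb <- nb + L + nchar(reads$seq2[i])
  }
  expect_lt(abs(nmm / nb - rate), 3 * sqrt(rate * (1 - rate) / nb))
})

test_that("mis-assembly fixtures plant exactly the advertised defect", {
  g <- test_genome()
  fx_tr <- test_fixture("TR_COLLAPSE")
  unit <- sub(".*unit=", "", g$truth[g$truth$feature == "tr_array", "info"])
  expect_true(grepl(strrep(unit, 2), fx_tr$draft$seq, fixed = TRUE))
  expect_false(grepl(strrep(unit, 3), fx_tr$draft$seq, fixed = TRUE))
  expect_true(grepl(strrep(unit, 4), fx_tr$truth$seq, fixed = TRUE))

  fx_mo <- test_fixture("MONOPOLYMER")
  expect_equal(fx_mo$meta$mono$truth_len, 17L)
  expect_equal(fx_mo$meta$mono$draft_len, 8L)
  st <- fx_mo$meta$mono$start
  expect_identical(substr(fx_mo$draft$seq, st, st + 7L), strrep("T", 8))
  expect_false(substr(fx_mo$draft$seq, st + 8L, st + 8L) == "T")
  expect_identical(substr(fx_mo$truth$seq, st, st + 16L), strrep("T", 17))

  fx_fg <- test_fixture("FALSE_GAP")
  # removing the N run and one duplicated flank copy restores the truth
  m <- regexpr("N+", fx_fg$draft$seq)
  a <- as.integer(m); L <- attr(m, "match.length")
  rebuilt <- paste0(substr(fx_fg$draft$seq, 1, a - 1L),
                    substring(fx_fg$draft$seq, a + L + fx_fg$meta$gap$dup_len))
  expect_identical(rebuilt, fx_fg$truth$seq)

  fx_sn <- test_fixture("FALSE_SNP")
  for (j in seq_along(fx_sn$meta$snp$pos)) {
    p <- fx_sn$meta$snp$pos[j]
    expect_identical(substr(fx_sn$draft$seq, p, p), fx_sn$meta$snp$alt[j])
    expect_identical(substr(fx_sn$truth$seq, p, p), fx_sn$meta$snp$ref[j])
  }
})
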