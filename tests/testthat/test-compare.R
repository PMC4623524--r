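test_that("monopolymer census reports maximal runs strictly over the threshold", {
  s <- paste0("GC", strrep("A", 9), "GC", strrep("A", 8), "GC")
  out <- scan_monopolymers(s, 8)
  expect_equal(nrow(out), 1)
  expect_equal(out$base, "A")
  expect_equal(out$start, 3)
  expect_equal(out$length, 9)
  # runs crossing the origin of a circular sequence are merged
  circ <- paste0(strrep("T", 5), "A", rnd_dna(48), "C", strrep("T", 5))
  out2 <- scan_monopolymers(circ, 8, circular = TRUE)
  expect_equal(nrow(out2), 1)
  expect_equal(out2$length, 10)
  # N runs are never reported
  expect_equal(nrow(scan_monopolymers(strrep("N", 20), 8)), 0)
})

test_that("monopolymer census equals a regex scan on random sequence", {
  set.seed(55)
  for (trial in 1:5) {
    s <- paste(sample(c("A", "C", "G", "T"), 100000,
                      replace = TRUE, prob = c(0.4, 0.1, 0.1, 0.4)),
               collapse = "")
    got <- scan_monopolymers(s, 8)
    want <- oracle_monopolymers(s, 8)
    expect_equal(got$start, want$start)
    expect_equal(got$length, want$length)
    expect_equal(got$base, want$base)
    # intervals are disjoint and maximal
    if (nrow(got) > 1)
      expect_true(all(got$start[-1] > got$start[-nrow(got)] +
                      got$length[-nrow(got)]))
  }
})

test_that("pairwise variant enumeration recovers planted SNPs and InDels", {
  set.seed(66)
  a <- rnd_dna(5000)
  b <- a
  snp_pos <- c(400, 1700, 3900)
  for (p in snp_pos) {
    substr(b, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                      substr(a, p, p)), 1)
  }
  # two deletions (3 bp and 5 bp), applied right-to-left
  b <- paste0(substr(b, 1, 2999), substring(b, 3003))
  b <- paste0(substr(b, 1, 999), substring(b, 1005))
  v <- pairwise_variants(a, b)
  expect_equal(v$n_snps, 3)
  expect_equal(v$n_indels, 2)
  expect_setequal(v$snps$pos, snp_pos)
  # gap placement may shift within a local repeat; events stay put to ~5 bp
  expect_true(all(vapply(c(999, 2999), function(p)
    any(abs(v$indels$pos - p) <= 5), logical(1))))
  # symmetry of event counts
  w <- pairwise_variants(b, a)
  expect_equal(w$n_snps, v$n_snps)
  expect_equal(w$n_indels, v$n_indels)
  # identical sequences and circular rotations are variant-free
  v0 <- pairwise_variants(a, a)
  expect_equal(v0$n_snps + v0$n_indels, 0)
  rot <- paste0(substring(a, 2001), substr(a, 1, 2000))
  vr <- pairwise_variants(a, rot, circular = TRUE)
  expect_equal(vr$n_snps + vr$n_indels, 0)
  # diverged input is refused
  expect_error(pairwise_variants(a, rnd_dna(5000)), "too diverged")
})

test_that("variants export as minimal VCF", {
  a <- paste0(rnd_dna(100), "A", rnd_dna(100))
  b <- a; substr(b, 101, 101) <- "G"
  # short sequences lack 31-mer anchors on both flanks? they have them
  v <- pairwise_variants(a, b)
  p <- tempfile(fileext = ".vcf")
  write_variants_vcf(v, p)
  lines <- readLines(p)
  expect_identical(lines[1], "##fileformat=VCFv4.2")
  expect_equal(sum(!startsWith(lines, "#")), 1)
  expect_match(lines[3], "^seqA\t101\t")
})
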