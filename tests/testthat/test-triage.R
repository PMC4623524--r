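test_that("plastid read fraction estimation recovers known mixtures", {
  g <- test_genome()
  bait <- g$components$cp
  pure <- simulate_reads(g, c(cp = 20), seed = 3)
  est <- estimate_cp_fraction(pure, bait, seed = 1)
  expect_gt(est$fraction, 0.98)
  # known 5% plastid bases over a plastid-free background
  clean <- list(components = list(bg = rnd_dna(100000),
                                  cp = g$components$cp),
                circular = c(bg = FALSE, cp = TRUE))
  cov_cp <- 0.05 * 100000 / (0.95 * 30000)
  mix <- simulate_reads(clean, c(bg = 1, cp = cov_cp), seed = 4)
  est2 <- estimate_cp_fraction(mix, bait, seed = 1)
  expect_lt(abs(est2$fraction - 0.05), 0.01)
  # with an NMPT-bearing nuclear background the estimate is biased upward
  # (plastid-homologous insertions map too), as in real skims
  mix2 <- simulate_reads(g, c(nuclear = 1,
                              cp = 0.05 * 200000 / (0.95 * 30000)), seed = 4)
  est2b <- estimate_cp_fraction(mix2, bait, seed = 1)
  expect_gte(est2b$fraction, 0.05 - 0.01)
  expect_lt(est2b$fraction, 0.12)
  # reads with no plastid homology at all give a fraction of zero
  rand <- list(components = list(bg = rnd_dna(50000)),
               circular = c(bg = FALSE))
  none <- simulate_reads(rand, c(bg = 2), seed = 5)
  est3 <- estimate_cp_fraction(none, bait, seed = 1)
  expect_lt(est3$fraction, 0.005)
  expect_error(estimate_cp_fraction(pure, ""), "empty bait")
})

test_that("subsampling is arithmetic-exact, deterministic and bounded", {
  g <- test_genome()
  reads <- simulate_reads(g, c(cp = 150), seed = 6)
  plan <- coverage_plan(genome_size = 1e6, cp_size_estimate = 30000,
                        cp_fraction = 1, target_cp_coverage = 100, seed = 2)
  sub <- subsample(reads, plan)
  target <- 100 * 30000
  got <- attr(sub, "selected_bases")
  expect_lte(got, target + 2 * max(nchar(reads$seq1)))
  expect_gte(got, target - 2 * max(nchar(reads$seq1)))
  sub2 <- subsample(reads, plan)
  expect_identical(sub$id, sub2$id)
  # never returns more bases than requested plus one pair
  expect_lte(got - target, nchar(sub$seq1[1]) + nchar(sub$seq2[1]))
  # over-request returns everything with a warning
  plan_all <- coverage_plan(1e6, 30000, 1, target_cp_coverage = 400, seed = 2)
  expect_warning(all_back <- subsample(reads, plan_all), "exceed")
  expect_equal(length(all_back), length(reads))
  # the 20x whole-genome threshold warns about NMPT interference
  plan20 <- coverage_plan(genome_size = 100000, cp_size_estimate = 30000,
                          cp_fraction = 1, target_cp_coverage = 100, seed = 2)
  expect_warning(subsample(reads, plan20), "NMPT")
})

test_that("contig classification follows shared k-mer fractions", {
  g <- test_genome()
  panel <- test_panel()
  slice <- substr(g$components$cp, 2001, 7000)
  noise <- rnd_dna(3000)
  out <- classify_contigs(list(slice, noise), panel)
  expect_identical(out$label[out$length == 5000], "cp")
  expect_equal(out$fraction[out$length == 5000], 1.0)
  expect_identical(out$label[out$length == 3000], "other")
  # reverse-complement invariance
  out_rc <- classify_contigs(list(rc(slice)), panel)
  expect_identical(out_rc$label, "cp")
  expect_equal(out_rc$fraction, 1.0)
  # contigs from the mock assembly receive their true source label
  reads <- simulate_reads(g, c(cp = 100, nuclear = 2, mt1 = 10, mt2 = 10,
                               rdna_45s = 2, rdna_5s = 2), seed = 11)
  ctgs <- assemble(build_graph(reads, k = 31, min_count = 3))
  cls <- classify_contigs(ctgs, panel)
  big <- cls[cls$length >= 1000, ]
  expect_true(all(big$label %in% c("cp", "mt", "nR")))
  expect_true(any(big$label == "cp") && any(big$label == "mt") &&
              any(big$label == "nR"))
  seqs <- vapply(ctgs, `[[`, character(1), "seq")
  names(seqs) <- vapply(ctgs, `[[`, character(1), "id")
  for (i in seq_len(nrow(big))) {
    s <- seqs[[big$id[i]]]
    truth_label <- NULL
    for (lbl in names(panel)) {
      tt <- paste0(panel[[lbl]], collapse = "#")
      probe <- substr(s, nchar(s) %/% 2 - 15, nchar(s) %/% 2 + 15)
      if (grepl(probe, tt, fixed = TRUE) || grepl(rc(probe), tt, fixed = TRUE))
        truth_label <- c(truth_label, lbl)
    }
    if (length(truth_label) == 1)
      expect_identical(big$label[i], truth_label)
  }
})
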