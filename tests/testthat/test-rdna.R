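test_that("two-unit tandem construction completes the 45S unit exactly", {
  g <- test_genome()
  reads <- memo("reads_45s", simulate_reads(g, c(rdna_45s = 100), seed = 9))
  unit <- g$unit_45s
  model <- substr(g$cistron_45s, 1, 200)
  init <- substr(unit, 1, 3600)   # cistron + 60% of the IGS
  u <- complete_45s(init, reads, cistron_model = model)
  expect_true(u$complete)
  expect_equal(nchar(u$seq), nchar(unit))
  expect_identical(u$seq, unit)
  # the GC-rich sub-repeat gap cannot close under the first (N)100 stage:
  # closure required advancing the N-length schedule
  expect_gt(u$n_used, 100)
  # a complete unit is a fixed point (returned unchanged after rotation)
  u2 <- complete_45s(u$seq, reads, cistron_model = model)
  expect_identical(u2$seq, u$seq)
})

test_that("45S sub-regions tile the unit without gaps or overlaps", {
  g <- test_genome()
  reads <- memo("reads_45s", simulate_reads(g, c(rdna_45s = 100), seed = 9))
  subm <- list(`18S` = substr(g$unit_45s, g$regions_45s$start[1],
                              g$regions_45s$end[1]),
               `5.8S` = substr(g$unit_45s, g$regions_45s$start[3],
                               g$regions_45s$end[3]),
               `26S` = substr(g$unit_45s, g$regions_45s$start[5],
                              g$regions_45s$end[5]))
  u <- complete_45s(substr(g$unit_45s, 1, 3600), reads,
                    cistron_model = substr(g$cistron_45s, 1, 200),
                    sub_models = subm)
  sr <- u$sub_regions
  expect_identical(sr$region, c("18S", "ITS1", "5.8S", "ITS2", "26S", "IGS"))
  expect_equal(sr$start[1], 1L)
  expect_equal(sr$end[6], nchar(u$seq))
  expect_true(all(sr$start[-1] == sr$end[-6] + 1L))
  expect_equal(u$cistron_length + u$igs_length, nchar(u$seq))
})

test_that("5S unit extraction finds the minimal tandem period", {
  g <- test_genome()
  unit <- g$unit_5s
  two_and_half <- paste0(unit, unit, substr(unit, 1, 160))
  u <- extract_5s(two_and_half, g$gene_5s)
  expect_equal(nchar(u$seq), 320)
  expect_true(seq_eq_circ(u$seq, unit))
  # a circular collapsed tandem is exactly one unit
  ct <- contig(paste0(substring(unit, 51), substr(unit, 1, 50)),
               circular = TRUE)
  u2 <- extract_5s(ct, g$gene_5s)
  expect_true(seq_eq_circ(u2$seq, unit))
  # no model match errors out
  expect_error(extract_5s(rnd_dna(1000), g$gene_5s), "no contig matches")
})

test_that("copy-number estimation recovers the single-copy baseline and normalizes", {
  g <- test_genome()
  # a genome carrying exactly one copy of the unit
  single <- list(components = list(host = paste0(rnd_dna(20000), g$unit_5s,
                                                 rnd_dna(20000))),
                 circular = c(host = FALSE))
  gsz <- nchar(single$components$host)
  reads1 <- simulate_reads(single, c(host = 3), seed = 4)
  est1 <- estimate_copy_number(g$unit_5s, reads1, gsz, seed = 1)
  expect_lt(abs(est1$copy_number_estimate - 1), 0.25)
  # rotation invariance
  rot <- paste0(substring(g$unit_5s, 101), substr(g$unit_5s, 1, 100))
  est_rot <- estimate_copy_number(rot, reads1, gsz, seed = 1)
  expect_lt(abs(est_rot$copy_number_estimate - est1$copy_number_estimate),
            0.15)
  # doubling the read amount before the 1x-equivalent subsample is neutral
  reads2 <- simulate_reads(single, c(host = 6), seed = 9)
  est2 <- estimate_copy_number(g$unit_5s, reads2, gsz, seed = 1)
  expect_lt(abs(est2$copy_number_estimate - est1$copy_number_estimate), 0.3)
  # unit shorter than the read length errors
  expect_error(estimate_copy_number(substr(g$unit_5s, 1, 100), reads1, gsz),
               "shorter than the read length")
})
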