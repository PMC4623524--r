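test_that("k-mer graph counts match a brute-force canonical enumeration", {
  # hand case: two copies of ACGTACGT at k=5 collapse to two canonical
  # 5-mers (ACGTA/TACGT and CGTAC/GTACG are reverse-complement pairs)
  g <- build_graph(c("ACGTACGT", "ACGTACGT"), k = 5, min_count = 1)
  expected <- oracle_kmer_counts(c("ACGTACGT", "ACGTACGT"), 5)
  expect_identical(stats::setNames(g$count, g$kmer), expected)
  # threshold above the counts empties the graph
  g2 <- build_graph(c("ACGTACGT", "ACGTACGT"), k = 5,
                    min_count = max(expected) + 1L)
  expect_length(g2$kmer, 0)
  expect_error(build_graph("ACGT", k = 6, allow_even_k = TRUE), "k bases long")
  expect_error(build_graph("ACGTACGTACGT", k = 6), "allow_even_k")
})

test_that("error-free reads reproduce exactly the truth k-mer set", {
  set.seed(31)
  truth <- rnd_dna(10000)
  mg <- list(components = list(x = truth), circular = c(x = FALSE))
  reads <- simulate_reads(mg, c(x = 50), seed = 1)
  g <- build_graph(reads, k = 31, min_count = 1)
  truth_set <- names(oracle_kmer_counts(truth, 31))
  # reads can miss the extreme ends of a linear sequence but must never
  # contain a k-mer absent from the truth
  expect_true(all(g$kmer %in% c(truth_set,
                                names(oracle_kmer_counts(rc(truth), 31)))))
  expect_gt(mean(truth_set %in% g$kmer), 0.995)
})

test_that("a circular sequence assembles into one circular contig equal to the truth", {
  set.seed(9)
  truth <- rnd_dna(10000)
  mg <- list(components = list(x = truth), circular = c(x = TRUE))
  reads <- simulate_reads(mg, c(x = 50), seed = 4)
  ctgs <- assemble(build_graph(reads, k = 31, min_count = 1))
  expect_length(ctgs, 1)
  expect_true(ctgs[[1]]$circular)
  expect_true(seq_eq_circ(ctgs[[1]]$seq, truth))
  # determinism
  ctgs2 <- assemble(build_graph(reads, k = 31, min_count = 1))
  expect_identical(ctgs[[1]]$seq, ctgs2[[1]]$seq)
})

test_that("gap closing recovers a central deletion and stalls on unreachable gaps", {
  set.seed(42)
  truth <- rnd_dna(5000)
  mg <- list(components = list(x = truth), circular = c(x = FALSE))
  reads <- simulate_reads(mg, c(x = 100), seed = 1)
  draft <- paste0(substr(truth, 1, 2450), strrep("N", 100),
                  substr(truth, 2551, 5000))
  st <- close_gaps(draft, reads)
  expect_identical(st$seq, truth)
  expect_false(st$stalled)
  expect_equal(st$n_gaps, 0)

  # gap larger than the insert with no spanning support stays open
  big <- paste0(substr(truth, 1, 1000), strrep("N", 2000),
                substr(truth, 4500, 5000))
  ends <- simulate_reads(list(components = list(a = substr(truth, 1, 1000),
                                                b = substr(truth, 4500, 5000)),
                              circular = c(a = FALSE, b = FALSE)),
                         c(a = 60, b = 60), insert_mean = 400, insert_sd = 40,
                         seed = 2)
  st2 <- close_gaps(big, ends)
  expect_true(st2$stalled)
  expect_equal(st2$n_gaps, 1)

  # two gaps, one closable: exactly one N run remains
  tg <- paste0(substr(truth, 1, 1500), strrep("N", 60),
               substr(truth, 1561, 3000), strrep("N", 2000),
               substr(truth, 4900, 5000))
  st3 <- close_gaps(tg, reads)
  expect_equal(st3$n_gaps, 1)
  expect_error(close_gaps(truth, reads), "nothing to close")
})
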