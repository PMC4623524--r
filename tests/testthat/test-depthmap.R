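test_that("exact substrings place at their origin with zero edit distance", {
  set.seed(5)
  ref <- rnd_dna(2000)
  r <- substr(ref, 501, 600)
  pl <- map_reads(r, ref)
  expect_equal(nrow(pl), 1)
  expect_equal(pl$rstart, 500)
  expect_equal(pl$rend, 600)
  expect_equal(pl$nm, 0)
  expect_true(pl$unique)
  # one mismatch under a 100%-identity requirement goes unplaced
  r2 <- r; substr(r2, 50, 50) <- if (substr(r2, 50, 50) == "A") "C" else "A"
  expect_equal(nrow(map_reads(r2, ref, max_mm_rate = 0, require_full = TRUE)),
               0)
})

test_that("placements agree with a brute-force all-positions alignment", {
  set.seed(6)
  for (trial in 1:10) {
    ref <- rnd_dna(800)
    p <- sample(700, 1)
    r <- substr(ref, p, p + 59)
    if (runif(1) < 0.5) r <- rc(r)
    nmut <- sample(0:2, 1)
    for (j in seq_len(nmut)) {
      i <- sample(5:56, 1)   # interior: terminal mismatches would be clipped
      substr(r, i, i) <- sample(setdiff(c("A", "C", "G", "T"),
                                        substr(r, i, i)), 1)
    }
    got <- map_reads(r, ref, max_mm_rate = 0.1)
    want <- oracle_map(r, ref)
    expect_equal(sort(got$rstart), sort(want$start0))
    expect_equal(unique(got$nm), unique(want$mm))
  }
})

test_that("placements mirror under global reverse-complement of the reference", {
  set.seed(8)
  ref <- rnd_dna(3000)
  mg <- list(components = list(x = ref), circular = c(x = FALSE))
  reads <- simulate_reads(mg, c(x = 10), seed = 3)
  a <- map_reads(reads, ref)
  b <- map_reads(reads, rc(ref))
  a <- a[order(a$qidx, a$rstart), ]
  b <- b[order(b$qidx, -b$rstart), ]
  expect_equal(a$qidx, b$qidx)
  expect_equal(a$rstart, nchar(ref) - b$rend)
  expect_equal(a$nm, b$nm)
  expect_true(all(a$strand != b$strand))
})

test_that("pileup conserves aligned bases and partitions linked haplotypes", {
  set.seed(12)
  ref <- rnd_dna(200)
  mk <- function(a1, a2, n) {
    s <- ref; substr(s, 101, 101) <- a1; substr(s, 105, 105) <- a2
    rep(substr(s, 41, 160), n)
  }
  # the classic three-source pattern: 186 plastid, 24 mitochondrial,
  # 2 nuclear reads over two linked positions
  rds <- c(mk("T", "A", 186), mk("G", "T", 24), mk("T", "T", 2))
  refG <- ref
  substr(refG, 101, 101) <- "G"; substr(refG, 105, 105) <- "T"
  pl <- map_reads(rds, refG, max_mm_rate = 0.05)
  pu <- pileup(pl, rds, refG)
  expect_equal(sum(pu$counts), sum(pl$qend - pl$qstart))
  expect_length(pu$link_groups, 1)
  groups <- pu$link_groups[[1]]$groups
  expect_equal(unname(groups), c(186, 24, 2))
  expect_equal(names(groups), c("TA", "GT", "TT"))
  expect_equal(sum(groups), 212)
  expect_equal(pu$link_groups[[1]]$positions, c(101, 105))
  # the false-SNP fix assigns the majority vector
  iss <- structure(list(kind = "FALSE_SNP", start = 101, end = 105,
                        evidence = list(partition = groups),
                        payload = list(positions = c(101, 105))),
                   class = "assembly_issue")
  fixed <- fix_false_snp(refG, iss)
  expect_true(fixed$resolved)
  expect_identical(substr(fixed$seq, 101, 101), "T")
  expect_identical(substr(fixed$seq, 105, 105), "A")
  # reads identical to the reference: one allele per column, no variants
  same <- rep(substr(ref, 41, 160), 50)
  pl2 <- map_reads(same, ref)
  pu2 <- pileup(pl2, same, ref)
  expect_equal(nrow(pu2$variants), 0)
  expect_length(pu2$link_groups, 0)
  covered <- pu2$depth > 0
  expect_true(all(apply(pu2$counts[, covered, drop = FALSE] > 0, 2, sum) == 1))
})

test_that("anomaly profile is silent on concordant data and flags planted gaps", {
  g <- test_genome()
  reads <- simulate_reads(g, c(cp = 60), seed = 8)
  pl <- map_reads(reads, g$components$cp, circular = TRUE)
  an <- anomaly_profile(pl, reads)
  expect_equal(sum(an$discordant), 0)
  expect_false(an$unreliable)

  fx <- test_fixture("FALSE_GAP")
  plf <- map_reads(fx$reads, fx$draft$seq, circular = TRUE)
  anf <- anomaly_profile(plf, fx$reads)
  expect_gt(sum(anf$discordant), 0)
  peak <- which.max(anf$discordant)
  gap <- regexpr("N+", fx$draft$seq)
  expect_lt(abs(peak - as.integer(gap)),
            fx$reads$insert_mean + 3 * fx$reads$insert_sd)
})

test_that("majority haplotype fraction follows the simulated source proportions", {
  fx <- test_fixture("FALSE_SNP")
  pl <- map_reads(fx$reads, fx$draft$seq, circular = TRUE)
  pu <- pileup(pl, fx$reads, fx$draft$seq)
  hit <- Filter(function(lg) all(fx$meta$snp$pos %in% lg$positions),
                pu$link_groups)
  expect_length(hit, 1)
  groups <- hit[[1]]$groups
  p_cp <- 200 / 204   # plastome at 200x vs NMPT-bearing nuclear at 4x
  n <- sum(groups)
  expect_lt(abs(groups[1] / n - p_cp), 3 * sqrt(p_cp * (1 - p_cp) / n) + 0.02)
})
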