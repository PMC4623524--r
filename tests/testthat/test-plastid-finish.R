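test_that("overlap-tiled fragments rejoin into the original circle", {
  set.seed(77)
  truth <- rnd_dna(12000)
  cuts <- c(1, 2500, 5000, 7500, 10000)
  frags <- vapply(seq_along(cuts), function(i) {
    a <- cuts[i]
    b <- if (i < length(cuts)) cuts[i + 1] + 19 else 12000
    s <- substr(truth, a, b)
    if (i == length(cuts)) s <- paste0(s, substr(truth, 1, 20))  # closure
    s
  }, character(1))
  # shuffle and strand-flip some fragments
  frags <- frags[c(3, 1, 5, 2, 4)]
  frags[2] <- rc(frags[2])
  draft <- join_and_circularize(frags, min_overlap = 15)
  expect_true(draft$circular)
  expect_true(seq_eq_circ(draft$seq, truth))
  # a single circular contig passes through unchanged
  ct <- contig(truth, circular = TRUE)
  expect_identical(join_and_circularize(list(ct))$seq, truth)
})

test_that("sub-threshold overlaps are bridged with N and inconsistent ties error", {
  set.seed(78)
  truth <- rnd_dna(6000)
  a <- substr(truth, 1, 3009)        # 10-bp overlap with b only
  b <- substr(truth, 3000, 6000)
  draft <- join_and_circularize(list(a, b), min_overlap = 15)
  expect_true(grepl("N", draft$seq))
  # two contigs sharing the same 30-bp junction but with different
  # continuations cannot be laid out
  core <- rnd_dna(2000)
  j <- rnd_dna(30)
  expect_error(join_and_circularize(list(paste0(core, j),
                                         paste0(j, rnd_dna(1500)),
                                         paste0(j, rnd_dna(1500))),
                                    min_overlap = 15),
               "ambiguous joins")
})

test_that("quadripartite detection recovers planted regions and is rotation-invariant", {
  g <- test_genome()
  cp <- g$components$cp
  q <- detect_quadripartite(cp)
  tr <- g$truth
  expect_identical(q$regions$name, c("LSC", "IRb", "SSC", "IRa"))
  for (nm in c("LSC", "IRb", "SSC", "IRa")) {
    want <- tr[tr$feature == nm & tr$component == "cp", ]
    row <- q$regions[q$regions$name == nm, ]
    expect_equal(row$end - row$start, want$end - want$start)
  }
  expect_true(seq_eq_circ(q$seq, cp))
  # rotation by 1000 bp gives the identical canonical output
  rot <- paste0(substring(cp, 1001), substr(cp, 1, 1000))
  q2 <- detect_quadripartite(rot)
  expect_identical(q2$seq, q$seq)
  expect_identical(q2$regions, q$regions)
  # strand flip too
  q3 <- detect_quadripartite(rc(rot))
  expect_identical(q3$seq, q$seq)
  # an IR-free circle warns and sets no regions
  expect_warning(q4 <- detect_quadripartite(rnd_dna(8000)), "no inverted repeat")
  expect_null(q4$regions)
})

test_that("each planted defect is detected exactly once and repaired byte-exactly", {
  for (kind in c("FALSE_GAP", "FALSE_SNP", "TR_COLLAPSE", "MONOPOLYMER")) {
    fx <- test_fixture(kind)
    iss <- detect_issues(fx$draft, fx$reads)
    kinds <- vapply(iss, `[[`, character(1), "kind")
    expect_identical(kinds, kind, label = paste("kinds for", kind))
    i <- iss[[1]]
    res <- switch(kind,
      FALSE_GAP = fix_false_gap(fx$draft$seq, i, fx$reads),
      FALSE_SNP = fix_false_snp(fx$draft$seq, i),
      TR_COLLAPSE = fix_tr_copy(fx$draft$seq, i, fx$reads,
                                placements = attr(iss, "placements")),
      MONOPOLYMER = fix_monopolymer(fx$draft$seq, i, fx$reads))
    expect_true(res$resolved, label = paste("resolved", kind))
    expect_identical(res$seq, fx$truth$seq, label = paste("exact", kind))
  }
  # a clean draft yields no issues
  g <- test_genome()
  clean <- simulate_reads(g, c(cp = 100), seed = 5)
  expect_length(detect_issues(g$components$cp, clean), 0)
})

test_that("every fix reduces the anomaly mass of its fixture", {
  for (kind in c("FALSE_GAP", "TR_COLLAPSE", "MONOPOLYMER")) {
    fx <- test_fixture(kind)
    before <- skim2organelle:::anomaly_mass(suppressWarnings(
      anomaly_profile(map_reads(fx$reads, fx$draft$seq, circular = TRUE),
                      fx$reads)))
    after <- skim2organelle:::anomaly_mass(suppressWarnings(
      anomaly_profile(map_reads(fx$reads, fx$truth$seq, circular = TRUE),
                      fx$reads)))
    expect_lte(after, before)
  }
})

test_that("gap repair honours thresholds and falls back to gap closing", {
  set.seed(90)
  truth <- rnd_dna(4000)
  # duplication of 9 bp (< 10): unresolved
  d9 <- paste0(substr(truth, 1, 2000), strrep("N", 50),
               substr(truth, 1992, 4000))
  iss <- structure(list(kind = "FALSE_GAP", start = 2001, end = 2050,
                        evidence = list(), payload = list()),
                   class = "assembly_issue")
  mg <- list(components = list(x = truth), circular = c(x = FALSE))
  reads <- simulate_reads(mg, c(x = 80), seed = 3)
  r9 <- fix_false_gap(d9, iss, reads, min_dup = 10)
  expect_false(r9$resolved)
  # unrelated flanks: unresolved (routed to close_gaps by the finisher)
  dx <- paste0(substr(truth, 1, 2000), strrep("N", 50),
               substr(truth, 2051, 4000))
  rx <- fix_false_gap(dx, iss, reads)
  expect_false(rx$resolved)
})

test_that("monopolymer candidate selection keeps the draft length on ties", {
  fx <- test_fixture("MONOPOLYMER")
  iss <- detect_issues(fx$draft, fx$reads)
  i <- iss[[1]]
  # the published candidate set: the eight putative tract lengths
  res <- fix_monopolymer(fx$draft$seq, i, fx$reads,
                         candidate_lengths = c(7, 8, 9, 10, 11, 12, 15, 17))
  expect_true(res$resolved)
  expect_identical(res$seq, fx$truth$seq)
  expect_equal(as.integer(names(which.max(res$depths))), 17L)
  # truth length equal to draft length: unchanged
  g <- test_genome()
  clean_reads <- simulate_reads(g, c(cp = 100), seed = 5)
  mo <- g$truth[g$truth$feature == "monopolymer" & g$truth$component == "cp", ]
  i2 <- structure(list(kind = "MONOPOLYMER", start = mo$start, end = mo$end,
                       evidence = list(),
                       payload = list(base = "T", draft_len = 17L)),
                  class = "assembly_issue")
  res2 <- fix_monopolymer(g$components$cp, i2, clean_reads)
  expect_true(res2$resolved)
  expect_identical(res2$seq, g$components$cp)
})

test_that("finishing is idempotent and repairs the combined fixture", {
  fx <- test_fixture("ALL")
  fin <- finish(fx$draft, fx$reads)
  expect_true(seq_eq_circ(fin$seq, fx$truth$seq))
  expect_gte(sum(!grepl("^verified", fin$finishing_log$action)), 4)
  expect_length(fin$residual_issues, 0)
  # re-finishing the finished sequence applies zero fixes
  fin2 <- finish(fin$seq, fx$reads)
  expect_identical(fin2$seq, fin$seq)
  expect_equal(sum(!grepl("^verified", fin2$finishing_log$action)), 0)
})

test_that("long collapsed arrays are rewritten to within a copy-number tolerance", {
  set.seed(21)
  unit <- rnd_dna(18)
  truth <- paste0(rnd_dna(3000), strrep(unit, 40), rnd_dna(3000))
  draft <- paste0(substr(truth, 1, 3000), strrep(unit, 20),
                  substring(truth, 3721))
  mg <- list(components = list(x = truth), circular = c(x = FALSE))
  reads <- simulate_reads(mg, c(x = 100), seed = 2)
  iss <- detect_issues(draft, reads)
  kinds <- vapply(iss, `[[`, character(1), "kind")
  expect_true("TR_COLLAPSE" %in% kinds)
  i <- iss[[which(kinds == "TR_COLLAPSE")[1]]]
  expect_equal(i$payload$unit_len, 18)
  res <- fix_tr_copy(draft, i, reads, placements = attr(iss, "placements"))
  expect_true(res$resolved)
  n_copies <- (nchar(res$seq) - nchar(truth) + 720) / 18
  expect_lt(abs(n_copies - 40), 4)   # read-depth estimate, ~10% tolerance
})
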