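test_that("paired FASTQ round-trips and quality trimming matches a brute-force re-scan", {
  set.seed(101)
  n <- 1000
  rl <- 100
  qhigh <- strrep(rawToChar(as.raw(33 + 35)), rl)      # Q35
  qlow <- strrep(rawToChar(as.raw(33 + 15)), rl)       # Q15
  seqs1 <- vapply(seq_len(n), function(i) rnd_dna(rl), character(1))
  seqs2 <- vapply(seq_len(n), function(i) rnd_dna(rl), character(1))
  lowq <- runif(2 * n) < 0.05                          # 5% of reads poor
  q1 <- ifelse(lowq[1:n], qlow, qhigh)
  q2 <- ifelse(lowq[(n + 1):(2 * n)], qlow, qhigh)
  rp <- read_pairs(sprintf("p%04d", 1:n), seqs1, seqs2, q1, q2)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  write_reads(rp, f1, f2)
  got <- load_reads(f1, f2, qmin = 20)
  # independent oracle: a pair survives iff neither mate has mean Phred <= 20
  phred <- function(q) utf8ToInt(q) - 33
  keep <- vapply(1:n, function(i)
    mean(phred(q1[i])) > 20 && mean(phred(q2[i])) > 20, logical(1))
  expect_equal(length(got), sum(keep))
  expect_equal(got$id, rp$id[keep])
  expect_equal(got$seq1, seqs1[keep])
  # idempotence: re-trimming changes nothing
  again <- trim_read_pairs(got, qmin = 20)
  expect_identical(again$seq1, got$seq1)
  expect_identical(again$qual2, got$qual2)
  expect_equal(attr(again, "n_dropped"), 0)
})

test_that("trailing low-quality bases are trimmed before the mean test", {
  rl <- 60
  q <- paste0(strrep(rawToChar(as.raw(33 + 35)), rl - 10),
              strrep(rawToChar(as.raw(33 + 5)), 10))
  rp <- read_pairs("a", rnd_dna(rl), rnd_dna(rl), q,
                   strrep(rawToChar(as.raw(33 + 35)), rl))
  out <- trim_read_pairs(rp, qmin = 20)
  expect_equal(length(out), 1L)
  expect_equal(nchar(out$seq1), rl - 10L)
  expect_equal(nchar(out$seq2), rl)
})

test_that("desynchronized or malformed FASTQ inputs fail with located errors", {
  rl <- 50
  q <- strrep(rawToChar(as.raw(33 + 35)), rl)
  rp <- read_pairs(c("a", "b"), c(rnd_dna(rl), rnd_dna(rl)),
                   c(rnd_dna(rl), rnd_dna(rl)), c(q, q), c(q, q))
  f1 <- tempfile(); f2 <- tempfile()
  write_reads(rp, f1, f2)
  # swap a record id in file 2
  l2 <- readLines(f2); l2[5] <- "@zzz"
  writeLines(l2, f2)
  expect_error(load_reads(f1, f2), "desynchronized.*record 2")
  # malformed: quality shorter than sequence
  l1 <- readLines(f1); l1[4] <- substr(l1[4], 1, 10)
  writeLines(l1, f1)
  expect_error(load_reads(f1, f2), "length mismatch at line 2")
})

test_that("FASTA io round-trips, uppercases, and rejects duplicate ids", {
  set.seed(7)
  lens <- sample(1:10000, 20)
  seqs <- stats::setNames(vapply(lens, rnd_dna, character(1)),
                          sprintf("rec%02d", seq_along(lens)))
  p <- tempfile(fileext = ".fasta")
  write_fasta(seqs, p)
  back <- read_fasta(p)
  expect_identical(unname(back[names(seqs)]), unname(seqs))
  # one large record round-trips intact
  big <- stats::setNames(rnd_dna(134551), "plastome")
  write_fasta(big, p)
  expect_identical(as.character(read_fasta(p)), as.character(big))
  # lowercase input is uppercased with the record flagged
  writeLines(c(">low", "acgtACGT", ">up", "ACGT"), p)
  x <- read_fasta(p)
  expect_identical(unname(x["low"]), "ACGTACGT")
  expect_identical(attr(x, "lowercase"), "low")
  writeLines(c(">dup", "ACGT", ">dup", "ACGT"), p)
  expect_error(read_fasta(p), "duplicate")
  writeLines(character(), p)
  expect_warning(y <- read_fasta(p), "empty")
  expect_length(y, 0)
})
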