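#' Paired-end read container
#'
#' A `read_pairs` object holds synchronized paired-end reads as parallel
#' character vectors: ids, the two mate sequences (A/C/G/T/N) and their
#' Phred+33 quality strings, plus the library's expected insert-size model.
#'
#' @param id character vector of pair identifiers.
#' @param seq1,seq2 mate sequences.
#' @param qual1,qual2 Phred+33 quality strings (same lengths as the mates).
#' @param insert_mean,insert_sd expected insert size model in bp.
#' @return An object of class `read_pairs`.
#' @export
read_pairs <- function(id, seq1, seq2, qual1, qual2,
                       insert_mean = 500, insert_sd = 50) {
  stopifnot(length(id) == length(seq1), length(seq1) == length(seq2),
            length(qual1) == length(seq1), length(qual2) == length(seq2))
  if (length(seq1) && (any(nchar(seq1) != nchar(qual1)) ||
                       any(nchar(seq2) != nchar(qual2))))
    stop("sequence/quality length mismatch")
  structure(list(id = as.character(id), seq1 = seq1, seq2 = seq2,
                 qual1 = qual1, qual2 = qual2,
                 insert_mean = insert_mean, insert_sd = insert_sd),
            class = "read_pairs")
}

#' @export
length.read_pairs <- function(x) length(x$id)

#' @export
print.read_pairs <- function(x, ...) {
  cat(sprintf("read_pairs: %d pairs, insert %g +/- %g bp\n",
              length(x), x$insert_mean, x$insert_sd))
  invisible(x)
}

#' Subset read pairs
#' @param x a `read_pairs` object.
#' @param i index vector.
#' @param ... ignored.
#' @export
`[.read_pairs` <- function(x, i, ...) {
  read_pairs(x$id[i], x$seq1[i], x$seq2[i], x$qual1[i], x$qual2[i],
             x$insert_mean, x$insert_sd)
}

# All mates flattened; keeps pair and mate bookkeeping.
all_mates <- function(rp) {
  n <- length(rp)
  list(seq = c(rp$seq1, rp$seq2),
       pair = c(seq_len(n), seq_len(n)),
       mate = rep(c(1L, 2L), each = n))
}

total_bases <- function(rp) sum(nchar(rp$seq1)) + sum(nchar(rp$seq2))

phred_vec <- function(qual) utf8ToInt(qual) - 33L

#' Quality-trim paired reads
#'
#' Trailing bases with Phred scores at or below `qmin` are trimmed from the
#' 3' end of each mate, then any read whose mean Phred score is at or below
#' `qmin` (or whose trimmed length falls below `min_len`) is removed; a pair
#' is dropped when either mate is removed. The operation is idempotent.
#'
#' @param rp a [read_pairs] object.
#' @param qmin Phred threshold (default 20).
#' @param min_len minimum surviving mate length.
#' @return A filtered/trimmed `read_pairs` object with attribute `n_dropped`.
#' @export
trim_read_pairs <- function(rp, qmin = 20, min_len = 30) {
  n <- length(rp)
  if (n == 0) return(rp)
  trim_one <- function(seqs, quals) {
    keep_len <- integer(length(seqs))
    ok <- logical(length(seqs))
    out_s <- seqs; out_q <- quals
    for (i in seq_along(seqs)) {
      ph <- phred_vec(quals[i])
      L <- length(ph)
      while (L > 0 && ph[L] <= qmin) L <- L - 1L
      keep_len[i] <- L
      if (L >= min_len && mean(ph[seq_len(L)]) > qmin) {
        ok[i] <- TRUE
        if (L < length(ph)) {
          out_s[i] <- substr(seqs[i], 1, L)
          out_q[i] <- substr(quals[i], 1, L)
        }
      }
    }
    list(seq = out_s, qual = out_q, ok = ok)
  }
  t1 <- trim_one(rp$seq1, rp$qual1)
  t2 <- trim_one(rp$seq2, rp$qual2)
  keep <- t1$ok & t2$ok
  out <- read_pairs(rp$id[keep], t1$seq[keep], t2$seq[keep],
                    t1$qual[keep], t2$qual[keep],
                    rp$insert_mean, rp$insert_sd)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

parse_fastq_file <- function(path) {
  lines <- readLines(if (grepl("\\.gz$", path)) gzfile(path) else path)
  nl <- length(lines)
  if (nl %% 4 != 0)
    stop(sprintf("malformed FASTQ '%s': truncated record at line %d", path,
                 (nl %/% 4) * 4 + 1))
  hdr <- lines[seq(1, nl, by = 4)]
  seqs <- toupper(lines[seq(2, nl, by = 4)])
  plus <- lines[seq(3, nl, by = 4)]
  quals <- lines[seq(4, nl, by = 4)]
  bad <- which(!startsWith(hdr, "@"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': expected '@' at line %d", path,
                 (bad[1] - 1L) * 4L + 1L))
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': expected '+' at line %d", path,
                 (bad[1] - 1L) * 4L + 3L))
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stop(sprintf("malformed FASTQ '%s': sequence/quality length mismatch at line %d",
                 path, (bad[1] - 1L) * 4L + 2L))
  id <- sub("[/ ].*$", "", substring(hdr, 2))
  list(id = id, seq = seqs, qual = quals)
}

#' Load paired FASTQ files with quality trimming
#'
#' Reads two synchronized FASTQ files (plain or gzip), checks pairing, and
#' applies [trim_read_pairs] with the given threshold (reads with Phred
#' scores of `qmin` or less are removed).
#'
#' @param fastq1,fastq2 paths to the mate files.
#' @param qmin Phred threshold for trimming/removal (default 20).
#' @param insert_mean,insert_sd expected insert model.
#' @return A [read_pairs] object; attributes `n_input` and `n_dropped`
#'   report pair counts.
#' @export
load_reads <- function(fastq1, fastq2, qmin = 20,
                       insert_mean = 500, insert_sd = 50) {
  f1 <- parse_fastq_file(fastq1)
  f2 <- parse_fastq_file(fastq2)
  if (length(f1$id) != length(f2$id))
    stop(sprintf("desynchronized pair files: %d vs %d records",
                 length(f1$id), length(f2$id)))
  bad <- which(f1$id != f2$id)
  if (length(bad))
    stop(sprintf("desynchronized pair files at record %d: '%s' vs '%s'",
                 bad[1], f1$id[bad[1]], f2$id[bad[1]]))
  rp <- read_pairs(f1$id, f1$seq, f2$seq, f1$qual, f2$qual,
                   insert_mean, insert_sd)
  out <- trim_read_pairs(rp, qmin = qmin)
  attr(out, "n_input") <- length(rp)
  out
}

#' Write paired reads to two FASTQ files
#' @param rp a [read_pairs] object.
#' @param fastq1,fastq2 output paths.
#' @export
write_reads <- function(rp, fastq1, fastq2) {
  w <- function(path, seqs, quals) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", rp$id, "\n", seqs, "\n+\n", quals), con)
  }
  w(fastq1, rp$seq1, rp$qual1)
  w(fastq2, rp$seq2, rp$qual2)
  invisible(c(fastq1, fastq2))
}

#' Read a FASTA file
#'
#' Sequences are uppercased; records that contained lowercase characters are
#' recorded in the `"lowercase"` attribute. Duplicate ids are an error; an
#' empty file yields an empty vector with a warning.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0) {
    warning(sprintf("empty FASTA file '%s'", path))
    return(stats::setNames(character(), character()))
  }
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop(sprintf("duplicate FASTA id '%s' in '%s'",
                 ids[duplicated(ids)][1], path))
  x <- as.character(ss)
  lower <- grepl("[a-z]", x)
  x <- toupper(x)
  names(x) <- ids
  attr(x, "lowercase") <- ids[lower]
  x
}

#' Write sequences to FASTA (70-column wrap)
#' @param seqs named character vector.
#' @param path output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(length(seqs) > 0, all(nchar(seqs) > 0))
  ss <- Biostrings::BStringSet(seqs)
  names(ss) <- names(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Assembled contig
#'
#' @param seq DNA sequence (may contain N gaps).
#' @param id contig identifier.
#' @param circular logical; circular contigs must not start/end with N.
#' @param mean_count mean k-mer count of the contributing graph path.
#' @param provenance free-text assembler parameters.
#' @return An object of class `contig`.
#' @export
contig <- function(seq, id = "contig", circular = FALSE, mean_count = NA_real_,
                   provenance = "") {
  stopifnot(nchar(seq) > 0)
  if (circular && grepl("^N|N$", seq))
    stop("circular contig must not have a terminal N run")
  structure(list(id = id, seq = seq, circular = circular,
                 mean_count = mean_count, depth = NULL,
                 provenance = provenance),
            class = "contig")
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("contig %s: %d bp%s, mean k-mer count %.1f\n", x$id,
              nchar(x$seq), if (x$circular) " (circular)" else "",
              x$mean_count))
  invisible(x)
}

#' Coverage plan for plastid-window subsampling
#'
#' Captures the quantities needed to subsample a genome skim into a target
#' plastid coverage window (default 100-250x).
#'
#' @param genome_size haploid genome size in bp.
#' @param cp_size_estimate expected plastome size in bp.
#' @param cp_fraction proportion of read bases of plastid origin (0, 1].
#' @param target_cp_coverage desired fold coverage of the plastome.
#' @param seed subsampling seed.
#' @export
coverage_plan <- function(genome_size, cp_size_estimate, cp_fraction,
                          target_cp_coverage = 150, seed = 1) {
  stopifnot(cp_fraction > 0, cp_fraction <= 1, target_cp_coverage > 0,
            genome_size > 0, cp_size_estimate > 0)
  structure(list(genome_size = genome_size,
                 cp_size_estimate = cp_size_estimate,
                 cp_fraction = cp_fraction,
                 target_cp_coverage = target_cp_coverage, seed = seed),
            class = "coverage_plan")
}
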