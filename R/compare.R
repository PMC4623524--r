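#' Monopolymer census
#'
#' Reports every maximal single-base run strictly longer than
#' `min_len_exclusive` (default 8, i.e. runs of 9 nt or more, reading
#' "more than 8 nt" literally). Circular sequences are checked across the
#' origin; N runs are never reported.
#'
#' @param sequence DNA sequence.
#' @param min_len_exclusive runs must be strictly longer than this.
#' @param circular check across the origin.
#' @return data.frame `base`, `start` (1-based), `length`, sorted by
#'   position; a run crossing the origin is reported at its (pre-wrap)
#'   start with its full length.
#' @export
scan_monopolymers <- function(sequence, min_len_exclusive = 8,
                              circular = FALSE) {
  stopifnot(nchar(sequence) > 0, min_len_exclusive >= 1)
  n <- nchar(sequence)
  runs <- base_runs(sequence)
  wrap <- NULL
  if (circular && nrow(runs) >= 2) {
    first <- runs[1, ]; last <- runs[nrow(runs), ]
    if (first$base == last$base && first$start == 1 &&
        last$start + last$length - 1L == n && first$base %in% BASES) {
      wrap <- data.frame(base = first$base, start = last$start,
                         length = first$length + last$length,
                         stringsAsFactors = FALSE)
      runs <- runs[-c(1, nrow(runs)), , drop = FALSE]
    }
  }
  out <- rbind(runs, wrap)
  out <- out[out$length > min_len_exclusive & out$base %in% BASES, ,
             drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# collinear chain of unique shared k-mers between two sequences
anchor_chain <- function(a, b, k = 31) {
  na <- nchar(a); nb <- nchar(b)
  if (na < k || nb < k) return(NULL)
  sa <- seq_len(na - k + 1L); sb <- seq_len(nb - k + 1L)
  ka <- substring(a, sa, sa + k - 1L)
  kb <- substring(b, sb, sb + k - 1L)
  ua <- !(duplicated(ka) | duplicated(ka, fromLast = TRUE))
  ub <- !(duplicated(kb) | duplicated(kb, fromLast = TRUE))
  m <- match(ka, kb)
  ok <- ua & !is.na(m) & ub[ifelse(is.na(m), 1L, m)]
  if (!any(ok)) return(NULL)
  pa <- sa[ok]; pb <- sb[m[ok]]
  o <- order(pa)
  pa <- pa[o]; pb <- pb[o]
  # longest increasing subsequence on pb (patience; O(n log n))
  tails <- integer(0); links <- integer(length(pb)); tidx <- integer(0)
  for (i in seq_along(pb)) {
    pos <- findInterval(pb[i] - 1L, pb[tidx]) + 1L
    links[i] <- if (pos > 1) tidx[pos - 1L] else 0L
    if (pos > length(tidx)) tidx <- c(tidx, i) else tidx[pos] <- i
  }
  chain <- integer(0)
  cur <- tidx[length(tidx)]
  while (cur > 0) { chain <- c(cur, chain); cur <- links[cur] }
  ca <- pa[chain]; cb <- pb[chain]
  # prune to non-overlapping anchors: an anchor overlapping its
  # predecessor can span (and hide) a short indel
  keep <- logical(length(ca))
  last_a <- -k; last_b <- -k
  for (i in seq_along(ca)) {
    if (ca[i] >= last_a + k && cb[i] >= last_b + k) {
      keep[i] <- TRUE
      last_a <- ca[i]; last_b <- cb[i]
    }
  }
  data.frame(a = ca[keep], b = cb[keep], k = k)
}

#' Enumerate SNPs and InDels between near-identical sequences
#'
#' Anchor-based comparison: maximal unique shared 31-mers are chained
#' collinearly (longest increasing chain); the inter-anchor segments are
#' globally aligned at edit distance and adjacent gap columns are merged
#' into single InDel events. Coordinates are 1-based on `seq_a`. Circular
#' inputs are rotation-canonicalized before comparison.
#'
#' @param seq_a,seq_b the two sequences (>= 90% identical).
#' @param circular treat the sequences as circular (rotation-invariant).
#' @return List: `snps` (data.frame pos, ref, alt), `indels` (data.frame
#'   pos, ref, alt: one row per event, anchored VCF-style on the preceding
#'   base), `n_snps`, `n_indels`.
#' @export
pairwise_variants <- function(seq_a, seq_b, circular = FALSE) {
  a <- toupper(as.character(seq_a)[1]); b <- toupper(as.character(seq_b)[1])
  if (circular) {
    # rotate b (strand-aware) to align with a on a shared unique 31-mer
    ch <- anchor_chain(a, paste0(b, substr(b, 1, 30)), k = 31)
    if (is.null(ch)) {
      b <- cpp_revcomp(b)
      ch <- anchor_chain(a, paste0(b, substr(b, 1, 30)), k = 31)
    }
    if (is.null(ch))
      stop("sequences too diverged for this comparator (no shared anchors)")
    shift <- ((ch$b[1] - ch$a[1]) %% nchar(b))
    b <- paste0(substring(b, shift + 1L), substr(b, 1, shift))
  }
  ch <- anchor_chain(a, b)
  if (is.null(ch))
    stop("sequences too diverged for this comparator (no shared anchors)")
  k <- ch$k[1]
  # bound identity: aligned anchor coverage must dominate
  if (nrow(ch) * 1 < 1) stop("empty anchor chain")
  snps <- list(); indels <- list()
  seg_bounds <- rbind(
    data.frame(a0 = c(1L, ch$a + k), a1 = c(ch$a - 1L, nchar(a)),
               b0 = c(1L, ch$b + k), b1 = c(ch$b - 1L, nchar(b))))
  total_mismatch <- 0L
  for (i in seq_len(nrow(seg_bounds))) {
    sa <- substr(a, seg_bounds$a0[i], seg_bounds$a1[i])
    sb <- substr(b, seg_bounds$b0[i], seg_bounds$b1[i])
    if (!nchar(sa) && !nchar(sb)) next
    off <- seg_bounds$a0[i] - 1L
    if (nchar(sa) == nchar(sb)) {
      va <- seq_chars(sa); vb <- seq_chars(sb)
      d <- which(va != vb)
      total_mismatch <- total_mismatch + length(d)
      for (p in d) snps[[length(snps) + 1L]] <-
        data.frame(pos = off + p, ref = va[p], alt = vb[p],
                   stringsAsFactors = FALSE)
      next
    }
    if (!nchar(sa) || !nchar(sb)) {
      # pure insertion/deletion between anchors
      anchor_pos <- max(off, 1L)
      indels[[length(indels) + 1L]] <- data.frame(
        pos = anchor_pos,
        ref = if (nchar(sa)) paste0(substr(a, anchor_pos, anchor_pos), sa)
              else substr(a, anchor_pos, anchor_pos),
        alt = if (nchar(sb)) paste0(substr(a, anchor_pos, anchor_pos), sb)
              else substr(a, anchor_pos, anchor_pos),
        stringsAsFactors = FALSE)
      total_mismatch <- total_mismatch + abs(nchar(sa) - nchar(sb))
      next
    }
    al <- Biostrings::pairwiseAlignment(sb, sa, type = "global")
    pa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    pb <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    apos <- off
    j <- 1L
    while (j <= length(pa)) {
      if (pa[j] != "-" && pb[j] != "-") {
        apos <- apos + 1L
        if (pa[j] != pb[j]) {
          snps[[length(snps) + 1L]] <- data.frame(
            pos = apos, ref = pa[j], alt = pb[j], stringsAsFactors = FALSE)
          total_mismatch <- total_mismatch + 1L
        }
        j <- j + 1L
      } else {
        # merge the whole gap run into one InDel event
        j0 <- j
        gap_in_a <- pa[j] == "-"
        while (j <= length(pa) &&
               ((gap_in_a && pa[j] == "-") || (!gap_in_a && pb[j] == "-")))
          j <- j + 1L
        run <- (j - j0)
        anchor_pos <- max(apos, 1L)
        if (gap_in_a) {  # insertion in b
          ins <- paste(pb[j0:(j - 1L)], collapse = "")
          indels[[length(indels) + 1L]] <- data.frame(
            pos = anchor_pos, ref = substr(a, anchor_pos, anchor_pos),
            alt = paste0(substr(a, anchor_pos, anchor_pos), ins),
            stringsAsFactors = FALSE)
        } else {         # deletion from a
          del <- paste(pa[j0:(j - 1L)], collapse = "")
          indels[[length(indels) + 1L]] <- data.frame(
            pos = anchor_pos,
            ref = paste0(substr(a, anchor_pos, anchor_pos), del),
            alt = substr(a, anchor_pos, anchor_pos),
            stringsAsFactors = FALSE)
          apos <- apos + run
        }
        total_mismatch <- total_mismatch + run
      }
    }
  }
  identity <- 1 - total_mismatch / max(nchar(a), 1)
  if (identity < 0.9)
    stop("sequences too diverged for this comparator (identity < 90%)")
  snps <- if (length(snps)) do.call(rbind, snps) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
  indels <- if (length(indels)) do.call(rbind, indels) else
    data.frame(pos = integer(), ref = character(), alt = character(),
               stringsAsFactors = FALSE)
  snps <- snps[order(snps$pos), , drop = FALSE]
  indels <- indels[order(indels$pos), , drop = FALSE]
  rownames(snps) <- rownames(indels) <- NULL
  list(snps = snps, indels = indels,
       n_snps = nrow(snps), n_indels = nrow(indels))
}

#' Write variants as a minimal VCF
#' @param variants result of [pairwise_variants].
#' @param path output path.
#' @param chrom chromosome name for the CHROM column.
#' @export
write_variants_vcf <- function(variants, path, chrom = "seqA") {
  v <- rbind(variants$snps, variants$indels)
  v <- v[order(v$pos), , drop = FALSE]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
  if (nrow(v))
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", chrom, v$pos, v$ref,
                       v$alt), con)
  invisible(path)
}

#' Fetch a GenBank nucleotide record as FASTA (network required)
#'
#' Thin wrapper over NCBI efetch used for checks against published genomes.
#'
#' @param accession GenBank accession.
#' @param dest destination FASTA path.
#' @param timeout seconds before giving up.
#' @return `dest`, or an error when the fetch fails (e.g. offline).
#' @export
fetch_genbank_fasta <- function(accession, dest = tempfile(fileext = ".fasta"),
                                timeout = 20) {
  url <- paste0("https://eutils.ncbi.nlm.nih.gov/entrez/eutils/efetch.fcgi",
                "?db=nuccore&rettype=fasta&retmode=text&id=", accession)
  old <- options(timeout = timeout)
  on.exit(options(old))
  status <- tryCatch(utils::download.file(url, dest, quiet = TRUE,
                                          method = "libcurl"),
                     error = function(e) stop(sprintf(
                       "could not fetch %s (offline?): %s", accession,
                       conditionMessage(e)), call. = FALSE),
                     warning = function(w) stop(sprintf(
                       "could not fetch %s (offline?): %s", accession,
                       conditionMessage(w)), call. = FALSE))
  if (!identical(status, 0L) || !file.exists(dest) || file.size(dest) < 100)
    stop(sprintf("could not fetch %s (offline?)", accession))
  dest
}
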