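#' Mock genome specification
#'
#' Describes the synthetic plant genome skim used throughout testing: a
#' random nuclear background carrying NMPT insertions (diverged plastid
#' fragments) and monopolymer decoys, a circular quadripartite plastome with
#' a planted tandem repeat and a planted (T)17 monopolymer, mitochondrial
#' fragments sharing segments with the plastome, and tandem 45S and 5S
#' ribosomal DNA arrays. Generation is a pure function of (spec, seed).
#'
#' @param nuclear_size nuclear background length (bp).
#' @param cp_size plastome length (bp); quadripartite proportions are fixed
#'   at LSC 0.60, IR 0.13 each, SSC 0.14.
#' @param mt_fragment_sizes lengths of mitochondrial fragments.
#' @param mt_shared_len length of the plastome segment shared (identical)
#'   with each mitochondrial fragment.
#' @param nmpt_count number of NMPT insertions in the nuclear background.
#' @param nmpt_divergence substitution rate applied to NMPT copies.
#' @param nmpt_lengths NMPT tract lengths (recycled to `nmpt_count`).
#' @param rdna_45s_unit,rdna_45s_copies 45S unit length and tandem copy
#'   number. The unit is cistron (3/4 of the unit: 18S, ITS1, 5.8S, ITS2,
#'   26S) plus IGS (1/4) containing a GC-rich 60-bp sub-repeat triplet.
#' @param rdna_5s_unit,rdna_5s_copies 5S unit length and copy number.
#' @param tr_unit_len,tr_copies planted plastid tandem repeat (LSC).
#' @param monopolymer_len planted plastid poly-T tract length.
#' @param decoy_monopolymers nuclear poly-T decoy lengths.
#' @param seed generation seed.
#' @return An object of class `mock_genome_spec`.
#' @export
mock_genome_spec <- function(nuclear_size = 200000, cp_size = 30000,
                             mt_fragment_sizes = c(8000, 8000),
                             mt_shared_len = 2000,
                             nmpt_count = 4, nmpt_divergence = 0.03,
                             nmpt_lengths = c(500, 800, 1200, 1500),
                             rdna_45s_unit = 4000, rdna_45s_copies = 100,
                             rdna_5s_unit = 320, rdna_5s_copies = 300,
                             tr_unit_len = 18, tr_copies = 4,
                             monopolymer_len = 17,
                             decoy_monopolymers = c(7, 8, 9, 10, 11, 12, 15),
                             seed = 1) {
  spec <- as.list(environment())
  stopifnot(nuclear_size > 0, cp_size > 0, all(mt_fragment_sizes > 0),
            nmpt_divergence >= 0, nmpt_divergence < 1,
            rdna_45s_copies >= 2, rdna_5s_copies >= 2)
  structure(spec, class = "mock_genome_spec")
}

# fixed landmark offsets inside the plastome LSC (1-based)
.cp_landmarks <- function(lsc_len) {
  list(tr_at = 6001L, mono_at = 12001L, snp_nmpt_src = 3001L)
}

#' Build a deterministic mock genome
#'
#' @param spec a [mock_genome_spec].
#' @return A `mock_genome`: named component sequences (`nuclear`, `cp`,
#'   `mt1`, ..., `rdna_45s`, `rdna_5s` arrays), per-feature truth table,
#'   the 45S/5S unit truths with sub-region annotation, and the spec.
#' @export
build_mock_genome <- function(spec = mock_genome_spec()) {
  stopifnot(inherits(spec, "mock_genome_spec"))
  with_seed(spec$seed, {
    truth <- list()
    note <- function(component, feature, start, end, info = "") {
      truth[[length(truth) + 1L]] <<- data.frame(
        component = component, feature = feature,
        start = start, end = end, info = info, stringsAsFactors = FALSE)
    }

    lsc_len <- round(spec$cp_size * 0.60)
    ir_len <- round(spec$cp_size * 0.13)
    ssc_len <- spec$cp_size - lsc_len - 2L * ir_len
    lm <- .cp_landmarks(lsc_len)
    if (lsc_len < lm$mono_at + 100)
      stop("infeasible spec: plastome LSC too small for planted features")

    lsc <- random_dna(lsc_len)
    # guard bases: block inverted-repeat boundary extension so the
    # quadripartite detector recovers the planted boundaries exactly
    substr(lsc, 1, 1) <- "A"; substr(lsc, lsc_len, lsc_len) <- "A"

    # planted tandem repeat: unit must not itself be periodic
    repeat {
      tr_unit <- random_dna(spec$tr_unit_len)
      periods <- vapply(seq_len(spec$tr_unit_len - 1), function(p)
        substr(tr_unit, 1, spec$tr_unit_len - p) ==
          substr(tr_unit, p + 1, spec$tr_unit_len), logical(1))
      if (!any(periods) && !grepl("TTTT|N", tr_unit)) break
    }
    tr_span <- spec$tr_unit_len * spec$tr_copies
    if (lm$tr_at + tr_span + 2 > lm$mono_at)
      stop("infeasible spec: tandem repeat collides with monopolymer site")
    lsc <- splice_at(lsc, lm$tr_at, strrep(tr_unit, spec$tr_copies))
    # phase guards so the planted array is the maximal periodic extent
    substr(lsc, lm$tr_at - 1L, lm$tr_at - 1L) <-
      setdiff(BASES, substr(tr_unit, spec$tr_unit_len, spec$tr_unit_len))[1]
    substr(lsc, lm$tr_at + tr_span, lm$tr_at + tr_span) <-
      setdiff(BASES, substr(tr_unit, 1, 1))[1]
    note("cp", "tr_array", lm$tr_at, lm$tr_at + tr_span - 1L,
         sprintf("unit_len=%d;copies=%d;unit=%s", spec$tr_unit_len,
                 spec$tr_copies, tr_unit))

    lsc <- splice_at(lsc, lm$mono_at, strrep("T", spec$monopolymer_len))
    substr(lsc, lm$mono_at - 1L, lm$mono_at - 1L) <- "A"
    mono_end <- lm$mono_at + spec$monopolymer_len
    substr(lsc, mono_end, mono_end) <- "C"
    note("cp", "monopolymer", lm$mono_at, mono_end - 1L,
         sprintf("base=T;len=%d", spec$monopolymer_len))

    ir <- random_dna(ir_len)
    ssc <- random_dna(ssc_len)
    substr(ssc, 1, 1) <- "A"; substr(ssc, ssc_len, ssc_len) <- "A"
    if (ssc > revcomp(ssc)) ssc <- revcomp(ssc)  # SSC-lex-min isomer
    substr(ssc, 1, 1) <- "A"; substr(ssc, ssc_len, ssc_len) <- "A"
    cp <- paste0(lsc, ir, ssc, revcomp(ir))
    note("cp", "LSC", 1L, lsc_len, "")
    note("cp", "IRb", lsc_len + 1L, lsc_len + ir_len, "")
    note("cp", "SSC", lsc_len + ir_len + 1L, lsc_len + ir_len + ssc_len, "")
    note("cp", "IRa", lsc_len + ir_len + ssc_len + 1L, spec$cp_size, "")

    # mitochondrial fragments with identical shared plastome segments
    mt <- list()
    mt_src <- c(501L, lsc_len + ir_len + 201L)  # LSC early, SSC
    for (i in seq_along(spec$mt_fragment_sizes)) {
      sz <- spec$mt_fragment_sizes[i]
      frag <- random_dna(sz)
      src <- mt_src[((i - 1L) %% length(mt_src)) + 1L]
      shared <- substr(cp, src, src + spec$mt_shared_len - 1L)
      at <- round(sz / 2 - spec$mt_shared_len / 2)
      if (at < 1 || at + spec$mt_shared_len > sz)
        stop("infeasible spec: mt fragment smaller than shared segment")
      frag <- splice_at(frag, at, shared)
      mt[[paste0("mt", i)]] <- frag
      note(paste0("mt", i), "cp_shared", at, at + spec$mt_shared_len - 1L,
           sprintf("cp_src=%d", src))
    }

    # nuclear background with NMPT insertions and monopolymer decoys
    nuc <- random_dna(spec$nuclear_size)
    nmpt_len <- rep_len(spec$nmpt_lengths, spec$nmpt_count)
    nmpt_src <- c(lm$snp_nmpt_src, 8201L, 14001L, 16001L)
    nmpt_src <- rep_len(nmpt_src, spec$nmpt_count)
    nmpt_at <- round(seq(20000, spec$nuclear_size * 0.7,
                         length.out = max(spec$nmpt_count, 1)))
    snp_offsets <- c(200L, 204L)  # forced divergent sites in NMPT 1
    snp_info <- ""
    for (i in seq_len(spec$nmpt_count)) {
      if (nmpt_src[i] + nmpt_len[i] - 1L > nchar(cp))
        stop("infeasible spec: NMPT source outside plastome")
      tract <- substr(cp, nmpt_src[i], nmpt_src[i] + nmpt_len[i] - 1L)
      tract <- mutate_seq(tract, spec$nmpt_divergence)
      if (i == 1L && spec$nmpt_divergence > 0 && nmpt_len[i] > max(snp_offsets)) {
        # guarantee two linked divergent sites for false-SNP fixtures
        alt <- character(2)
        for (j in 1:2) {
          o <- snp_offsets[j]
          cpb <- substr(cp, nmpt_src[i] + o - 1L, nmpt_src[i] + o - 1L)
          alt[j] <- setdiff(BASES, cpb)[1]
          substr(tract, o, o) <- alt[j]
        }
        snp_info <- sprintf("cp_pos=%d,%d;alt=%s,%s",
                            nmpt_src[i] + snp_offsets[1] - 1L,
                            nmpt_src[i] + snp_offsets[2] - 1L, alt[1], alt[2])
      }
      if (nmpt_at[i] + nmpt_len[i] - 1L > spec$nuclear_size)
        stop("infeasible spec: NMPT larger than host sequence")
      nuc <- splice_at(nuc, nmpt_at[i], tract)
      note("nuclear", "nmpt", nmpt_at[i], nmpt_at[i] + nmpt_len[i] - 1L,
           sprintf("cp_src=%d;len=%d;%s", nmpt_src[i], nmpt_len[i],
                   if (i == 1L) snp_info else ""))
    }
    decoy_at <- round(seq(spec$nuclear_size * 0.75,
                          spec$nuclear_size * 0.95,
                          length.out = max(length(spec$decoy_monopolymers), 1)))
    for (i in seq_along(spec$decoy_monopolymers)) {
      L <- spec$decoy_monopolymers[i]
      nuc <- splice_at(nuc, decoy_at[i], strrep("T", L))
      substr(nuc, decoy_at[i] - 1L, decoy_at[i] - 1L) <- "A"
      substr(nuc, decoy_at[i] + L, decoy_at[i] + L) <- "C"
      note("nuclear", "decoy_monopolymer", decoy_at[i], decoy_at[i] + L - 1L,
           sprintf("base=T;len=%d", L))
    }

    # 45S unit: cistron (3/4) + IGS (1/4) with GC-rich 60-bp triplet
    cis_len <- round(spec$rdna_45s_unit * 0.75)
    igs_len <- spec$rdna_45s_unit - cis_len
    sub <- round(cis_len * c(0, 0.40, 0.485, 0.538, 0.615, 1))
    regions_45s <- data.frame(
      region = c("18S", "ITS1", "5.8S", "ITS2", "26S", "IGS"),
      start = c(sub[1:5] + 1L, cis_len + 1L),
      end = c(sub[2:6], spec$rdna_45s_unit), stringsAsFactors = FALSE)
    cistron <- random_dna(cis_len)
    if (igs_len < 260) stop("infeasible spec: IGS too short for sub-repeats")
    sr_at <- igs_len - 350L + 1L          # triplet sits in the distal IGS
    if (sr_at < 2) stop("infeasible spec: IGS too short for sub-repeats")
    sr <- random_dna(60, gc = 0.7)
    igs <- random_dna(igs_len)
    igs <- splice_at(igs, sr_at,
                     paste0(sr, mutate_seq(sr, 0.03), mutate_seq(sr, 0.03)))
    unit_45s <- paste0(cistron, igs)
    note("rdna_45s", "unit", 1L, spec$rdna_45s_unit,
         sprintf("copies=%d;cistron=%d;igs=%d;subrepeat_at=%d",
                 spec$rdna_45s_copies, cis_len, igs_len, cis_len + sr_at))

    # 5S unit: 120-bp gene + spacer
    gene_len <- min(120L, spec$rdna_5s_unit - 50L)
    unit_5s <- random_dna(spec$rdna_5s_unit)
    note("rdna_5s", "unit", 1L, spec$rdna_5s_unit,
         sprintf("copies=%d;gene=%d", spec$rdna_5s_copies, gene_len))

    components <- c(list(nuclear = nuc, cp = cp), mt,
                    list(rdna_45s = strrep(unit_45s, spec$rdna_45s_copies),
                         rdna_5s = strrep(unit_5s, spec$rdna_5s_copies)))
    structure(list(
      components = components,
      circular = stats::setNames(names(components) == "cp", names(components)),
      truth = do.call(rbind, truth),
      unit_45s = unit_45s, regions_45s = regions_45s,
      unit_5s = unit_5s, gene_5s = substr(unit_5s, 1, gene_len),
      cistron_45s = cistron, spec = spec), class = "mock_genome")
  })
}

#' @export
print.mock_genome <- function(x, ...) {
  cat("mock_genome components:\n")
  for (nm in names(x$components))
    cat(sprintf("  %-10s %8d bp%s\n", nm, nchar(x$components[[nm]]),
                if (x$circular[[nm]]) " (circular)" else ""))
  invisible(x)
}

#' Simulate paired-end reads from a mock genome
#'
#' Fragments are drawn uniformly per component at the requested fold
#' coverage; insert sizes follow a Gaussian truncated to
#' `[2*read_len, 2*insert_mean]`; mate 2 is the reverse complement of the
#' fragment end; circular components are sampled across the origin.
#' Substitution errors are applied at `error_rate` per base.
#'
#' @param genome a `mock_genome` (or a named list with `components` and
#'   `circular` entries).
#' @param coverage named numeric vector of fold coverages per component;
#'   components absent from the vector are not sampled.
#' @param read_len read length (default 150).
#' @param insert_mean,insert_sd insert-size model (default 500 +/- 50).
#' @param error_rate per-base substitution error rate.
#' @param seed simulation seed.
#' @return A [read_pairs] object; attribute `truth` records per-read source
#'   component and fragment position.
#' @export
simulate_reads <- function(genome, coverage, read_len = 150,
                           insert_mean = 500, insert_sd = 50,
                           error_rate = 0, seed = 1) {
  stopifnot(all(coverage >= 0), read_len <= insert_mean)
  qual_str <- strrep(rawToChar(as.raw(33L + 37L)), read_len)
  with_seed(seed, {
    ids <- seqs1 <- seqs2 <- character(0)
    src_comp <- character(0); src_pos <- integer(0)
    for (nm in names(coverage)) {
      cov <- coverage[[nm]]
      if (cov <= 0) next
      s <- genome$components[[nm]]
      if (is.null(s)) stop(sprintf("unknown component '%s'", nm))
      len <- nchar(s)
      if (read_len > len) stop(sprintf("read_len %d exceeds component '%s' (%d bp)",
                                       read_len, nm, len))
      circ <- isTRUE(genome$circular[[nm]])
      npair <- round(cov * len / (2 * read_len))
      if (npair == 0) next
      ins <- pmin(pmax(round(stats::rnorm(npair, insert_mean, insert_sd)),
                       2L * read_len), 2L * insert_mean)
      ins <- pmin(ins, len)
      if (circ) {
        pos <- sample.int(len, npair, replace = TRUE)   # 1-based start
        s2x <- paste0(s, s)
        frag <- substring(s2x, pos, pos + ins - 1L)
      } else {
        pos <- vapply(ins, function(i) sample.int(len - i + 1L, 1L), integer(1))
        frag <- substring(s, pos, pos + ins - 1L)
      }
      r1 <- substring(frag, 1L, read_len)
      r2 <- vapply(frag, function(f)
        cpp_revcomp(substring(f, nchar(f) - read_len + 1L, nchar(f))),
        character(1), USE.NAMES = FALSE)
      flip <- sample(c(TRUE, FALSE), npair, replace = TRUE)
      m1 <- ifelse(flip, r2, r1)
      m2 <- ifelse(flip, r1, r2)
      if (error_rate > 0) {
        m1 <- vapply(m1, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
        m2 <- vapply(m2, mutate_seq, character(1), rate = error_rate,
                     USE.NAMES = FALSE)
      }
      ids <- c(ids, sprintf("%s_%06d", nm, seq_len(npair)))
      seqs1 <- c(seqs1, m1); seqs2 <- c(seqs2, m2)
      src_comp <- c(src_comp, rep(nm, npair)); src_pos <- c(src_pos, pos)
      if (!exists("src_ins", inherits = FALSE)) { src_ins <- integer(0); src_flip <- logical(0) }
      src_ins <- c(src_ins, ins); src_flip <- c(src_flip, flip)
    }
    rp <- read_pairs(ids, seqs1, seqs2,
                     rep(qual_str, length(ids)), rep(qual_str, length(ids)),
                     insert_mean, insert_sd)
    if (!exists("src_ins", inherits = FALSE)) { src_ins <- integer(0); src_flip <- logical(0) }
    attr(rp, "truth") <- data.frame(component = src_comp, pos = src_pos,
                                    insert = src_ins, flip = src_flip,
                                    stringsAsFactors = FALSE)
    rp
  })
}

truth_feature <- function(genome, component, feature) {
  t <- genome$truth
  t[t$component == component & t$feature == feature, , drop = FALSE][1, ]
}

#' Construct a targeted mis-assembly fixture
#'
#' Builds a draft plastome that differs from the truth only by one planted
#' defect of the requested class, together with reads simulated from the
#' truth:
#' \describe{
#'   \item{FALSE_GAP}{an N run whose flanks carry a duplicated 60-bp block.}
#'   \item{FALSE_SNP}{the draft carries the nuclear-insertion (NMPT) alleles
#'     at two linked positions; reads include the nuclear background at low
#'     coverage (plastome at ~50-fold excess).}
#'   \item{TR_COLLAPSE}{the planted tandem array collapsed from 4 to 2
#'     copies.}
#'   \item{MONOPOLYMER}{the planted (T)17 tract replaced by (T)8.}
#'   \item{ALL}{all four defects at once.}
#' }
#'
#' @param kind one of FALSE_GAP, FALSE_SNP, TR_COLLAPSE, MONOPOLYMER, ALL.
#' @param genome a `mock_genome`.
#' @param seed read-simulation seed.
#' @param gap_n length of the planted N run for FALSE_GAP.
#' @return List with `draft` and `truth` [contig]s, `reads`, and `meta`
#'   describing the planted defect.
#' @export
make_misassembly_fixture <- function(kind = c("FALSE_GAP", "FALSE_SNP",
                                              "TR_COLLAPSE", "MONOPOLYMER",
                                              "ALL"),
                                     genome = build_mock_genome(),
                                     seed = 1, gap_n = 400) {
  kind <- match.arg(kind)
  cp <- genome$components$cp
  spec <- genome$spec
  meta <- list(kind = kind)
  draft <- cp
  coverage <- c(cp = 100)

  plant_gap <- function(s) {
    a <- 10000L
    dup <- substr(s, a - 59L, a)
    meta$gap <<- list(at = a, dup_len = 60L, n_len = gap_n)
    paste0(substr(s, 1, a), strrep("N", gap_n), dup,
           substr(s, a + 1L, nchar(s)))
  }
  plant_snp <- function(s) {
    nm <- truth_feature(genome, "nuclear", "nmpt")
    info <- nm$info
    pos <- as.integer(strsplit(sub(".*cp_pos=([0-9,]+);.*", "\\1", info),
                               ",")[[1]])
    alt <- strsplit(sub(".*alt=([ACGT],[ACGT])", "\\1", info), ",")[[1]]
    for (j in seq_along(pos)) substr(s, pos[j], pos[j]) <- alt[j]
    meta$snp <<- list(pos = pos, alt = alt,
                      ref = vapply(pos, function(p) substr(cp, p, p),
                                   character(1)))
    s
  }
  plant_tr <- function(s) {
    tr <- truth_feature(genome, "cp", "tr_array")
    u <- spec$tr_unit_len
    keep <- 2L
    meta$tr <<- list(start = tr$start, unit_len = u,
                     truth_copies = spec$tr_copies, draft_copies = keep)
    paste0(substr(s, 1, tr$start - 1L),
           substr(s, tr$start, tr$start + keep * u - 1L),
           substr(s, tr$end + 1L, nchar(s)))
  }
  plant_mono <- function(s) {
    mo <- truth_feature(genome, "cp", "monopolymer")
    wrong <- 8L
    meta$mono <<- list(start = mo$start, truth_len = spec$monopolymer_len,
                       draft_len = wrong)
    paste0(substr(s, 1, mo$start - 1L), strrep("T", wrong),
           substr(s, mo$end + 1L, nchar(s)))
  }

  # apply right-to-left so recorded coordinates stay valid on the draft
  if (kind %in% c("MONOPOLYMER", "ALL")) draft <- plant_mono(draft)
  if (kind %in% c("FALSE_GAP", "ALL")) draft <- plant_gap(draft)
  if (kind %in% c("TR_COLLAPSE", "ALL")) draft <- plant_tr(draft)
  if (kind %in% c("FALSE_SNP", "ALL")) {
    draft <- plant_snp(draft)
    coverage <- c(cp = 200, nuclear = 4)
  }
  # defect order above: mono(12001) < gap(10001)? apply in descending
  # coordinate order instead
  if (kind == "ALL") {
    draft <- cp
    coverage <- c(cp = 200, nuclear = 4)
    draft <- plant_mono(draft)   # 12001
    draft <- plant_gap(draft)    # 10001
    draft <- plant_tr(draft)     # 6001
    draft <- plant_snp(draft)    # 3201/3205
  }

  reads <- simulate_reads(genome, coverage, seed = seed)
  list(kind = kind,
       draft = contig(draft, id = paste0("draft_", kind), circular = TRUE,
                      provenance = "misassembly fixture"),
       truth = contig(cp, id = "truth_cp", circular = TRUE),
       reads = reads, meta = meta)
}
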