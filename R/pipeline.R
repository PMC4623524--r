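#' Default pipeline configuration
#'
#' @param out_dir run directory.
#' @param seed master seed; every stochastic stage derives its own seed
#'   from it.
#' @param ... overrides for any configuration entry.
#' @return A named list of configuration values.
#' @export
pipeline_config <- function(out_dir, seed = 1, ...) {
  cfg <- list(
    out_dir = out_dir, seed = seed,
    # inputs: either fastq1/fastq2 + panel FASTA paths, or simulate = TRUE
    simulate = TRUE,
    fastq1 = NULL, fastq2 = NULL,
    panel = NULL,               # named list of reference sequences
    genome_size = NULL,         # haploid genome size (bp)
    qmin = 20,
    # simulation
    sim_coverage = c(cp = 100, nuclear = 2, mt1 = 10, mt2 = 10,
                     rdna_45s = 2, rdna_5s = 2),
    sim_error_rate = 0,
    read_len = 150, insert_mean = 500, insert_sd = 50,
    # triage
    target_cp_coverage = 150, cp_size_estimate = 30000,
    # assembly
    k = 31, min_count = 3,
    # finishing
    max_rounds = 5,
    min_overlap = 15)
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

#' Read a flat YAML-style configuration file
#' @param path YAML file.
#' @param out_dir,seed defaults when absent from the file.
#' @export
read_pipeline_config <- function(path, out_dir = "run", seed = 1) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(list(out_dir = y$out_dir %||% out_dir, seed = y$seed %||% seed),
            y[setdiff(names(y), c("out_dir", "seed"))]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full skim-to-organelle pipeline
#'
#' Stages: load (or simulate) reads, estimate the plastid read fraction,
#' subsample into the target plastid-coverage window, assemble, classify
#' contigs against the panel, join/finish the plastome, complete the 45S
#' and 5S units, and estimate rDNA copy numbers. Every stage's parameters
#' and seed are logged; a machine-readable manifest is written; partial
#' failures leave completed stage outputs intact.
#'
#' @param config list from [pipeline_config] or [read_pipeline_config].
#' @param verbose print stage logs.
#' @return Invisible list with the principal results (`plastome`,
#'   `unit_45s`, `unit_5s`, `classification`, `manifest`).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config = config[setdiff(names(config), "panel")],
                   stages = list())
  stage <- function(name, value) {
    manifest$stages[[name]] <<- value
    write_manifest()
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest,
                         file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         force = TRUE, null = "null")
  }
  result <- list()

  # --- inputs ---------------------------------------------------------------
  if (isTRUE(config$simulate)) {
    vlog("simulating mock genome and reads (seed ", config$seed, ")",
         verbose = verbose)
    genome <- build_mock_genome(mock_genome_spec(seed = config$seed))
    reads <- simulate_reads(genome, config$sim_coverage,
                            read_len = config$read_len,
                            insert_mean = config$insert_mean,
                            insert_sd = config$insert_sd,
                            error_rate = config$sim_error_rate,
                            seed = child_seed(config$seed, 1))
    panel <- list(cp = genome$components$cp,
                  mt = unname(unlist(genome$components[grep("^mt",
                        names(genome$components))])),
                  nR = c(genome$unit_45s, genome$unit_5s))
    models <- list(cistron = substr(genome$cistron_45s, 1, 200),
                   gene_5s = genome$gene_5s)
    comp_len <- vapply(genome$components, nchar, numeric(1))
    nuclear_cov <- config$sim_coverage[["nuclear"]]
    genome_size <- config$genome_size %||%
      (sum(comp_len * config$sim_coverage[names(comp_len)]) / nuclear_cov)
    result$genome <- genome
  } else {
    if (is.null(config$fastq1) || is.null(config$fastq2))
      stop("missing inputs: fastq1/fastq2 required when simulate = FALSE")
    if (is.null(config$panel)) stop("missing inputs: panel references required")
    vlog("loading reads", verbose = verbose)
    reads <- load_reads(config$fastq1, config$fastq2, qmin = config$qmin,
                        insert_mean = config$insert_mean,
                        insert_sd = config$insert_sd)
    panel <- lapply(config$panel, function(p)
      if (file.exists(p[1])) unname(read_fasta(p[1])) else p)
    models <- list(cistron = substr(panel$nR[1], 1, 200),
                   gene_5s = if (length(panel$nR) > 1)
                     substr(panel$nR[2], 1, 120) else NULL)
    genome_size <- config$genome_size %||% stop("genome_size required")
  }
  stage("load", list(n_pairs = length(reads), bases = total_bases(reads)))
  vlog(sprintf("%d pairs (%.2f Mbp)", length(reads),
               total_bases(reads) / 1e6), verbose = verbose)

  # --- plastid fraction and subsampling -------------------------------------
  frac <- estimate_cp_fraction(reads, panel$cp[1],
                               seed = child_seed(config$seed, 2))
  stage("cp_fraction", list(fraction = frac$fraction, ci = frac$ci))
  vlog(sprintf("plastid read fraction %.3f", frac$fraction), verbose = verbose)
  plan <- coverage_plan(genome_size, config$cp_size_estimate,
                        max(frac$fraction, 1e-6),
                        target_cp_coverage = config$target_cp_coverage,
                        seed = child_seed(config$seed, 3))
  warn20 <- FALSE
  sub <- withCallingHandlers(
    subsample(reads, plan),
    warning = function(w) {
      if (grepl("NMPT", conditionMessage(w))) warn20 <<- TRUE
      invokeRestart("muffleWarning")
    })
  stage("subsample", list(selected_pairs = length(sub),
                          selected_bases = attr(sub, "selected_bases"),
                          nmpt_warning = warn20))

  # --- assembly and classification ------------------------------------------
  vlog("assembling (k=", config$k, ", min_count=", config$min_count, ")",
       verbose = verbose)
  graph <- build_graph(sub, k = config$k, min_count = config$min_count)
  contigs <- assemble(graph)
  stage("assemble", list(k = config$k, min_count = config$min_count,
                         n_contigs = length(contigs)))
  vlog(length(contigs), " contigs", verbose = verbose)
  cls <- classify_contigs(contigs, panel)
  utils::write.table(cls, file.path(config$out_dir, "classification.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("classify", list(n_cp = sum(cls$label == "cp"),
                         n_mt = sum(cls$label == "mt"),
                         n_nR = sum(cls$label == "nR"),
                         n_other = sum(cls$label == "other")))
  ids <- vapply(contigs, `[[`, character(1), "id")
  write_fasta(stats::setNames(vapply(contigs, `[[`, character(1), "seq"), ids),
              file.path(config$out_dir, "contigs.fasta"))

  # --- plastome finishing ----------------------------------------------------
  cp_ids <- cls$id[cls$label == "cp"]
  if (!length(cp_ids)) stop("no cp-labelled contig: cannot finish plastome")
  cp_contigs <- contigs[ids %in% cp_ids]
  # high-copy dominance filter: drop diverged-homolog (NMPT) stubs whose
  # k-mer depth is a small fraction of the plastid depth
  cpc <- vapply(cp_contigs, `[[`, numeric(1), "mean_count")
  cpl <- vapply(cp_contigs, function(x) nchar(x$seq), numeric(1))
  ref_depth <- stats::median(rep(cpc, pmax(cpl %/% 100, 1)))
  cp_contigs <- cp_contigs[cpc >= 0.25 * ref_depth]
  vlog("joining ", length(cp_contigs), " cp contigs", verbose = verbose)
  draft <- join_and_circularize(cp_contigs, min_overlap = config$min_overlap,
                                reference = panel$cp[1])
  fin <- finish(draft, sub, max_rounds = config$max_rounds)
  write_fasta(c(plastome = fin$seq),
              file.path(config$out_dir, "plastome.fasta"))
  if (!is.null(fin$regions))
    utils::write.table(fin$regions, file.path(config$out_dir, "regions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(fin$finishing_log,
                     file.path(config$out_dir, "finishing_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  stage("finish", list(length = nchar(fin$seq),
                       fixes = nrow(fin$finishing_log),
                       residual = length(fin$residual_issues)))
  vlog(sprintf("plastome %d bp, %d log entries", nchar(fin$seq),
               nrow(fin$finishing_log)), verbose = verbose)
  result$plastome <- fin

  # --- ribosomal units --------------------------------------------------------
  nr_ids <- cls$id[cls$label == "nR"]
  nr_contigs <- contigs[ids %in% nr_ids]
  unit45 <- unit5 <- NULL
  if (length(nr_contigs)) {
    has45 <- vapply(nr_contigs, function(ct)
      !is.null(locate_model(models$cistron, ct$seq)), logical(1))
    if (any(has45)) {
      cand <- nr_contigs[has45]
      cand <- cand[[which.max(vapply(cand, function(x) nchar(x$seq),
                                     numeric(1)))]]
      unit45 <- tryCatch(
        complete_45s(cand, reads, cistron_model = models$cistron),
        error = function(e) { vlog("45S completion failed: ",
                                   conditionMessage(e), verbose = verbose); NULL })
    }
    if (!is.null(models$gene_5s)) {
      unit5 <- tryCatch(extract_5s(nr_contigs, models$gene_5s),
                        error = function(e) NULL)
    }
  }
  # --- copy numbers -----------------------------------------------------------
  cn <- list()
  for (u in list(`45S` = unit45, `5S` = unit5)) {
    if (is.null(u) || !isTRUE(u$complete)) next
    est <- estimate_copy_number(u, reads, genome_size,
                                seed = child_seed(config$seed, 4))
    cn[[u$unit_class]] <- est$copy_number_estimate
    if (u$unit_class == "45S") unit45 <- est else unit5 <- est
  }
  units <- Filter(Negate(is.null), list(unit45, unit5))
  if (length(units)) {
    write_fasta(stats::setNames(
      vapply(units, `[[`, character(1), "seq"),
      vapply(units, `[[`, character(1), "unit_class")),
      file.path(config$out_dir, "rdna_units.fasta"))
    cn_df <- data.frame(
      unit_class = vapply(units, `[[`, character(1), "unit_class"),
      length = vapply(units, function(u) nchar(u$seq), numeric(1)),
      copy_number = vapply(units, function(u)
        u$copy_number_estimate %||% NA_real_, numeric(1)))
    utils::write.table(cn_df, file.path(config$out_dir, "copy_numbers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  stage("rdna", list(
    unit_45s = if (!is.null(unit45)) nchar(unit45$seq) else NA,
    unit_5s = if (!is.null(unit5)) nchar(unit5$seq) else NA,
    copy_45s = cn[["45S"]] %||% NA, copy_5s = cn[["5S"]] %||% NA))
  vlog(sprintf("45S %s bp, 5S %s bp",
               if (!is.null(unit45)) nchar(unit45$seq) else "-",
               if (!is.null(unit5)) nchar(unit5$seq) else "-"),
       verbose = verbose)
  result$unit_45s <- unit45
  result$unit_5s <- unit5
  result$classification <- cls

  manifest$outputs <- as.list(tools::md5sum(list.files(config$out_dir,
                                                       full.names = TRUE,
                                                       pattern = "\\.(fasta|tsv)$")))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  write_manifest()
  result$manifest <- manifest
  invisible(result)
}
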