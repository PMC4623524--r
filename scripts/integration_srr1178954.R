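#!/usr/bin/env Rscript
# Full-scale integration run against the public Oryza sativa 'Nipponbare'
# skim (SRA accession SRR1178954). This needs a multi-gigabyte download and
# several CPU-hours; it is not part of the test suite.
#
# Expected outcome: a 134,551-bp plastome identical to GenBank GU592207 /
# KM088016, a 324-bp 5S unit (KM036298) and a 7,928-bp 45S unit (KM036282).
#
# Preparation (outside R):
#   prefetch SRR1178954 && fasterq-dump --split-files SRR1178954
#   # bait/panel references (FASTA): a related plastome (e.g. GU592207),
#   # mitochondrial and rDNA references for classification
#
# Usage:
#   Rscript scripts/integration_srr1178954.R <fastq1> <fastq2> \
#       <cp_bait.fasta> <mt_panel.fasta> <nr_panel.fasta> <out_dir>

suppressPackageStartupMessages(library(skim2organelle))

a <- commandArgs(trailingOnly = TRUE)
if (length(a) < 6) stop("six arguments required; see the header comment")

cfg <- pipeline_config(
  out_dir = a[6], seed = 1,
  simulate = FALSE,
  fastq1 = a[1], fastq2 = a[2],
  panel = list(cp = a[3], mt = a[4], nR = a[5]),
  genome_size = 430e6,          # haploid rice genome
  cp_size_estimate = 134551,
  target_cp_coverage = 150)     # the 100-250x optimum window

res <- run_pipeline(cfg)
cat(sprintf("plastome: %d bp\n", nchar(res$plastome$seq)))
if (!is.null(res$unit_45s)) cat(sprintf("45S: %d bp\n", nchar(res$unit_45s$seq)))
if (!is.null(res$unit_5s)) cat(sprintf("5S: %d bp\n", nchar(res$unit_5s$seq)))
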