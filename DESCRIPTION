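Package: skim2organelle
Title: Complete Chloroplast Genomes and Ribosomal DNA Units from Genome Skims
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: Simultaneous de novo reconstruction of complete chloroplast
    genomes and nuclear ribosomal DNA (5S and 45S) tandem units from
    low-coverage whole-genome shotgun paired-end reads. Provides a
    canonical k-mer de Bruijn assembler with paired-read gap closing,
    coverage-window subsampling and contig triage, in-silico detection and
    correction of false gaps, false SNPs, tandem-repeat copy-number
    collapse and monopolymer length errors, two-unit tandem gap closing
    for the 45S intergenic spacer, read-depth rDNA copy-number estimation
    per haploid genome equivalent, pairwise plastome variant enumeration,
    and a deterministic genome-skim simulator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
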