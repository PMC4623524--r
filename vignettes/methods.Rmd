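---
title: "Methods: organelle and rDNA reconstruction from genome skims"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: organelle and rDNA reconstruction from genome skims}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Plant whole-genome shotgun data is a mixture of sequences at very
different copy numbers. Per haploid genome equivalent, single-copy
nuclear DNA contributes depth 1, the plastome contributes depth equal to
its cellular copy number (tens to hundreds), ribosomal DNA tandem arrays
contribute depth equal to their copy number (hundreds to thousands), and
diverged plastid insertions in the nuclear and mitochondrial genomes
(NMPTs) contribute low depth at high sequence identity to the plastome.
A skim of a fraction of 1x nuclear coverage therefore carries the
plastome and the rDNA units at assembly-grade depth while the nuclear
background stays below the assembler's noise floor. This package
assembles exactly that high-copy fraction and then removes the
characteristic artefacts such assemblies carry.

The artefacts all stem from the mixture structure:

* **false gaps** — the assembler emits an N run whose flanks duplicate
  the same sequence, a signature of an aborted graph traversal;
* **false SNPs** — at positions where an NMPT diverges from the plastome,
  the draft can carry the NMPT allele; the read pileup then splits into
  linked haplotype groups whose sizes mirror the source copy numbers
  (plastid reads exceed their homologs roughly 8-100-fold);
* **tandem-repeat collapse** — a repeat unit shorter than the k-mer
  length creates a cycle in the graph and the emitted copy number is
  wrong;
* **monopolymer length errors** — homopolymer tracts are similarly
  compressible, and nuclear homologs carrying different tract lengths
  interfere.

Each artefact class has a detector driven by read-mapping evidence and a
fixer whose output is validated by re-mapping, iterated in rounds until
the draft is evidence-clean (`finish()`, default 5 rounds, structural
fixes before substitutional ones within a round, coordinates protected by
right-to-left application and re-detection between rounds).

## Parameters that matter

| parameter | default | rationale |
|---|---|---|
| assembly k | 31 (odd) | standard skim practice; odd k avoids palindromic self-canonical k-mers; even k only via explicit override (k = 64 resolves an 18-bp x 4 array because 64 exceeds span - unit = 54) |
| `min_count` | 3 (1 for error-free tests) | removes the sub-noise nuclear background at skim depth |
| tip clip | < max(2k, 300) bp and < 25% of neighbour depth | NMPT branch stubs run up to a couple of read lengths, hence the absolute floor over the 2k rule |
| relative branch cut | 5% of the strongest neighbour | prunes diverged-homolog edges without touching the 10x mitochondrial fraction |
| subsample window | 100-250x plastid coverage | below ~100x assemblies fragment; above ~20x whole-genome coverage NMPTs co-assemble (a warning is raised) |
| mapping | 15-bp exact seeds, gapless X-drop extension (match +1 / mismatch -3, drop 12), soft clipping | references are small, so cheap exact seeding is sensitive; the simulator's error model is substitution-only, and soft clips are themselves the evidence the detectors need |
| discordance | insert beyond 4 sd or wrong orientation | conservative under the truncated-Gaussian insert model |
| depth z threshold | 3, with the window sd floored at 15% of the baseline | window means are autocorrelated over a read length, so the trimmed sd alone collapses; the floor makes z >= 3 mean a >= 45% excursion |
| minor-haplotype floor | 5% | below the plastid:NMPT mixture proportions yet above sequencing noise at the target depths |
| gap budget | N-run length + 2 insert sd | the N annotation is the gap-size prior, exactly why under-estimated 45S spacer gaps need the N-length schedule (100, 300, 1000) |

## What the simulator emulates

`build_mock_genome()` is a pure function of its spec and seed: a 200-kb
i.i.d.-uniform nuclear background carrying four NMPT insertions (plastome
fragments at 3% divergence, two of whose divergent sites are forced so
false-SNP fixtures always exist) and seven poly-T decoys (7-15 nt); a
30-kb circular quadripartite plastome (LSC 0.60 / IR 0.13 each /
SSC 0.14) with an 18-bp x 4 tandem array and a (T)17 tract planted in the
LSC; two 8-kb mitochondrial fragments each sharing a 2-kb plastome
segment (identical, modelling recent transfer, in contrast to the
ancient, diverged NMPTs); a 45S array of 100 identical 4,000-bp units
(3/4 cistron subdivided 18S/ITS1/5.8S/ITS2/26S, 1/4 IGS containing a
GC-rich 60-bp sub-repeat triplet whose copies are ~3% mutually diverged);
and a 5S array of 300 x 320 bp. Guard bases flank every planted feature
so that detected boundaries equal planted boundaries exactly.

The read simulator draws fragments uniformly per component (circular
components across the origin), inserts from a Gaussian (500 +/- 50 bp)
truncated to [2 read lengths, 2 means], and applies substitution errors
only; realized coverage is within 5% of the request.

What the simulator does **not** model: quality-by-cycle error profiles,
indel sequencing errors, PCR duplicates, GC-coverage bias, heteroplasmy,
and within-species rDNA unit heterogeneity beyond the IGS sub-repeats.
Passing the synthetic suite therefore demonstrates the correctness of the
graph, mapping and correction machinery under the mixture model, not
robustness to platform-specific artefacts; for real data the
quality-trimming front end and the mismatch budgets carry that weight.

## Numerical and design choices

* **Trimming rule.** "Reads with Phred <= 20 removed" is ambiguous between
  per-base and per-read; the package end-trims trailing bases at or below
  the threshold and then drops reads whose mean quality is at or below
  it, pairs dropping with either mate. Deterministic and idempotent.
* **Coordinates.** 0-based half-open internally (the placement tables);
  1-based inclusive in every report.
* **Canonical k-mers.** Lexicographic minimum of a k-mer and its reverse
  complement; all tie-breaks package-wide are lexicographic, making every
  stage byte-deterministic for fixed inputs.
* **Joining.** With no reference, a greedy maximal-terminal-overlap walk
  from the longest contig (each contig usable twice so a collapsed
  inverted repeat serves both orientations); equal-overlap ties between
  distinct contigs are broken by k-mer depth dominance when one candidate
  is >5x deeper (the high-copy argument again) and are otherwise an
  error. With a related reference plastome — the normal case, since
  triage already requires a bait — contigs are ordered and oriented by
  their best placements on it before overlap joining, which also fixes
  the single-copy-region isomer.
* **The isomer question.** When the inverted repeats exceed the insert
  size, the two SSC orientations are indistinguishable from read data
  and both molecules co-exist in vivo. The canonicaliser
  (`detect_quadripartite`) therefore rotates to the LSC start, flips the
  SSC to its lexicographically smaller strand and picks the
  lexicographically smaller whole-molecule strand; the generator emits
  its truth in the same normal form, making end-to-end equality
  well-defined.
* **Projected vs aligned depth.** The anomaly track projects each read's
  full extent along its placement diagonal (soft-clipped tails included):
  that is the depth a local-alignment viewer shows, and it keeps the
  depth signature of a collapsed repeat visible. Copy-number *ratios*,
  however, are measured in k-mer space (array-phase k-mer counts vs
  unique flank k-mer counts), which is free of the placement edge effects
  that bias mapped depth over a collapsed tandem: an n-copy array carries
  (n u - k + 1)/u occurrences of each of its u phase k-mers.
* **Short vs long arrays.** Local re-assembly at k just under the read
  length (capped at 99) resolves arrays the reads can span and is
  byte-exact; longer arrays fall back to the k-mer depth rewrite, which
  is accurate to a few percent — read depth cannot count 40 copies to
  +/-1, and the package does not pretend otherwise.
* **Monopolymer candidates.** Default lengths 5-25 plus the draft's
  current length; candidate variants are re-mapped requiring perfect
  full-length matches within tract +/- one read length, ties keep the
  draft (the do-no-harm rule).
* **rDNA unit delimitation.** The completed two-unit array is cut between
  the two cistron-model match positions, i.e. units start at the 18S
  start; 5S units are the minimal rotation period at >= 99%
  self-identity, with secondary period candidates reported rather than
  suppressed. Detection models are caller-supplied FASTA panels (the
  synthetic workflow uses truth-derived models), keeping the package free
  of shipped third-party sequence.
* **Copy-number normalisation.** Estimates subsample the raw reads to
  exactly one haploid genome equivalent and report mean mapped depth of
  the unit (circular mapping, fractional multi-mapping weights). For a
  simulated pool with non-uniform per-component coverage the pipeline
  derives the effective genome size as total read bases divided by the
  single-copy coverage; for real data the user supplies the published
  genome size, as is conventional.

## Problem sizes

The test suite and the acceptance script run entirely on the synthetic
system: a 742-kb mock genome, ~15,000 read pairs per skim, twenty
end-to-end seeds for the recovery property, and one hundred randomized
trials per brute-force oracle (k-mer counting, mapping, monopolymer
census, variant enumeration). A full pipeline run takes a few seconds on
one CPU; the complete suite runs in minutes.

## Known limitations

* The mapper is gapless: indel sequencing errors (off by default in the
  simulator) would be soft-clipped rather than aligned through.
* Mitochondrial contigs are classified but not finished — mitochondrial
  genome structure is hyper-variable and out of scope.
* The pairwise variant comparator requires near-identical inputs
  (>= 90% identity, collinear anchor chain); it is a barcoding tool, not
  a general aligner.
* Copy-number estimates inherit the usual depth-based caveats (GC bias
  and library effects in real data; see above for long-array rounding).
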