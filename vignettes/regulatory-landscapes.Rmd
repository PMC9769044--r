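---
title: "Inferring regulatory-element landscapes from methylomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring regulatory-element landscapes from methylomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regland)
```

## The model

DNA methylation marks out regulatory DNA: where transcription factors bind,
CpG methylation is locally depleted. In a plant methylome with a highly
methylated CG background, **lowly methylated regions** (LMRs) — CpG-poor
segments with methylation under a threshold — behave like distal enhancers,
while CpG-rich unmethylated segments (UMRs) are typically promoters.
`regland` implements the full inference chain from per-cytosine methylation
calls to a transcription-factor regulatory network:

1. **Segmentation** (`call_lmrs`). Per chromosome, each covered CG's
   methylation level (methylated reads / total reads) is smoothed over a
   centered window of `smooth_k = 3` CpGs; maximal runs of CpGs with
   smoothed level strictly below `lmr_threshold = 0.20` become segments.
   Segments with 4–29 CpGs are LMRs; 30 or more CpGs makes a UMR, which is
   reported separately and excluded from the enhancer set. The 20 %
   threshold is the common operational definition; parts of the LMR
   literature use 30 %, selectable via `lmr_threshold`.
2. **Differential methylation** (`call_dmrs`). Fixed non-overlapping
   200-bp windows, pooled CG counts per sample, Fisher's exact test on the
   2×2 methylated/unmethylated table, BH correction across tested windows,
   and filters `q < 0.05`, `|Δ| ≥ 0.1`.
3. **Annotation and overlap** (`classify_regions`, `mark_overlap_report`,
   `snp_density`). Genomic category by region midpoint with precedence
   promoter > exonic > intronic > intergenic (promoter = 2 kb upstream of
   the TSS on the coding strand); LMR overlap counts against H3K4me3 and
   H3K27me3 peak sets; SNPs per kb inside the merged regions versus the
   genomic complement.
4. **Enhancer–gene linking** (`link_enhancers`). Candidate targets are the
   10 nearest genes by TSS on each side of the enhancer midpoint. For each
   candidate, enhancer methylation is correlated with `log2(TPM + 1)`
   expression across samples (Pearson by default); pairs with a
   significantly negative correlation (one-sided p < 0.05, optionally BH)
   are retained. An enhancer whose expression rises as its methylation
   falls is the signature of positive regulation.
5. **Motif scanning and enrichment** (`scan_pwm`, `enrich_motifs`). PWMs
   are scored as summed log2 likelihood ratios over a background model;
   the p-value of a window score is the exact tail probability under the
   background, computed by dynamic-programming convolution of the
   discretized per-position score distribution. Hits at p < 1e-4 define
   region-level motif presence; foreground (condition-specific LMRs)
   versus background presence is tested per motif with a one-sided Fisher
   exact test and BH correction. Lowercase (repeat-masked) sequence is
   skipped by default.
6. **Network assembly** (`build_network`). A directed edge TF → gene is
   drawn when some enhancer linked to the gene carries a binding-site hit
   of a motif mapped to that TF; site counts aggregate over enhancers, and
   self-loops are allowed. `tf_subnetwork` restricts to TF→TF edges and
   aggregates them at the family level.

`run_all` orchestrates all stages from a single YAML configuration and
writes per-stage tables plus a `summary.json` whose every number is
recomputable from the stage outputs.

## Numerical choices

* **Coordinates.** All region tables are 0-based half-open; CGmap input is
  1-based and converted at the parser boundary. Touching intervals do not
  overlap.
* **Threshold convention.** A CpG at exactly the LMR threshold is *not*
  hypomethylated (strictly `<`), mirroring the "under 20 %" definition.
* **Missing signal.** A region with zero covered CG reads has methylation
  `NA`, never 0; enhancers with undefined methylation in more than half
  the samples are skipped in linking, and zero-variance vectors are
  skipped with a reason code rather than producing undefined correlations.
* **Score discretization.** The scanner rounds per-position log-odds onto
  a grid whose bin is 1/1000 of the widest per-position score range. The
  resulting p-values agree with exhaustive enumeration within about 2 %
  (relative), which is the tolerance the test suite asserts for widths up
  to 8. The minus strand is scored by reverse-complementing each window
  and sharing the forward null distribution, which makes
  reverse-complement symmetry exact.
* **DMR family.** Windows below the per-sample coverage floor are not
  tested and therefore not part of the BH family; they are counted and
  reported.
* **Ties in candidate selection.** Candidate genes are ordered by TSS
  distance with deterministic tie-breaks (smaller TSS, then lexicographic
  gene id), so runs are reproducible to the byte.

## The synthetic study design

`generate_dataset` emulates, at desk scale, an eight-variety bisulfite
study with four tolerant/susceptible pairs: two 2-Mb chromosomes, CpGs
every ~100 bp, a 0.80 CG methylation background, Poisson(20) per-cytosine
coverage (floor 1), and 60 planted hypomethylated segments of 0.8–1.5 kb.
Three planted subpopulations exercise the downstream stages:

* **shared** LMRs (methylation 0.10 in every sample) test plain
  segmentation;
* **tolerant-specific** LMRs (0.10 in tolerant, background in susceptible
  samples) feed the DMR, condition-specific and motif-enrichment stages;
  80 % carry a planted NAC-like motif instance versus 5 % of other LMRs;
* **linked** LMRs vary across samples on an evenly spaced methylation grid
  in [0.02, 0.18] (permuted per region), staying below the calling
  threshold everywhere while providing the across-sample variance that a
  correlation can detect. Each linked LMR drives one target gene within
  its 10-gene neighborhood with `log2` expression
  `10 − 10 × methylation + ε`, ε ~ N(0, 0.1²).

Histone peaks cover fixed fractions of each sample's planted LMRs (35 %
for H3K27me3, 5 % for H3K4me3 — a planted 7:1 ratio), SNPs fall at 6/kb
outside and 12/kb inside LMRs (the 6/kb background and 2× regulatory
enrichment are typical genome-wide figures for a diverse crop panel), and
an unmethylated `lambda` spike-in contig with a 0.5 % conversion-failure
rate supports `conversion_rate`. The generator returns full ground truth
(planted intervals, per-sample levels, pairs, motif instances, expected
network edges, SNP counts), and identical seeds give byte-identical files.

The upper end of the linked-LMR grid (0.18) sits deliberately close to the
0.20 calling threshold: in samples near the top of the grid, binomial
sampling noise fragments some of these segments, which is why per-sample
recovery at the default settings is imperfect by construction, while the
consensus across samples (`consensus_enhancers`) still captures every
linked locus from the samples where it is clearly hypomethylated.
Parameter-recovery claims are therefore made under the cleaner benchmark
configuration (50 planted LMRs at methylation 0.05 against a 0.85
background, 20× coverage), where the caller reaches precision and recall
≥ 0.9 at 50 % reciprocal overlap.

What the generator does *not* emulate: read-level bisulfite conversion,
CHG/CHH methylation (only CG rows are emitted, which is what the segmenter
consumes), realistic repeat families (repeats are uniform lowercase-masked
stretches kept clear of planted LMRs), linkage disequilibrium among SNPs,
and biological covariance structure in expression beyond the planted
links. Passing tests on this design demonstrate the correctness of the
machinery, not performance on real methylomes, where smoothing bandwidth,
coverage heterogeneity and partially methylated domains matter.

## Design decisions on open points

* **Pooling.** Segmentation is per sample; per-sample LMRs are unified for
  linking by merging any that overlap by ≥ 1 bp into consensus enhancers,
  and methylation is then recomputed at the consensus interval in every
  sample so that samples lacking a called LMR still contribute values.
* **Significance in linking.** The default is the raw one-sided p < 0.05
  (negative), with BH available via `correction = "BH"`; both p and q are
  reported for every pair.
* **Upstream/downstream** of an enhancer is taken in genomic coordinates
  relative to the region midpoint, not gene strand; distance is |midpoint −
  TSS|.
* **Category assignment** uses the region midpoint by default (`by =
  "any"` is available), so the fractions sum to exactly 1.
* **Edge confidence** in the network is the aggregated binding-site count;
  no p-value weighting by default.
* **Background for enrichment** is supplied by the caller (here, the
  non-specific LMR set) with mononucleotide frequencies estimated from it;
  no GC-matched resampling is attempted.

## Problem sizes

The test suite and the acceptance script run entirely on synthetic data
at the scales above: 2×2 Mb genomes, 8 (or 2–4) samples, ~40,000 CpGs per
sample, 50–60 planted LMRs, ≥ 1,000 null correlation tests, exhaustive
motif enumeration up to width 8, and 1,000 null DMR windows. These sizes
keep every stage in seconds-to-minutes while leaving all statistical
checks well powered.

## Worked example

```{r example, eval = FALSE}
gt <- generate_dataset(sim_config(seed = 1), "sim")
cfg <- config_from_truth(gt, "run")
summary <- run_all(cfg)
summary$pair_stats
summary$snp_density
```

## Known limitations

* The segmenter implements the explicit-threshold definition of LMRs, not
  FDR-calibrated cutoff selection or partially-methylated-domain masking;
  on methylomes with large PMDs the LMR set will be contaminated.
* The DMR caller tests fixed windows, so a true DMR straddling a window
  boundary can be split or diluted.
* Enrichment p-values treat regions as exchangeable; foreground and
  background sets with very different length or GC composition will bias
  the odds ratios.
* Correlation-based linking cannot distinguish direct regulation from
  shared confounding; with 8 samples its power is limited, and the network
  built on top inherits both caveats.
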