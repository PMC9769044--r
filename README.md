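# regland

Infer a regulatory-element landscape from whole-genome bisulfite
methylomes and companion assays, and assemble the transcription-factor
network it implies.

`regland` is aimed at plant (and other high-methylation) genomics groups
who have per-cytosine methylation calls for a panel of samples — e.g.
stress-tolerant and susceptible crop varieties — plus expression, histone
ChIP peaks, variants and a motif library, and want to go from those to
candidate enhancers, enhancer–gene links and a TF regulatory network with
transparent, testable statistics.

## What it computes

* **LMR segmentation.** In a CG-methylated background, transcription-factor
  binding leaves CpG-poor, lowly methylated regions (LMRs). Per chromosome,
  each covered CpG's level m_i = meth_i/total_i is smoothed over a centered
  3-CpG window; maximal runs with smoothed level < 0.20 become segments.
  Runs of 4–29 CpGs are LMRs (candidate distal enhancers); ≥ 30 CpGs makes
  an unmethylated region (UMR, typically a promoter), reported separately.
* **DMRs.** Fixed 200-bp windows; Fisher's exact test on the pooled 2×2
  methylated/unmethylated counts of two samples; BH across tested windows;
  keep q < 0.05 and |Δm| ≥ 0.1, labelled hypo/hyper.
* **Annotation, peak overlap, SNP density.** Midpoint category with
  precedence promoter > exonic > intronic > intergenic; LMR overlap counts
  against H3K4me3/H3K27me3 peaks; SNPs·kb⁻¹ inside merged regions versus
  the genomic complement.
* **Enhancer–gene linking.** For each consensus enhancer, the 10 nearest
  genes by TSS on each side are candidates; a pair is kept when Pearson
  r(methylation, log2(TPM+1)) across samples is negative with one-sided
  p < 0.05 (optionally BH). Pair statistics include genes/enhancer,
  enhancers/gene, distance histograms in 50-kb bins, and the
  nearest-TSS fraction among single-target enhancers.
* **Motif scanning and enrichment.** FIMO-style PWM scanning: windows are
  scored by the summed log2 likelihood ratio against a background model and
  assigned the exact tail probability of that score under the background,
  computed by dynamic-programming convolution of the discretized
  per-position score distribution; hits require p < 1e-4. Known-motif
  enrichment compares region-level motif presence between foreground
  (condition-specific LMRs) and background sets with one-sided Fisher tests
  on repeat-masked sequence.
* **Network assembly.** Edge TF → gene whenever an enhancer linked to the
  gene contains a binding site of a motif mapped to that TF; site counts
  aggregate; TF→TF subnetworks and family×family adjacencies are derived.
* **Synthetic data.** `generate_dataset()` writes a complete miniature
  multi-sample dataset (CGmap, FASTA, GFF3, expression TSV, narrowPeak,
  VCF, MEME motifs, TF maps) with planted ground truth, so the entire
  pipeline is testable offline and every claim in the test suite traces to
  a planted quantity.

## Worked example

Generate a synthetic eight-sample study and run the whole pipeline:

```r
library(regland)
gt  <- generate_dataset(sim_config(seed = 1), "sim")
cfg <- config_from_truth(gt, "run")
s   <- run_all(cfg)
```

The run prints per-stage logs to `run/run.log` and writes
`run/summary.json`. With seed 1 the summary contains (values produced by
the code above):

```
lmr_counts:        66 47 61 46 63 44 61 46        # per sample
conversion_rate:   0.9945 (tol1)                  # lambda spike-in
category_fractions: promoter 0.08, exonic 0.10, intergenic 0.82
mark_overlap:      frac_k27 0.34, K27:K4 ratio 7.3
snp_density:       12.7 SNPs/kb inside LMRs vs 6.0 outside (ratio 2.1)
pair_stats:        114 pairs, 58 enhancers, 2.0 genes/enhancer
network:           85 edges, 18 TF->TF
```

Reading the numbers: the caller finds the ~60 planted hypomethylated
segments per sample (susceptible samples lack the tolerant-specific ones);
the planted peak design covers 35 % of LMRs with H3K27me3 versus 5 % with
H3K4me3, recovered as a ~7-fold overlap ratio; SNPs were planted 2-fold
enriched in LMRs at a 6/kb background, recovered as 12 vs 6 per kb; and the
planted methylation–expression links drive the pair and network tables.

A thin command-line wrapper is installed with the package
(`system.file("exec", "regland", package = "regland")`) with subcommands
`simulate`, `lmr`, `dmr`, `run`.

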