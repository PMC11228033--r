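# cimpomics

Multi-omics integration pipeline for CpG Island Methylator Phenotype
(CIMP) leukemias.

CIMP acute leukemias are a mixed myeloid/lymphoid entity defined by
genome-wide DNA hypermethylation concentrated at CpG islands. Dissecting
them requires joining many layers of evidence: enrichment-based
methylation (MCIP-seq), chromatin accessibility (ATAC-seq), histone and
CTCF ChIP-seq, RNA-seq, Hi-C loops/TADs and tumor-only exome variant
calls. `cimpomics` re-implements the bespoke computational procedures of
such a study as a tested, reusable R package, and ships a synthetic
cohort generator that plants every effect the analyses are designed to
detect — so the whole pipeline is testable end-to-end without any
restricted-access patient data.

The package is aimed at computational biologists who want either the
individual building blocks (consensus-peak differential analysis,
methylation–expression integration, motif activity, CTCF–methylation
coupling, Hi-C linkage, a tumor-only variant sieve) or the full
orchestrated pipeline on simulated or real input tables.

## What it computes

- **Feature catalogs** — CpG islands by the Gardiner-Garden & Frommer
  criteria (windows ≥ 200 bp, GC > 0.5, observed/expected CpG > 0.6 with
  expected = #C·#G/length); strand-aware promoter windows (−1500/+500 bp
  around the TSS); an enhancer catalog from H3K27ac regions recurrent in
  ≥ 3 samples, excluding regions overlapping TSS ± 1 kb windows by ≥ 5%
  of their width, intersected with recurrent open chromatin and CAGE
  enhancers; ATAC peak promoter/enhancer labels (TSS ± 500 bp).
- **Consensus-peak quantification** — a master peak list (per-sample
  −log10 q > 10, present in ≥ 2 samples, blacklist-filtered, merged into
  maximal unions), input-DNA subtraction floored at zero, and TMM
  normalization (trim 30% M / 5% A, precision weights, consensus-peak
  library sizes).
- **Differential statistics** — per-feature negative-binomial Wald tests
  (log link, offsets = log effective library size, method-of-moments
  dispersion) with Benjamini–Hochberg FDR; Welch's t with Cohen's
  d = (x̄₁ − x̄₂)/√((s₁² + s₂²)/2); one-sided Fisher region-set
  enrichment; pre-ranked GSEA on the metric −log10(FDR)·sign(log2FC)
  with the weighted running-sum score and gene-label permutation
  p-values.
- **Integration** — the methylation–expression "starburst" join with the
  dual gate FDR < 0.05 and |log2FC| > 2 on both layers; an ensemble
  enhancer→gene assignment (distance, accessibility correlation, same
  TAD, loop contact, database prior); chromVAR-style bias-corrected
  motif-accessibility deviations with GC/accessibility-matched
  backgrounds and Wilcoxon differential activity (gates p < 0.01,
  |Δ| > 0.01); CTCF site classes (FDR < 0.05, |log2FC| > 1), the
  CTCF–methylation coupling correlation, and CpG positional enrichment
  within the 19-bp CTCF motif (positions 5 and 15); TAD-boundary CTCF
  annotation (5 kb boundaries, smallest-FDR peak), enhancer-promoter
  loop calling (5 kb anchor padding, 25 kb vicinity, opposite anchors),
  loop–CTCF linkage fractions and loop–expression correlation.
- **Variant sieve** — multi-caller merge with indel normalization, the
  ordered tumor-only quality cascade (strand bias, depth 8/4, MAPQ 40 /
  BQ 30, other-allele < 40%, alt-alignment ≤ 10%, indels ≥ 500 bp,
  repeats, self-chain ≥ 95%, SNV clusters of ≥ 3 within < 5 bp), somatic
  selection with COSMIC (≥ 5 hematological reports) and
  clonal-hematopoiesis gene rescues, oncogenicity flags, and fusion
  majority voting (≥ 3 tools after artifact exclusion).

## Worked example

```r
library(cimpomics)
cfg <- cohort_config(seed = 1, n_genes = 500)
report <- run_cohort_analysis(cfg)
print(report)
#> <cohort_report>
#>   n_genes                          500
#>   n_samples                        47
#>   n_master_peaks                   399
#>   starburst_r_signed               -0.5381
#>   starburst_r_lfc                  -0.5471
#>   n_hyper_silenced                 27
#>   enhancer_target_recovery         0.82
#>   enhancer_join_r                  0.7407
#>   planted_motif_delta              7.378
#>   planted_motif_p                  1.997e-07
#>   ctcf_meth_spearman               -0.536
#>   n_ctcf_lost                      44
#>   lost_loop_ctcf_fraction          0.7333
#>   gained_loop_ctcf_fraction        0.2
#>   loop_expression_rho              0.7208
#>   n_variants                       208
#>   variant_verdict_discrepancies    0
#>   n_somatic                        186
#>   n_fusions_kept                   2
```

Reading the output: the cohort has 47 samples (9 CIMP, 20 AML, 15 T-ALL,
3 HSPC). The starburst correlation between promoter-methylation and
expression changes is negative (−0.55), and 27 genes fall in the
hypermethylated-silenced quadrant — the planted silenced-TF program.
82% of enhancers are assigned to their true target gene by the ensemble
rule. The planted motif shows a strong CIMP accessibility deviation
(Δ = 7.4, Wilcoxon p = 2×10⁻⁷). CTCF binding changes anticorrelate with
methylation changes (Spearman ρ = −0.54), 73% of lost loops show an
anchor-CTCF decrease versus 20% of gained loops, and differential
enhancer-promoter loop strength correlates with target-gene expression
(ρ = 0.72). All 208 synthetic variants receive exactly the filter
verdict recorded in the generator's truth ledger.

The fixture bundle (BED/narrowPeak/BEDPE/FASTA/JASPAR/TSV + manifest)
can be written with `run_cohort_analysis(cfg, out_dir = "out")` or
`write_fixture_bundle()`.

## Vignette

`vignettes/cimpomics-methods.Rmd` documents the statistical models, the
planted structure of the synthetic cohort, every tunable parameter with
its default and rationale, numerical conventions (0-based half-open
coordinates throughout), and known limitations.
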