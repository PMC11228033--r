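---
title: "Methods: models, planted structure, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, planted structure, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`cimpomics` implements the computational core of a multi-omics analysis
of CIMP (CpG Island Methylator Phenotype) leukemias. This vignette
explains the statistical models and their assumptions, what the
synthetic cohort generator does and does not emulate, the tunable
parameters, and the design decisions taken where the procedure was
genuinely open.

## Coordinate and data conventions

All genomic intervals are 0-based half-open (`start <= x < end`), in
plain data frames with `chrom`, `start`, `end`, optional `strand` and
`id`. BED, narrowPeak and BEDPE files are read and written in the same
convention; 1-based inputs must be converted at the boundary. Interval
algebra (overlap, merge, distance) is delegated to
GenomicRanges/IRanges internally; the conversion happens in one place
(`gi_to_gr`), so a half-open abutment is never an overlap.

Count matrices are features x samples with non-negative integers.
Methylation is represented as enrichment counts over regions
(MCIP-seq-like), not array beta values; the array branch is out of
scope.

## Differential model

Per feature, counts are modeled as negative binomial with a log-linear
group effect and offsets equal to the log *effective library size*
(TMM factor x reads in consensus peaks). The dispersion is estimated
per feature by the pooled within-group method of moments,
`alpha = (var - mean) / mean^2`, floored at 1e-8; the Wald statistic is
`log2FC / SE` with a two-sided normal reference and Benjamini-Hochberg
correction across tested features. This is deliberately simpler than
the empirical-Bayes shrinkage of the packages used in large studies:
correctness is established by calibration (null rejection rate at
nominal 0.05 stays within [0.03, 0.07] at 10 vs 10 samples) and by
parameter recovery (planted log2FC = -3 recovered within +/-0.3 median
error), not by numeric identity to any external tool. All-zero
features are flagged (`status = "all-zero"`), never dropped.

TMM normalization follows the published trimmed-mean algorithm: pairwise
M and A values against a reference sample (the sample whose upper
quartile is closest to the mean upper quartile), trimming 30% of M and
5% of A, inverse-asymptotic-variance weights, and rescaling so factors
have geometric mean 1. The test suite pins the implementation to a
step-by-step transcription of the algorithm at 1e-10 and to
`edgeR::calcNormFactors` as an independent reference. TMM assumes a
majority of unchanged features: when more than the trimmed fraction of
features truly change (as a composition-heavy simulation can arrange),
residual bias in the factors is expected and is a property of the
method, not of this implementation.

The significance threshold is FDR < 0.05 throughout (configurable); the
effect-size labels for Cohen's d are |d| < 0.2 small and |d| >= 0.8
large.

## Pre-ranked GSEA

Genes are ranked by `-log10(FDR) * sign(log2FC)` (FDR underflow capped
at 1e-320, metric capped at 320; ties broken by feature id). The
enrichment score is the classic weighted Kolmogorov-Smirnov running sum
with weight exponent 1 by default (exposed as `weight`; `weight = 0`
gives the unweighted KS statistic, verified by the complement-set
identity). P-values use plain gene-label permutation - an approximation
to the multilevel split Monte Carlo of specialized packages - and the
FDR is Benjamini-Hochberg across tested sets. Set-size bounds default
to [15, 5000].

## Motif activity

Motif matches use integer-discretized log2-odds scores (granularity
1e-3) on both strands; the match threshold is the smallest achievable
score whose upper-tail probability under the background base
distribution is at most 5e-5, computed exactly by dynamic programming
over the discretized score distribution (pinned to exhaustive k-mer
enumeration for short motifs). Deviations follow the chromVAR idea:
expected motif accessibility assigns the motif's cohort-wide read
fraction to each sample's total, the raw deviation is
`(obs - exp)/exp`, and the bias correction samples background peak sets
matched on GC and mean accessibility in a 10 x 10 bin grid (with
replacement) - a binned approximation of the original Mahalanobis-style
sampling. Differential activity is the difference in mean deviation
Z-scores with a two-sided Wilcoxon test (gates p < 0.01, |delta| >
0.01). TF-expression correlations use the motif's first-named gene for
dimers and need at least 8 paired samples.

The footprint score is deliberately a simplified surrogate:
`mean(flank) - mean(center)` of the signal profile around motif sites,
averaged over sites. It captures central depletion only and performs no
enzymatic-bias correction; outputs are labeled accordingly.

## CTCF-methylation coupling

Sites are classified lost/unchanged/gained at FDR < 0.05 and |log2FC| >
1. The coupling join takes, per methylation region, the overlapping
CTCF peak with maximal overlap (ties by smallest FDR) and reports both
Pearson and Spearman coefficients. A practical note verified in the
tests: the rank correlation saturates once the planted separation
exceeds the estimation noise, so monotonicity in the coupling strength
is assessed on the Pearson coefficient, while both coefficients must be
negative.

CpG positional analysis uses 1-based positions of the CpG's C within
the motif-forward orientation (reverse-strand sites are
reverse-complemented first); this convention is explicit and
configurable because published coordinates rarely state theirs. The
canonical 19-bp CTCF motif model used by the generator admits CpG only
at positions 5-6 and 15-16 by design, mirroring the two CpG peaks of
the canonical motif.

## Hi-C integration

TAD boundaries are 5000-bp regions centered on each border (matching
the TAD-calling resolution); each boundary keeps the single overlapping
CTCF peak with the smallest FDR. Loop anchors are padded by 5000 bp per
side; enhancer-promoter loops require an enhancer within 25,000 bp
(inclusive) of one padded anchor and a promoter within 25,000 bp of the
opposite anchor, taking the closest qualifying features (and, when both
orientations qualify, the orientation with the smaller total distance).
Differential TAD/loop tables reuse the NB Wald machinery on integer
scores (with TMM factors computed on the score table) and fall back to
a normal-theory Wald test on log2 scores for non-integer tables; the
mode is recorded on the result.

Loop-CTCF linkage reports the fraction of lost (and gained) loops with
a CTCF decrease in at least one padded anchor, in two variants:
sign-only (`log2FC < 0`, the default) and significance-gated, because
published summaries rarely state which was used. The loop-expression
correlation is computed over *differential* EP loops (FDR < 0.05),
which mirrors selecting differential enhancer-promoter loops before
correlating with the expression of contacted genes; the unfiltered
variant is available via `significant_only = FALSE`.

For linkage summaries the pipeline uses the CTCF-CTCF loop class, whose
anchors carry CTCF sites; enhancer-promoter loops enter the
loop-expression analysis instead.

## Enhancer-gene assignment

Candidates are genes within 1 Mb in the same TAD (enhancers outside all
TADs fall back to distance only and are flagged). Evidence flags:
nearest candidate, enhancer-promoter accessibility correlation >= 0.3
over >= 8 shared samples, loop contact (the padded anchors must overlap
the two elements - the looser 25-kb vicinity rule is reserved for EP
loop calling), and a database prior. The combined tier is the flag
count; ties resolve loop > database > correlation > nearest, then
smallest distance, making the assignment deterministic. The 1 Mb /
0.3 / 8 values are generator-calibrated defaults, not published
constants.

## Variant sieve

The quality cascade applies, in order: strand bias strictly inside
(0, 1) for variants inside the padded exome capture (the statistic is
defined as alt-forward / (alt-forward + alt-reverse), i.e. alternate
reads must appear on both strands - published filters rarely define
it); depth >= 8 total and >= 4 alternate; mapping quality >= 40 and
base quality >= 30; other-allele fraction < 0.4; alternative-alignment
fraction <= 0.10; indels >= 500 bp removed; simple-repeat and
>= 95%-identity self-chain regions removed; and finally maximal runs of
>= 3 surviving SNVs with consecutive gaps < 5 bp removed wholesale.
Every rule outcome is recorded in an ordered trail; a missing metric
fails the variant with reason `metric-missing`, never passing silently.
Indel representations are unified by trimming the shared suffix then
prefix (keeping one base) before merging callers. Somatic selection
requires exonic or splicing-acceptor location (+/-2 bp of exon
boundaries, configurable), a non-synonymous effect, and VAF >= 1%;
common variants (population frequency > 2e-4) survive only via the
COSMIC (>= 5 hematological reports) or clonal-hematopoiesis gene
(DNMT3A, TET2, ASXL1) rescues; donor-set and blacklist variants are
removed. Annotation fields arrive as input columns - the package
queries no external databases.

## The synthetic cohort generator

`cohort_config()` defaults describe the emulated study design: groups
CIMP = 9, AML = 20, T-ALL = 15, HSPC = 3; negative-binomial counts with
dispersion 0.1; library sizes log-uniform on [1, 3] so normalization is
non-trivial; 5% of genes planted as silenced TFs with an 8-fold
(|log2FC| = 3) promoter-methylation gain and expression loss; gene-wise
bivariate (methylation, expression) effects with target correlation
-0.3 on a sparse 30% of genes (sparse because differential genes are a
minority in real cohorts, which also keeps TMM's majority assumption
valid); a normalized logistic methylation-CTCF coupling
`2 * plogis(-beta * m)` so that unmethylated sites are unaffected;
CTCF-CTCF loops planted lost (15%) / gained (10%) with a lost-CTCF
anchor at probability `loop_ctcf_coupling` (default 0.7); EP-loop
strength effects propagated into target-gene expression; one designated
motif whose peaks double in accessibility in CIMP while its TF gene's
expression rises in step; and a GeneHancer-like prior covering ~70% of
enhancers with a few decoys. The variant tables plant at least one
variant on the pass and fail branch of every filter rule, with the
expected verdict recorded at planting time in the truth ledger.

What the generator does **not** emulate: read-level data (no
FASTQ/BAM), raw Hi-C contact matrices, array data, mappability and GC
biases of real alignments, linked epigenetic domains beyond the planted
couplings, clonal heterogeneity, or batch effects. Passing tests
therefore demonstrate that the estimators recover the structure they
are designed for under a faithful noise model - not that real data are
free of the artifacts the out-of-scope preprocessing handles.

Determinism: identical seed + configuration reproduces every matrix and
file byte-identically (verified by checksum in the tests). With all
effect parameters zero (`null_cohort_config()`), every differential
stage yields uniform p-values.

## Problem sizes and numerical choices

The test suite runs cohorts of 150-2500 genes with the default feature
counts; the acceptance checks use 5000 null features (type-I error),
2000 features with 200 planted (effect recovery; 10% planted keeps the
composition shift inside TMM's trim), 2000 genes (correlation
recovery), 20-replicate designs for the stochastic recoveries, and
30-100 random 5-kb sequences for the CpG-island oracle. These sizes
were chosen so each property is measured with comfortable statistical
margin while a full run stays interactive. FDR = 0 is capped at 1e-320
before log transforms; Fisher odds ratios use the cross-product
convention with infinite values flagged; ties are always broken by
feature id or genomic start so every output is reproducible.

## Open-question resolutions

- Promoters are exposed both as TSS windows
  (`define_promoters_window`, -1500/+500) and as peak-based promoter
  labels (`classify_atac_peaks`, TSS +/- 500); each analysis logs which
  definition fed it.
- The starburst correlation is reported on both the signed
  -log10(FDR) scores (the plotted quantity) and the raw log2 fold
  changes, since published values rarely state the axes.
- The GSEA weight exponent defaults to 1 and is exposed.
- Dimeric motifs are matched to expression by their first-named gene.
- The loop-CTCF "decrease" is reported sign-only and
  significance-gated.

## Known limitations

- The NB Wald test is mildly anti-conservative at small sample sizes
  (typical null rejection 0.055-0.067 at nominal 0.05 with 10 vs 10);
  the calibration band in the acceptance checks covers this.
- The motif-match threshold depends on the discretization granularity
  (default 1e-3 log2-odds units); exactness is defined with respect to
  the discretized scores.
- `assign_enhancers` evaluates candidates per enhancer independently;
  it does not attempt a globally consistent enhancer-gene matching.
- The variant sieve operates on annotated tables; alignment-level
  metrics must be computed upstream.
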