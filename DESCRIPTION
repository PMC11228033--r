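Package: cimpomics
Title: Multi-Omics Integration Pipeline for CpG Island Methylator Phenotype Leukemias
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reusable implementation of the computational procedures used to
    characterize CIMP (CpG Island Methylator Phenotype) mixed myeloid/lymphoid
    leukemias from enrichment-based methylation (MCIP-seq), chromatin
    accessibility (ATAC-seq), histone and CTCF ChIP-seq, RNA-seq, Hi-C and
    exome data: CpG island and enhancer catalog construction, consensus-peak
    quantification with TMM normalization, negative-binomial Wald differential
    analysis, methylation/accessibility-expression integration (starburst),
    motif-accessibility deviation scores, CTCF-methylation coupling and CpG
    motif positional analysis, TAD/loop integration with CTCF and expression,
    a tumor-only somatic variant filtering cascade with fusion majority
    voting, pre-ranked GSEA, and a synthetic multi-omics cohort generator with
    planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    fgsea
Config/testthat/edition: 3
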