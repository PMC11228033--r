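# Small shared cohort fixture, built once per test run.
.cohort_cache <- new.env(parent = emptyenv())

small_cohort <- function(seed = 1, n_genes = 400, null = FALSE, ...) {
  key <- paste(seed, n_genes, null,
               paste(deparse(list(...)), collapse = ""))
  if (is.null(.cohort_cache[[key]])) {
    cfg <- if (null) null_cohort_config(seed = seed, n_genes = n_genes, ...)
           else cohort_config(seed = seed, n_genes = n_genes, ...)
    g <- generate_genome(cfg)
    .cohort_cache[[key]] <- list(config = cfg, genome = g,
                                 sim = simulate_counts(g, cfg))
  }
  .cohort_cache[[key]]
}
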