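# End-to-end orchestration of the synthetic-cohort analysis and the
# top-variance feature selection used before clustering.

#' Select the top-variance features after a log transform
#'
#' Counts are scaled by size factors (effective library size normalized to
#' geometric mean 1), transformed with `log2(x + 1)`, and the `k` features
#' with the highest variance are returned; ties break deterministically by
#' feature id. Constant features are never selected while non-constant
#' features remain.
#'
#' @param m Feature x sample count matrix.
#' @param k Number of features to keep.
#' @param factors Optional [tmm_factors()] object.
#' @return Character vector of selected feature ids.
#' @export
top_variance_select <- function(m, k = 5000, factors = NULL) {
  m <- as.matrix(m)
  eff <- if (is.null(factors)) colSums(m) else factors$effective_lib_size
  sf <- eff / exp(mean(log(eff)))
  lt <- log2(sweep(m, 2, sf, "/") + 1)
  v <- apply(lt, 1, stats::var)
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  if (k > length(v)) {
    warning("k exceeds feature count; returning all features")
    k <- length(v)
  }
  ids[order(-v, ids)][seq_len(k)]
}

#' Run the full synthetic-cohort analysis
#'
#' Generates the genome and cohort, builds the ATAC consensus peak list
#' from the per-sample peak sets, normalizes with TMM, runs the
#' negative-binomial Wald differential tests for every assay
#' (CIMP vs AML by default), and executes the integrations: promoter
#' methylation-expression starburst, enhancer assignment and
#' accessibility-expression join, motif deviations and differential
#' activity, CTCF site classes, methylation coupling and CpG positional
#' enrichment, TAD boundary annotation, EP-loop calling, loop-CTCF linkage
#' and loop-expression correlation, and the variant sieve with fusion
#' voting. Set `stages` to run a subset.
#'
#' @param config A [cohort_config()].
#' @param contrast Two group labels, `c(reference, test)`.
#' @param stages Character subset of
#'   `c("epigenome", "motif", "ctcf", "hic", "variants")`.
#' @param out_dir Optional directory: writes the fixture bundle and a JSON
#'   run report.
#' @return List of class `"cohort_report"` with per-stage results and a
#'   `summary` list of the headline numbers.
#' @export
run_cohort_analysis <- function(config = cohort_config(),
                                contrast = c("AML", "CIMP"),
                                stages = c("epigenome", "motif", "ctcf",
                                           "hic", "variants"),
                                out_dir = NULL) {
  genome <- generate_genome(config)
  sim <- simulate_counts(genome, config)
  groups <- sim$samples$group
  rep <- list(config = config, genome = genome, sim = sim)
  summary <- list(n_genes = nrow(genome$genes),
                  n_samples = nrow(sim$samples))

  if ("epigenome" %in% stages) {
    master <- build_master_list(sim$atac_peaksets)
    factors_atac <- tmm_factors(sim$atac)
    diff_expr <- nb_wald(sim$expression, groups, contrast,
                         tmm_factors(sim$expression))
    diff_meth <- nb_wald(sim$mcip_promoters, groups, contrast,
                         tmm_factors(sim$mcip_promoters))
    diff_atac <- nb_wald(sim$atac, groups, contrast, factors_atac)
    star <- starburst_join(diff_meth, diff_expr,
                           annotation = data.frame(
                             gene_id = genome$genes$gene_id,
                             is_tf = genome$genes$is_tf,
                             is_hematopoietic = genome$genes$is_hematopoietic))
    promoters <- define_promoters_window(genome$genes)
    enh_int <- genomic_intervals(genome$enhancers$chrom,
                                 genome$enhancers$start,
                                 genome$enhancers$end,
                                 id = genome$enhancers$enhancer_id)
    prom_counts <- sim$atac[grep("^promopk_", rownames(sim$atac)), ,
                            drop = FALSE]
    rownames(prom_counts) <- sub("^promopk_", "", rownames(prom_counts))
    emap <- assign_enhancers(enh_int, genome$genes, genome$tads,
                             genome$loops, enh_counts = sim$atac,
                             prom_counts = prom_counts,
                             db_map = genome$db_map)
    ejoin <- enhancer_expression_join(diff_atac, emap, diff_expr)
    rep$epigenome <- list(master = master, diff_expr = diff_expr,
                          diff_meth = diff_meth, diff_atac = diff_atac,
                          starburst = star, enhancer_map = emap,
                          enhancer_join = ejoin)
    summary$n_master_peaks <- nrow(master)
    summary$starburst_r_signed <- star$r_signed
    summary$starburst_r_lfc <- star$r_lfc
    summary$n_hyper_silenced <-
      sum(star$records$class == "hypermethylated-silenced")
    summary$enhancer_target_recovery <-
      mean(emap$gene_id == sim$truth$enhancer_targets[emap$enhancer_id])
    summary$enhancer_join_r <- ejoin$r_lfc
  }

  if ("motif" %in% stages) {
    pwms <- filter_motifs_by_expression(sim$motifs, sim$tpm)
    matches <- scan_motifs(pwms, sim$peak_seqs)
    dev <- deviations(sim$atac, matches, sim$peak_gc,
                      seed = config$seed + 3L)
    dma <- differential_motif_activity(dev, groups, rev(contrast))
    tfc <- tf_expression_correlation(
      dev, stats::setNames(vapply(pwms, `[[`, "", "tf"),
                           vapply(pwms, `[[`, "", "id")), sim$tpm)
    rep$motif <- list(matches = matches, deviations = dev,
                      differential = dma, tf_correlation = tfc)
    pm <- sim$truth$planted_motif_id
    summary$planted_motif_delta <- dma$delta[dma$motif == pm]
    summary$planted_motif_p <- dma$pvalue[dma$motif == pm]
  }

  if ("ctcf" %in% stages) {
    diff_ctcf <- nb_wald(sim$ctcf, groups, contrast, tmm_factors(sim$ctcf))
    diff_mc <- nb_wald(sim$mcip_ctcf, groups, contrast,
                       tmm_factors(sim$mcip_ctcf))
    cls <- classify_ctcf_sites(diff_ctcf)
    ctcf_int <- genomic_intervals(genome$ctcf_sites$chrom,
                                  genome$ctcf_sites$start,
                                  genome$ctcf_sites$end,
                                  id = genome$ctcf_sites$site_id)
    coup <- coupling_correlation(diff_ctcf, ctcf_int, diff_mc, ctcf_int)
    pos_enr <- if (sum(cls == "lost") > 0 && sum(cls == "unchanged") > 0)
      positional_enrichment(genome$ctcf_sites$motif_seq[cls == "lost"],
                            genome$ctcf_sites$motif_seq[cls == "unchanged"])
    rep$ctcf <- list(diff_ctcf = diff_ctcf, diff_meth_ctcf = diff_mc,
                     classes = cls, coupling = coup,
                     positional = pos_enr)
    summary$ctcf_meth_spearman <- coup$spearman_rho
    summary$n_ctcf_lost <- sum(cls == "lost")
  }

  if ("hic" %in% stages) {
    if (is.null(rep$ctcf))
      stop("hic stage requires the ctcf stage")
    diff_loops <- differential_3d(sim$loop_scores, groups, contrast)
    diff_tads <- differential_3d(sim$tad_scores, groups, contrast)
    ctcf_int <- genomic_intervals(genome$ctcf_sites$chrom,
                                  genome$ctcf_sites$start,
                                  genome$ctcf_sites$end,
                                  id = genome$ctcf_sites$site_id)
    bounds <- annotate_boundaries(genome$tads, rep$ctcf$diff_ctcf, ctcf_int)
    promoters <- define_promoters_window(genome$genes, 500, 500)
    enh_int <- genomic_intervals(genome$enhancers$chrom,
                                 genome$enhancers$start,
                                 genome$enhancers$end,
                                 id = genome$enhancers$enhancer_id)
    ep <- call_ep_loops(genome$loops, enh_int, promoters)
    cc_loops <- genome$loops[genome$loops$type == "CTCF", ]
    link <- ctcf_loop_linkage(cc_loops, diff_loops, rep$ctcf$diff_ctcf,
                              ctcf_int)
    lec <- loop_expression_correlation(ep, diff_loops,
                                       rep$epigenome$diff_expr %||%
                                         nb_wald(sim$expression, groups,
                                                 contrast),
                                       significant_only = TRUE)
    rep$hic <- list(diff_loops = diff_loops, diff_tads = diff_tads,
                    boundaries = bounds, ep_loops = ep, linkage = link,
                    loop_expression = lec)
    summary$lost_loop_ctcf_fraction <- link$lost_fraction
    summary$gained_loop_ctcf_fraction <- link$gained_fraction
    summary$loop_expression_rho <- lec$rho
  }

  if ("variants" %in% stages) {
    vt <- simulate_variant_tables(genome, config)
    merged <- merge_caller_calls(vt$caller_tables)
    sieved <- apply_quality_filters(merged)
    som <- select_somatic(sieved[sieved$qc_pass, , drop = FALSE])
    onc <- flag_oncogenic(som[som$somatic_candidate, , drop = FALSE])
    fus <- fusion_majority_vote(vt$fusion_tables,
                                artifact_db = vt$artifact_db,
                                leukemia_genes = vt$leukemia_genes)
    truth <- vt$variants
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
    qc_truth <- truth$expected_qc_pass[match(key(sieved), key(truth))]
    rep$variants <- list(tables = vt, merged = merged, sieved = sieved,
                         somatic = som, oncogenic = onc, fusions = fus)
    summary$n_variants <- nrow(sieved)
    summary$variant_verdict_discrepancies <-
      sum(sieved$qc_pass != qc_truth, na.rm = TRUE) +
      sum(is.na(qc_truth))
    summary$n_somatic <- sum(som$somatic_candidate)
    summary$n_fusions_kept <- nrow(fus)
  }

  rep$summary <- summary
  class(rep) <- "cohort_report"
  if (!is.null(out_dir)) {
    vt <- rep$variants$tables %||% simulate_variant_tables(genome, config)
    write_fixture_bundle(genome, sim, vt, out_dir)
    jsonlite::write_json(summary, file.path(out_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  rep
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  for (nm in names(x$summary)) {
    val <- x$summary[[nm]]
    cat(sprintf("  %-32s %s\n", nm,
                if (is.numeric(val)) format(signif(val, 4)) else val))
  }
  invisible(x)
}
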