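base_variant <- function(n = 1, pos = 1000) {
  data.frame(chrom = "chr1", pos = pos + (seq_len(n) - 1) * 1000,
             ref = "A", alt = "T", type = "SNV",
             depth_total = 100, depth_alt = 30, VAF = 0.3,
             strand_bias = 0.5, mapping_quality = 60, base_quality = 35,
             other_allele_fraction = 0.1, alt_alignment_fraction = 0.02,
             indel_length = 0, in_capture_pad200 = TRUE,
             in_simple_repeat = FALSE, in_selfchain95 = FALSE,
             stringsAsFactors = FALSE)
}

test_that("variant normalization unifies padded representations", {
  nv <- normalize_variant(99, "CA", "CAT")
  expect_equal(nv, list(pos = 100, ref = "A", alt = "AT"))
  # suffix padding
  nv2 <- normalize_variant(100, "ATG", "AG")
  expect_equal(nv2$ref, "AT"); expect_equal(nv2$alt, "A")
  # SNV untouched
  expect_equal(normalize_variant(5, "C", "T"),
               list(pos = 5, ref = "C", alt = "T"))
})

test_that("caller merge deduplicates and accumulates caller provenance", {
  v <- base_variant(3)
  tabs <- list(c1 = v, c2 = v[1:2, ], c3 = v[1, , drop = FALSE])
  m <- merge_caller_calls(tabs)
  expect_equal(nrow(m), 3)
  expect_equal(m$n_callers, c(3L, 2L, 1L))
  expect_equal(m$callers[1], "c1,c2,c3")
  # differently represented indel unified
  ins <- base_variant(1, pos = 5000)
  ins$type <- "insertion"; ins$ref <- "A"; ins$alt <- "AT"
  pad <- ins; pad$pos <- 4999; pad$ref <- "CA"; pad$alt <- "CAT"
  m2 <- merge_caller_calls(list(a = ins, b = pad))
  expect_equal(nrow(m2), 1)
  expect_equal(m2$n_callers, 2L)
  expect_equal(nrow(merge_caller_calls(list())), 0)
})

test_that("quality rules fail exactly the planted branches", {
  cases <- list(
    list(mod = list(depth_total = 7), rule = "depth"),
    list(mod = list(depth_alt = 3), rule = "depth"),
    list(mod = list(strand_bias = 0), rule = "strand_bias"),
    list(mod = list(strand_bias = 1), rule = "strand_bias"),
    list(mod = list(mapping_quality = 39), rule = "alignment_quality"),
    list(mod = list(base_quality = 29), rule = "alignment_quality"),
    list(mod = list(other_allele_fraction = 0.4), rule = "other_allele"),
    list(mod = list(alt_alignment_fraction = 0.11), rule = "alt_alignment"),
    list(mod = list(type = "deletion", indel_length = 500),
         rule = "long_indel"),
    list(mod = list(in_simple_repeat = TRUE), rule = "simple_repeat"),
    list(mod = list(in_selfchain95 = TRUE), rule = "selfchain"))
  for (cs in cases) {
    v <- base_variant(1)
    for (nm in names(cs$mod)) v[[nm]] <- cs$mod[[nm]]
    out <- apply_quality_filters(v)
    expect_false(out$qc_pass, info = cs$rule)
    expect_match(out$fail_reasons, cs$rule)
  }
  # inclusive/exclusive edges that must pass
  edges <- list(list(depth_total = 8, depth_alt = 4),
                list(other_allele_fraction = 0.399),
                list(alt_alignment_fraction = 0.10),
                list(type = "deletion", indel_length = 499),
                list(strand_bias = 0, in_capture_pad200 = FALSE))
  for (mod in edges) {
    v <- base_variant(1)
    for (nm in names(mod)) v[[nm]] <- mod[[nm]]
    expect_true(apply_quality_filters(v)$qc_pass,
                info = paste(names(mod), collapse = ","))
  }
  # missing metric fails, never silently passes
  v <- base_variant(1); v$strand_bias <- NA_real_
  out <- apply_quality_filters(v)
  expect_false(out$qc_pass)
  expect_match(out$fail_reasons, "metric-missing")
})

test_that("SNV cluster rule removes gap<5 runs of three wholesale", {
  v <- base_variant(3)
  v$pos <- c(100, 103, 107)   # gaps 3 and 4 -> one run of three
  out <- apply_quality_filters(v)
  expect_equal(out$qc_pass, c(FALSE, FALSE, FALSE))
  v2 <- base_variant(3)
  v2$pos <- c(100, 103, 108)  # gap 5 breaks the run
  expect_true(all(apply_quality_filters(v2)$qc_pass))
  # a failing variant inside the window does not join the cluster
  v3 <- base_variant(3)
  v3$pos <- c(100, 103, 107)
  v3$depth_total[2] <- 5
  out3 <- apply_quality_filters(v3)
  expect_equal(out3$qc_pass, c(TRUE, FALSE, TRUE))
})

test_that("filter trail is total and matches the brute-force rule oracle", {
  co <- small_cohort()
  vt <- simulate_variant_tables(co$genome, co$config)
  merged <- merge_caller_calls(vt$caller_tables)
  out <- apply_quality_filters(merged)
  # trail records every rule for every variant
  expect_true(all(grepl("snv_cluster:", out$trail)))
  expect_equal(nrow(out), nrow(merged))
  ok <- !is.na(merged$strand_bias)
  oracle <- oracle_variant_verdicts(merged[ok, ])
  expect_equal(out$qc_pass[ok], oracle)
  # and the truth-ledger verdicts agree exactly
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt)
  truth <- vt$variants$expected_qc_pass[match(key(out), key(vt$variants))]
  expect_equal(sum(out$qc_pass != truth), 0)
})

test_that("somatic selection applies rescues and exclusions as stated", {
  v <- base_variant(8)
  v$region_class <- c("exonic", "intronic", rep("exonic", 6))
  v$exonic_func <- c("nonsynonymous_SNV", "nonsynonymous_SNV",
                     "synonymous_SNV", rep("nonsynonymous_SNV", 5))
  v$VAF <- c(0.3, 0.3, 0.3, 0.009, rep(0.3, 4))
  v$popfreq <- c(0, 0, 0, 0, 0.001, 0.001, 0.001, 0)
  v$cosmic_heme_count <- c(0, 0, 0, 0, 6, 0, 0, 0)
  v$gene <- c(rep("GENE1", 5), "DNMT3A", "GENE2", "GENE3")
  v$in_donor_set <- c(rep(FALSE, 7), TRUE)
  v$in_panel_blacklist <- FALSE
  out <- select_somatic(v)
  expect_equal(out$somatic_candidate,
               c(TRUE, FALSE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(out$somatic_reason[5], "rescued")
  expect_equal(out$somatic_reason[7], "popfreq")
})

test_that("oncogenic flags follow the three conditions", {
  v <- data.frame(in_cosmic = c(FALSE, TRUE, FALSE, FALSE),
                  exonic_func = c("stopgain", "nonsynonymous_SNV",
                                  "nonsynonymous_SNV", "nonsynonymous_SNV"),
                  damaging_prediction_majority = c(FALSE, FALSE, TRUE,
                                                   FALSE))
  out <- flag_oncogenic(v)
  expect_equal(out$oncogenic, c(TRUE, TRUE, TRUE, FALSE))
  expect_equal(out$oncogenic_source[1:3],
               c("truncating", "cosmic", "prediction"))
})

test_that("fusion vote excludes artifacts first, then requires 3 tools", {
  co <- small_cohort()
  vt <- simulate_variant_tables(co$genome, co$config)
  fus <- fusion_majority_vote(vt$fusion_tables,
                              artifact_db = vt$artifact_db,
                              leukemia_genes = vt$leukemia_genes)
  got <- fus[order(fus$sample), c("sample", "gene5", "gene3")]
  rownames(got) <- NULL
  expect_equal(got, vt$expected_kept_fusions)
  expect_true(all(fus$n_tools >= 3))
  expect_true(all(fus$leukemia_flag))
})
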