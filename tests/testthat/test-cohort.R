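test_that("config validation rejects degenerate inputs", {
  expect_error(cohort_config(n_genes = 0), "positive")
  expect_error(cohort_config(nb_dispersion = 0), "dispersion")
  expect_error(cohort_config(frac_silenced_tfs = 1.5), "fractions")
  expect_error(cohort_config(meth_expr_rho = 0.5), "meth_expr_rho")
  expect_error(generate_genome(cohort_config(n_genes = 1e5,
                                             genome_length = 1e6)),
               "genome_length too small")
})

test_that("genome generation is deterministic and seed-sensitive", {
  cfg <- cohort_config(n_genes = 200)
  g1 <- generate_genome(cfg)
  g2 <- generate_genome(cfg)
  expect_identical(g1, g2)
  g3 <- generate_genome(cohort_config(seed = 2, n_genes = 200))
  expect_false(identical(g1$cgi_truth, g3$cgi_truth))
  # structural invariants
  expect_true(all(g1$tads$start < g1$tads$end))
  expect_equal(g1$tads$start[-1], g1$tads$end[-nrow(g1$tads)]) # tiling
  expect_true(all(nchar(g1$ctcf_sites$motif_seq) == 19))
  # flagged sites carry a CpG where declared
  s5 <- substr(g1$ctcf_sites$motif_seq, 5, 6)
  expect_true(all(s5[g1$ctcf_sites$has_cpg_5] == "CG"))
  expect_true(all(s5[!g1$ctcf_sites$has_cpg_5] != "CG"))
  # every EP loop promoter anchor within 25 kb of a TSS
  ep <- g1$loops[g1$loops$type == "EP", ]
  tssd <- vapply(seq_len(nrow(ep)), function(i) {
    tss <- g1$genes$tss[g1$genes$gene_id == ep$gene_id[i]]
    min(abs(tss - c(ep$start1[i], ep$end1[i], ep$start2[i], ep$end2[i])))
  }, 0)
  expect_true(all(tssd <= 25000))
})

test_that("simulated counts match their configured means and effects", {
  co <- small_cohort(seed = 41, n_genes = 2000, frac_silenced_tfs = 0.05)
  sim <- co$sim
  gr <- sim$samples$group
  lib <- sim$samples$lib_factor
  expect_gte(max(lib) / min(lib), 2.5)
  # silenced TFs: CIMP/AML expression ratio ~ 2^-3 (library-corrected)
  sil <- sim$truth$silenced_tf_ids
  norm <- sweep(sim$expression, 2, lib, "/")
  ratio <- rowMeans(norm[sil, gr == "CIMP"]) /
    rowMeans(norm[sil, gr == "AML"])
  expect_lt(abs(median(log2(ratio)) - (-3)), 0.35)
  # promoter methylation up by the mirrored effect
  normm <- sweep(sim$mcip_promoters, 2, lib, "/")
  ratio_m <- rowMeans(normm[sil, gr == "CIMP"]) /
    rowMeans(normm[sil, gr == "AML"])
  expect_lt(abs(median(log2(ratio_m)) - 3), 0.35)
  # NB moments: empirical dispersion near configured value
  base <- sim$expression[, gr == "AML"]
  m <- rowMeans(sweep(base, 2, lib[gr == "AML"], "/"))
  v <- apply(sweep(base, 2, lib[gr == "AML"], "/"), 1, var)
  disp <- median((v - m) / m^2, na.rm = TRUE)
  expect_lt(abs(disp - co$config$nb_dispersion), 0.06)
})

test_that("CTCF coupling suppresses flagged hypermethylated sites", {
  co <- small_cohort(seed = 42, n_genes = 300, ctcf_coupling_beta = 6,
                     n_regions = c(ctcf = 1000))
  sim <- co$sim; g <- co$genome
  gr <- sim$samples$group; lib <- sim$samples$lib_factor
  lost <- g$ctcf_sites$site_id %in% sim$truth$lost_ctcf_site_ids
  norm <- sweep(sim$ctcf, 2, lib, "/")
  ratio <- rowMeans(norm[, gr == "CIMP"]) / rowMeans(norm[, gr == "AML"])
  expect_gte(mean(ratio[lost] < 1), 0.9)
  expect_lt(mean(ratio[lost]), mean(ratio[!lost]))
})

test_that("null cohort produces uniform differential p-values", {
  co <- small_cohort(seed = 43, n_genes = 2500, null = TRUE)
  gr <- co$sim$samples$group
  res <- nb_wald(co$sim$expression, gr, c("AML", "CIMP"),
                 tmm_factors(co$sim$expression))
  p <- res$pvalue[!is.na(res$pvalue)]
  expect_gt(suppressWarnings(ks.test(p, "punif")$p.value), 0.01)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})

test_that("variant tables are deterministic and cover every rule branch", {
  co <- small_cohort(n_genes = 200)
  vt1 <- simulate_variant_tables(co$genome, co$config)
  vt2 <- simulate_variant_tables(co$genome, co$config)
  expect_identical(vt1, vt2)
  rules <- vt1$variants$planted_rule
  needed <- c("strand_bias_zero", "depth_total_low", "depth_alt_low",
              "mapping_quality_low", "base_quality_low",
              "other_allele_at_limit", "alt_alignment_high", "indel_500",
              "simple_repeat", "selfchain", "snv_cluster",
              "metric_missing", "region_intronic", "synonymous",
              "vaf_low", "popfreq_excluded", "popfreq_cosmic_rescue",
              "popfreq_ch_gene_rescue", "donor_removed",
              "blacklist_removed")
  expect_true(all(needed %in% rules))
  expect_gte(nrow(vt1$variants), 200)
})

test_that("fixture bundle round-trips through the package readers", {
  co <- small_cohort(n_genes = 200)
  vt <- simulate_variant_tables(co$genome, co$config)
  dir <- withr::local_tempdir()
  man <- write_fixture_bundle(co$genome, co$sim, vt, dir)
  expect_true(all(c("tss.bed", "loops.bedpe", "motifs.jaspar") %in%
                    man$file))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  # narrowPeak: 10 columns, half-open, q in column 9
  npf <- file.path(dir, sprintf("atac_%s.narrowPeak",
                                co$sim$samples$sample[1]))
  raw <- read.table(npf, sep = "\t")
  expect_equal(ncol(raw), 10)
  pk <- read_narrowpeak(npf)
  orig <- co$sim$atac_peaksets[[1]]
  expect_equal(pk$start, orig$start)
  expect_equal(pk$neglog10q, orig$neglog10q)
  # BEDPE anchors ordered
  lp <- read_bedpe(file.path(dir, "loops.bedpe"))
  expect_true(all(lp$start1 < lp$start2))
  expect_equal(lp$start1, co$genome$loops$start1)
  # count matrix round-trip
  m <- read_counts_tsv(file.path(dir, "expression_counts.tsv"))
  expect_equal(m, co$sim$expression)
  # PWM round-trip (probabilities re-normalized from scaled counts)
  pwms <- read_jaspar(file.path(dir, "motifs.jaspar"), pseudo = 0)
  expect_equal(length(pwms), length(co$sim$motifs))
  expect_equal(pwms[[1]]$prob, co$sim$motifs[[1]]$prob, tolerance = 1e-5)
  # determinism: rewriting yields identical checksums
  dir2 <- withr::local_tempdir()
  man2 <- write_fixture_bundle(co$genome, co$sim, vt, dir2)
  expect_equal(man$md5, man2$md5)
  suppressWarnings(
    expect_error(write_fixture_bundle(co$genome, co$sim, vt,
                                      "/dev/null/nope"),
                 "directory|create"))
})
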