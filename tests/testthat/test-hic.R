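test_that("boundary annotation keeps the smallest-FDR peak deterministically", {
  tads <- genomic_intervals("chr1", c(0, 100000), c(100000, 200000),
                            id = c("t1", "t2"))
  peaks <- genomic_intervals("chr1", c(98000, 99000, 99100),
                             c(99000, 101000, 99500),
                             id = c("pA", "pB", "pC"))
  dc <- data.frame(feature = c("pA", "pB", "pC"),
                   log2FC = c(-1, 0.5, 2), FDR = c(0.3, 0.01, 0.01))
  b <- annotate_boundaries(tads, dc, peaks)
  expect_equal(nrow(b), 4)  # two boundaries per TAD
  right_t1 <- b[b$tad_id == "t1" & b$side == "right", ]
  # boundary [97500,102500): pB and pC tie at FDR 0.01; pB starts first
  expect_equal(right_t1$ctcf_feature, "pB")
  left_t1 <- b[b$tad_id == "t1" & b$side == "left", ]
  expect_true(is.na(left_t1$ctcf_feature))  # no peak, TAD still emitted
  # idempotent and input-order independent
  b2 <- annotate_boundaries(tads, dc[c(3, 1, 2), ], peaks[c(3, 1, 2), ])
  expect_equal(b2$ctcf_feature, b$ctcf_feature)
})

test_that("EP loop calling obeys the inclusive 25 kb opposite-anchor rule", {
  enh <- genomic_intervals("chr1", 100000, 100600, id = "e1")
  prom <- genomic_intervals("chr1", 500000, 501000, id = "gA")
  mkloop <- function(s1, s2, id) {
    data.frame(chrom = "chr1", start1 = s1, end1 = s1 + 5000,
               start2 = s2, end2 = s2 + 5000, id = id,
               stringsAsFactors = FALSE)
  }
  loops <- rbind(
    mkloop(90000, 480000, "ep_ok"),      # both within 25 kb of padded anchors
    mkloop(90000, 90200, "same_side"),   # enhancer and promoter same anchor
    mkloop(100600 + 5000 + 25000, 480000, "exact_25k"),
    mkloop(200000, 300000, "far"))
  res <- call_ep_loops(loops, enh, prom)
  expect_true(res$ep[res$id == "ep_ok"])
  expect_equal(res$gene_id[res$id == "ep_ok"], "gA")
  expect_false(res$ep[res$id == "same_side"])
  # anchor1 padded start = 130600 - 5000 = 125600; gap to enhancer end
  # 100600 is exactly 25000 -> inclusive
  expect_true(res$ep[res$id == "exact_25k"])
  expect_false(res$ep[res$id == "far"])
})

test_that("EP flagging equals the brute-force all-pairs oracle on random toys", {
  set.seed(31)
  for (rep in 1:5) {
    es <- sort(sample(1:5e5, 8)); ps <- sort(sample(1:5e5, 8))
    enh <- genomic_intervals("chr1", es, es + 600, id = paste0("e", 1:8))
    prom <- genomic_intervals("chr1", ps, ps + 1000, id = paste0("g", 1:8))
    s1 <- sample(1:4e5, 12); s2 <- s1 + sample(5e4:2e5, 12)
    loops <- data.frame(chrom = "chr1", start1 = s1, end1 = s1 + 5000,
                        start2 = s2, end2 = s2 + 5000,
                        id = paste0("l", 1:12), stringsAsFactors = FALSE)
    got <- call_ep_loops(loops, enh, prom)$ep
    expect_equal(got, oracle_ep_loops(loops, enh, prom),
                 info = paste("toy", rep))
  }
})

test_that("differential 3D recovers planted loop changes and negates on swap", {
  co <- small_cohort()
  gr <- co$sim$samples$group
  d1 <- differential_3d(co$sim$loop_scores, gr, c("AML", "CIMP"))
  d2 <- differential_3d(co$sim$loop_scores, gr, c("CIMP", "AML"))
  expect_lt(max(abs(d1$log2FC + d2$log2FC), na.rm = TRUE), 1e-6)
  lost <- co$sim$truth$lost_loop_ids
  lost_cc <- intersect(lost, co$genome$loops$id[co$genome$loops$type == "CTCF"])
  hit <- d1$FDR[match(lost_cc, d1$feature)] < 0.05 &
    d1$log2FC[match(lost_cc, d1$feature)] < 0
  expect_gte(mean(hit), 0.8)
  # lognormal mode for non-integer scores
  sc <- co$sim$loop_scores + 0.25
  dl <- differential_3d(sc, gr, c("AML", "CIMP"))
  expect_equal(attr(dl, "mode"), "lognormal")
  expect_true(all(dl$FDR >= dl$pvalue, na.rm = TRUE))
})

test_that("loop-CTCF linkage is extreme under full coupling and detects direction", {
  co <- small_cohort(seed = 32, n_genes = 300, loop_ctcf_coupling = 1)
  gr <- co$sim$samples$group
  g <- co$genome
  cc <- g$loops[g$loops$type == "CTCF", ]
  dl <- differential_3d(co$sim$loop_scores, gr, c("AML", "CIMP"))
  dc <- nb_wald(co$sim$ctcf, gr, c("AML", "CIMP"),
                tmm_factors(co$sim$ctcf))
  ivs <- genomic_intervals(g$ctcf_sites$chrom, g$ctcf_sites$start,
                           g$ctcf_sites$end, id = g$ctcf_sites$site_id)
  link <- ctcf_loop_linkage(cc, dl, dc, ivs)
  # every planted-lost loop carries a truly lost anchor under full coupling
  planted_lost <- cc$id[cc$planted_change == "lost"]
  est_lost <- link$loop_class == "lost"
  expect_gte(link$lost_fraction, 0.9)
  expect_gt(link$lost_fraction, link$gained_fraction)
  expect_true(all(link$lost_fraction >= 0, link$lost_fraction <= 1,
                  link$gained_fraction >= 0, link$gained_fraction <= 1))
  expect_lt(link$mean_delta_lost, link$mean_delta_gained)
})

test_that("loop-expression correlation recovers planted coupling and its null", {
  co <- small_cohort()
  gr <- co$sim$samples$group
  g <- co$genome
  promoters <- define_promoters_window(g$genes, 500, 500)
  enh_int <- genomic_intervals(g$enhancers$chrom, g$enhancers$start,
                               g$enhancers$end, id = g$enhancers$enhancer_id)
  ep <- call_ep_loops(g$loops, enh_int, promoters)
  dl <- differential_3d(co$sim$loop_scores, gr, c("AML", "CIMP"))
  de <- nb_wald(co$sim$expression, gr, c("AML", "CIMP"),
                tmm_factors(co$sim$expression))
  lec <- loop_expression_correlation(ep, dl, de)
  expect_gt(lec$rho, 0.5)
  # shuffled gene assignment: mean permuted rho near zero
  set.seed(33)
  perm_rho <- vapply(1:50, function(i) {
    ep2 <- ep
    ep2$gene_id[ep2$ep] <- sample(ep2$gene_id[ep2$ep])
    loop_expression_correlation(ep2, dl, de)$rho
  }, 0)
  expect_lt(abs(mean(perm_rho)), 0.1)
})

test_that("CTCF 3D overlap fractions are consistent", {
  peaks <- genomic_intervals("chr1", c(1000, 50000, 90000),
                             c(1400, 50400, 90400))
  bounds <- genomic_intervals("chr1", c(900, 49000), c(1500, 51000))
  anchors <- genomic_intervals("chr1", 89000, 95000)
  s <- summarize_ctcf_3d_overlap(peaks, bounds, anchors,
                                 variable = c(TRUE, FALSE, FALSE))
  expect_equal(s$boundary_fraction, 2 / 3)
  expect_equal(s$anchor_fraction, 1 / 3)
  # stratified fractions recombine to the overall fraction
  expect_equal((s$boundary_fraction_variable * 1 +
                  s$boundary_fraction_unchanged * 2) / 3,
               s$boundary_fraction)
})
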