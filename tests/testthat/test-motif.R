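strong_pwm <- function(id = "T01", tf = "TFX", consensus = "ACGTACGTAA",
                       strength = 0.9) {
  b <- strsplit(consensus, "")[[1]]
  m <- matrix((1 - strength) / 3, 4, length(b),
              dimnames = list(c("A", "C", "G", "T")))
  for (k in seq_along(b)) m[b[k], k] <- strength
  motif_pwm(id, tf, m)
}

revcomp <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

test_that("motif scanning finds consensus hits on both strands", {
  pwm <- strong_pwm()
  cons <- "ACGTACGTAA"
  seqs <- c(hit = paste0(strrep("T", 60), cons, strrep("T", 60)),
            rc = paste0(strrep("T", 60), revcomp(cons), strrep("T", 60)),
            miss = strrep("TA", 60),
            short = "ACG")
  m <- scan_motifs(list(pwm), seqs)
  expect_true(m["hit", "T01"])
  expect_true(m["rc", "T01"])
  expect_false(m["miss", "T01"])
  expect_false(m["short", "T01"])
})

test_that("score threshold equals exhaustive k-mer enumeration (length <= 8)", {
  set.seed(8)
  for (len in c(5, 7)) {
    cons <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = "")
    pwm <- strong_pwm("e1", "E1", cons, strength = 0.8)
    sc <- cimpomics:::pwm_scoring(pwm, p_threshold = 5e-5)
    # enumerate all k-mers with identical integer discretization
    si <- round(log2(pwm$prob / pwm$background) / 1e-3)
    kmers <- as.matrix(expand.grid(rep(list(1:4), len)))
    scores <- numeric(nrow(kmers))
    for (k in seq_len(len)) scores <- scores + si[cbind(kmers[, k], k)]
    # group k-mers by score so tied scores share one tail probability
    us <- sort(unique(scores), decreasing = TRUE)
    grp_p <- vapply(us, function(s) sum(scores == s) / 4^len, 0)
    tailp <- cumsum(grp_p)
    qualifying <- us[tailp <= 5e-5]
    expected_thr <- if (length(qualifying)) min(qualifying) else
      max(scores) + 1
    expect_equal(sc$threshold, expected_thr)
  }
})

test_that("expression filter keeps motifs at the inclusive TPM threshold", {
  pwms <- list(strong_pwm("a", "TF_ON"), strong_pwm("b", "TF_OFF"),
               strong_pwm("c", "TF_EDGE"), strong_pwm("d", "DIMER::X"))
  tpm <- rbind(TF_ON = c(5, 0), TF_OFF = c(0, 0), TF_EDGE = c(1, 0))
  colnames(tpm) <- c("s1", "s2")
  expect_warning(kept <- filter_motifs_by_expression(pwms, tpm),
                 "DIMER")
  expect_equal(vapply(kept, `[[`, "", "id"), c("a", "c", "d"))
})

test_that("deviations are near zero without compositional signal and reproducible", {
  set.seed(9)
  profile <- rpois(120, 60)
  counts <- outer(profile, c(1L, 2L, 4L, 1L, 3L, 2L))  # pure depth scaling
  dimnames(counts) <- list(paste0("p", 1:120), paste0("s", 1:6))
  matches <- matrix(FALSE, 120, 2, dimnames = list(rownames(counts),
                                                   c("m1", "m2")))
  matches[1:30, 1] <- TRUE
  gc <- runif(120, 0.3, 0.7)
  d1 <- deviations(counts, matches, gc, seed = 4)
  expect_true(all(abs(d1$raw[1, ]) < 1e-12))  # exact proportionality
  expect_true(all(is.na(d1$z["m2", ])))
  expect_equal(d1$flagged, "m2")
  d2 <- deviations(counts, matches, gc, seed = 4)
  expect_identical(d1$z, d2$z)
})

test_that("planted group signal yields correct-sign differential deviations", {
  co <- small_cohort()
  sim <- co$sim
  pwms <- sim$motifs
  matches <- scan_motifs(pwms, sim$peak_seqs)
  dev <- deviations(sim$atac, matches, sim$peak_gc, seed = 7)
  dma <- differential_motif_activity(dev, sim$samples$group,
                                     c("CIMP", "AML"))
  pm <- sim$truth$planted_motif_id
  expect_gt(dma$delta[dma$motif == pm], 0.01)
  expect_lt(dma$pvalue[dma$motif == pm], 0.01)
  expect_true(dma$significant[dma$motif == pm])
  # permuting sample labels destroys the group difference
  set.seed(10)
  perm <- sample(sim$samples$group)
  dma_p <- differential_motif_activity(dev, perm, c("CIMP", "AML"))
  expect_lt(abs(dma_p$delta[dma_p$motif == pm]),
            abs(dma$delta[dma$motif == pm]) / 2)
})

test_that("differential activity applies the dual significance gates", {
  z <- rbind(m1 = c(rep(1, 10), rep(0, 10)),
             m2 = c(rep(0.005, 10), rep(0, 10)),
             m3 = rnorm(20, 0, 1e-3))
  colnames(z) <- paste0("s", 1:20)
  groups <- rep(c("A", "B"), each = 10)
  res <- differential_motif_activity(z, groups, c("A", "B"))
  expect_true(res$significant[res$motif == "m1"])
  expect_false(res$significant[res$motif == "m2"])   # delta gate
  expect_false(res$significant[res$motif == "m3"])   # p gate
})

test_that("TF-expression correlation identifies the planted activator", {
  co <- small_cohort()
  sim <- co$sim
  matches <- scan_motifs(sim$motifs, sim$peak_seqs)
  dev <- deviations(sim$atac, matches, sim$peak_gc, seed = 7)
  tf_of <- setNames(vapply(sim$motifs, `[[`, "", "tf"),
                    vapply(sim$motifs, `[[`, "", "id"))
  tfc <- tf_expression_correlation(dev, tf_of, sim$tpm)
  pm <- sim$truth$planted_motif_id
  expect_gt(tfc$r[tfc$motif == pm], 0.5)
  expect_true(tfc$putative_positive_regulator[tfc$motif == pm])
  # affine relation gives r = 1
  z <- matrix(1:10, 1, dimnames = list("mx", paste0("s", 1:10)))
  e <- matrix(2 * (1:10) + 5, 1, dimnames = list("GX", paste0("s", 1:10)))
  r1 <- tf_expression_correlation(z, c(mx = "GX"), e)
  expect_equal(r1$r, 1)
})

test_that("footprint score measures center depletion", {
  flat <- matrix(5, 10, 101)
  expect_equal(footprint_score(flat, 21, 30), 0)
  dip <- flat; dip[, 41:61] <- 3
  expect_equal(footprint_score(dip, 21, 30), 2)
  # planted bound sites score above unbound in most replicates
  set.seed(13)
  wins <- vapply(1:20, function(i) {
    bound <- matrix(rpois(50 * 101, 10), 50, 101)
    bound[, 45:57] <- matrix(rpois(50 * 13, 5), 50, 13)
    unbound <- matrix(rpois(50 * 101, 10), 50, 101)
    footprint_score(bound, 13, 30) > footprint_score(unbound, 13, 30)
  }, TRUE)
  expect_gte(mean(wins), 0.95)
})
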