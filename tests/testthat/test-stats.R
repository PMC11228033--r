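sim_counts <- function(nfeat, n1, n2, mu = 100, dispersion = 0.1,
                       lfc = 0, frac_affected = 0) {
  n <- n1 + n2
  lib <- exp(runif(n, 0, log(3)))
  mu_mat <- matrix(mu, nfeat, n)
  affected <- seq_len(floor(nfeat * frac_affected))
  if (length(affected))
    mu_mat[affected, (n1 + 1):n] <- mu * 2^lfc
  mu_mat <- sweep(mu_mat, 2, lib, "*")
  m <- matrix(rnbinom(nfeat * n, mu = mu_mat, size = 1 / dispersion),
              nfeat, n, dimnames = list(paste0("f", seq_len(nfeat)),
                                        paste0("s", seq_len(n))))
  list(counts = m, groups = rep(c("g1", "g2"), c(n1, n2)),
       affected = affected)
}

test_that("nb_wald flags degenerate features and validates inputs", {
  set.seed(1)
  d <- sim_counts(20, 4, 4)
  d$counts[1, ] <- 0
  res <- nb_wald(d$counts, d$groups, c("g1", "g2"))
  expect_equal(res$status[1], "all-zero")
  expect_true(is.na(res$log2FC[1]) && is.na(res$FDR[1]))
  expect_equal(nrow(res), 20)
  expect_error(nb_wald(d$counts, d$groups, c("g1", "gX")), "unknown group")
  expect_error(nb_wald(d$counts[, 1:5], d$groups[1:5], c("g1", "g2")),
               "at least 2 samples")
})

test_that("nb_wald is symmetric under contrast swap and recovers planted effects", {
  set.seed(2)
  # a small planted fraction, as TMM assumes a majority of unchanged features
  d <- sim_counts(400, 8, 8, lfc = -2, frac_affected = 0.05)
  f <- tmm_factors(d$counts)
  r12 <- nb_wald(d$counts, d$groups, c("g1", "g2"), factors = f)
  r21 <- nb_wald(d$counts, d$groups, c("g2", "g1"), factors = f)
  expect_lt(max(abs(r12$log2FC + r21$log2FC)), 1e-6)
  expect_lt(max(abs(r12$pvalue - r21$pvalue)), 1e-8)
  expect_lt(abs(median(r12$log2FC[d$affected]) - (-2)), 0.3)
  expect_lt(abs(median(r12$log2FC[-d$affected])), 0.2)
  # FDR >= p elementwise and in [0,1]
  ok <- !is.na(r12$FDR)
  expect_true(all(r12$FDR[ok] >= r12$pvalue[ok]))
  expect_true(all(r12$FDR[ok] <= 1))
})

test_that("welch_cohen computes Cohen's d by the pooled-sd formula", {
  set.seed(3)
  g1 <- rnorm(20, 2, 1); g2 <- rnorm(20, 1, 1)
  es <- welch_cohen(g1, g2)
  expect_equal(es$cohen_d,
               (mean(g1) - mean(g2)) / sqrt((var(g1) + var(g2)) / 2))
  expect_equal(es$welch_p, t.test(g1, g2)$p.value)
  # scale equivariance
  es2 <- welch_cohen(3 * g1, 3 * g2)
  expect_equal(es2$cohen_d, es$cohen_d)
  # sign and labels
  expect_equal(sign(es$cohen_d), sign(mean(g1) - mean(g2)))
  # base vector has mean 0 and sd 1, so a shift of delta gives d = delta
  base <- c(-1, 0, 1)
  expect_equal(welch_cohen(base + 0.1, base)$cohen_d, 0.1)
  expect_equal(welch_cohen(base + 0.1, base)$size_label, "small")
  expect_equal(welch_cohen(base + 0.9, base)$size_label, "large")
  expect_equal(welch_cohen(base + 0.5, base)$size_label, "medium")
  expect_equal(welch_cohen(c(1, 1, 1), c(1, 1, 1))$flag, "zero-variance")
})

test_that("fisher enrichment matches the hypergeometric tail and OR convention", {
  # universe of 100 regions: 8 query&set, 2 query only, 10 set only, 80 rest
  u <- genomic_intervals("chr1", (0:99) * 1000, (0:99) * 1000 + 100)
  query <- u[1:10, ]
  setA <- u[c(1:8, 11:20), ]
  res <- fisher_region_enrichment(query, u, list(A = setA))
  expect_equal(res$a, 8); expect_equal(res$b, 2)
  expect_equal(res$c, 10); expect_equal(res$d, 80)
  expect_equal(res$odds_ratio, 32.0)
  # exact enumeration of the hypergeometric upper tail
  p_exact <- sum(dhyper(8:10, 18, 82, 10))
  expect_equal(res$pvalue, p_exact, tolerance = 1e-12)
  # perfect-coincidence table yields flagged infinite OR
  res2 <- fisher_region_enrichment(u[1:50, ], u, list(A = u[1:50, ]))
  expect_true(is.infinite(res2$odds_ratio) && res2$flagged)
  expect_error(fisher_region_enrichment(query, u[0, ], list(A = setA)),
               "empty universe")
})

test_that("rank metric is signed -log10(FDR) with caps and deterministic ties", {
  diff <- data.frame(feature = c("b", "a", "c", "d", "e"),
                     log2FC = c(-1, 1, 2, -2, 1),
                     FDR = c(0.01, 0.01, 1, 0, NA))
  m <- rank_metric(diff)
  expect_equal(unname(m["b"]), -2)
  expect_equal(unname(m["a"]), 2)
  expect_equal(unname(m["c"]), 0)
  expect_equal(unname(m["d"]), -320)
  expect_false("e" %in% names(m))
  expect_equal(attr(m, "capped"), "d")
  # ties broken by feature id; sorted decreasing
  expect_equal(names(m), c("a", "c", "b", "d"))
})

test_that("GSEA ES equals the brute-force running sum and behaves at extremes", {
  set.seed(5)
  metric <- sort(rnorm(10), decreasing = TRUE)
  names(metric) <- letters[1:10]
  set3 <- c("a", "d", "h")
  res <- preranked_gsea(metric, list(s = set3), min_size = 3, n_perm = 50,
                        seed = 1)
  expect_equal(res$ES, oracle_gsea_es(metric, set3), tolerance = 1e-12)
  expect_true(abs(res$ES) <= 1)

  # strictly decreasing 1000-gene ranking, set = top 20
  metric2 <- seq(1000, 1, -1) / 100
  names(metric2) <- sprintf("g%04d", 1:1000)
  top <- names(metric2)[1:20]
  res2 <- preranked_gsea(metric2, list(top = top), min_size = 15,
                         n_perm = 100, seed = 1)
  expect_gte(res2$ES, 0.9)
  expect_lt(res2$pvalue, 0.05)

  # complement-set identity under weight 0 (classic KS)
  es_set <- preranked_gsea(metric, list(s = set3), min_size = 3, n_perm = 10,
                           weight = 0, seed = 1)$ES
  es_comp <- preranked_gsea(metric, list(s = setdiff(names(metric), set3)),
                            min_size = 3, n_perm = 10, weight = 0,
                            seed = 1)$ES
  expect_equal(es_set, -es_comp, tolerance = 1e-12)

  # undersized sets are skipped with a note
  res3 <- preranked_gsea(metric, list(tiny = c("a", "b")), min_size = 3,
                         n_perm = 10, seed = 1)
  expect_equal(attr(res3, "skipped"), "tiny")
})

test_that("GSEA ES agrees with fgsea on a fixed ranking", {
  skip_if_not_installed("fgsea")
  set.seed(6)
  metric <- sort(rnorm(200), decreasing = TRUE)
  names(metric) <- sprintf("g%03d", 1:200)
  sets <- list(A = sample(names(metric), 25), B = sample(names(metric), 40))
  res <- preranked_gsea(metric, sets, min_size = 15, n_perm = 100, seed = 1)
  fg <- suppressWarnings(fgsea::fgsea(sets, metric, minSize = 15,
                                      maxSize = 5000, nproc = 1))
  expect_equal(res$ES[match(fg$pathway, res$set)], fg$ES, tolerance = 1e-10)
})
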