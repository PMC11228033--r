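# Core statistics: negative-binomial Wald differential test, Welch's t with
# Cohen's d, one-sided Fisher region-set enrichment, GSEA ranking metric,
# and pre-ranked GSEA with gene-label permutation p-values.

#' Negative-binomial Wald differential test for a two-group contrast
#'
#' Fits, per feature, a negative-binomial log-linear model with a group
#' indicator and offsets equal to the log effective library size, using a
#' per-feature method-of-moments dispersion estimate (floored). The Wald
#' statistic is `log2FC / SE`, with a two-sided normal p-value and
#' Benjamini-Hochberg FDR across tested features. All-zero features are
#' returned as `NA` with `status = "all-zero"`, never dropped.
#'
#' @param counts Feature x sample matrix of non-negative counts.
#' @param groups Group label per sample (character or factor).
#' @param contrast Length-2 character vector `c(group1, group2)`; fold
#'   changes are group2 vs group1.
#' @param factors Optional [tmm_factors()] object; otherwise effective
#'   library sizes default to column sums.
#' @param dispersion_floor Lower bound on the dispersion estimate.
#' @return Data frame with columns `feature`, `baseMean`, `log2FC`, `SE`,
#'   `stat`, `pvalue`, `FDR`, `status`.
#' @export
nb_wald <- function(counts, groups, contrast, factors = NULL,
                    dispersion_floor = 1e-8) {
  counts <- as.matrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(counts), length(contrast) == 2)
  if (!all(contrast %in% groups))
    stop("unknown group label in contrast: ",
         paste(setdiff(contrast, groups), collapse = ", "))
  sel <- groups %in% contrast
  y <- counts[, sel, drop = FALSE]
  g <- groups[sel]
  if (any(table(factor(g, levels = contrast)) < 2))
    stop("each contrast group needs at least 2 samples")
  eff <- if (is.null(factors)) colSums(y) else
    factors$effective_lib_size[sel]
  if (any(eff <= 0)) stop("non-positive effective library size")

  sf <- eff / exp(mean(log(eff)))      # size factors, geometric mean 1
  z <- sweep(y, 2, sf, "/")            # normalized counts for moments
  is2 <- g == contrast[2]
  X <- cbind(1, as.numeric(is2))
  off <- log(eff)
  nfeat <- nrow(y)
  res <- data.frame(feature = rownames(y) %||% as.character(seq_len(nfeat)),
                    baseMean = rowMeans(z), log2FC = NA_real_, SE = NA_real_,
                    stat = NA_real_, pvalue = NA_real_, FDR = NA_real_,
                    status = "ok", stringsAsFactors = FALSE)
  for (i in seq_len(nfeat)) {
    yi <- y[i, ]
    if (all(yi == 0)) { res$status[i] <- "all-zero"; next }
    alpha <- mom_dispersion(z[i, ], is2, dispersion_floor)
    fam <- MASS::negative.binomial(theta = 1 / alpha, link = "log")
    fit <- tryCatch(
      suppressWarnings(stats::glm.fit(X, yi, family = fam, offset = off)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged || fit$rank < 2L) {
      res$status[i] <- "fit-failed"; next
    }
    beta <- fit$coefficients[2]
    p <- fit$rank
    R <- fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE]
    covmat <- chol2inv(R)
    se <- sqrt(covmat[2, 2])
    res$log2FC[i] <- beta / log(2)
    res$SE[i] <- se / log(2)
    res$stat[i] <- beta / se
    res$pvalue[i] <- 2 * stats::pnorm(-abs(res$stat[i]))
  }
  ok <- !is.na(res$pvalue)
  res$FDR[ok] <- stats::p.adjust(res$pvalue[ok], method = "BH")
  res
}

# internal: pooled within-group method-of-moments NB dispersion
mom_dispersion <- function(z, is2, floor_ = 1e-8) {
  est <- function(v) {
    m <- mean(v); s2 <- stats::var(v)
    if (m <= 0) return(NA_real_)
    (s2 - m) / m^2
  }
  a <- c(est(z[!is2]), est(z[is2]))
  w <- c(sum(!is2) - 1, sum(is2) - 1)
  ok <- !is.na(a)
  if (!any(ok)) return(floor_)
  max(floor_, sum(a[ok] * w[ok]) / sum(w[ok]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Welch's t-test with Cohen's d effect size
#'
#' Cohen's d standardizes the mean difference by the pooled standard
#' deviation, `d = (mean1 - mean2) / sqrt((s1^2 + s2^2) / 2)`; the result is
#' the number of standard deviation units separating the two groups.
#' Labels: `|d| < 0.2` small, `|d| >= 0.8` large, otherwise medium.
#'
#' @param group1,group2 Numeric vectors (>= 2 values each).
#' @return List of class `"effect_size_summary"` with `mean1`, `mean2`,
#'   `sd1`, `sd2`, `cohen_d`, `welch_t`, `welch_p`, `size_label`, `flag`.
#' @export
welch_cohen <- function(group1, group2) {
  stopifnot(length(group1) >= 2, length(group2) >= 2)
  m1 <- mean(group1); m2 <- mean(group2)
  s1 <- stats::sd(group1); s2 <- stats::sd(group2)
  pooled <- sqrt((s1^2 + s2^2) / 2)
  flag <- NULL
  if (pooled == 0) {
    d <- NA_real_; t <- NA_real_; p <- NA_real_
    flag <- "zero-variance"
  } else {
    d <- (m1 - m2) / pooled
    tt <- stats::t.test(group1, group2)   # Welch by default
    t <- unname(tt$statistic); p <- tt$p.value
  }
  label <- if (is.na(d)) NA_character_
    else if (abs(d) < 0.2) "small"
    else if (abs(d) >= 0.8) "large"
    else "medium"
  structure(list(mean1 = m1, mean2 = m2, sd1 = s1, sd2 = s2,
                 cohen_d = d, welch_t = t, welch_p = p,
                 size_label = label, flag = flag),
            class = "effect_size_summary")
}

#' @export
print.effect_size_summary <- function(x, ...) {
  cat(sprintf("Cohen's d = %.3f (%s); Welch t = %.3f, p = %.3g\n",
              x$cohen_d, x$size_label, x$welch_t, x$welch_p))
  invisible(x)
}

#' One-sided Fisher region-set enrichment
#'
#' For each database set, builds the 2x2 table of universe regions by query
#' membership and set membership (membership is >= 1 bp overlap) and tests
#' enrichment of the query in the set with a one-sided (greater) Fisher's
#' exact test. Odds ratios use the sample (cross-product) convention; tables
#' with a zero off-diagonal cell give an infinite odds ratio and are flagged.
#'
#' @param query Interval table of regions of interest (intersected with the
#'   universe by overlap).
#' @param universe Interval table of all eligible regions.
#' @param database Named list of interval tables.
#' @return Data frame per set: support counts `a`,`b`,`c`,`d`, `odds_ratio`,
#'   `pvalue`, `FDR`, `flagged`; sorted by p then decreasing odds ratio.
#' @export
fisher_region_enrichment <- function(query, universe, database) {
  if (is.null(universe) || nrow(universe) == 0L) stop("empty universe")
  in_query <- overlaps_any(universe, query)
  res <- lapply(names(database), function(nm) {
    in_set <- overlaps_any(universe, database[[nm]])
    a <- sum(in_query & in_set); b <- sum(in_query & !in_set)
    cc <- sum(!in_query & in_set); d <- sum(!in_query & !in_set)
    p <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                            alternative = "greater")$p.value
    or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
    data.frame(set = nm, a = a, b = b, c = cc, d = d, odds_ratio = or,
               pvalue = p, flagged = !is.finite(or),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$FDR <- stats::p.adjust(res$pvalue, method = "BH")
  res[order(res$pvalue, -res$odds_ratio), , drop = FALSE]
}

#' GSEA ranking metric from a differential result
#'
#' `metric = -log10(FDR) * sign(log2FC)`; features with `NA` FDR or fold
#' change are excluded, FDR underflow is capped, and ties in the metric are
#' broken deterministically by feature id.
#'
#' @param diff Data frame with `feature`, `log2FC`, `FDR` columns
#'   (as returned by [nb_wald()]).
#' @param cap Cap on `-log10(FDR)` when FDR underflows to 0.
#' @return Named numeric vector sorted in decreasing metric order; capped
#'   entries are recorded in `attr(, "capped")`.
#' @export
rank_metric <- function(diff, cap = 320) {
  ok <- !is.na(diff$FDR) & !is.na(diff$log2FC)
  d <- diff[ok, , drop = FALSE]
  neglog <- -log10(d$FDR)
  capped <- !is.finite(neglog) | neglog > cap
  neglog[capped] <- cap
  metric <- neglog * sign(d$log2FC)
  names(metric) <- d$feature
  ord <- order(-metric, d$feature)
  out <- metric[ord]
  attr(out, "capped") <- d$feature[capped]
  out
}

#' Pre-ranked gene set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running-sum enrichment score with
#' metric weight exponent `weight`; the ES is the running sum at its maximal
#' absolute deviation. P-values come from gene-label permutation (random
#' sets of the same size), the NES scales the ES by the mean same-sign
#' permutation magnitude, and FDR is Benjamini-Hochberg across tested sets.
#'
#' @param ranked Named numeric vector of metrics (any order; re-sorted
#'   decreasingly with ties broken by name).
#' @param gene_sets Named list of character vectors.
#' @param min_size,max_size Set-size bounds after intersecting with the
#'   ranked universe; out-of-bounds sets are skipped with a note.
#' @param n_perm Number of permutations.
#' @param weight Metric weight exponent (0 = unweighted KS).
#' @param seed Optional seed for the permutations.
#' @return Data frame per tested set: `set`, `size`, `ES`, `NES`, `pvalue`,
#'   `FDR`, `leading_edge` (semicolon-joined ids); skipped sets are listed
#'   in `attr(, "skipped")`.
#' @export
preranked_gsea <- function(ranked, gene_sets, min_size = 15, max_size = 5000,
                           n_perm = 1000, weight = 1, seed = NULL) {
  ord <- order(-ranked, names(ranked))
  r <- ranked[ord]
  genes <- names(r)
  N <- length(r)
  sets <- lapply(gene_sets, function(s) intersect(s, genes))
  sizes <- lengths(sets)
  keep <- sizes >= min_size & sizes <= max_size
  skipped <- names(gene_sets)[!keep]
  sets <- sets[keep]
  if (length(sets) == 0L) {
    out <- data.frame(set = character(), size = integer(), ES = numeric(),
                      NES = numeric(), pvalue = numeric(), FDR = numeric(),
                      leading_edge = character(), stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    return(out)
  }
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  res <- lapply(names(sets), function(nm) {
    hit <- genes %in% sets[[nm]]
    es <- gsea_es(r, hit, weight, leading = TRUE)
    perm <- vapply(seq_len(n_perm), function(i) {
      h <- logical(N); h[sample.int(N, sum(hit))] <- TRUE
      gsea_es(r, h, weight)$ES
    }, 0)
    same <- if (es$ES >= 0) perm[perm >= 0] else perm[perm < 0]
    pval <- (1 + sum(abs(same) >= abs(es$ES))) / (1 + length(same))
    nes <- if (length(same)) es$ES / mean(abs(same)) else NA_real_
    data.frame(set = nm, size = sum(hit), ES = es$ES, NES = nes,
               pvalue = pval,
               leading_edge = paste(es$leading, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  res$FDR <- stats::p.adjust(res$pvalue, method = "BH")
  res <- res[, c("set", "size", "ES", "NES", "pvalue", "FDR", "leading_edge")]
  attr(res, "skipped") <- skipped
  res
}

# internal: weighted KS running-sum enrichment score on a sorted ranking
gsea_es <- function(r, hit, weight, leading = FALSE) {
  N <- length(r); Nh <- sum(hit)
  w <- abs(r)^weight
  NR <- sum(w[hit])
  inc <- numeric(N)
  inc[hit] <- if (NR > 0) w[hit] / NR else 1 / Nh
  inc[!hit] <- -1 / (N - Nh)
  running <- cumsum(inc)
  i_max <- which.max(abs(running))
  ES <- running[i_max]
  le <- NULL
  if (leading) {
    le <- if (ES >= 0) names(r)[seq_len(i_max)][hit[seq_len(i_max)]]
      else names(r)[i_max:N][hit[i_max:N]]
  }
  list(ES = ES, leading = le)
}
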