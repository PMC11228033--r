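# Motif machinery: JASPAR text PWMs, log-odds scanning with an exact
# discretized score-distribution threshold, chromVAR-style bias-corrected
# accessibility deviations, differential motif activity, TF-expression
# correlation, and a simplified center-vs-flank footprint score.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix object
#'
#' @param id Motif identifier.
#' @param tf TF (gene) name; for dimers like `"TFA::TFB"` the first-named
#'   gene is used for expression matching.
#' @param mat 4 x L matrix of counts or probabilities, rows A, C, G, T.
#' @param background Background base frequencies (A, C, G, T).
#' @param pseudo Pseudo-probability added before renormalizing columns.
#' @return Object of class `"motif_pwm"` with probability columns summing
#'   to 1.
#' @export
motif_pwm <- function(id, tf, mat, background = rep(0.25, 4),
                      pseudo = 1e-3) {
  mat <- as.matrix(mat)
  stopifnot(nrow(mat) == 4, ncol(mat) >= 4, all(mat >= 0))
  prob <- apply(mat, 2, function(col) {
    col <- col / sum(col) + pseudo
    col / sum(col)
  })
  rownames(prob) <- BASES
  structure(list(id = id, tf = tf, prob = prob,
                 background = background / sum(background)),
            class = "motif_pwm")
}

#' @export
print.motif_pwm <- function(x, ...) {
  cat(sprintf("<motif_pwm> %s (%s), length %d\n", x$id, x$tf, ncol(x$prob)))
  invisible(x)
}

#' Filter motifs by TF expression
#'
#' Keeps a motif iff its TF gene reaches at least `min_tpm` TPM (inclusive)
#' in at least one of the given samples. Dimer motifs are matched by their
#' first-named gene; motifs whose TF is absent from the expression matrix
#' are kept with a warning.
#'
#' @param pwms List of [motif_pwm()] objects.
#' @param expression_tpm Gene x sample TPM matrix.
#' @param min_tpm Inclusive expression threshold.
#' @param samples Optional subset of sample names (e.g. leukemia samples).
#' @return Filtered list of PWMs.
#' @export
filter_motifs_by_expression <- function(pwms, expression_tpm, min_tpm = 1,
                                        samples = colnames(expression_tpm)) {
  tpm <- expression_tpm[, samples, drop = FALSE]
  keep <- vapply(pwms, function(p) {
    gene <- strsplit(p$tf, "::", fixed = TRUE)[[1]][1]
    if (!(gene %in% rownames(tpm))) {
      warning("TF '", gene, "' not in expression matrix; motif ", p$id,
              " kept", call. = FALSE)
      return(TRUE)
    }
    max(tpm[gene, ]) >= min_tpm
  }, TRUE)
  pwms[keep]
}

# internal: integer-discretized log2-odds score matrix (4+1 rows; row 5 is
# the N penalty) and its exact score-distribution threshold
pwm_scoring <- function(pwm, p_threshold = 5e-5, granularity = 1e-3) {
  s <- log2(pwm$prob / pwm$background)
  si <- round(s / granularity)                      # integer scores
  L <- ncol(si)
  # exact distribution of the total integer score under the background
  # model, by iterative convolution; dp[i] = P(total == part_lo + i - 1)
  dp <- 1
  part_lo <- 0
  for (k in seq_len(L)) {
    mink <- min(si[, k]); maxk <- max(si[, k])
    newlen <- length(dp) + (maxk - mink)
    nd <- numeric(newlen)
    for (b in 1:4) {
      sh <- si[b, k] - mink
      nd[(1 + sh):(length(dp) + sh)] <-
        nd[(1 + sh):(length(dp) + sh)] + dp * pwm$background[b]
    }
    dp <- nd
    part_lo <- part_lo + mink
  }
  # dp[i] = P(total == part_lo + i - 1)
  tail_p <- rev(cumsum(rev(dp)))
  # smallest achievable score whose upper tail is within the threshold
  idx <- which(tail_p <= p_threshold & dp > 0)
  thr <- if (length(idx)) part_lo + idx[1] - 1 else part_lo + length(dp)
  list(si = si, threshold = thr, granularity = granularity)
}

# internal: encode a DNA string as integers (A=1..T=4, N/other = 5)
encode_dna <- function(s) {
  v <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]], BASES)
  v[is.na(v)] <- 5L
  v
}

#' Scan peak sequences for motif matches
#'
#' Scores every window on both strands with the integer-discretized
#' log2-odds matrix and calls a match when the best window score reaches
#' the motif's threshold. The threshold is the smallest score whose upper
#' tail probability under the background base distribution is at most
#' `p_threshold`, computed exactly by dynamic programming over the
#' discretized score distribution. Sequences shorter than the motif never
#' match; `N` bases take a strongly negative score.
#'
#' @param pwms List of [motif_pwm()] objects.
#' @param peak_sequences Named character vector of peak DNA sequences.
#' @param p_threshold Match p-value threshold under the background model.
#' @param granularity Score discretization step (log2-odds units).
#' @return Logical peaks x motifs matrix.
#' @export
scan_motifs <- function(pwms, peak_sequences, p_threshold = 5e-5,
                        granularity = 1e-3) {
  enc <- lapply(peak_sequences, encode_dna)
  out <- matrix(FALSE, length(peak_sequences), length(pwms),
                dimnames = list(names(peak_sequences),
                                vapply(pwms, `[[`, "", "id")))
  for (m in seq_along(pwms)) {
    sc <- pwm_scoring(pwms[[m]], p_threshold, granularity)
    si_f <- rbind(sc$si, N = min(sc$si) - 10000L)     # N penalty row
    si_r <- si_f[c(4:1, 5), rev(seq_len(ncol(si_f)))] # reverse complement
    L <- ncol(si_f)
    for (p in seq_along(enc)) {
      v <- enc[[p]]
      if (length(v) < L) next
      out[p, m] <- max(window_scores(v, si_f), window_scores(v, si_r)) >=
        sc$threshold
    }
  }
  out
}

# internal: best window score of an encoded sequence against an integer
# score matrix (5 rows x L)
window_scores <- function(v, si) {
  L <- ncol(si); n <- length(v) - L + 1
  tot <- numeric(n)
  for (k in seq_len(L)) tot <- tot + si[v[k:(k + n - 1)], k]
  max(tot)
}

#' Bias-corrected motif accessibility deviations
#'
#' For every motif and sample, the observed count is the total
#' accessibility in motif-containing peaks and the expectation assigns the
#' motif's cohort-wide read fraction to the sample's total; the raw
#' deviation is `(observed - expected) / expected`. Bias correction draws
#' `n_background` background peak sets matched to the motif's peaks on GC
#' content and mean accessibility (10 x 10 binning, sampling with
#' replacement within bins) and reports
#' `Z = (raw - mean(background)) / sd(background)`.
#'
#' @param counts Peak x sample accessibility count matrix.
#' @param matches Logical peak x motif matrix from [scan_motifs()].
#' @param peak_gc GC fraction per peak.
#' @param n_background Number of background sets.
#' @param seed Optional seed for background sampling.
#' @return Object of class `"motif_deviations"`: list with `z` (motif x
#'   sample), `raw`, `variability` (sd of Z per motif), and `flagged`
#'   (motifs without matching peaks, returned as `NA` rows).
#' @export
deviations <- function(counts, matches, peak_gc, n_background = 50,
                       seed = NULL) {
  counts <- as.matrix(counts)
  stopifnot(nrow(counts) == nrow(matches),
            length(peak_gc) == nrow(counts))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  frac <- rowSums(counts) / sum(counts)
  totals <- colSums(counts)
  # 10 x 10 GC x mean-accessibility bins
  gc_bin <- bin10(peak_gc)
  acc_bin <- bin10(rowMeans(sweep(counts, 2, totals / mean(totals), "/")))
  bin_id <- paste(gc_bin, acc_bin)
  bin_members <- split(seq_len(nrow(counts)), bin_id)
  dev_of <- function(idx) {
    obs <- colSums(counts[idx, , drop = FALSE])
    expd <- sum(frac[idx]) * totals
    (obs - expd) / expd
  }
  nm <- ncol(matches)
  z <- raw <- matrix(NA_real_, nm, ncol(counts),
                     dimnames = list(colnames(matches), colnames(counts)))
  flagged <- character(0)
  for (m in seq_len(nm)) {
    idx <- which(matches[, m])
    if (length(idx) == 0L) { flagged <- c(flagged, colnames(matches)[m]); next }
    raw[m, ] <- dev_of(idx)
    bg <- matrix(0, n_background, ncol(counts))
    for (b in seq_len(n_background)) {
      samp <- vapply(idx, function(i) {
        mem <- bin_members[[bin_id[i]]]
        if (length(mem) == 1L) mem else mem[sample.int(length(mem), 1L)]
      }, 0L)
      bg[b, ] <- dev_of(samp)
    }
    mu <- colMeans(bg); sdev <- apply(bg, 2, stats::sd)
    sdev[sdev == 0] <- NA_real_
    z[m, ] <- (raw[m, ] - mu) / sdev
  }
  structure(list(z = z, raw = raw,
                 variability = apply(z, 1, stats::sd),
                 flagged = flagged),
            class = "motif_deviations")
}

bin10 <- function(x) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, 0.1)))
  if (length(br) < 3) return(rep(1L, length(x)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' @export
print.motif_deviations <- function(x, ...) {
  cat(sprintf("<motif_deviations> %d motifs x %d samples (%d flagged)\n",
              nrow(x$z), ncol(x$z), length(x$flagged)))
  invisible(x)
}

#' Differential motif activity between two groups
#'
#' Per motif, the differential deviation is the difference of mean
#' deviation Z-scores between the groups; significance is a two-sided
#' Wilcoxon rank-sum test, with the dual gate p < `p_cut` and
#' |difference| > `delta_cut`.
#'
#' @param dev [deviations()] result or a motif x sample Z matrix.
#' @param groups Group label per sample.
#' @param contrast `c(groupA, groupB)`; the difference is A minus B.
#' @param p_cut,delta_cut Significance gates.
#' @return Data frame `motif`, `delta`, `pvalue`, `significant`.
#' @export
differential_motif_activity <- function(dev, groups, contrast,
                                        p_cut = 0.01, delta_cut = 0.01) {
  z <- if (inherits(dev, "motif_deviations")) dev$z else dev
  ga <- groups == contrast[1]; gb <- groups == contrast[2]
  res <- lapply(rownames(z), function(m) {
    a <- z[m, ga]; b <- z[m, gb]
    if (all(is.na(a)) || all(is.na(b)))
      return(data.frame(motif = m, delta = NA_real_, pvalue = NA_real_,
                        significant = NA))
    delta <- mean(a, na.rm = TRUE) - mean(b, na.rm = TRUE)
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    data.frame(motif = m, delta = delta, pvalue = p,
               significant = p < p_cut & abs(delta) > delta_cut,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Correlate motif deviations with TF expression
#'
#' Pearson correlation, per motif, between its deviation Z-scores and the
#' TPM expression of its TF gene across samples matched by id; motifs with
#' fewer than `min_samples` paired samples give `NA`. A positive
#' correlation labels the TF a putative positive regulator.
#'
#' @param dev [deviations()] result or Z matrix.
#' @param tf_of Named character vector mapping motif id to TF gene.
#' @param expression_tpm Gene x sample TPM matrix.
#' @param min_samples Minimum paired samples.
#' @return Data frame `motif`, `tf`, `n`, `r`, `pvalue`,
#'   `putative_positive_regulator`.
#' @export
tf_expression_correlation <- function(dev, tf_of, expression_tpm,
                                      min_samples = 8) {
  z <- if (inherits(dev, "motif_deviations")) dev$z else dev
  res <- lapply(rownames(z), function(m) {
    gene <- strsplit(tf_of[[m]], "::", fixed = TRUE)[[1]][1]
    na_row <- data.frame(motif = m, tf = gene, n = 0L, r = NA_real_,
                         pvalue = NA_real_,
                         putative_positive_regulator = NA)
    if (!(gene %in% rownames(expression_tpm))) return(na_row)
    shared <- intersect(colnames(z), colnames(expression_tpm))
    zz <- z[m, shared]; ee <- expression_tpm[gene, shared]
    ok <- !is.na(zz) & !is.na(ee)
    if (sum(ok) < min_samples) return(na_row)
    ct <- stats::cor.test(zz[ok], ee[ok])
    data.frame(motif = m, tf = gene, n = sum(ok),
               r = unname(ct$estimate), pvalue = ct$p.value,
               putative_positive_regulator = unname(ct$estimate) > 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Simplified footprint score
#'
#' Depletion of signal at the motif center relative to its flanks:
#' `mean(flank) - mean(center)` per site, averaged over sites. Higher
#' scores indicate stronger footprints (deeper central depletion).
#'
#' @param coverage_profiles Site x position signal matrix, centered on the
#'   motif.
#' @param center_width Width of the central window (positions).
#' @param flank_width Width of each flanking window adjacent to the center.
#' @return Single numeric score.
#' @export
footprint_score <- function(coverage_profiles, center_width = 20,
                            flank_width = 50) {
  p <- ncol(coverage_profiles)
  mid <- (p + 1) / 2
  ctr <- seq(ceiling(mid - center_width / 2), floor(mid + center_width / 2 - 1e-9))
  ctr <- ctr[ctr >= 1 & ctr <= p]
  left <- seq(max(1, min(ctr) - flank_width), min(ctr) - 1)
  right <- seq(max(ctr) + 1, min(p, max(ctr) + flank_width))
  fl <- c(left, right)
  mean(rowMeans(coverage_profiles[, fl, drop = FALSE]) -
         rowMeans(coverage_profiles[, ctr, drop = FALSE]))
}
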