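# Hi-C integration: TAD boundary CTCF annotation, enhancer-promoter loop
# calling, differential TAD/loop scores, loop-CTCF linkage and
# loop-expression correlation.

#' Annotate TAD boundaries with their best CTCF peak
#'
#' Boundaries are `boundary_width` bp regions centered on each TAD border.
#' Per boundary, the overlapping CTCF peak with the smallest differential
#' FDR is kept (ties: smallest genomic start); TADs without an overlapping
#' peak are still emitted with `NA` annotation.
#'
#' @param tads Interval table of TADs with unique `id`.
#' @param diff_ctcf Differential table aligned with `ctcf_intervals`.
#' @param ctcf_intervals Interval table of CTCF peaks.
#' @param boundary_width Boundary width in bp.
#' @return Data frame, two rows per TAD (`side` left/right), with boundary
#'   coordinates and `ctcf_feature`, `ctcf_log2FC`, `ctcf_FDR`.
#' @export
annotate_boundaries <- function(tads, diff_ctcf, ctcf_intervals,
                                boundary_width = 5000) {
  stopifnot(nrow(diff_ctcf) == nrow(ctcf_intervals))
  half <- boundary_width / 2
  bounds <- rbind(
    data.frame(tad_id = tads$id, side = "left",
               chrom = tads$chrom,
               start = pmax(0, tads$start - half), end = tads$start + half),
    data.frame(tad_id = tads$id, side = "right",
               chrom = tads$chrom,
               start = pmax(0, tads$end - half), end = tads$end + half))
  bounds$ctcf_feature <- NA_character_
  bounds$ctcf_log2FC <- NA_real_
  bounds$ctcf_FDR <- NA_real_
  hits <- gi_overlap_pairs(bounds, ctcf_intervals)
  if (nrow(hits)) {
    ord <- order(hits$a, diff_ctcf$FDR[hits$b],
                 ctcf_intervals$start[hits$b])
    hits <- hits[ord, ]
    best <- hits[!duplicated(hits$a), ]
    bounds$ctcf_feature[best$a] <- diff_ctcf$feature[best$b]
    bounds$ctcf_log2FC[best$a] <- diff_ctcf$log2FC[best$b]
    bounds$ctcf_FDR[best$a] <- diff_ctcf$FDR[best$b]
  }
  rownames(bounds) <- NULL
  bounds
}

#' Call enhancer-promoter loops
#'
#' Anchors are padded by `pad` bp on each side; a loop is an EP loop iff an
#' enhancer lies within `max_dist` bp (inclusive; 0 if overlapping) of one
#' padded anchor and a promoter within `max_dist` of the opposite anchor.
#' The contacted gene id comes from the closest qualifying promoter.
#'
#' @param loops Loop table: `chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `id`.
#' @param enhancers Interval table with `id`.
#' @param promoters Interval table with `id` = gene id.
#' @param pad Anchor padding in bp.
#' @param max_dist Maximum feature-anchor distance in bp (inclusive).
#' @return `loops` with added `ep` flag, `enhancer_id`, `gene_id`.
#' @export
call_ep_loops <- function(loops, enhancers, promoters, pad = 5000,
                          max_dist = 25000) {
  loops$ep <- FALSE
  loops$enhancer_id <- NA_character_
  loops$gene_id <- NA_character_
  for (i in seq_len(nrow(loops))) {
    a1 <- c(loops$start1[i] - pad, loops$end1[i] + pad)
    a2 <- c(loops$start2[i] - pad, loops$end2[i] + pad)
    near <- function(anchor, feats) {
      same <- feats$chrom == loops$chrom[i]
      d <- gi_gap(anchor[1], anchor[2], feats$start, feats$end)
      which(same & d <= max_dist)
    }
    e1 <- near(a1, enhancers); e2 <- near(a2, enhancers)
    p1 <- near(a1, promoters); p2 <- near(a2, promoters)
    pick <- function(anchor, idx, feats) {
      d <- gi_gap(anchor[1], anchor[2], feats$start[idx], feats$end[idx])
      j <- order(d, feats$start[idx])[1]
      list(idx = idx[j], d = d[j])
    }
    cand <- list()
    if (length(e1) && length(p2))
      cand <- c(cand, list(list(e = pick(a1, e1, enhancers),
                                p = pick(a2, p2, promoters))))
    if (length(e2) && length(p1))
      cand <- c(cand, list(list(e = pick(a2, e2, enhancers),
                                p = pick(a1, p1, promoters))))
    if (length(cand)) {
      # when both orientations qualify, the tighter total distance wins
      tot <- vapply(cand, function(x) x$e$d + x$p$d, 0)
      best <- cand[[which.min(tot)]]
      loops$ep[i] <- TRUE
      loops$enhancer_id[i] <- enhancers$id[best$e$idx]
      loops$gene_id[i] <- promoters$id[best$p$idx]
    }
  }
  loops
}

#' Differential analysis of TAD or loop score tables
#'
#' Integer score tables are tested with the negative-binomial Wald test
#' ([nb_wald()]); non-integer tables fall back to a normal-theory Wald test
#' on log2 scores (difference of group means over its standard error).
#' The mode used is recorded in `attr(, "mode")`.
#'
#' @param scores Feature x sample score matrix.
#' @param groups,contrast As in [nb_wald()].
#' @param factors Optional [tmm_factors()] object (nb mode); defaults to
#'   TMM on the rounded scores, so composition shifts from planted or real
#'   lost/gained features do not masquerade as changes elsewhere.
#' @param mode `"auto"`, `"nb"` or `"lognormal"`.
#' @param pseudo Pseudo-count for the log transform.
#' @return Differential table in the [nb_wald()] layout.
#' @export
differential_3d <- function(scores, groups, contrast, factors = NULL,
                            mode = "auto", pseudo = 0.5) {
  scores <- as.matrix(scores)
  if (mode == "auto")
    mode <- if (all(scores == round(scores))) "nb" else "lognormal"
  if (mode == "nb") {
    if (is.null(factors)) factors <- tmm_factors(round(scores))
    res <- nb_wald(round(scores), groups, contrast, factors)
    attr(res, "mode") <- "nb"
    return(res)
  }
  groups <- as.character(groups)
  sel1 <- groups == contrast[1]; sel2 <- groups == contrast[2]
  stopifnot(sum(sel1) >= 2, sum(sel2) >= 2)
  lg <- log2(scores + pseudo)
  res <- data.frame(feature = rownames(scores) %||%
                      as.character(seq_len(nrow(scores))),
                    baseMean = rowMeans(scores),
                    log2FC = NA_real_, SE = NA_real_, stat = NA_real_,
                    pvalue = NA_real_, FDR = NA_real_, status = "ok",
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(lg))) {
    x1 <- lg[i, sel1]; x2 <- lg[i, sel2]
    se <- sqrt(stats::var(x1) / length(x1) + stats::var(x2) / length(x2))
    if (!is.finite(se) || se == 0) { res$status[i] <- "degenerate"; next }
    res$log2FC[i] <- mean(x2) - mean(x1)
    res$SE[i] <- se
    res$stat[i] <- res$log2FC[i] / se
    res$pvalue[i] <- 2 * stats::pnorm(-abs(res$stat[i]))
  }
  ok <- !is.na(res$pvalue)
  res$FDR[ok] <- stats::p.adjust(res$pvalue[ok], method = "BH")
  attr(res, "mode") <- "lognormal"
  res
}

#' Link differential loops to anchor CTCF changes
#'
#' Lost loops are FDR < `fdr` with log2FC < 0, gained loops FDR < `fdr`
#' with log2FC > 0. A loop shows a CTCF decrease when any CTCF peak
#' overlapping either padded anchor has log2FC < 0 (sign-only default); a
#' significance-gated variant additionally requires peak FDR < `fdr`.
#' Reports the lost/gained fractions under both variants and compares the
#' mean anchor CTCF log2FC of lost vs gained loops by rank-sum test.
#'
#' @param loops Loop table with `id`.
#' @param diff_loops Differential loop table keyed by loop `id`.
#' @param diff_ctcf,ctcf_intervals Differential CTCF table and aligned
#'   peak intervals.
#' @param pad Anchor padding in bp.
#' @param fdr Significance threshold.
#' @return List with per-variant fractions, loop counts, mean anchor
#'   delta-CTCF per class, and the rank-sum p-value.
#' @export
ctcf_loop_linkage <- function(loops, diff_loops, diff_ctcf, ctcf_intervals,
                              pad = 5000, fdr = 0.05) {
  idx <- match(loops$id, diff_loops$feature)
  lfc <- diff_loops$log2FC[idx]; lf <- diff_loops$FDR[idx]
  class <- rep("unchanged", nrow(loops))
  class[!is.na(lf) & lf < fdr & lfc < 0] <- "lost"
  class[!is.na(lf) & lf < fdr & lfc > 0] <- "gained"

  anchors <- rbind(
    data.frame(loop = seq_len(nrow(loops)), chrom = loops$chrom,
               start = pmax(0, loops$start1 - pad), end = loops$end1 + pad),
    data.frame(loop = seq_len(nrow(loops)), chrom = loops$chrom,
               start = pmax(0, loops$start2 - pad), end = loops$end2 + pad))
  hits <- gi_overlap_pairs(anchors, ctcf_intervals)
  dec_sign <- dec_sig <- logical(nrow(loops))
  mean_delta <- rep(NA_real_, nrow(loops))
  if (nrow(hits)) {
    hits$loop <- anchors$loop[hits$a]
    cl <- diff_ctcf$log2FC[hits$b]; cf <- diff_ctcf$FDR[hits$b]
    for (lp in unique(hits$loop)) {
      sel <- hits$loop == lp
      mean_delta[lp] <- mean(cl[sel], na.rm = TRUE)
      dec_sign[lp] <- any(cl[sel] < 0, na.rm = TRUE)
      dec_sig[lp] <- any(cl[sel] < 0 & cf[sel] < fdr, na.rm = TRUE)
    }
  }
  frac <- function(dec, cls) {
    n <- sum(class == cls)
    if (n == 0) NA_real_ else sum(dec[class == cls]) / n
  }
  lost_d <- mean_delta[class == "lost"]
  gained_d <- mean_delta[class == "gained"]
  p_rs <- if (sum(!is.na(lost_d)) >= 2 && sum(!is.na(gained_d)) >= 2)
    suppressWarnings(stats::wilcox.test(lost_d, gained_d)$p.value)
  else NA_real_
  list(n_lost = sum(class == "lost"), n_gained = sum(class == "gained"),
       lost_fraction = frac(dec_sign, "lost"),
       gained_fraction = frac(dec_sign, "gained"),
       lost_fraction_sig = frac(dec_sig, "lost"),
       gained_fraction_sig = frac(dec_sig, "gained"),
       mean_delta_lost = mean(lost_d, na.rm = TRUE),
       mean_delta_gained = mean(gained_d, na.rm = TRUE),
       ranksum_p = p_rs, loop_class = class)
}

#' Correlate EP-loop strength changes with contacted-gene expression
#'
#' Spearman correlation over (loop log2FC, contacted gene expression
#' log2FC) pairs across enhancer-promoter loops; with
#' `significant_only = TRUE` the pairs are restricted to differential
#' loops (FDR < `fdr`), mirroring the selection of differential EP loops
#' before correlating with expression.
#'
#' @param ep_loops Loop table from [call_ep_loops()] (rows with `ep`).
#' @param diff_loops Differential loop table keyed by loop `id`.
#' @param diff_expr Differential expression keyed by gene id.
#' @param significant_only Restrict to differential loops.
#' @param fdr FDR threshold for `significant_only`.
#' @return List with `pairs`, `rho`, `pvalue`, `n`.
#' @export
loop_expression_correlation <- function(ep_loops, diff_loops, diff_expr,
                                        significant_only = FALSE,
                                        fdr = 0.05) {
  ep <- ep_loops[ep_loops$ep, , drop = FALSE]
  lidx <- match(ep$id, diff_loops$feature)
  lfc <- diff_loops$log2FC[lidx]
  efc <- diff_expr$log2FC[match(ep$gene_id, diff_expr$feature)]
  ok <- !is.na(lfc) & !is.na(efc)
  if (significant_only)
    ok <- ok & !is.na(diff_loops$FDR[lidx]) & diff_loops$FDR[lidx] < fdr
  if (sum(ok) < 3) return(list(pairs = NULL, rho = NA_real_,
                               pvalue = NA_real_, n = sum(ok)))
  ct <- suppressWarnings(stats::cor.test(lfc[ok], efc[ok],
                                         method = "spearman"))
  list(pairs = data.frame(loop_id = ep$id[ok], gene_id = ep$gene_id[ok],
                          loop_log2FC = lfc[ok], expr_log2FC = efc[ok]),
       rho = unname(ct$estimate), pvalue = ct$p.value, n = sum(ok))
}

#' Overlap of CTCF peaks with TAD boundaries and loop anchors
#'
#' @param ctcf_intervals CTCF peak intervals.
#' @param boundaries Boundary intervals (e.g. from
#'   [annotate_boundaries()]).
#' @param anchors Padded loop-anchor intervals.
#' @param variable Optional logical per peak (variable vs unchanged) for
#'   stratified fractions.
#' @return List of fractions overall and, when `variable` is given, per
#'   stratum.
#' @export
summarize_ctcf_3d_overlap <- function(ctcf_intervals, boundaries, anchors,
                                      variable = NULL) {
  in_b <- overlaps_any(ctcf_intervals, boundaries)
  in_a <- overlaps_any(ctcf_intervals, anchors)
  out <- list(boundary_fraction = mean(in_b), anchor_fraction = mean(in_a),
              n = nrow(ctcf_intervals))
  if (!is.null(variable)) {
    out$boundary_fraction_variable <- mean(in_b[variable])
    out$boundary_fraction_unchanged <- mean(in_b[!variable])
    out$anchor_fraction_variable <- mean(in_a[variable])
    out$anchor_fraction_unchanged <- mean(in_a[!variable])
  }
  out
}
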