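# CTCF-methylation coupling: differential-binding site classes, coupling
# correlation between binding and methylation changes, and CpG positional
# analysis within the motif.

#' Classify CTCF sites by differential binding
#'
#' `lost` iff FDR < `fdr` and log2FC < -`lfc`; `gained` iff FDR < `fdr`
#' and log2FC > `lfc`; otherwise `unchanged` (including `NA` results).
#'
#' @param diff_ctcf Differential table as from [nb_wald()].
#' @param fdr,lfc Class thresholds.
#' @return Character vector of classes, one per site.
#' @export
classify_ctcf_sites <- function(diff_ctcf, fdr = 0.05, lfc = 1) {
  cls <- rep("unchanged", nrow(diff_ctcf))
  ok <- !is.na(diff_ctcf$FDR) & !is.na(diff_ctcf$log2FC)
  cls[ok & diff_ctcf$FDR < fdr & diff_ctcf$log2FC < -lfc] <- "lost"
  cls[ok & diff_ctcf$FDR < fdr & diff_ctcf$log2FC > lfc] <- "gained"
  cls
}

#' Correlate CTCF binding change with methylation change
#'
#' Methylation regions are joined to CTCF peaks by >= 1 bp overlap; when a
#' region overlaps several peaks, the peak with maximal overlap wins, ties
#' broken by smallest binding FDR. Pearson and Spearman coefficients are
#' computed over the joined (binding log2FC, methylation log2FC) pairs,
#' and a 2-D binned count table is returned for plotting.
#'
#' @param diff_ctcf,diff_meth Differential tables keyed by feature.
#' @param ctcf_intervals,meth_intervals Interval tables aligned row-wise
#'   with the differential tables.
#' @param n_bins Bins per axis for the binned table.
#' @return List with `pairs`, `pearson_r`, `pearson_p`, `spearman_rho`,
#'   `spearman_p`, `binned`.
#' @export
coupling_correlation <- function(diff_ctcf, ctcf_intervals,
                                 diff_meth, meth_intervals, n_bins = 30) {
  stopifnot(nrow(diff_ctcf) == nrow(ctcf_intervals),
            nrow(diff_meth) == nrow(meth_intervals))
  hits <- gi_overlap_pairs(meth_intervals, ctcf_intervals)
  if (nrow(hits) == 0L) stop("no overlapping regions to join")
  ov <- pmin(meth_intervals$end[hits$a], ctcf_intervals$end[hits$b]) -
    pmax(meth_intervals$start[hits$a], ctcf_intervals$start[hits$b])
  fdr <- diff_ctcf$FDR[hits$b]
  ord <- order(hits$a, -ov, fdr, hits$b)
  hits <- hits[ord, ]
  best <- hits[!duplicated(hits$a), ]
  pairs <- data.frame(meth_feature = diff_meth$feature[best$a],
                      ctcf_feature = diff_ctcf$feature[best$b],
                      meth_log2FC = diff_meth$log2FC[best$a],
                      ctcf_log2FC = diff_ctcf$log2FC[best$b],
                      stringsAsFactors = FALSE)
  ok <- stats::complete.cases(pairs[, c("meth_log2FC", "ctcf_log2FC")])
  if (sum(ok) < 3)
    return(list(pairs = pairs, pearson_r = NA_real_, pearson_p = NA_real_,
                spearman_rho = NA_real_, spearman_p = NA_real_,
                binned = NULL))
  pe <- stats::cor.test(pairs$meth_log2FC[ok], pairs$ctcf_log2FC[ok])
  sp <- suppressWarnings(
    stats::cor.test(pairs$meth_log2FC[ok], pairs$ctcf_log2FC[ok],
                    method = "spearman"))
  bx <- cut(pairs$meth_log2FC[ok], n_bins)
  by <- cut(pairs$ctcf_log2FC[ok], n_bins)
  list(pairs = pairs,
       pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       binned = as.data.frame(table(meth_bin = bx, ctcf_bin = by)))
}

#' CpG start frequency at every motif position
#'
#' For motif-aligned, equal-length, motif-forward sequences (reverse-strand
#' sites already reverse-complemented), returns the fraction of sites whose
#' bases at positions (p, p+1) are C, G — 1-based positions of the CpG's C.
#'
#' @param sequences Character vector of aligned site sequences.
#' @return Numeric vector of length `nchar - 1`.
#' @export
cpg_motif_profile <- function(sequences) {
  if (length(sequences) == 0L) stop("empty site list")
  L <- unique(nchar(sequences))
  if (length(L) != 1L) stop("sequences must be equal length")
  mat <- do.call(rbind, strsplit(toupper(sequences), "", fixed = TRUE))
  vapply(seq_len(L - 1), function(p)
    mean(mat[, p] == "C" & mat[, p + 1] == "G"), 0)
}

#' Positional CpG enrichment between two site groups
#'
#' Per motif position, tests whether group A sites carry a CpG starting at
#' that position more often than group B sites (one-sided Fisher, greater),
#' with Benjamini-Hochberg correction across positions. Odds ratios use the
#' cross-product convention.
#'
#' @param group_a,group_b Character vectors of aligned site sequences.
#' @param positions Positions to test (default: all).
#' @return Data frame `position`, `cpg_a`, `n_a`, `cpg_b`, `n_b`,
#'   `odds_ratio`, `pvalue`, `FDR`.
#' @export
positional_enrichment <- function(group_a, group_b, positions = NULL) {
  La <- unique(nchar(group_a)); Lb <- unique(nchar(group_b))
  stopifnot(length(La) == 1L, identical(La, Lb))
  if (is.null(positions)) positions <- seq_len(La - 1)
  has_cpg <- function(seqs, p) {
    m <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
    m[, p] == "C" & m[, p + 1] == "G"
  }
  res <- lapply(positions, function(p) {
    a <- sum(has_cpg(group_a, p)); b <- length(group_a) - a
    cc <- sum(has_cpg(group_b, p)); d <- length(group_b) - cc
    pv <- stats::fisher.test(matrix(c(a, b, cc, d), 2, byrow = TRUE),
                             alternative = "greater")$p.value
    or <- if (b * cc == 0) Inf else (a * d) / (b * cc)
    data.frame(position = p, cpg_a = a, n_a = a + b, cpg_b = cc,
               n_b = cc + d, odds_ratio = or, pvalue = pv)
  })
  res <- do.call(rbind, res)
  res$FDR <- stats::p.adjust(res$pvalue, method = "BH")
  res
}
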