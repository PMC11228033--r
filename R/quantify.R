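# Consensus-peak quantification: master peak list, input-DNA subtraction,
# and TMM normalization with consensus-peak library sizes.

#' Build the consensus master peak list
#'
#' Per-sample peaks are first filtered to significance `-log10(q)` strictly
#' greater than `min_neglog10q`, then peaks overlapping the blacklist are
#' removed, and finally surviving peaks present (>= 1 bp overlap) in at least
#' `min_samples` samples are merged into maximal unions.
#'
#' @param peaksets Named list of per-sample interval tables, each with a
#'   `neglog10q` column.
#' @param min_samples Minimum number of supporting samples.
#' @param min_neglog10q Per-peak significance cutoff (exclusive).
#' @param blacklist Optional interval table of excluded regions.
#' @return Sorted, disjoint interval table with an `n_samples` support column.
#' @export
build_master_list <- function(peaksets, min_samples = 2, min_neglog10q = 10,
                              blacklist = NULL) {
  stopifnot(length(peaksets) >= min_samples)
  filt <- lapply(peaksets, function(p) {
    stopifnot("neglog10q" %in% names(p))
    p <- p[p$neglog10q > min_neglog10q, , drop = FALSE]
    if (!is.null(blacklist) && nrow(blacklist) > 0 && nrow(p) > 0)
      p <- p[!overlaps_any(p, blacklist), , drop = FALSE]
    p
  })
  out <- recurrent_regions(filt, min_samples)
  if (nrow(out) == 0L)
    warning("no consensus peaks survive filtering")
  rownames(out) <- NULL
  out
}

#' Subtract input-DNA counts from sample counts
#'
#' Per feature and sample, returns `max(0, sample - input)`; negative
#' pseudo-counts are floored at zero. When `input_counts` is `NULL` the
#' counts pass through unchanged and the returned matrix carries
#' `attr(, "input_subtracted") = FALSE`.
#'
#' @param sample_counts,input_counts Feature x sample integer matrices with
#'   identical dimnames (input may be `NULL`).
#' @return Matrix of corrected counts with an `input_subtracted` attribute.
#' @export
count_with_input_subtraction <- function(sample_counts, input_counts = NULL) {
  if (is.null(input_counts)) {
    attr(sample_counts, "input_subtracted") <- FALSE
    return(sample_counts)
  }
  if (!identical(dim(sample_counts), dim(input_counts)) ||
      !identical(rownames(sample_counts), rownames(input_counts)) ||
      !identical(colnames(sample_counts), colnames(input_counts)))
    stop("sample and input count matrices are not aligned")
  out <- pmax(sample_counts - input_counts, 0)
  attr(out, "input_subtracted") <- TRUE
  out
}

#' Trimmed mean of M-values normalization factors
#'
#' Computes the TMM factor of every sample against a reference sample:
#' features with a zero count in either library are excluded pairwise,
#' M (log2 count ratio) and A (mean log2 abundance) are formed after
#' library-size scaling, the most extreme `logratio_trim` of M and
#' `sum_trim` of A are trimmed, and the factor is the inverse-variance
#' weighted mean of the remaining M-values (asymptotic binomial variance
#' weights). Factors are rescaled so their geometric mean is 1. The library
#' size is the column sum of `counts` (reads in consensus peaks).
#'
#' @param counts Feature x sample count matrix.
#' @param reference_sample Optional sample name; defaults to the sample whose
#'   upper quartile of scaled counts is closest to the mean upper quartile.
#' @param logratio_trim,sum_trim Total trimmed fractions of M and A.
#' @return Object of class `"tmm_factors"`: list with `factors`, `lib_size`,
#'   `effective_lib_size`, `reference`, `logratio_trim`, `sum_trim`.
#' @export
tmm_factors <- function(counts, reference_sample = NULL,
                        logratio_trim = 0.30, sum_trim = 0.05) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) >= 2)
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  if (is.null(reference_sample)) {
    uq <- apply(counts, 2, function(y) stats::quantile(y / sum(y), 0.75))
    ref <- which.min(abs(uq - mean(uq)))
  } else {
    ref <- match(reference_sample, colnames(counts))
    if (is.na(ref)) stop("unknown reference sample: ", reference_sample)
  }
  f <- vapply(seq_len(ncol(counts)), function(j)
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, sum_trim), 0)
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  structure(list(factors = f, lib_size = lib,
                 effective_lib_size = f * lib,
                 reference = colnames(counts)[ref],
                 logratio_trim = logratio_trim, sum_trim = sum_trim),
            class = "tmm_factors")
}

# internal: single-pair TMM factor (observed vs reference)
tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0L) return(1)
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1; hiL <- n + 1 - loL
  loS <- floor(n * sum_trim) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
    sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' @export
print.tmm_factors <- function(x, ...) {
  cat("TMM normalization factors (reference:", x$reference, ")\n")
  print(round(x$factors, 4))
  invisible(x)
}
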