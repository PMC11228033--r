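# Feature-catalog construction: CpG islands, promoter windows, the
# H3K27ac/ATAC/CAGE enhancer catalog, and promoter-vs-enhancer peak labels.

#' Detect CpG islands with the Gardiner-Garden & Frommer criteria
#'
#' Scans a DNA sequence with a sliding window of width `min_length` (step 1),
#' keeps windows with GC fraction above `min_gc` and observed/expected CpG
#' ratio above `min_oe` (expected CpG = #C x #G / window length), merges
#' overlapping qualifying windows, and re-tests each merged region against the
#' same criteria. `N` bases are excluded from all base and dinucleotide counts
#' but still contribute to window length.
#'
#' @param sequence A single DNA string over `A`, `C`, `G`, `T`, `N`.
#' @param min_length Minimum island length in bp (also the window width).
#' @param min_gc Minimum GC fraction (exclusive).
#' @param min_oe Minimum observed/expected CpG ratio (exclusive).
#' @return Interval table of islands (0-based half-open), sorted and disjoint,
#'   with `gc` and `oe` columns for the merged region.
#' @export
find_cpg_islands <- function(sequence, min_length = 200, min_gc = 0.5,
                             min_oe = 0.6) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) == 0L) return(cpg_island_frame())
  bases <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T", "N")))
    stop("sequence contains characters outside {A,C,G,T,N}")
  L <- length(bases)
  if (L < min_length) return(cpg_island_frame())

  isC <- bases == "C"
  isG <- bases == "G"
  isCpG <- c(isC[-L] & isG[-1], FALSE)  # CpG starting at each position
  cumC <- c(0, cumsum(isC))
  cumG <- c(0, cumsum(isG))
  cumCpG <- c(0, cumsum(isCpG))

  w <- min_length
  starts <- seq_len(L - w + 1L)            # 1-based window starts
  nC <- cumC[starts + w] - cumC[starts]
  nG <- cumG[starts + w] - cumG[starts]
  # CpG dinucleotides fully inside the window start at positions s..s+w-2
  nCpG <- cumCpG[starts + w - 1L] - cumCpG[starts]
  gc <- (nC + nG) / w
  expected <- nC * nG / w
  oe <- ifelse(expected > 0, nCpG / expected, 0)
  ok <- gc > min_gc & oe > min_oe
  if (!any(ok)) return(cpg_island_frame())

  # merge overlapping qualifying windows (step 1, width w: starts within w
  # of each other overlap)
  s <- starts[ok]
  brk <- which(diff(s) > w)
  run_start <- s[c(1L, brk + 1L)]
  run_end <- s[c(brk, length(s))] + w - 1L   # 1-based inclusive end

  # re-test merged regions with the same criteria
  keep <- logical(length(run_start))
  gc_m <- oe_m <- numeric(length(run_start))
  for (i in seq_along(run_start)) {
    a <- run_start[i]; b <- run_end[i]; len <- b - a + 1L
    nC <- cumC[b + 1L] - cumC[a]
    nG <- cumG[b + 1L] - cumG[a]
    nCpG <- cumCpG[b] - cumCpG[a]
    gc_m[i] <- (nC + nG) / len
    exp_m <- nC * nG / len
    oe_m[i] <- if (exp_m > 0) nCpG / exp_m else 0
    keep[i] <- len >= min_length && gc_m[i] > min_gc && oe_m[i] > min_oe
  }
  if (!any(keep)) return(cpg_island_frame())
  out <- data.frame(chrom = "seq", start = run_start[keep] - 1,
                    end = run_end[keep], gc = gc_m[keep], oe = oe_m[keep],
                    stringsAsFactors = FALSE)
  out[order(out$start), , drop = FALSE]
}

cpg_island_frame <- function() {
  data.frame(chrom = character(), start = numeric(), end = numeric(),
             gc = numeric(), oe = numeric(), stringsAsFactors = FALSE)
}

#' Promoter windows around transcription start sites
#'
#' Strand-aware windows spanning `upstream` bp before and `downstream` bp
#' after each TSS (default 1500/500), clipped to chromosome bounds.
#'
#' @param tss_list Data frame with columns `gene_id`, `chrom`, `tss`
#'   (0-based position), `strand` (`"+"` or `"-"`).
#' @param upstream,downstream Window extents in bp.
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   clipping.
#' @return Interval table with `id` = gene id.
#' @export
define_promoters_window <- function(tss_list, upstream = 1500,
                                    downstream = 500,
                                    chrom_lengths = NULL) {
  stopifnot(all(c("gene_id", "chrom", "tss", "strand") %in% names(tss_list)))
  if (any(is.na(tss_list$strand)) || !all(tss_list$strand %in% c("+", "-")))
    stop("every TSS must have strand '+' or '-'")
  plus <- tss_list$strand == "+"
  start <- ifelse(plus, tss_list$tss - upstream, tss_list$tss - downstream)
  end <- ifelse(plus, tss_list$tss + downstream, tss_list$tss + upstream)
  start <- pmax(0, start)
  if (!is.null(chrom_lengths))
    end <- pmin(end, unname(chrom_lengths[tss_list$chrom]))
  genomic_intervals(tss_list$chrom, start, end, tss_list$strand,
                    tss_list$gene_id)
}

#' Build the enhancer catalog from H3K27ac, ATAC and CAGE evidence
#'
#' Candidate enhancers are merged H3K27ac regions recurrent in at least
#' `min_recurrence` samples, excluding regions that overlap TSS +/- `tss_pad`
#' windows by at least `max_tss_overlap_frac` of their own width, then
#' intersected (>= 1 bp) with open-chromatin regions recurrent in at least
#' `min_recurrence` ATAC samples and with CAGE-defined enhancers.
#'
#' @param h3k27ac_peaksets,atac_peaksets Lists of per-sample interval tables.
#' @param cage_enhancers Interval table of CAGE enhancers.
#' @param tss_list TSS table as in [define_promoters_window()].
#' @param min_recurrence Minimum supporting samples per assay.
#' @param tss_pad Half-width of the TSS exclusion window in bp.
#' @param max_tss_overlap_frac Exclusion threshold on the overlapped fraction
#'   of the candidate's width (inclusive).
#' @return Interval table of enhancers with provenance columns
#'   `n_samples`, `atac_support`, `cage_support`.
#' @export
build_enhancer_catalog <- function(h3k27ac_peaksets, atac_peaksets,
                                   cage_enhancers, tss_list,
                                   min_recurrence = 3, tss_pad = 1000,
                                   max_tss_overlap_frac = 0.05) {
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_samples = integer(), stringsAsFactors = FALSE)
  if (length(h3k27ac_peaksets) == 0L ||
      sum(vapply(h3k27ac_peaksets, nrow, 0L)) == 0L) {
    warning("no H3K27ac peaks supplied; empty enhancer catalog")
    return(empty)
  }
  cand <- recurrent_regions(h3k27ac_peaksets, min_recurrence)
  if (nrow(cand) == 0L) return(empty)

  # TSS-proximity exclusion: fraction of candidate width covered by the
  # union of TSS +/- tss_pad windows, inclusive at the threshold
  tss_win <- genomic_intervals(tss_list$chrom,
                               pmax(0, tss_list$tss - tss_pad),
                               tss_list$tss + tss_pad)
  cov_frac <- covered_fraction(cand, gi_merge(tss_win))
  cand <- cand[cov_frac < max_tss_overlap_frac, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)

  atac_rec <- recurrent_regions(atac_peaksets, min_recurrence)
  atac_hit <- overlaps_any(cand, atac_rec)
  cage_hit <- overlaps_any(cand, cage_enhancers)
  cand$atac_support <- atac_hit
  cand$cage_support <- cage_hit
  out <- cand[atac_hit & cage_hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# internal: merged regions supported by >= min_samples of the supplied peak sets
recurrent_regions <- function(peaksets, min_samples) {
  peaksets <- Filter(function(p) !is.null(p) && nrow(p) > 0, peaksets)
  if (length(peaksets) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), n_samples = integer(),
                      stringsAsFactors = FALSE))
  all_pk <- do.call(rbind, lapply(peaksets, function(p)
    p[, c("chrom", "start", "end")]))
  merged <- gi_merge(all_pk)
  n <- integer(nrow(merged))
  for (p in peaksets) {
    hits <- gi_overlap_pairs(merged, p)
    n[unique(hits$a)] <- n[unique(hits$a)] + 1L
  }
  merged$n_samples <- n
  merged[n >= min_samples, , drop = FALSE]
}

# internal: fraction of each interval in a covered by the union of b
covered_fraction <- function(a, b) {
  if (nrow(a) == 0L) return(numeric())
  if (nrow(b) == 0L) return(numeric(nrow(a)))
  b <- gi_merge(b)
  frac <- numeric(nrow(a))
  hits <- gi_overlap_pairs(a, b)
  if (nrow(hits)) {
    ov <- pmin(a$end[hits$a], b$end[hits$b]) -
      pmax(a$start[hits$a], b$start[hits$b])
    tot <- tapply(ov, hits$a, sum)
    frac[as.integer(names(tot))] <- tot / (a$end - a$start)[as.integer(names(tot))]
  }
  frac
}

# internal: does each interval in a overlap any interval in b (>= 1 bp)
overlaps_any <- function(a, b) {
  out <- logical(nrow(a))
  if (nrow(a) == 0L || is.null(b) || nrow(b) == 0L) return(out)
  out[unique(gi_overlap_pairs(a, b)$a)] <- TRUE
  out
}

#' Classify ATAC peaks as promoter or enhancer peaks
#'
#' A peak is a putative promoter iff it overlaps (>= 1 bp, half-open) any
#' TSS +/- `promoter_halfwidth` window; all other peaks are putative
#' enhancers.
#'
#' @param atac_peaks Interval table of peaks.
#' @param tss_list TSS table as in [define_promoters_window()].
#' @param promoter_halfwidth Half-width of the TSS window in bp.
#' @return Character vector `"promoter"`/`"enhancer"`, one label per peak.
#' @export
classify_atac_peaks <- function(atac_peaks, tss_list,
                                promoter_halfwidth = 500) {
  win <- genomic_intervals(tss_list$chrom,
                           pmax(0, tss_list$tss - promoter_halfwidth),
                           tss_list$tss + promoter_halfwidth)
  ifelse(overlaps_any(atac_peaks, win), "promoter", "enhancer")
}
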