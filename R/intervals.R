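# Genomic intervals are plain data.frames with columns chrom, start, end
# (0-based, half-open), and optionally strand ("+", "-", ".") and id.
# GenomicRanges does the heavy lifting internally; conversion happens at this
# boundary only, so every user-facing coordinate stays 0-based half-open.

#' Construct a genomic interval table
#'
#' @param chrom Chromosome names.
#' @param start,end 0-based half-open coordinates (`start < end`).
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."` (recycled).
#' @param id Optional feature identifiers.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`, `id`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".", id = NA_character_) {
  start <- as.numeric(start); end <- as.numeric(end)
  n <- length(start)
  if (n == 0L) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      strand = character(), id = character(),
                      stringsAsFactors = FALSE))
  }
  if (any(is.na(chrom)) || any(!nzchar(chrom)))
    stop("chrom must be nonempty")
  if (any(start < 0) || any(start >= end))
    stop("intervals must satisfy 0 <= start < end (0-based half-open)")
  if (!all(strand %in% c("+", "-", ".")))
    stop("strand must be '+', '-' or '.'")
  data.frame(chrom = rep_len(as.character(chrom), n), start = start,
             end = end,
             strand = rep_len(as.character(strand), n),
             id = rep_len(as.character(id), n),
             stringsAsFactors = FALSE)
}

# internal: interval table -> GRanges (1-based closed)
gi_to_gr <- function(x) {
  strand <- if ("strand" %in% names(x)) sub("^\\.$", "*", x$strand) else "*"
  GenomicRanges::GRanges(x$chrom,
                         IRanges::IRanges(start = x$start + 1L, end = x$end),
                         strand = strand)
}

# internal: GRanges -> interval table
gr_to_gi <- function(gr, id = NA_character_) {
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1,
             end = as.numeric(GenomicRanges::end(gr)),
             strand = strand,
             id = rep_len(as.character(id), length(gr)),
             stringsAsFactors = FALSE)
}

# internal: overlap index pairs between two interval tables (>= 1 bp overlap)
gi_overlap_pairs <- function(a, b) {
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gi_to_gr(a), gi_to_gr(b),
                                ignore.strand = TRUE))
  data.frame(a = S4Vectors::queryHits(hits), b = S4Vectors::subjectHits(hits))
}

# internal: merge overlapping intervals into maximal unions (strand-blind)
gi_merge <- function(x) {
  if (nrow(x) == 0L) return(x[, c("chrom", "start", "end")])
  red <- GenomicRanges::reduce(gi_to_gr(x), ignore.strand = TRUE)
  out <- gr_to_gi(red)
  out[order(out$chrom, out$start), c("chrom", "start", "end")]
}

#' Fraction of interval `a` covered by interval `b`
#'
#' Both intervals are 0-based half-open; the fraction is measured against the
#' width of `a` and is 0 for disjoint intervals (including half-open abutment).
#'
#' @param a,b Single-row interval tables or lists with `chrom`, `start`, `end`.
#' @return Overlap width divided by `width(a)`, in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  if (!identical(as.character(a$chrom), as.character(b$chrom))) return(0)
  ov <- min(a$end, b$end) - max(a$start, b$start)
  max(0, ov) / (a$end - a$start)
}

# internal: gap between two half-open intervals on one chromosome (0 if overlap)
gi_gap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmax(b_start - a_end, a_start - b_end))
}
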