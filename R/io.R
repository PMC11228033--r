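# Plain-text readers/writers for the formats the pipeline exchanges:
# BED, ENCODE narrowPeak, BEDPE, JASPAR PWM text, GMT gene sets, TSV count
# matrices. All coordinates on disk are 0-based half-open, matching the
# in-memory convention.

#' Write intervals as BED
#'
#' BED3 by default; BED6 (name/score/strand) when `id`/`strand` columns are
#' present.
#' @param x Interval table.
#' @param path Output file.
#' @export
write_bed <- function(x, path) {
  cols <- data.frame(x$chrom, format(x$start, scientific = FALSE, trim = TRUE),
                     format(x$end, scientific = FALSE, trim = TRUE))
  if (!is.null(x$id)) {
    cols$name <- ifelse(is.na(x$id), ".", x$id)
    cols$score <- 0
    cols$strand <- if (is.null(x$strand)) "." else x$strand
  }
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BED3/BED6 file into an interval table
#' @param path Input file.
#' @export
read_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  genomic_intervals(x[[1]], x[[2]], x[[3]],
                    strand = if (ncol(x) >= 6) x[[6]] else ".",
                    id = if (ncol(x) >= 4) x[[4]] else NA_character_)
}

#' Write peaks in ENCODE narrowPeak format (10 columns)
#'
#' Column 9 carries `-log10(q)`; signalValue and pValue are set from the
#' available columns or 0; peak summit offset is -1 (not called).
#' @param peaks Interval table with `neglog10q` (and optionally `id`).
#' @param path Output file.
#' @export
write_narrowpeak <- function(peaks, path) {
  n <- nrow(peaks)
  df <- data.frame(peaks$chrom,
                   format(peaks$start, scientific = FALSE, trim = TRUE),
                   format(peaks$end, scientific = FALSE, trim = TRUE),
                   name = if (is.null(peaks$id)) paste0("peak_", seq_len(n))
                          else peaks$id,
                   score = 0, strand = ".",
                   signalValue = if (is.null(peaks$signal)) 0 else peaks$signal,
                   pValue = -1, qValue = peaks$neglog10q, peak = -1)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read an ENCODE narrowPeak file
#' @param path Input file.
#' @export
read_narrowpeak <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(ncol(x) == 10)
  out <- genomic_intervals(x[[1]], x[[2]], x[[3]], strand = ".", id = x[[4]])
  out$signal <- x[[7]]
  out$neglog10q <- x[[9]]
  out
}

#' Write loops as BEDPE
#' @param loops Loop table (`chrom`, `start1`, `end1`, `start2`, `end2`,
#'   `id`; extra numeric columns appended as score fields).
#' @param path Output file.
#' @export
write_bedpe <- function(loops, path) {
  df <- data.frame(loops$chrom,
                   format(loops$start1, scientific = FALSE, trim = TRUE),
                   format(loops$end1, scientific = FALSE, trim = TRUE),
                   loops$chrom,
                   format(loops$start2, scientific = FALSE, trim = TRUE),
                   format(loops$end2, scientific = FALSE, trim = TRUE),
                   name = loops$id, score = 0, strand1 = ".", strand2 = ".")
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a BEDPE file into a loop table
#' @param path Input file.
#' @export
read_bedpe <- function(path) {
  x <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(x[[1]] == x[[4]])
  data.frame(chrom = x[[1]], start1 = x[[2]], end1 = x[[3]],
             start2 = x[[5]], end2 = x[[6]],
             id = if (ncol(x) >= 7) x[[7]] else paste0("loop_", seq_len(nrow(x))),
             stringsAsFactors = FALSE)
}

#' Write PWMs in JASPAR text format
#' @param pwms List of [motif_pwm()] objects (probabilities are written
#'   scaled to a column total of 1e6).
#' @param path Output file.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(sprintf(">%s %s", p$id, p$tf), con)
    m <- round(p$prob * 1e6, 2)
    for (b in seq_len(4))
      writeLines(sprintf("%s  [ %s ]", BASES[b],
                         paste(format(m[b, ], trim = TRUE), collapse = " ")),
                 con)
  }
}

#' Read a JASPAR-format PWM text file
#' @param path Input file.
#' @param background,pseudo Passed to [motif_pwm()].
#' @export
read_jaspar <- function(path, background = rep(0.25, 4), pseudo = 1e-3) {
  lines <- readLines(path)
  hdr <- grep("^>", lines)
  lapply(hdr, function(h) {
    meta <- strsplit(sub("^>", "", lines[h]), "\\s+")[[1]]
    rows <- lines[(h + 1):(h + 4)]
    mat <- do.call(rbind, lapply(rows, function(l) {
      nums <- regmatches(l, gregexpr("[0-9.eE+-]+", sub("^\\s*[ACGT]", "", l)))[[1]]
      as.numeric(nums)
    }))
    motif_pwm(meta[1], if (length(meta) > 1) meta[2] else meta[1], mat,
              background = background, pseudo = pseudo)
  })
}

#' Write gene sets in GMT format
#' @param gene_sets Named list of character vectors.
#' @param path Output file.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, "na", gene_sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
}

#' Read a GMT gene-set file
#' @param path Input file.
#' @export
read_gmt <- function(path) {
  lines <- strsplit(readLines(path), "\t")
  stats::setNames(lapply(lines, function(x) x[-(1:2)]),
                  vapply(lines, `[[`, "", 1))
}

#' Write a count matrix as TSV (header row = sample ids)
#' @param m Matrix with dimnames.
#' @param path Output file.
#' @export
write_counts_tsv <- function(m, path) {
  utils::write.table(data.frame(feature = rownames(m), m,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a TSV count matrix written by [write_counts_tsv()]
#' @param path Input file.
#' @export
read_counts_tsv <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = TRUE,
                         check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(x[, -1, drop = FALSE])
  rownames(m) <- x[[1]]
  m
}
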