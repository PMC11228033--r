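# Tumor-only somatic variant sieve: multi-caller merge with indel
# normalization, the ordered quality-filter cascade (with SNV cluster
# removal), somatic selection with its two rescues, oncogenicity flags,
# and fusion majority voting.

QUALITY_RULES <- c("strand_bias", "depth", "alignment_quality",
                   "other_allele", "alt_alignment", "long_indel",
                   "simple_repeat", "selfchain", "snv_cluster")

#' Normalize a variant representation
#'
#' Trims the shared suffix, then the shared prefix (advancing the
#' position), keeping at least one base of both alleles — removing the
#' redundant padding that makes equivalent caller representations differ.
#'
#' @param pos,ref,alt Position (1-based) and allele strings.
#' @return List `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 &&
         r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

#' Merge per-caller variant tables into unified records
#'
#' Variants are normalized ([normalize_variant()]) and unified by
#' (chrom, pos, ref, alt); the supporting callers are accumulated and the
#' site metrics are taken from the first table that reports the variant
#' (metrics come from a single annotation source, not per caller).
#'
#' @param tables Named list (caller name -> data frame with at least
#'   `chrom`, `pos`, `ref`, `alt` plus metric columns).
#' @return Unified data frame with a `callers` column
#'   (comma-joined caller names) and `n_callers`.
#' @export
merge_caller_calls <- function(tables) {
  rows <- list(); seen <- character(0)
  callers <- list()
  for (caller in names(tables)) {
    tb <- tables[[caller]]
    if (is.null(tb) || nrow(tb) == 0L) next
    for (i in seq_len(nrow(tb))) {
      nv <- normalize_variant(tb$pos[i], tb$ref[i], tb$alt[i])
      key <- paste(tb$chrom[i], nv$pos, nv$ref, nv$alt, sep = ":")
      if (key %in% seen) {
        callers[[key]] <- union(callers[[key]], caller)
      } else {
        seen <- c(seen, key)
        row <- tb[i, , drop = FALSE]
        row$pos <- nv$pos; row$ref <- nv$ref; row$alt <- nv$alt
        rows[[key]] <- row
        callers[[key]] <- caller
      }
    }
  }
  if (length(rows) == 0L) return(data.frame())
  out <- do.call(rbind, rows)
  out$callers <- vapply(seen, function(k)
    paste(sort(callers[[k]]), collapse = ","), "")
  out$n_callers <- lengths(callers)[seen]
  rownames(out) <- NULL
  out
}

#' Apply the tumor-only quality-filter cascade
#'
#' The per-site rules, applied in order with every outcome recorded in the
#' filter trail: strand bias strictly inside (0, 1) for variants within
#' the padded exome capture; total depth >= 8 and alt depth >= 4;
#' alignment quality >= 40 and base quality >= 30; under 40% of reads on
#' an allele other than reference/alternative; at most 10% of reads with
#' an alternative alignment; indels of 500 bp or more removed; simple
#' repeat and >= 95%-identity self-chain regions removed. After the
#' per-site rules, maximal runs of 3 or more surviving SNVs with
#' consecutive gaps under 5 bp are removed wholesale. A missing metric
#' fails the variant with reason `metric-missing`.
#'
#' @param variants Data frame with the metric columns named in the rules
#'   (`strand_bias`, `depth_total`, `depth_alt`, `mapping_quality`,
#'   `base_quality`, `other_allele_fraction`, `alt_alignment_fraction`,
#'   `type`, `indel_length`, `in_capture_pad200`, `in_simple_repeat`,
#'   `in_selfchain95`, `chrom`, `pos`).
#' @return `variants` with logical `qc_pass`, a `trail` string
#'   (`rule:pass|fail|skip` joined by `;`), and `fail_reasons`.
#' @export
apply_quality_filters <- function(variants) {
  n <- nrow(variants)
  trail <- matrix("pass", n, length(QUALITY_RULES),
                  dimnames = list(NULL, QUALITY_RULES))
  need <- function(cols, i) {
    vals <- unlist(variants[i, cols])
    !any(is.na(vals))
  }
  rule <- function(i, name, cols, test) {
    if (!need(cols, i)) return("metric-missing")
    if (test) "pass" else "fail"
  }
  for (i in seq_len(n)) {
    v <- variants[i, ]
    trail[i, "strand_bias"] <-
      if (is.na(v$in_capture_pad200)) "metric-missing"
      else if (!v$in_capture_pad200) "skip"
      else rule(i, "strand_bias", "strand_bias",
                isTRUE(v$strand_bias > 0 && v$strand_bias < 1))
    trail[i, "depth"] <- rule(i, "depth", c("depth_total", "depth_alt"),
                              isTRUE(v$depth_total >= 8 && v$depth_alt >= 4))
    trail[i, "alignment_quality"] <-
      rule(i, "alignment_quality", c("mapping_quality", "base_quality"),
           isTRUE(v$mapping_quality >= 40 && v$base_quality >= 30))
    trail[i, "other_allele"] <-
      rule(i, "other_allele", "other_allele_fraction",
           isTRUE(v$other_allele_fraction < 0.4))
    trail[i, "alt_alignment"] <-
      rule(i, "alt_alignment", "alt_alignment_fraction",
           isTRUE(v$alt_alignment_fraction <= 0.1))
    trail[i, "long_indel"] <-
      if (v$type == "SNV") "skip"
      else rule(i, "long_indel", "indel_length",
                isTRUE(v$indel_length < 500))
    trail[i, "simple_repeat"] <-
      rule(i, "simple_repeat", "in_simple_repeat",
           isTRUE(!v$in_simple_repeat))
    trail[i, "selfchain"] <- rule(i, "selfchain", "in_selfchain95",
                                  isTRUE(!v$in_selfchain95))
  }
  persite_fail <- apply(trail[, setdiff(QUALITY_RULES, "snv_cluster"),
                              drop = FALSE], 1,
                        function(r) any(r %in% c("fail", "metric-missing")))
  # SNV cluster rule, on SNVs that pass all per-site rules
  trail[, "snv_cluster"] <- ifelse(variants$type == "SNV" & !persite_fail,
                                   "pass", "skip")
  for (chr in unique(variants$chrom)) {
    idx <- which(variants$chrom == chr & variants$type == "SNV" &
                   !persite_fail)
    idx <- idx[order(variants$pos[idx])]
    if (length(idx) < 3) next
    gaps <- diff(variants$pos[idx])
    run_id <- cumsum(c(0, gaps >= 5))
    for (rid in unique(run_id)) {
      members <- idx[run_id == rid]
      if (length(members) >= 3) trail[members, "snv_cluster"] <- "fail"
    }
  }
  fail_any <- apply(trail, 1, function(r)
    any(r %in% c("fail", "metric-missing")))
  variants$qc_pass <- !fail_any
  variants$trail <- apply(trail, 1, function(r)
    paste(paste(QUALITY_RULES, r, sep = ":"), collapse = ";"))
  variants$fail_reasons <- apply(trail, 1, function(r) {
    bad <- QUALITY_RULES[r %in% c("fail", "metric-missing")]
    miss <- QUALITY_RULES[r == "metric-missing"]
    reasons <- c(setdiff(bad, miss), if (length(miss)) "metric-missing")
    paste(reasons, collapse = ",")
  })
  variants
}

#' Select likely somatic variants
#'
#' Keeps variants that are (a) exonic or in splicing acceptor regions,
#' (b) non-synonymous SNVs or indels, and (c) at VAF >= `vaf_min`.
#' Variants with population frequency above `popfreq_max` are excluded
#' unless rescued by at least `cosmic_min` COSMIC hematological cancer
#' reports or by residing in a clonal-hematopoiesis gene (`ch_genes`).
#' Variants seen in the healthy donor set or on the panel blacklist are
#' removed.
#'
#' @param variants QC-passing variants with annotation columns
#'   `region_class` (`exonic`/`splicing_acceptor`/other), `exonic_func`,
#'   `VAF`, `popfreq`, `cosmic_heme_count`, `gene`, `in_donor_set`,
#'   `in_panel_blacklist`.
#' @param vaf_min Minimum VAF (inclusive).
#' @param popfreq_max Maximum population frequency without rescue
#'   (exclusive).
#' @param cosmic_min COSMIC hematological report count that rescues.
#' @param ch_genes Clonal-hematopoiesis rescue genes.
#' @param nonsyn_funcs `exonic_func` values accepted as non-synonymous.
#' @return `variants` with logical `somatic_candidate` and
#'   `somatic_reason`.
#' @export
select_somatic <- function(variants, vaf_min = 0.01, popfreq_max = 2e-4,
                           cosmic_min = 5,
                           ch_genes = c("DNMT3A", "TET2", "ASXL1"),
                           nonsyn_funcs = c("nonsynonymous_SNV",
                                            "frameshift", "stopgain",
                                            "startloss",
                                            "nonframeshift_indel")) {
  region_ok <- variants$region_class %in% c("exonic", "splicing_acceptor")
  func_ok <- variants$exonic_func %in% nonsyn_funcs
  vaf_ok <- !is.na(variants$VAF) & variants$VAF >= vaf_min
  rescued <- variants$cosmic_heme_count >= cosmic_min |
    variants$gene %in% ch_genes
  popfreq_ok <- variants$popfreq <= popfreq_max | rescued
  donor_ok <- !variants$in_donor_set
  blacklist_ok <- !variants$in_panel_blacklist
  keep <- region_ok & func_ok & vaf_ok & popfreq_ok & donor_ok &
    blacklist_ok
  reason <- character(nrow(variants))
  reason[!region_ok] <- "region"
  reason[region_ok & !func_ok] <- "synonymous"
  reason[region_ok & func_ok & !vaf_ok] <- "vaf"
  reason[region_ok & func_ok & vaf_ok & !popfreq_ok] <- "popfreq"
  reason[region_ok & func_ok & vaf_ok & popfreq_ok & !donor_ok] <- "donor"
  reason[region_ok & func_ok & vaf_ok & popfreq_ok & donor_ok &
           !blacklist_ok] <- "blacklist"
  reason[keep & rescued & variants$popfreq > popfreq_max] <- "rescued"
  variants$somatic_candidate <- keep
  variants$somatic_reason <- reason
  variants
}

#' Flag probable oncogenic variants
#'
#' A candidate is flagged iff (i) it is in COSMIC, (ii) its effect is
#' frameshift, stopgain or startloss, or (iii) the majority of damaging
#' functional predictions call it damaging. The first matching condition
#' is recorded.
#'
#' @param candidates Data frame with `in_cosmic`, `exonic_func`,
#'   `damaging_prediction_majority`.
#' @return `candidates` with logical `oncogenic` and `oncogenic_source`.
#' @export
flag_oncogenic <- function(candidates) {
  truncating <- candidates$exonic_func %in%
    c("frameshift", "stopgain", "startloss")
  src <- rep(NA_character_, nrow(candidates))
  src[candidates$damaging_prediction_majority %in% TRUE] <- "prediction"
  src[truncating] <- "truncating"
  src[candidates$in_cosmic %in% TRUE] <- "cosmic"
  candidates$oncogenic <- !is.na(src)
  candidates$oncogenic_source <- src
  candidates
}

#' Majority voting over fusion-caller tables
#'
#' Fusions found in the artifact database are removed first (exclusion
#' precedes voting); survivors are kept iff called by at least
#' `min_tools` distinct tools in the same sample, then merged into a
#' cohort master list with leukemia-gene annotation.
#'
#' @param tables Named list (tool -> data frame `sample`, `gene5`,
#'   `gene3`).
#' @param min_tools Minimum supporting tools.
#' @param artifact_db Data frame `gene5`, `gene3` of known-false fusions.
#' @param leukemia_genes Character vector for the `leukemia_flag`.
#' @return Data frame `sample`, `gene5`, `gene3`, `tools`, `n_tools`,
#'   `leukemia_flag`.
#' @export
fusion_majority_vote <- function(tables, min_tools = 3,
                                 artifact_db = NULL,
                                 leukemia_genes = character(0)) {
  rows <- lapply(names(tables), function(tool) {
    tb <- tables[[tool]]
    if (is.null(tb) || nrow(tb) == 0L) return(NULL)
    cbind(tb[, c("sample", "gene5", "gene3")], tool = tool)
  })
  all_calls <- do.call(rbind, rows)
  if (is.null(all_calls) || nrow(all_calls) == 0L)
    return(data.frame(sample = character(), gene5 = character(),
                      gene3 = character(), tools = character(),
                      n_tools = integer(), leukemia_flag = logical()))
  if (!is.null(artifact_db) && nrow(artifact_db)) {
    bad <- paste(all_calls$gene5, all_calls$gene3) %in%
      paste(artifact_db$gene5, artifact_db$gene3)
    all_calls <- all_calls[!bad, , drop = FALSE]
  }
  if (nrow(all_calls) == 0L)
    return(data.frame(sample = character(), gene5 = character(),
                      gene3 = character(), tools = character(),
                      n_tools = integer(), leukemia_flag = logical()))
  key <- paste(all_calls$sample, all_calls$gene5, all_calls$gene3,
               sep = "|")
  agg <- lapply(split(seq_len(nrow(all_calls)), key), function(idx) {
    tools <- sort(unique(all_calls$tool[idx]))
    cbind(all_calls[idx[1], c("sample", "gene5", "gene3")],
          tools = paste(tools, collapse = ","),
          n_tools = length(tools))
  })
  out <- do.call(rbind, agg)
  out <- out[out$n_tools >= min_tools, , drop = FALSE]
  out$leukemia_flag <- out$gene5 %in% leukemia_genes |
    out$gene3 %in% leukemia_genes
  rownames(out) <- NULL
  out
}
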