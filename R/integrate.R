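# Epigenome-expression integration: promoter-methylation starburst joins
# and the ensemble enhancer-gene assignment feeding the accessibility
# starburst.

#' Starburst join of differential methylation and expression
#'
#' Left-joins two differential tables on the intersection of their feature
#' ids and classifies every gene with the dual gate FDR < `fdr_cut` and
#' |log2FC| > `lfc_cut` on both layers: methylation up with expression down
#' is `hypermethylated-silenced`, methylation down with expression up is
#' `hypomethylated-activated`, any other doubly significant combination is
#' `discordant`, everything else `not-significant`. The correlation between
#' the layers is reported both on the plotted signed scores
#' (`-log10(FDR) * sign(log2FC)`, FDR capped at 1e-320) and on the raw
#' log2 fold changes.
#'
#' @param diff_meth,diff_expr Differential tables as from [nb_wald()].
#' @param fdr_cut,lfc_cut Dual significance gates.
#' @param annotation Optional data frame `gene_id`, `is_tf`,
#'   `is_hematopoietic`.
#' @return List with `records` (per-gene table with signed scores and
#'   class), `r_signed`/`p_signed` and `r_lfc`/`p_lfc` Pearson summaries.
#' @export
starburst_join <- function(diff_meth, diff_expr, fdr_cut = 0.05,
                           lfc_cut = 2, annotation = NULL) {
  shared <- intersect(diff_meth$feature, diff_expr$feature)
  if (length(shared) == 0L) stop("no shared gene ids between the two layers")
  m <- diff_meth[match(shared, diff_meth$feature), ]
  e <- diff_expr[match(shared, diff_expr$feature), ]
  rec <- data.frame(gene_id = shared,
                    meth_log2FC = m$log2FC, meth_FDR = m$FDR,
                    expr_log2FC = e$log2FC, expr_FDR = e$FDR,
                    stringsAsFactors = FALSE)
  rec$meth_score <- signed_score(rec$meth_log2FC, rec$meth_FDR)
  rec$expr_score <- signed_score(rec$expr_log2FC, rec$expr_FDR)
  sig_m <- !is.na(rec$meth_FDR) & rec$meth_FDR < fdr_cut &
    abs(rec$meth_log2FC) > lfc_cut
  sig_e <- !is.na(rec$expr_FDR) & rec$expr_FDR < fdr_cut &
    abs(rec$expr_log2FC) > lfc_cut
  cls <- rep("not-significant", nrow(rec))
  both <- sig_m & sig_e
  cls[both & rec$meth_log2FC > 0 & rec$expr_log2FC < 0] <-
    "hypermethylated-silenced"
  cls[both & rec$meth_log2FC < 0 & rec$expr_log2FC > 0] <-
    "hypomethylated-activated"
  cls[both & cls == "not-significant"] <- "discordant"
  rec$class <- cls
  if (!is.null(annotation)) {
    idx <- match(rec$gene_id, annotation$gene_id)
    rec$is_tf <- annotation$is_tf[idx]
    rec$is_hematopoietic <- annotation$is_hematopoietic[idx]
  }
  ok <- stats::complete.cases(rec[, c("meth_score", "expr_score")])
  cs <- stats::cor.test(rec$meth_score[ok], rec$expr_score[ok])
  ok2 <- stats::complete.cases(rec[, c("meth_log2FC", "expr_log2FC")])
  cl <- stats::cor.test(rec$meth_log2FC[ok2], rec$expr_log2FC[ok2])
  list(records = rec,
       r_signed = unname(cs$estimate), p_signed = cs$p.value,
       r_lfc = unname(cl$estimate), p_lfc = cl$p.value)
}

# internal: signed significance score for starburst axes
signed_score <- function(lfc, fdr, cap = 320) {
  s <- -log10(pmax(fdr, 1e-320)) * sign(lfc)
  pmin(pmax(s, -cap), cap)
}

#' Ensemble enhancer-to-gene assignment
#'
#' Candidate genes for every enhancer are the genes whose TSS lies within
#' `max_distance` and in the same TAD; enhancers outside every TAD fall
#' back to distance only and are flagged. Four evidence flags are scored
#' per candidate: `nearest` (closest candidate TSS), `correlation`
#' (enhancer-promoter accessibility correlation >= `corr_min` over at least
#' `min_corr_samples` shared samples), `loop` (a loop whose padded anchors
#' contact enhancer and promoter on opposite sides, 25 kb rule), and
#' `database` (prior assignment). The winner has the highest flag count;
#' ties resolve loop > database > correlation > nearest, then smallest
#' distance.
#'
#' @param enhancers Interval table with unique `id`.
#' @param tss_list TSS table (`gene_id`, `chrom`, `tss`, `strand`).
#' @param tads Interval table of disjoint TADs.
#' @param loops Loop table (`chrom`, `start1`, `end1`, `start2`, `end2`).
#' @param enh_counts,prom_counts Optional accessibility matrices keyed by
#'   enhancer id / gene id (columns = shared samples).
#' @param db_map Optional data frame `enhancer_id`, `gene_id`.
#' @param max_distance Candidate search radius in bp.
#' @param corr_min Correlation evidence threshold.
#' @param min_corr_samples Minimum shared samples for the correlation flag.
#' @param anchor_pad,contact_dist Loop-anchor padding and the maximum
#'   feature-anchor gap counted as contact (default 0: the padded anchor
#'   must overlap the element).
#' @return Data frame, one row per assigned enhancer: `enhancer_id`,
#'   `gene_id`, evidence flags, `tier`, `distance`, `outside_tad`.
#' @export
assign_enhancers <- function(enhancers, tss_list, tads, loops = NULL,
                             enh_counts = NULL, prom_counts = NULL,
                             db_map = NULL, max_distance = 1e6,
                             corr_min = 0.3, min_corr_samples = 8,
                             anchor_pad = 5000, contact_dist = 0) {
  stopifnot(!anyDuplicated(enhancers$id))
  out <- list()
  tad_idx <- if (!is.null(tads) && nrow(tads)) gi_overlap_pairs(enhancers, tads)
  for (i in seq_len(nrow(enhancers))) {
    enh <- enhancers[i, ]
    same_chr <- tss_list$chrom == enh$chrom
    dist <- gi_gap(enh$start, enh$end, tss_list$tss, tss_list$tss + 1)
    cand <- which(same_chr & dist <= max_distance)
    outside <- TRUE
    if (!is.null(tad_idx)) {
      my_tads <- tad_idx$b[tad_idx$a == i]
      if (length(my_tads)) {
        outside <- FALSE
        in_tad <- vapply(cand, function(j) {
          any(tss_list$tss[j] >= tads$start[my_tads] &
                tss_list$tss[j] < tads$end[my_tads])
        }, TRUE)
        cand <- cand[in_tad]
      }
    }
    if (length(cand) == 0L) next
    d <- dist[cand]
    fl_nearest <- seq_along(cand) == which.min(d)
    fl_loop <- vapply(cand, function(j)
      loop_contacts(loops, enh, tss_list$tss[j], enh$chrom,
                    anchor_pad, contact_dist), TRUE)
    fl_db <- if (is.null(db_map)) rep(FALSE, length(cand)) else
      paste(enh$id, tss_list$gene_id[cand]) %in%
        paste(db_map$enhancer_id, db_map$gene_id)
    fl_cor <- vapply(cand, function(j)
      corr_evidence(enh$id, tss_list$gene_id[j], enh_counts, prom_counts,
                    corr_min, min_corr_samples), TRUE)
    tier <- fl_nearest + fl_loop + fl_db + fl_cor
    # precedence: loop > database > correlation > nearest, then distance
    ordkey <- order(-tier, -fl_loop, -fl_db, -fl_cor, -fl_nearest, d)
    w <- ordkey[1]
    out[[length(out) + 1]] <- data.frame(
      enhancer_id = enh$id, gene_id = tss_list$gene_id[cand[w]],
      nearest = fl_nearest[w], correlation = fl_cor[w], loop = fl_loop[w],
      database = fl_db[w], tier = tier[w], distance = d[w],
      outside_tad = outside, stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(enhancer_id = character(), gene_id = character(),
                      nearest = logical(), correlation = logical(),
                      loop = logical(), database = logical(),
                      tier = integer(), distance = numeric(),
                      outside_tad = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

# internal: does any loop contact the enhancer and the TSS on opposite
# padded anchors?
loop_contacts <- function(loops, enh, tss, chrom, pad, max_dist) {
  if (is.null(loops) || nrow(loops) == 0L) return(FALSE)
  l <- loops[loops$chrom == chrom, , drop = FALSE]
  if (nrow(l) == 0L) return(FALSE)
  d_e1 <- gi_gap(l$start1 - pad, l$end1 + pad, enh$start, enh$end)
  d_e2 <- gi_gap(l$start2 - pad, l$end2 + pad, enh$start, enh$end)
  d_t1 <- gi_gap(l$start1 - pad, l$end1 + pad, tss, tss + 1)
  d_t2 <- gi_gap(l$start2 - pad, l$end2 + pad, tss, tss + 1)
  any((d_e1 <= max_dist & d_t2 <= max_dist) |
        (d_e2 <= max_dist & d_t1 <= max_dist))
}

# internal: accessibility-correlation evidence between enhancer and promoter
corr_evidence <- function(enh_id, gene_id, enh_counts, prom_counts,
                          corr_min, min_samples) {
  if (is.null(enh_counts) || is.null(prom_counts)) return(FALSE)
  if (!(enh_id %in% rownames(enh_counts)) ||
      !(gene_id %in% rownames(prom_counts))) return(FALSE)
  shared <- intersect(colnames(enh_counts), colnames(prom_counts))
  if (length(shared) < min_samples) return(FALSE)
  x <- enh_counts[enh_id, shared]; y <- prom_counts[gene_id, shared]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(FALSE)
  stats::cor(x, y) >= corr_min
}

#' Join differential enhancer accessibility to target-gene expression
#'
#' Produces one record per (enhancer, gene) pair from the enhancer-gene
#' map; a gene targeted by several enhancers yields several records.
#' Pairs are classified with the same dual FDR/fold-change gates as
#' [starburst_join()] (`concordant-activated`, `concordant-repressed`,
#' `discordant`, `not-significant`) and labeled by enhancer-TSS distance.
#' Unmapped enhancers are excluded and counted.
#'
#' @param diff_atac Differential accessibility keyed by enhancer id.
#' @param map Assignment table from [assign_enhancers()].
#' @param diff_expr Differential expression keyed by gene id.
#' @param fdr_cut,lfc_cut Significance gates.
#' @param distance_breaks Breaks in bp for the distance label.
#' @return List with `records`, Pearson `r_signed`/`p_signed`,
#'   `r_lfc`/`p_lfc`, and `n_unmapped`.
#' @export
enhancer_expression_join <- function(diff_atac, map, diff_expr,
                                     fdr_cut = 0.05, lfc_cut = 2,
                                     distance_breaks = c(0, 1e4, 1e5, Inf)) {
  n_unmapped <- sum(!(diff_atac$feature %in% map$enhancer_id))
  idx_a <- match(map$enhancer_id, diff_atac$feature)
  idx_e <- match(map$gene_id, diff_expr$feature)
  keep <- !is.na(idx_a) & !is.na(idx_e)
  map <- map[keep, , drop = FALSE]
  a <- diff_atac[idx_a[keep], ]; e <- diff_expr[idx_e[keep], ]
  rec <- data.frame(enhancer_id = map$enhancer_id, gene_id = map$gene_id,
                    atac_log2FC = a$log2FC, atac_FDR = a$FDR,
                    expr_log2FC = e$log2FC, expr_FDR = e$FDR,
                    distance = map$distance, stringsAsFactors = FALSE)
  rec$atac_score <- signed_score(rec$atac_log2FC, rec$atac_FDR)
  rec$expr_score <- signed_score(rec$expr_log2FC, rec$expr_FDR)
  lab <- cut(rec$distance, breaks = distance_breaks, include.lowest = TRUE,
             labels = c("<10kb", "10-100kb", ">100kb"))
  rec$distance_label <- as.character(lab)
  sig_a <- !is.na(rec$atac_FDR) & rec$atac_FDR < fdr_cut &
    abs(rec$atac_log2FC) > lfc_cut
  sig_e <- !is.na(rec$expr_FDR) & rec$expr_FDR < fdr_cut &
    abs(rec$expr_log2FC) > lfc_cut
  cls <- rep("not-significant", nrow(rec))
  both <- sig_a & sig_e
  cls[both & rec$atac_log2FC > 0 & rec$expr_log2FC > 0] <-
    "concordant-activated"
  cls[both & rec$atac_log2FC < 0 & rec$expr_log2FC < 0] <-
    "concordant-repressed"
  cls[both & cls == "not-significant"] <- "discordant"
  rec$class <- cls
  ok <- stats::complete.cases(rec[, c("atac_score", "expr_score")])
  cs <- if (sum(ok) >= 3) stats::cor.test(rec$atac_score[ok],
                                          rec$expr_score[ok])
  ok2 <- stats::complete.cases(rec[, c("atac_log2FC", "expr_log2FC")])
  cl <- if (sum(ok2) >= 3) stats::cor.test(rec$atac_log2FC[ok2],
                                           rec$expr_log2FC[ok2])
  list(records = rec,
       r_signed = if (is.null(cs)) NA_real_ else unname(cs$estimate),
       p_signed = if (is.null(cs)) NA_real_ else cs$p.value,
       r_lfc = if (is.null(cl)) NA_real_ else unname(cl$estimate),
       p_lfc = if (is.null(cl)) NA_real_ else cl$p.value,
       n_unmapped = n_unmapped)
}
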