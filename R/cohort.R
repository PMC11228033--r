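# Synthetic multi-omics cohort generator. Plants the statistical structure
# the downstream stages are designed to detect -- promoter hypermethylation
# coupled to TF silencing, CpG-position-dependent methylation-sensitive
# CTCF binding, loop/TAD changes coupled to anchor CTCF loss and target
# expression, group-structured negative-binomial counts, and variant tables
# with known-truth filter verdicts -- so the whole pipeline is testable
# without any restricted-access data.

#' Cohort generator configuration
#'
#' Defaults describe the emulated study: a CIMP leukemia group against AML,
#' T-ALL and healthy HSPC comparators, negative-binomial counts with a
#' common dispersion, ~5% of genes as silenced transcription factors with a
#' strong (8-fold) planted promoter-hypermethylation / expression-loss
#' effect, a logistic methylation-CTCF coupling, 70% loop-CTCF coupling,
#' and a target methylation-expression anticorrelation of -0.3.
#'
#' @param seed Integer seed; identical seed + config reproduces every
#'   output exactly.
#' @param n_per_group Named sample counts.
#' @param n_genes Number of genes.
#' @param n_regions Named feature counts per assay
#'   (`atac`, `ctcf`, `enhancers`, `loops`, `tads`).
#' @param genome_length Genome size in bp (single chromosome `chr1`).
#' @param nb_dispersion Negative-binomial dispersion (> 0).
#' @param effect_log2fc Planted silencing effect (log2; applied as
#'   `2^|effect|` promoter methylation gain and expression loss in CIMP).
#' @param frac_silenced_tfs Fraction of genes planted as silenced TFs.
#' @param ctcf_coupling_beta Methylation-to-CTCF logit slope (>= 0).
#' @param loop_ctcf_coupling Probability that a lost loop carries a lost
#'   CTCF anchor.
#' @param meth_expr_rho Target planted methylation-expression
#'   anticorrelation, in `[-1, 0]`.
#' @param meth_effect_sd,expr_effect_sd Standard deviations (log2) of the
#'   gene-wise planted methylation/expression effects.
#' @param frac_affected_genes Fraction of genes carrying the bivariate
#'   planted effects (the rest are unchanged between groups).
#' @param motif_effect_log2fc Planted CIMP accessibility effect in peaks of
#'   the designated motif.
#' @param ep_loop_expr_coupling Multiplier linking EP-loop strength changes
#'   to target-gene expression changes.
#' @param loop_effect_log2fc Planted CIMP effect for lost/gained loops.
#' @param ep_loop_effect_sd Standard deviation (log2) of EP-loop strength
#'   effects.
#' @param tad_effect_log2fc Planted effect for differential TADs.
#' @param frac_cpg_flagged Fraction of CTCF sites carrying motif CpGs at
#'   positions 5/15 (the methylation-sensitive class).
#' @return Validated list of class `"cohort_config"`.
#' @export
cohort_config <- function(seed = 1,
                          n_per_group = c(CIMP = 9, AML = 20,
                                          `T-ALL` = 15, HSPC = 3),
                          n_genes = 2000,
                          n_regions = c(atac = 400, ctcf = 250,
                                        enhancers = 150, loops = 150,
                                        tads = 40),
                          genome_length = 5e7,
                          nb_dispersion = 0.1,
                          effect_log2fc = -3,
                          frac_silenced_tfs = 0.05,
                          ctcf_coupling_beta = 2,
                          loop_ctcf_coupling = 0.7,
                          meth_expr_rho = -0.3,
                          meth_effect_sd = 1.5,
                          expr_effect_sd = 1.5,
                          frac_affected_genes = 0.3,
                          motif_effect_log2fc = 1,
                          ep_loop_expr_coupling = 0.8,
                          loop_effect_log2fc = 1,
                          ep_loop_effect_sd = 1.2,
                          tad_effect_log2fc = 0.8,
                          frac_cpg_flagged = 0.4) {
  cfg <- as.list(environment())
  defaults <- c(atac = 400, ctcf = 250, enhancers = 150, loops = 150,
                tads = 40)
  missing_r <- setdiff(names(defaults), names(n_regions))
  cfg$n_regions <- c(n_regions, defaults[missing_r])
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (any(n_per_group <= 0) || n_genes <= 0 || any(cfg$n_regions <= 0))
    stop("all sample and feature counts must be positive")
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  fr <- c(frac_silenced_tfs, loop_ctcf_coupling, frac_cpg_flagged,
          frac_affected_genes)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (meth_expr_rho < -1 || meth_expr_rho > 0)
    stop("meth_expr_rho must lie in [-1, 0]")
  if (ctcf_coupling_beta < 0) stop("ctcf_coupling_beta must be >= 0")
  structure(cfg, class = "cohort_config")
}

#' Null cohort configuration (all planted effects off)
#'
#' All group-differential parameters set to zero; every downstream
#' differential test should then be uniform under the null.
#' @param seed Integer seed.
#' @param ... Overrides passed to [cohort_config()].
#' @export
null_cohort_config <- function(seed = 1, ...) {
  cohort_config(seed = seed, effect_log2fc = 0, frac_silenced_tfs = 0,
                ctcf_coupling_beta = 0, loop_ctcf_coupling = 0,
                meth_expr_rho = 0, meth_effect_sd = 0, expr_effect_sd = 0,
                motif_effect_log2fc = 0, ep_loop_expr_coupling = 0,
                loop_effect_log2fc = 0, ep_loop_effect_sd = 0,
                tad_effect_log2fc = 0, ...)
}

# CTCF-like 19 bp consensus; CpG dinucleotides can only arise by design at
# positions 5-6 and 15-16 (other adjacent consensus pairs never form C,G)
CTCF_CONSENSUS <- c("T", "G", "G", "C", "C", "G", "C", "A", "G", "G",
                    "T", "G", "G", "C", "C", "G", "C", "T", "A")

#' Generate the synthetic genome model
#'
#' Lays out genes (with TF and hematopoietic flags), CpG-island truth,
#' tiling TADs, CTCF sites with motif sequences and CpG-position flags and
#' planted methylation levels, enhancers with target genes, and loops
#' (enhancer-promoter and CTCF-CTCF) with planted lost/gained classes and
#' CTCF-anchored coupling.
#'
#' @param config A [cohort_config()].
#' @return List of class `"genome_model"`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  L <- config$genome_length
  nr <- config$n_regions

  gene_slots <- seq(30000, L - 30000, by = 4000)
  if (length(gene_slots) < config$n_genes)
    stop("genome_length too small: ", length(gene_slots),
         " gene slots available for ", config$n_genes, " genes")
  tss <- sort(sample(gene_slots, config$n_genes))
  genes <- data.frame(
    gene_id = sprintf("g%05d", seq_len(config$n_genes)),
    chrom = "chr1", tss = tss,
    strand = sample(c("+", "-"), config$n_genes, replace = TRUE),
    is_tf = stats::runif(config$n_genes) < 0.15,
    stringsAsFactors = FALSE)
  genes$is_hematopoietic <- stats::runif(config$n_genes) <
    ifelse(genes$is_tf, 0.4, 0.1)
  # name the motif-set TF genes after real hematopoietic TFs so the motif
  # stage can match deviations to expression
  motif_tfs <- vapply(synthetic_motif_set(), `[[`, "", "tf")
  tf_slots <- which(genes$is_tf)
  if (length(tf_slots) < length(motif_tfs)) {
    genes$is_tf[seq_along(motif_tfs)] <- TRUE
    tf_slots <- which(genes$is_tf)
  }
  motif_tf_idx <- sample(tf_slots, length(motif_tfs))
  genes$gene_id[motif_tf_idx] <- motif_tfs

  cgi_genes <- sort(sample(config$n_genes, round(0.4 * config$n_genes)))
  cgi_truth <- genomic_intervals("chr1", genes$tss[cgi_genes] - 250,
                                 genes$tss[cgi_genes] + 250,
                                 id = paste0("cgi_", genes$gene_id[cgi_genes]))

  tad_w <- floor(L / nr[["tads"]])
  tads <- genomic_intervals("chr1", (seq_len(nr[["tads"]]) - 1) * tad_w,
                            seq_len(nr[["tads"]]) * tad_w,
                            id = sprintf("tad_%03d", seq_len(nr[["tads"]])))

  # CTCF sites on a grid offset from promoters
  ctcf_slots <- seq(32000, L - 32000, by = 4000) + 2000
  if (length(ctcf_slots) < nr[["ctcf"]])
    stop("genome_length too small for ", nr[["ctcf"]], " CTCF sites")
  cpos <- sort(sample(ctcf_slots, nr[["ctcf"]]))
  n_ctcf <- nr[["ctcf"]]
  flagged <- stats::runif(n_ctcf) < config$frac_cpg_flagged
  has5 <- flagged & stats::runif(n_ctcf) < 0.85
  has15 <- flagged & (stats::runif(n_ctcf) < 0.85 | !has5)
  seqs <- vapply(seq_len(n_ctcf), function(i) {
    b <- ifelse(stats::runif(19) < 0.95, CTCF_CONSENSUS,
                sample(c("A", "C", "G", "T"), 19, replace = TRUE))
    b[5] <- "C"; b[15] <- "C"
    b[6] <- if (has5[i]) "G" else "A"
    b[16] <- if (has15[i]) "G" else "A"
    paste(b, collapse = "")
  }, "")
  # planted methylation level: sensitive (flagged) sites split into a
  # hypermethylated half and a low-methylation half
  meth <- stats::runif(n_ctcf, 0, 0.15)
  hyper <- flagged & stats::runif(n_ctcf) < 0.5
  meth[hyper] <- stats::runif(sum(hyper), 0.6, 1)
  ctcf_sites <- data.frame(
    site_id = sprintf("ctcf_%04d", seq_len(n_ctcf)), chrom = "chr1",
    start = cpos - 200, end = cpos + 200, motif_seq = seqs,
    has_cpg_5 = has5, has_cpg_15 = has15, meth_level = meth,
    stringsAsFactors = FALSE)
  lost_truth <- flagged & hyper & config$ctcf_coupling_beta > 0

  # enhancers target a gene 20-90 kb away inside the same TAD
  n_enh <- nr[["enhancers"]]
  target <- sample(config$n_genes, n_enh, replace = n_enh > config$n_genes)
  offs <- stats::runif(n_enh, 20000, 90000) *
    sample(c(-1, 1), n_enh, replace = TRUE)
  epos <- genes$tss[target] + offs
  same_tad <- floor(epos / tad_w) == floor(genes$tss[target] / tad_w)
  epos[!same_tad] <- genes$tss[target[!same_tad]] - offs[!same_tad]
  epos <- pmin(pmax(epos, 1000), L - 1000)
  enhancers <- data.frame(
    enhancer_id = sprintf("enh_%04d", seq_len(n_enh)), chrom = "chr1",
    start = round(epos - 300), end = round(epos + 300),
    target_gene = genes$gene_id[target], stringsAsFactors = FALSE)
  # GeneHancer-like prior: covers ~60% of enhancers, with a few wrong
  # decoy assignments
  db_cover <- stats::runif(n_enh) < 0.7
  n_decoy <- max(1, round(0.05 * n_enh))
  decoy <- sample(n_enh, n_decoy)
  db_map <- rbind(
    data.frame(enhancer_id = enhancers$enhancer_id[db_cover],
               gene_id = enhancers$target_gene[db_cover],
               stringsAsFactors = FALSE),
    data.frame(enhancer_id = enhancers$enhancer_id[decoy],
               gene_id = sample(genes$gene_id, n_decoy),
               stringsAsFactors = FALSE))

  # loops: 40% enhancer-promoter, rest CTCF-CTCF; CTCF loops carry the
  # planted lost/gained classes with anchor coupling
  n_loops <- nr[["loops"]]
  n_ep <- min(round(0.4 * n_loops), n_enh)
  n_cc <- n_loops - n_ep
  ep_idx <- sample(n_enh, n_ep)
  mk_anchor <- function(center) {
    cbind(pmax(0, round(center) - 2500), round(center) + 2500)
  }
  a_e <- mk_anchor((enhancers$start[ep_idx] + enhancers$end[ep_idx]) / 2)
  a_p <- mk_anchor(genes$tss[match(enhancers$target_gene[ep_idx],
                                   genes$gene_id)])
  swap <- a_e[, 1] > a_p[, 1]
  ep_loops <- data.frame(
    id = sprintf("loop_ep_%03d", seq_len(n_ep)), chrom = "chr1",
    start1 = ifelse(swap, a_p[, 1], a_e[, 1]),
    end1 = ifelse(swap, a_p[, 2], a_e[, 2]),
    start2 = ifelse(swap, a_e[, 1], a_p[, 1]),
    end2 = ifelse(swap, a_e[, 2], a_p[, 2]),
    type = "EP", enhancer_id = enhancers$enhancer_id[ep_idx],
    gene_id = enhancers$target_gene[ep_idx],
    anchor_site1 = NA_character_, anchor_site2 = NA_character_,
    planted_change = "stable", coupled = FALSE, stringsAsFactors = FALSE)

  # CTCF-CTCF loops: planted classes lost (15%), gained (10%), stable --
  # kept inside the trim tolerance of TMM score normalization
  cls <- sample(rep(c("lost", "gained", "stable"),
                    times = c(round(0.15 * n_cc), round(0.10 * n_cc),
                              n_cc - round(0.15 * n_cc) - round(0.10 * n_cc))))
  coupled <- cls == "lost" & stats::runif(n_cc) < config$loop_ctcf_coupling
  lost_pool <- which(lost_truth)
  other_pool <- which(!lost_truth)
  cc <- lapply(seq_len(n_cc), function(i) {
    s1 <- if (coupled[i] && length(lost_pool))
      sample(lost_pool, 1) else sample(other_pool, 1)
    cand <- which(abs(cpos - cpos[s1]) > 50000 &
                    abs(cpos - cpos[s1]) < 1e6 &
                    floor(cpos / tad_w) == floor(cpos[s1] / tad_w) &
                    !lost_truth)
    s2 <- if (length(cand)) cand[sample.int(length(cand), 1)] else
      other_pool[sample.int(length(other_pool), 1)]
    lo <- min(cpos[s1], cpos[s2]); hi <- max(cpos[s1], cpos[s2])
    data.frame(id = sprintf("loop_cc_%03d", i), chrom = "chr1",
               start1 = lo - 2500, end1 = lo + 2500,
               start2 = hi - 2500, end2 = hi + 2500, type = "CTCF",
               enhancer_id = NA_character_, gene_id = NA_character_,
               anchor_site1 = ctcf_sites$site_id[s1],
               anchor_site2 = ctcf_sites$site_id[s2],
               planted_change = cls[i], coupled = coupled[i],
               stringsAsFactors = FALSE)
  })
  loops <- rbind(ep_loops, do.call(rbind, cc))

  structure(list(chromosomes = data.frame(name = "chr1", length = L),
                 genes = genes, cgi_truth = cgi_truth, tads = tads,
                 ctcf_sites = ctcf_sites, lost_ctcf_truth = lost_truth,
                 enhancers = enhancers, db_map = db_map, loops = loops,
                 config = config),
            class = "genome_model")
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf(paste0("<genome_model> %d genes, %d CTCF sites, %d enhancers, ",
                     "%d TADs, %d loops on %s (%g bp)\n"),
              nrow(x$genes), nrow(x$ctcf_sites), nrow(x$enhancers),
              nrow(x$tads), nrow(x$loops), x$chromosomes$name[1],
              x$chromosomes$length[1]))
  invisible(x)
}

# internal: NB draw tolerating zero dispersion (Poisson limit)
rnb <- function(n, mu, dispersion) {
  if (dispersion < 1e-12) stats::rpois(n, mu)
  else stats::rnbinom(n, mu = mu, size = 1 / dispersion)
}

#' Simulate the cohort count matrices
#'
#' Draws all assay matrices as negative-binomial counts with group-specific
#' means and >= 3-fold library-size variation (log-uniform on [1,3]):
#' expression and promoter methylation (with the planted bivariate gene
#' effects and TF silencing), CTCF binding scaled in CIMP by a normalized
#' logistic function of the planted site methylation (CpG-flagged sites
#' only), methylation over CTCF regions, loop density and TAD inclusion
#' scores with the planted lost/gained classes, ATAC accessibility over
#' enhancer/promoter/background peaks with motif-planted group effects, and
#' per-sample ATAC peak sets for consensus-list construction.
#'
#' @param genome A [generate_genome()] result.
#' @param config The same [cohort_config()].
#' @return List of class `"cohort_simulation"`: count matrices, sample
#'   annotation, peak metadata (sequences, GC), per-sample peak sets, and
#'   the `truth` ledger.
#' @export
simulate_counts <- function(genome, config) {
  stopifnot(inherits(genome, "genome_model"))
  if (config$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  set.seed(config$seed + 1L)
  npg <- config$n_per_group
  groups <- rep(names(npg), npg)
  samples <- paste(groups, unlist(lapply(npg, seq_len)), sep = "_")
  n <- length(samples)
  lib <- exp(stats::runif(n, 0, log(3)))   # >= 3-fold range by design
  names(lib) <- samples
  is_cimp <- groups == "CIMP"
  disp <- config$nb_dispersion
  ng <- nrow(genome$genes)

  # gene-wise planted effects: bivariate normal with target correlation
  rho <- config$meth_expr_rho
  z1 <- stats::rnorm(ng); z2 <- stats::rnorm(ng)
  affected <- stats::runif(ng) < config$frac_affected_genes
  dm <- config$meth_effect_sd * z1 * affected
  de <- config$expr_effect_sd * (rho * z1 + sqrt(1 - rho^2) * z2) * affected
  motif_tfs <- vapply(synthetic_motif_set(), `[[`, "", "tf")
  motif_tf_idx <- match(motif_tfs, genome$genes$gene_id)
  tf_pool <- setdiff(which(genome$genes$is_tf), motif_tf_idx)
  n_sil <- min(round(config$frac_silenced_tfs * ng), length(tf_pool))
  silenced <- sort(sample(tf_pool, n_sil))
  eff <- abs(config$effect_log2fc)
  dm[silenced] <- eff; de[silenced] <- -eff

  draw <- function(base, lfc_cimp) {
    mu <- outer(base, lib) * 2^(outer(lfc_cimp, is_cimp) * 1)
    m <- matrix(rnb(length(mu), mu, disp), nrow = length(base))
    colnames(m) <- samples
    m
  }

  base_expr <- stats::rlnorm(ng, log(100), 0.7)
  base_meth <- stats::rlnorm(ng, log(80), 0.6)
  mcip_prom <- draw(base_meth, dm)
  rownames(mcip_prom) <- genome$genes$gene_id

  # CTCF binding: normalized logistic coupling to planted methylation
  cs <- genome$ctcf_sites
  flaggedc <- cs$has_cpg_5 | cs$has_cpg_15
  scale_c <- ifelse(flaggedc,
                    2 * stats::plogis(-config$ctcf_coupling_beta *
                                        cs$meth_level), 1)
  ctcf <- draw(stats::rlnorm(nrow(cs), log(120), 0.5), log2(scale_c))
  rownames(ctcf) <- cs$site_id
  # methylation counts over CTCF site regions (3-fold per unit meth level)
  meth_lfc_ctcf <- if (config$ctcf_coupling_beta > 0) 3 * cs$meth_level
                   else numeric(nrow(cs))
  mcip_ctcf <- draw(stats::rlnorm(nrow(cs), log(60), 0.5), meth_lfc_ctcf)
  rownames(mcip_ctcf) <- cs$site_id

  # loops: planted classes, EP-loop effects coupled to target expression
  lp <- genome$loops
  dl <- numeric(nrow(lp))
  dl[lp$planted_change == "lost"] <- -config$loop_effect_log2fc
  dl[lp$planted_change == "gained"] <- config$loop_effect_log2fc
  is_ep <- lp$type == "EP"
  dl[is_ep] <- stats::rnorm(sum(is_ep), 0, config$ep_loop_effect_sd)
  gi <- match(lp$gene_id[is_ep], genome$genes$gene_id)
  # loop-contacted genes: expression change dominated by loop change
  coupled_gi <- setdiff(gi, silenced)
  dl_gi <- dl[is_ep][match(coupled_gi, gi)]
  if (config$ep_loop_expr_coupling > 0)
    de[coupled_gi] <- 0.3 * de[coupled_gi] +
      config$ep_loop_expr_coupling * dl_gi
  # the planted motif's TF is expressed higher in CIMP, in step with the
  # planted accessibility gain at its motif peaks
  de[motif_tf_idx[1]] <- config$motif_effect_log2fc
  expr <- draw(base_expr, de); rownames(expr) <- genome$genes$gene_id
  tpm <- sweep(expr, 2, colSums(expr), "/") * 1e6
  loop_scores <- draw(stats::rlnorm(nrow(lp), log(50), 0.4), dl)
  rownames(loop_scores) <- lp$id
  lost_loop_ids <- lp$id[dl < -0.5]
  gained_loop_ids <- lp$id[dl > 0.5]

  # TAD inclusion-ratio scores: 20% differential
  nt <- nrow(genome$tads)
  dt <- ifelse(stats::runif(nt) < 0.2,
               sample(c(-1, 1), nt, replace = TRUE) *
                 config$tad_effect_log2fc, 0)
  tad_scores <- draw(stats::rlnorm(nt, log(200), 0.3), dt)
  rownames(tad_scores) <- genome$tads$id

  # ATAC peaks: enhancer peaks + promoter peaks + background; one planted
  # motif with a group accessibility effect in its peaks
  enh <- genome$enhancers
  n_enh <- nrow(enh)
  n_prom <- min(100, ng)
  prom_genes <- sort(sample(ng, n_prom))
  n_bg <- max(0, config$n_regions[["atac"]] - n_enh - n_prom)
  bg_pos <- sort(sample(seq(20000, genome$chromosomes$length[1] - 20000,
                            by = 1000), n_bg))
  peaks <- rbind(
    data.frame(peak_id = enh$enhancer_id, chrom = "chr1",
               start = enh$start, end = enh$end, kind = "enhancer",
               stringsAsFactors = FALSE),
    data.frame(peak_id = paste0("promopk_", genome$genes$gene_id[prom_genes]),
               chrom = "chr1", start = genome$genes$tss[prom_genes] - 300,
               end = genome$genes$tss[prom_genes] + 300, kind = "promoter",
               stringsAsFactors = FALSE),
    data.frame(peak_id = sprintf("bgpk_%04d", seq_len(n_bg)), chrom = "chr1",
               start = bg_pos - 300, end = bg_pos + 300, kind = "background",
               stringsAsFactors = FALSE))
  npk <- nrow(peaks)
  motifs <- synthetic_motif_set()
  planted_motif <- motifs[[1]]$id
  peak_seqs <- vapply(seq_len(npk), function(i)
    paste(sample(c("A", "C", "G", "T"), 200, replace = TRUE,
                 prob = c(0.275, 0.225, 0.225, 0.275)), collapse = ""), "")
  names(peak_seqs) <- peaks$peak_id
  # plant each motif's consensus into a disjoint quarter/eighth of peaks
  slots <- sample(npk)
  n_plant <- round(npk / 4)
  motif_peaks <- list()
  at <- 1
  for (m in seq_along(motifs)) {
    take <- if (m == 1) n_plant else round(npk / 12)
    idx <- slots[at:(at + take - 1)]; at <- at + take
    cons <- apply(motifs[[m]]$prob, 2, function(p) BASES[which.max(p)])
    for (i in idx) {
      pos <- sample(50, 1)
      substr(peak_seqs[i], pos, pos + length(cons) - 1) <-
        paste(cons, collapse = "")
    }
    motif_peaks[[motifs[[m]]$id]] <- peaks$peak_id[idx]
  }
  da <- numeric(npk)
  # enhancer accessibility tracks its target gene's expression effect;
  # the residual noise only exists when expression effects are planted
  eff_on <- config$expr_effect_sd > 0 || config$effect_log2fc != 0
  da[peaks$kind == "enhancer"] <-
    0.8 * de[match(enh$target_gene, genome$genes$gene_id)] +
    stats::rnorm(n_enh, 0, 0.3) * eff_on
  da[peaks$kind == "promoter"] <- 0.5 * de[prom_genes]
  in_planted <- peaks$peak_id %in% motif_peaks[[planted_motif]]
  da[in_planted] <- da[in_planted] + config$motif_effect_log2fc
  atac <- draw(stats::rlnorm(npk, log(90), 0.5), da)
  rownames(atac) <- peaks$peak_id

  # per-sample ATAC peak sets with -log10(q) significance
  atac_peaksets <- lapply(seq_len(n), function(j) {
    keep <- stats::runif(npk) < 0.85
    q <- ifelse(stats::runif(npk) < 0.94,
                stats::runif(npk, 12, 60), stats::runif(npk, 5, 9))
    cbind(genomic_intervals(peaks$chrom[keep], peaks$start[keep],
                            peaks$end[keep], id = peaks$peak_id[keep]),
          neglog10q = q[keep])
  })
  names(atac_peaksets) <- samples

  truth <- list(
    silenced_tf_ids = genome$genes$gene_id[silenced],
    hypermethylated_promoter_ids =
      genome$genes$gene_id[dm > 1 | seq_len(ng) %in% silenced],
    lost_ctcf_site_ids = cs$site_id[genome$lost_ctcf_truth],
    lost_loop_ids = lost_loop_ids, gained_loop_ids = gained_loop_ids,
    enhancer_targets = stats::setNames(enh$target_gene, enh$enhancer_id),
    planted_motif_id = planted_motif, motif_peaks = motif_peaks,
    gene_effects = data.frame(gene_id = genome$genes$gene_id,
                              meth_log2fc = dm, expr_log2fc = de))
  structure(list(samples = data.frame(sample = samples, group = groups,
                                      lib_factor = lib,
                                      stringsAsFactors = FALSE),
                 expression = expr, tpm = tpm, mcip_promoters = mcip_prom,
                 ctcf = ctcf, mcip_ctcf = mcip_ctcf,
                 loop_scores = loop_scores, tad_scores = tad_scores,
                 atac = atac, peaks = peaks, peak_seqs = peak_seqs,
                 peak_gc = gc_content(peak_seqs), motifs = motifs,
                 atac_peaksets = atac_peaksets, truth = truth,
                 config = config),
            class = "cohort_simulation")
}

#' GC fraction of DNA strings
#' @param seqs Character vector of sequences.
#' @export
gc_content <- function(seqs) {
  vapply(strsplit(toupper(seqs), "", fixed = TRUE), function(ch)
    mean(ch %in% c("C", "G")), 0)
}

# internal: small fixed motif collection; motif 1 is the planted one
synthetic_motif_set <- function() {
  mk <- function(id, tf, consensus, strength = 0.85) {
    b <- strsplit(consensus, "")[[1]]
    m <- matrix((1 - strength) / 3, 4, length(b), dimnames = list(BASES))
    for (k in seq_along(b)) m[b[k], k] <- strength
    motif_pwm(id, tf, m)
  }
  list(mk("M001", "GATA2", "AGATAAGATG"),
       mk("M002", "SPI1", "AAAGAGGAAGTG"),
       mk("M003", "CEBPA", "ATTGCGCAAT"),
       mk("M004", "TCF7", "CCTTTGATGT"),
       mk("M005", "RUNX1", "TGTGGTTTCC"),
       mk("M006", "MYB", "TAACGGTTAC"))
}

#' Simulate multi-caller variant and fusion tables with truth verdicts
#'
#' Produces a variant table covering the pass and fail branch of every
#' quality rule (strand bias, depth, alignment/base quality, other-allele
#' and alternative-alignment fractions, long indels, simple repeats,
#' self-chain, SNV clusters, missing metrics) and of the somatic selection
#' rules (region, functional class, VAF, population frequency with COSMIC
#' and clonal-hematopoiesis rescues, donor set, blacklist) plus oncogenic
#' flags -- with the expected verdict of each variant recorded at planting
#' time. The table is split across three caller tables (with one
#' equivalent-but-differently-represented indel pair), and six fusion-tool
#' tables exercise the majority vote and artifact exclusion.
#'
#' @param genome A [generate_genome()] result.
#' @param config The [cohort_config()].
#' @return List with `caller_tables`, `variants` (the unified truth table
#'   with `expected_qc_pass`, `expected_somatic`, `expected_oncogenic`,
#'   `planted_rule`), `fusion_tables`, `artifact_db`,
#'   `expected_kept_fusions`, `leukemia_genes`.
#' @export
simulate_variant_tables <- function(genome, config) {
  set.seed(config$seed + 2L)
  clean <- function(n, start_pos) {
    vaf <- stats::runif(n, 0.2, 0.5)
    dt <- sample(30:200, n, replace = TRUE)
    data.frame(
      chrom = "chr1", pos = start_pos + seq_len(n) * 1000,
      ref = sample(c("A", "C", "G", "T"), n, replace = TRUE),
      alt = "T", type = "SNV",
      depth_total = dt, depth_alt = pmax(4, round(vaf * dt)),
      VAF = vaf, strand_bias = stats::runif(n, 0.3, 0.7),
      mapping_quality = 60, base_quality = 35,
      other_allele_fraction = stats::runif(n, 0, 0.2),
      alt_alignment_fraction = stats::runif(n, 0, 0.05),
      indel_length = 0, in_capture_pad200 = TRUE,
      in_simple_repeat = FALSE, in_selfchain95 = FALSE,
      region_class = "exonic", exonic_func = "nonsynonymous_SNV",
      popfreq = 0, cosmic_heme_count = 0,
      gene = paste0("GENE", start_pos + seq_len(n)),
      in_donor_set = FALSE, in_panel_blacklist = FALSE,
      in_cosmic = FALSE, damaging_prediction_majority = FALSE,
      planted_rule = "none", expected_qc_pass = TRUE,
      expected_somatic = TRUE, expected_oncogenic = FALSE,
      stringsAsFactors = FALSE)
  }
  v <- clean(170, 0)
  plant <- function(rule, qc = FALSE, somatic = FALSE, onco = FALSE, ...) {
    row <- clean(1, 8e5 + nrow(v) * 1000)
    mods <- list(...)
    for (nm in names(mods)) row[[nm]] <- mods[[nm]]
    row$planted_rule <- rule
    row$expected_qc_pass <- qc
    row$expected_somatic <- somatic
    row$expected_oncogenic <- onco
    v <<- rbind(v, row)
  }
  # quality-rule branches
  plant("strand_bias_zero", strand_bias = 0)
  plant("strand_bias_one", strand_bias = 1)
  plant("strand_bias_outside_capture", qc = TRUE, somatic = TRUE,
        strand_bias = 0, in_capture_pad200 = FALSE)
  plant("depth_total_low", depth_total = 7, depth_alt = 4, VAF = 4 / 7)
  plant("depth_alt_low", depth_total = 50, depth_alt = 3, VAF = 3 / 50)
  plant("mapping_quality_low", mapping_quality = 39)
  plant("base_quality_low", base_quality = 29)
  plant("other_allele_at_limit", other_allele_fraction = 0.4)
  plant("other_allele_below_limit", qc = TRUE, somatic = TRUE,
        other_allele_fraction = 0.39)
  plant("alt_alignment_high", alt_alignment_fraction = 0.11)
  plant("alt_alignment_at_limit", qc = TRUE, somatic = TRUE,
        alt_alignment_fraction = 0.10)
  plant("indel_500", type = "deletion", indel_length = 500,
        exonic_func = "frameshift")
  plant("indel_499", qc = TRUE, somatic = TRUE, onco = TRUE,
        type = "deletion", indel_length = 499, exonic_func = "frameshift")
  plant("simple_repeat", in_simple_repeat = TRUE)
  plant("selfchain", in_selfchain95 = TRUE)
  plant("metric_missing", strand_bias = NA_real_)
  # SNV cluster: gaps 3 and 4 -> removed; gap-5 trio -> kept
  for (p in c(900100, 900103, 900107))
    plant("snv_cluster", pos = p, ref = "A")
  for (p in c(950100, 950103, 950108))
    plant("snv_cluster_kept", qc = TRUE, somatic = TRUE, pos = p, ref = "A")
  # somatic-selection branches (all pass QC)
  plant("region_intronic", qc = TRUE, region_class = "intronic")
  plant("splicing_acceptor", qc = TRUE, somatic = TRUE,
        region_class = "splicing_acceptor")
  plant("synonymous", qc = TRUE, exonic_func = "synonymous_SNV")
  plant("vaf_low", qc = TRUE, VAF = 0.009, depth_total = 2000,
        depth_alt = 18)
  plant("vaf_at_limit", qc = TRUE, somatic = TRUE, VAF = 0.01,
        depth_total = 2000, depth_alt = 20)
  plant("popfreq_excluded", qc = TRUE, popfreq = 0.001)
  plant("popfreq_cosmic_rescue", qc = TRUE, somatic = TRUE, onco = TRUE,
        popfreq = 0.001, cosmic_heme_count = 6, in_cosmic = TRUE)
  plant("popfreq_cosmic_insufficient", qc = TRUE, popfreq = 0.001,
        cosmic_heme_count = 4)
  plant("popfreq_ch_gene_rescue", qc = TRUE, somatic = TRUE,
        popfreq = 0.001, gene = "DNMT3A")
  plant("popfreq_at_limit", qc = TRUE, somatic = TRUE, popfreq = 2e-4)
  plant("donor_removed", qc = TRUE, in_donor_set = TRUE)
  plant("blacklist_removed", qc = TRUE, in_panel_blacklist = TRUE)
  # oncogenic branches
  plant("onco_stopgain", qc = TRUE, somatic = TRUE, onco = TRUE,
        exonic_func = "stopgain")
  plant("onco_damaging_majority", qc = TRUE, somatic = TRUE, onco = TRUE,
        damaging_prediction_majority = TRUE)
  plant("onco_cosmic", qc = TRUE, somatic = TRUE, onco = TRUE,
        in_cosmic = TRUE)

  # split across callers; every variant in >= 1 table
  callers <- c("gatk", "varscan", "strelka")
  assign <- lapply(seq_len(nrow(v)), function(i)
    sample(callers, sample(1:3, 1)))
  caller_tables <- lapply(callers, function(cl) {
    idx <- which(vapply(assign, function(a) cl %in% a, TRUE))
    v[idx, setdiff(names(v), c("planted_rule", "expected_qc_pass",
                               "expected_somatic", "expected_oncogenic"))]
  })
  names(caller_tables) <- callers
  # equivalent representations of one insertion: normalized in gatk,
  # suffix/prefix-padded in varscan
  ins <- clean(1, 9.9e5)
  ins$type <- "insertion"; ins$ref <- "A"; ins$alt <- "AT"
  ins$indel_length <- 1
  padded <- ins
  padded$pos <- ins$pos - 1; padded$ref <- "CA"; padded$alt <- "CAT"
  caller_tables$gatk <- rbind(caller_tables$gatk,
                              ins[, names(caller_tables$gatk)])
  caller_tables$varscan <- rbind(caller_tables$varscan,
                                 padded[, names(caller_tables$varscan)])
  ins$planted_rule <- "indel_representation"
  ins$expected_qc_pass <- TRUE; ins$expected_somatic <- TRUE
  ins$expected_oncogenic <- FALSE
  v <- rbind(v, ins)

  # fusion tables across six tools
  tools <- c("starfusion", "fusioncatcher", "arriba", "pizzly", "jaffa",
             "squid")
  fus <- function(sample, g5, g3, ntools) {
    lapply(tools[seq_len(ntools)], function(t)
      data.frame(sample = sample, gene5 = g5, gene3 = g3, tool = t,
                 stringsAsFactors = FALSE))
  }
  calls <- c(fus("CIMP_1", "KMT2A", "MLLT3", 4),
             fus("CIMP_1", "AAAA", "BBBB", 2),
             fus("CIMP_2", "ARTE", "FACT", 6),
             fus("CIMP_2", "NUP98", "NSD1", 3))
  calls <- do.call(rbind, calls)
  fusion_tables <- lapply(tools, function(t)
    calls[calls$tool == t, c("sample", "gene5", "gene3")])
  names(fusion_tables) <- tools
  list(caller_tables = caller_tables, variants = v,
       fusion_tables = fusion_tables,
       artifact_db = data.frame(gene5 = "ARTE", gene3 = "FACT",
                                stringsAsFactors = FALSE),
       expected_kept_fusions = data.frame(
         sample = c("CIMP_1", "CIMP_2"), gene5 = c("KMT2A", "NUP98"),
         gene3 = c("MLLT3", "NSD1"), stringsAsFactors = FALSE),
       leukemia_genes = c("KMT2A", "MLLT3", "NUP98", "NSD1"))
}

#' Write the fixture bundle to disk
#'
#' Emits the cohort as plain-text files (BED features, per-sample
#' narrowPeak, TSV count matrices, BEDPE loops, FASTA sequences, JASPAR
#' PWMs, TSV variant/fusion tables) plus a JSON manifest with md5
#' checksums.
#'
#' @param genome,sim,variants Generator outputs.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_fixture_bundle <- function(genome, sim, variants, dir) {
  ok <- dir.exists(dir) || dir.create(dir, recursive = TRUE)
  if (!ok || file.access(dir, 2) != 0)
    stop("cannot write to directory: ", dir)
  p <- function(f) file.path(dir, f)
  tssbed <- genomic_intervals(genome$genes$chrom, genome$genes$tss,
                              genome$genes$tss + 1, genome$genes$strand,
                              genome$genes$gene_id)
  write_bed(tssbed, p("tss.bed"))
  write_bed(genome$cgi_truth, p("cgi_truth.bed"))
  write_bed(genome$tads, p("tads.bed"))
  write_bed(genomic_intervals(genome$enhancers$chrom,
                              genome$enhancers$start, genome$enhancers$end,
                              id = genome$enhancers$enhancer_id),
            p("enhancers.bed"))
  write_bedpe(genome$loops, p("loops.bedpe"))
  for (s in names(sim$atac_peaksets))
    write_narrowpeak(sim$atac_peaksets[[s]],
                     p(sprintf("atac_%s.narrowPeak", s)))
  write_counts_tsv(sim$expression, p("expression_counts.tsv"))
  write_counts_tsv(sim$mcip_promoters, p("mcip_promoter_counts.tsv"))
  write_counts_tsv(sim$ctcf, p("ctcf_counts.tsv"))
  write_counts_tsv(sim$mcip_ctcf, p("mcip_ctcf_counts.tsv"))
  write_counts_tsv(sim$atac, p("atac_counts.tsv"))
  write_counts_tsv(sim$loop_scores, p("loop_scores.tsv"))
  write_counts_tsv(sim$tad_scores, p("tad_scores.tsv"))
  writeLines(paste0(">", names(sim$peak_seqs), "\n", sim$peak_seqs),
             p("peak_sequences.fa"))
  writeLines(paste0(">", genome$ctcf_sites$site_id, "\n",
                    genome$ctcf_sites$motif_seq), p("ctcf_motifs.fa"))
  write_jaspar(sim$motifs, p("motifs.jaspar"))
  for (cl in names(variants$caller_tables))
    utils::write.table(variants$caller_tables[[cl]],
                       p(sprintf("variants_%s.tsv", cl)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  for (t in names(variants$fusion_tables))
    utils::write.table(variants$fusion_tables[[t]],
                       p(sprintf("fusions_%s.tsv", t)), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  files <- list.files(dir)
  manifest <- data.frame(
    file = files,
    format = vapply(files, function(f)
      switch(sub(".*\\.", "", f), bed = "BED", bedpe = "BEDPE",
             narrowPeak = "narrowPeak", tsv = "TSV", fa = "FASTA",
             jaspar = "JASPAR", "other"), ""),
    md5 = unname(tools::md5sum(file.path(dir, files))),
    stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, p("manifest.json"), dataframe = "rows",
                       pretty = TRUE)
  invisible(manifest)
}
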