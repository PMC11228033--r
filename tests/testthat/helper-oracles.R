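# Independent brute-force oracles used across the test suite. These are
# deliberately written as plain loops / direct transcriptions of the written
# rules, sharing no code with the package internals.

# Exhaustive sliding-window CpG-island oracle (1-based internally, returns
# 0-based half-open intervals).
oracle_cgi <- function(sequence, min_length = 200, min_gc = 0.5,
                       min_oe = 0.6) {
  ch <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  L <- length(ch); w <- min_length
  empty <- data.frame(start = numeric(), end = numeric())
  if (L < w) return(empty)
  window_stats <- function(a, b) {
    seg <- ch[a:b]; n <- b - a + 1
    nC <- sum(seg == "C"); nG <- sum(seg == "G")
    nCpG <- sum(seg[-length(seg)] == "C" & seg[-1] == "G")
    gc <- (nC + nG) / n
    expd <- nC * nG / n
    oe <- if (expd > 0) nCpG / expd else 0
    c(gc, oe)
  }
  qual <- integer(0)
  for (a in seq_len(L - w + 1)) {
    st <- window_stats(a, a + w - 1)
    if (st[1] > min_gc && st[2] > min_oe) qual <- c(qual, a)
  }
  if (length(qual) == 0) return(empty)
  # merge overlapping qualifying windows
  regions <- list(); cur <- c(qual[1], qual[1] + w - 1)
  for (a in qual[-1]) {
    if (a <= cur[2]) cur[2] <- a + w - 1
    else { regions[[length(regions) + 1]] <- cur; cur <- c(a, a + w - 1) }
  }
  regions[[length(regions) + 1]] <- cur
  out <- empty
  for (r in regions) {
    st <- window_stats(r[1], r[2])
    if ((r[2] - r[1] + 1) >= min_length && st[1] > min_gc && st[2] > min_oe)
      out <- rbind(out, data.frame(start = r[1] - 1, end = r[2]))
  }
  out
}

# Step-by-step TMM factor for one sample against a reference (sort-based
# trimming; use on fixtures without ties in M or A).
oracle_tmm_pair <- function(obs, ref, n_obs, n_ref,
                            trim_m = 0.30, trim_a = 0.05) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / n_obs) / (ref / n_ref))
  A <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  n <- length(M)
  loM <- floor(n * trim_m) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
  sM <- sort(M); sA <- sort(A)
  k <- M >= sM[loM] & M <= sM[hiM] & A >= sA[loA] & A <= sA[hiA]
  w <- 1 / ((n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref))
  2^(sum(M[k] * w[k]) / sum(w[k]))
}

# Hand-transcribed GSEA running-sum ES for a sorted (decreasing) named
# metric vector and a gene set.
oracle_gsea_es <- function(metric, set, weight = 1) {
  genes <- names(metric)
  N <- length(genes); hit <- genes %in% set
  NR <- sum(abs(metric[hit])^weight)
  run <- 0; best <- 0
  for (i in seq_len(N)) {
    if (hit[i]) run <- run + abs(metric[i])^weight / NR
    else run <- run - 1 / (N - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  unname(best)
}

# Brute-force all-pairs enhancer-promoter loop caller: for every loop and
# every (enhancer, promoter) pair, check the 25 kb padded-anchor rule on
# opposite anchors.
oracle_ep_loops <- function(loops, enhancers, promoters, pad = 5000,
                            max_dist = 25000) {
  gap <- function(s1, e1, s2, e2) max(0, max(s2 - e1, s1 - e2))
  flags <- logical(nrow(loops))
  for (i in seq_len(nrow(loops))) {
    a1 <- c(loops$start1[i] - pad, loops$end1[i] + pad)
    a2 <- c(loops$start2[i] - pad, loops$end2[i] + pad)
    near <- function(anchor, feats) {
      any(vapply(seq_len(nrow(feats)), function(j)
        feats$chrom[j] == loops$chrom[i] &&
          gap(anchor[1], anchor[2], feats$start[j], feats$end[j]) <= max_dist,
        TRUE))
    }
    flags[i] <- (near(a1, enhancers) && near(a2, promoters)) ||
      (near(a2, enhancers) && near(a1, promoters))
  }
  flags
}

# Brute-force evaluation of the per-site variant quality rules plus the SNV
# cluster rule, written directly from the filter list.
oracle_variant_verdicts <- function(v) {
  n <- nrow(v)
  pass <- rep(TRUE, n)
  for (i in seq_len(n)) {
    ok <- TRUE
    if (v$in_capture_pad200[i] &&
        !(v$strand_bias[i] > 0 && v$strand_bias[i] < 1)) ok <- FALSE
    if (v$depth_total[i] < 8 || v$depth_alt[i] < 4) ok <- FALSE
    if (v$mapping_quality[i] < 40 || v$base_quality[i] < 30) ok <- FALSE
    if (v$other_allele_fraction[i] >= 0.4) ok <- FALSE
    if (v$alt_alignment_fraction[i] > 0.1) ok <- FALSE
    if (v$type[i] != "SNV" && v$indel_length[i] >= 500) ok <- FALSE
    if (v$in_simple_repeat[i]) ok <- FALSE
    if (v$in_selfchain95[i]) ok <- FALSE
    pass[i] <- ok
  }
  # cluster rule on passing SNVs: maximal runs of >= 3 with gaps < 5 bp
  for (chr in unique(v$chrom)) {
    idx <- which(v$chrom == chr & v$type == "SNV" & pass)
    idx <- idx[order(v$pos[idx])]
    if (length(idx) < 3) next
    run <- c(idx[1])
    flush <- function(run, pass) {
      if (length(run) >= 3) pass[run] <- FALSE
      pass
    }
    for (k in seq_along(idx)[-1]) {
      if (v$pos[idx[k]] - v$pos[run[length(run)]] < 5) run <- c(run, idx[k])
      else { pass <- flush(run, pass); run <- c(idx[k]) }
    }
    pass <- flush(run, pass)
  }
  pass
}
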