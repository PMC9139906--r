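# Shared fixtures and small oracles, built in code at test time.

# equal-width single-chromosome bin table for closed-form count checks
flat_bins <- function(n_bins, chrom = "chr1", width = 1e6, gc = 0.5) {
  data.frame(chrom = chrom, start = (seq_len(n_bins) - 1) * width,
             end = seq_len(n_bins) * width, gc = gc,
             stringsAsFactors = FALSE)
}

# construct a cn_profile directly from an integer CN vector (noise-free)
profile_from_cn <- function(cn, bins, cell_id = "cell", altered = NULL) {
  mean_cn <- mean(cn)
  ratio <- cn / mean_cn
  seg <- segment_profile(ratio, bins, min_seg_bins = 2, penalty = 0)
  fit <- fit_ploidy(seg, bins)
  seg$cn <- as.integer(round(fit$ploidy_scale * seg$mean_ratio))
  p <- structure(list(cell_id = cell_id, ratio = ratio, segments = seg,
                      cn = fit$cn, ploidy_scale = fit$ploidy_scale,
                      baseline_ploidy = fit$baseline_ploidy,
                      quality = fit$quality, degenerate = fit$degenerate),
                 class = "cn_profile")
  p$altered <- if (is.null(altered)) call_altered(p) else altered
  p
}

# adjusted Rand index (independent of any clustering code under test)
ari <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- sum(tab)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# brute-force exact two-sided rank-sum p by full enumeration
rank_sum_enum_oracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled); na <- length(a)
  r <- rank(pooled)
  ew <- na * (n + 1) / 2
  dev <- abs(sum(r[seq_len(na)]) - ew)
  idx <- utils::combn(n, na)
  w <- colSums(matrix(r[idx], nrow = na))
  mean(abs(w - ew) >= dev - 1e-9)
}
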