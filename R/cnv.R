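#' Normalize a bin-count profile to copy-number ratios
#'
#' Converts raw per-bin read counts to normalized ratios: counts are first
#' divided by bin width, then a locally weighted regression (lowess) of rate
#' on GC fraction is divided out to remove amplification GC bias, and the
#' result is scaled to a genome mean of exactly 1. Scaling all counts by a
#' constant leaves the ratios unchanged.
#'
#' @param counts Non-negative integer vector, one count per bin.
#' @param bins Bin table (`chrom`, `start`, `end`, `gc`).
#' @param gc_f lowess smoother span; default 0.3.
#' @return Numeric ratio vector with `mean(ratio) == 1` (to 1e-9).
#' @export
normalize_bins <- function(counts, bins, gc_f = 0.3) {
  stopifnot(length(counts) == nrow(bins))
  if (any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("cannot normalize an all-zero profile")
  width <- bins$end - bins$start
  rate <- counts / width
  gc <- bins$gc
  if (length(unique(gc)) > 2 && stats::sd(gc) > 0) {
    lo <- stats::lowess(gc, rate, f = gc_f)
    pred <- stats::approx(lo$x, lo$y, xout = gc, rule = 2, ties = mean)$y
    floor_val <- 0.01 * mean(rate)
    pred <- pmax(pred, floor_val)
    rate <- rate / pred
  }
  rate / mean(rate)
}

# best single split of x[lo..hi] by within-segment SSE reduction,
# honoring a minimum segment length; returns c(split_index, reduction)
best_split <- function(csum, csum2, lo, hi, min_len) {
  n <- hi - lo + 1L
  if (n < 2L * min_len) return(c(NA_integer_, 0))
  tot <- csum[hi + 1L] - csum[lo]
  tot2 <- csum2[hi + 1L] - csum2[lo]
  sse_all <- tot2 - tot^2 / n
  ks <- (lo + min_len - 1L):(hi - min_len)
  nl <- ks - lo + 1L
  sl <- csum[ks + 1L] - csum[lo]
  sl2 <- csum2[ks + 1L] - csum2[lo]
  sse_l <- sl2 - sl^2 / nl
  sr <- tot - sl
  sr2 <- tot2 - sl2
  nr <- n - nl
  sse_r <- sr2 - sr^2 / nr
  red <- sse_all - (sse_l + sse_r)
  i <- which.max(red)
  c(ks[i], red[i])
}

# recursive binary segmentation of one chromosome's ratio vector;
# returns breakpoint positions (last index of each left part), local indexing
binseg_chrom <- function(x, min_len, penalty) {
  csum <- c(0, cumsum(x))
  csum2 <- c(0, cumsum(x^2))
  brks <- integer(0)
  eps <- 1e-8  # floor against floating-point cancellation on flat input
  recurse <- function(lo, hi) {
    bs <- best_split(csum, csum2, lo, hi, min_len)
    if (is.na(bs[1]) || bs[2] <= penalty + eps) return(invisible())
    brks <<- c(brks, bs[1])
    recurse(lo, bs[1])
    recurse(bs[1] + 1L, hi)
  }
  recurse(1L, length(x))
  sort(brks)
}

#' Segment a normalized ratio profile
#'
#' Per-chromosome recursive binary segmentation minimizing within-segment
#' squared error, accepting a breakpoint only when the squared-error
#' reduction exceeds a BIC-like penalty. Segments never cross chromosome
#' boundaries and never fall below `min_seg_bins` bins, so change points
#' closer together than the minimum are merged.
#'
#' @param ratios Normalized ratio vector from [normalize_bins()].
#' @param bins Bin table aligned with `ratios`.
#' @param min_seg_bins Minimum bins per segment (>= 2); default 5.
#' @param penalty Penalty per breakpoint; the BIC-like default charges
#'   `log(n_bins)` per parameter of a new breakpoint (location, new segment
#'   mean, and the implied variance share: `3 log(n_bins)`) times a robust
#'   noise-variance estimate from first differences. An under-penalized
#'   segmentation fragments chromosomes into noise blobs at fractional copy
#'   levels, which later destabilizes the integer ploidy fit.
#' @return A `data.frame` of segments: `chrom`, `start_bin`, `end_bin`
#'   (1-based global bin indices, inclusive), `n_bins`, `mean_ratio`.
#' @export
segment_profile <- function(ratios, bins, min_seg_bins = 5, penalty = NULL) {
  stopifnot(length(ratios) == nrow(bins))
  if (min_seg_bins < 2) stop("min_seg_bins must be >= 2")
  if (is.null(penalty)) {
    sigma <- stats::mad(diff(ratios)) / sqrt(2)
    penalty <- 3 * log(length(ratios)) * sigma^2
  }
  segs <- list()
  offset <- 0L
  for (cn in unique(bins$chrom)) {
    idx <- which(bins$chrom == cn)
    x <- ratios[idx]
    brks <- if (length(x) >= 2 * min_seg_bins) {
      binseg_chrom(x, as.integer(min_seg_bins), penalty)
    } else integer(0)
    starts <- c(1L, brks + 1L)
    ends <- c(brks, length(x))
    segs[[cn]] <- data.frame(
      chrom = cn,
      start_bin = offset + starts,
      end_bin = offset + ends,
      n_bins = ends - starts + 1L,
      mean_ratio = vapply(seq_along(starts), function(i) {
        mean(x[starts[i]:ends[i]])
      }, numeric(1)),
      stringsAsFactors = FALSE)
    offset <- offset + length(x)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Fit an integer ploidy scale to a segmented profile
#'
#' Chooses the scale minimizing the bin-count-weighted mean squared
#' distance of per-chromosome mean ratios to the integer lattice `k / s`,
#' after subtracting each mean's expected sampling variance (a
#' noise-debiased objective). Three choices make the fit identifiable under
#' amplification-level noise: (1) working on the `k / s` lattice rather
#' than on `s x mean` keeps the noise contribution comparable across
#' scales — otherwise it inflates quadratically with the scale and drags
#' high-ploidy genomes toward spuriously low fits; (2) chromosome means
#' (not segment means) carry the ploidy evidence, so spurious
#' within-chromosome splits at fractional levels cannot be absorbed by a
#' fine harmonic lattice, while chromosomes with real internal structure
#' are down-weighted through their inflated variance; (3) because the
#' baseline ploidy is an integer by definition, candidate scales are
#' anchored so the modal chromosome level (weighted median) lands on each
#' integer ploidy in turn, each refined within a narrow window. A
#' karyotype-parsimony prior (scaled by the noise floor, so inactive on
#' noise-free input) further disfavors lattices that explain noisy
#' chromosomes as extreme copy numbers far from their own baseline. Only
#' autosomes enter the objective (sex chromosomes would confound the fit
#' for unmodeled patient sex). Among candidates within a noise-scaled
#' tolerance of the best fit the lowest ploidy wins: a perfectly flat
#' profile is called diploid.
#'
#' @param segments Segment table from [segment_profile()].
#' @param bins Bin table.
#' @param ratios Optional normalized ratio vector; used to estimate each
#'   segment mean's sampling variance for the debiased objective. Without it
#'   the raw lattice distance is used (appropriate for noise-free input).
#' @param grid Candidate scales; default `seq(1.5, 6, by = 0.05)`, covering
#'   diploid through pentaploid with margin.
#' @return List with `ploidy_scale`, `cn` (integer copy number per bin),
#'   `baseline_ploidy` (bin-count-weighted modal copy number over autosomes),
#'   `quality` (objective at the optimum) and `degenerate` (TRUE when all
#'   segment means coincide and the scale is set purely by the tie-break).
#' @export
fit_ploidy <- function(segments, bins, ratios = NULL,
                       grid = seq(1.5, 6, by = 0.05)) {
  auto <- segments$chrom %in% autosome_names()
  if (!any(auto)) auto <- rep(TRUE, nrow(segments))
  # The ploidy objective works on per-chromosome means: baseline ploidy is a
  # whole-genome property, and chromosome means are immune to spurious
  # within-chromosome splits whose fractional levels a fine (harmonic)
  # lattice would absorb. Chromosomes carrying real sub-chromosomal events
  # have inflated variance and are down-weighted by the debiasing; their
  # segment-level copy numbers are still assigned below.
  seg_auto <- segments[auto, , drop = FALSE]
  chroms <- unique(seg_auto$chrom)
  m <- vapply(chroms, function(cc) {
    sel <- seg_auto$chrom == cc
    sum(seg_auto$mean_ratio[sel] * seg_auto$n_bins[sel]) /
      sum(seg_auto$n_bins[sel])
  }, numeric(1))
  w <- vapply(chroms, function(cc) {
    sum(seg_auto$n_bins[seg_auto$chrom == cc])
  }, numeric(1))
  # sampling variance of each chromosome mean (includes any real internal
  # structure, which correctly weakens that chromosome's ploidy evidence)
  v <- if (is.null(ratios)) rep(0, length(m)) else {
    vapply(chroms, function(cc) {
      x <- ratios[bins$chrom == cc]
      if (length(x) < 2) return(0)
      stats::var(x) / length(x)
    }, numeric(1))
  }
  noise_floor <- sum(w * v) / sum(w)
  lattice_fit <- function(s) {
    d2 <- (m - round(s * m) / s)^2
    sum(w * pmax(d2 - v, 0)) / sum(w)
  }
  # karyotype-parsimony prior: among near-equivalent lattices prefer the one
  # implying the mildest deviations from its own baseline (a noisy diploid
  # chromosome dipping 3 sigma should not be explained as seven copies on a
  # pentaploid background); scaled by the noise floor so it vanishes on
  # noise-free input
  objective_for <- function(p) {
    function(s) {
      lattice_fit(s) +
        5 * noise_floor * sum(w * abs(round(s * m) - p)) / sum(w)
    }
  }
  # The baseline ploidy is an integer by definition, so admissible scales
  # must place the modal segment level on an integer: anchor one candidate
  # scale per integer ploidy at the weighted-median segment mean (the
  # baseline state), refine each within a narrow window, and pick the
  # smallest ploidy whose fit is within a noise-scaled tolerance of the
  # best. Free refinement over all scales would instead let doubled
  # (harmonic) lattices win by absorbing segment-mean noise.
  m_mode <- weighted_median(m, w)
  # a statistically flat profile (no chromosome beyond 4 sigma of the modal
  # level) carries no absolute ploidy information: relative ratios cannot
  # distinguish a flat diploid from a flat triploid, so by convention the
  # tie-break calls it diploid rather than letting a fine lattice absorb
  # noise
  z <- abs(m - m_mode) / sqrt(v + 1e-12)
  degenerate <- diff(range(m)) < 1e-9 || (any(v > 0) && all(z < 4))
  lo <- min(grid)
  hi <- max(grid)
  p_cand <- if (degenerate) 2L else 1:8
  s_anchor <- p_cand / m_mode
  keep <- s_anchor >= lo - 0.026 & s_anchor <= hi + 0.026
  p_cand <- p_cand[keep]
  s_anchor <- s_anchor[keep]
  if (!length(p_cand)) {
    obj <- vapply(grid, lattice_fit, numeric(1))
    s_anchor <- grid[which.min(obj)]
    p_cand <- round(s_anchor * m_mode)
  }
  cand <- vapply(seq_along(s_anchor), function(i) {
    s0 <- s_anchor[i]
    stats::optimize(objective_for(p_cand[i]), lower = s0 * 0.99,
                    upper = s0 * 1.01)$minimum
  }, numeric(1))
  cand_obj <- vapply(seq_along(cand), function(i) {
    objective_for(p_cand[i])(cand[i])
  }, numeric(1))
  tol <- max(1e-6, 0.25 * noise_floor)
  sel <- which(cand_obj <= min(cand_obj) + tol)[1]  # candidates by ploidy
  s <- cand[sel]
  # snap to a round scale when it fits equally well (cosmetic determinism)
  s_round <- round(s, 2)
  obj_sel <- objective_for(p_cand[sel])
  if (obj_sel(s_round) <= obj_sel(s) + 1e-12) s <- s_round
  cn <- integer(nrow(bins))
  for (i in seq_len(nrow(segments))) {
    cn[segments$start_bin[i]:segments$end_bin[i]] <-
      as.integer(round(s * segments$mean_ratio[i]))
  }
  auto_bins <- bins$chrom %in% autosome_names()
  tab <- table(cn[auto_bins])
  baseline <- as.integer(names(tab)[which.max(tab)])
  list(ploidy_scale = s, cn = cn, baseline_ploidy = baseline,
       quality = lattice_fit(s), degenerate = degenerate)
}

#' Decide whether a copy-number profile is altered
#'
#' Two copies are normal: a cell is altered when its baseline ploidy departs
#' from 2, or when any autosomal segment with integer copy number different
#' from 2 spans at least `min_event_bins` bins (the minimum discernable
#' event size; about arm scale at 5,000 genome bins).
#'
#' @param profile A `cn_profile` (see [fit_cnv()]).
#' @param min_event_bins Minimum event size in bins (>= 1); default 10.
#' @return Logical.
#' @export
call_altered <- function(profile, min_event_bins = 10) {
  if (min_event_bins < 1) stop("min_event_bins must be >= 1")
  if (profile$baseline_ploidy != 2L) return(TRUE)
  seg <- profile$segments
  auto <- seg$chrom %in% autosome_names()
  any(auto & seg$cn != 2L & seg$n_bins >= min_event_bins)
}

#' Call single-cell copy-number profiles from bin counts
#'
#' The central fitting routine: for every cell it normalizes bin counts
#' (width and GC correction), segments the ratio profile, fits an integer
#' ploidy scale, and calls the cell altered or normal. Returns a classed
#' object with the usual accessor methods (`print`, `summary`, `coef` for
#' the integer copy-number matrix, `residuals`, `plot`).
#'
#' @param counts Integer matrix, cells x bins, with cell ids as rownames
#'   (a single profile may be given as a vector).
#' @param bins Bin table from [make_bin_table()] (or read from disk).
#' @param min_seg_bins,penalty Passed to [segment_profile()].
#' @param grid Passed to [fit_ploidy()].
#' @param min_event_bins Passed to [call_altered()].
#' @return An object of class `"cnv_fit"`: list with `profiles` (a list of
#'   `cn_profile` objects, each holding `cell_id`, `ratio`, `segments`
#'   (with per-segment integer `cn`), `cn`, `ploidy_scale`,
#'   `baseline_ploidy`, `altered`, `quality`), plus `bins` and call
#'   parameters.
#' @examples
#' bins <- make_bin_table(300, seed = 1)
#' sim <- simulate_cnv_cells(
#'   cnv_sim_spec(clone_spec("d"), n_cells = 2, reads_per_cell = 3e4,
#'                n_bins = 300), bins)
#' fit <- fit_cnv(sim$counts, bins)
#' summary(fit)
#' @export
fit_cnv <- function(counts, bins, min_seg_bins = 5, penalty = NULL,
                    grid = seq(1.5, 6, by = 0.05), min_event_bins = 10) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1)
  if (is.null(rownames(counts))) {
    rownames(counts) <- sprintf("cell_%03d", seq_len(nrow(counts)))
  }
  profiles <- lapply(seq_len(nrow(counts)), function(i) {
    ratio <- normalize_bins(counts[i, ], bins)
    seg <- segment_profile(ratio, bins, min_seg_bins = min_seg_bins,
                           penalty = penalty)
    fit <- fit_ploidy(seg, bins, ratios = ratio, grid = grid)
    seg$cn <- as.integer(round(fit$ploidy_scale * seg$mean_ratio))
    p <- structure(list(cell_id = rownames(counts)[i], ratio = ratio,
                        segments = seg, cn = fit$cn,
                        ploidy_scale = fit$ploidy_scale,
                        baseline_ploidy = fit$baseline_ploidy,
                        quality = fit$quality, degenerate = fit$degenerate),
                   class = "cn_profile")
    p$altered <- call_altered(p, min_event_bins = min_event_bins)
    p
  })
  names(profiles) <- rownames(counts)
  structure(list(profiles = profiles, bins = bins,
                 params = list(min_seg_bins = min_seg_bins,
                               penalty = penalty, grid = grid,
                               min_event_bins = min_event_bins)),
            class = "cnv_fit")
}

#' Summarize a cnv_fit as a per-cell table
#'
#' @param object A `cnv_fit`.
#' @param ... Unused.
#' @return `data.frame` with `cell_id`, `ploidy_scale`, `baseline_ploidy`,
#'   `altered`, `n_segments`, `quality`.
#' @export
summary.cnv_fit <- function(object, ...) {
  do.call(rbind, lapply(object$profiles, function(p) {
    data.frame(cell_id = p$cell_id, ploidy_scale = p$ploidy_scale,
               baseline_ploidy = p$baseline_ploidy, altered = p$altered,
               n_segments = nrow(p$segments), quality = p$quality,
               stringsAsFactors = FALSE)
  })) -> out
  rownames(out) <- NULL
  out
}

#' @export
print.cnv_fit <- function(x, ...) {
  s <- summary(x)
  cat("Single-cell copy-number fit:", nrow(s), "cells,",
      nrow(x$bins), "bins\n")
  cat("  altered:", sum(s$altered), " normal:", sum(!s$altered), "\n")
  cat("  baseline ploidy:",
      paste(sprintf("%s(x%d)", names(table(s$baseline_ploidy)),
                    as.integer(table(s$baseline_ploidy))), collapse = " "),
      "\n")
  invisible(x)
}

#' @export
print.cn_profile <- function(x, ...) {
  cat("cn_profile", x$cell_id, "- ploidy", x$baseline_ploidy,
      if (x$altered) "(altered)" else "(normal)", "\n")
  cat("  scale", x$ploidy_scale, "quality", signif(x$quality, 3),
      "segments", nrow(x$segments), "\n")
  invisible(x)
}

#' Integer copy-number matrix of a cnv_fit
#' @param object A `cnv_fit`.
#' @param ... Unused.
#' @return Integer matrix, cells x bins.
#' @export
coef.cnv_fit <- function(object, ...) {
  do.call(rbind, lapply(object$profiles, `[[`, "cn"))
}

#' Residuals of the integer copy-number fit
#'
#' Per-bin difference between the scaled ratio and its fitted integer copy
#' number, on the copy-number scale.
#'
#' @param object A `cnv_fit`.
#' @param ... Unused.
#' @return Numeric matrix, cells x bins.
#' @export
residuals.cnv_fit <- function(object, ...) {
  do.call(rbind, lapply(object$profiles, function(p) {
    p$ploidy_scale * p$ratio - p$cn
  }))
}

#' Plot one cell of a cnv_fit
#'
#' Scaled bin ratios colored by chromosome with the fitted integer
#' copy-number steps overlaid.
#'
#' @param x A `cnv_fit`.
#' @param cell Cell id or index; default first cell.
#' @param ... Passed to `plot()`.
#' @export
plot.cnv_fit <- function(x, cell = 1, ...) {
  p <- if (is.character(cell)) x$profiles[[cell]] else x$profiles[[cell]]
  bins <- x$bins
  chrom_i <- match(bins$chrom, unique(bins$chrom))
  cols <- grDevices::adjustcolor(c("grey30", "grey60")[1 + chrom_i %% 2], 0.6)
  graphics::plot(seq_along(p$ratio), p$ploidy_scale * p$ratio, pch = 16,
                 cex = 0.4, col = cols, xlab = "genome bin",
                 ylab = "copy number",
                 main = paste0(p$cell_id, " (ploidy ", p$baseline_ploidy,
                               if (p$altered) ", altered)" else ", normal)"),
                 ...)
  seg <- p$segments
  graphics::segments(seg$start_bin, seg$cn, seg$end_bin, seg$cn,
                     col = "red", lwd = 2)
  invisible(x)
}
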