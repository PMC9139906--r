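#' Calibrate channel positivity thresholds
#'
#' On an enrichment-free slide the overwhelming majority of cells are
#' negative for any rare-cell marker, so the bulk of the per-channel
#' intensity distribution defines the negative population. The cutoff for a
#' channel is `median + k_mad * MAD` of `log1p` intensities over all admitted
#' cells, reported back on the original intensity scale.
#'
#' If the MAD is zero (degenerate constant channel) the cutoff falls back to
#' a fixed small epsilon above the median, with a warning; under the strict
#' `>` positivity comparison no cell is then positive.
#'
#' @param features Cell feature `data.frame` with columns `dapi`, `cd138`,
#'   `cd56`, `cd45` (at least 100 rows).
#' @param k_mad Positive MAD multiplier; default 5.
#' @return An object of class `"channel_thresholds"`: `data.frame` with one
#'   row per channel and columns `channel`, `cutoff` (original scale),
#'   `location`, `scale` (log1p scale) and `method`.
#' @export
calibrate_thresholds <- function(features, k_mad = 5) {
  channels <- c("dapi", "cd138", "cd56", "cd45")
  stopifnot(all(channels %in% names(features)))
  if (nrow(features) < 100) {
    stop("threshold calibration requires at least 100 cells")
  }
  if (k_mad <= 0) stop("k_mad must be > 0")
  rows <- lapply(channels, function(ch) {
    x <- log1p(features[[ch]])
    if (any(x < 0)) stop("intensities must be >= 0 (channel ", ch, ")")
    med <- stats::median(x)
    sc <- stats::mad(x)
    if (sc == 0) {
      warning("MAD is zero for channel ", ch,
              "; falling back to epsilon above the median")
      cut_log <- med + 1e-6
    } else {
      cut_log <- med + k_mad * sc
    }
    data.frame(channel = ch, cutoff = expm1(cut_log), location = med,
               scale = sc, method = "median_kmad_log1p",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "k_mad") <- k_mad
  class(out) <- c("channel_thresholds", "data.frame")
  out
}

threshold_for <- function(thresholds, channel) {
  stopifnot(inherits(thresholds, "channel_thresholds"))
  i <- match(channel, thresholds$channel)
  if (is.na(i)) stop("no threshold calibrated for channel ", channel)
  thresholds$cutoff[i]
}

#' Rank atypical cells by k-nearest-neighbor distance
#'
#' Distills morphologically distinct rare cells from the common-cell
#' background: each cell is scored by its mean Euclidean distance to its k
#' nearest neighbors in robust-standardized feature space (log1p channel
#' intensities plus area and eccentricity, each centered by the median and
#' scaled by the MAD). The score ranks candidates for review; it never
#' overrules marker-based classification.
#'
#' @param features Cell feature `data.frame`.
#' @param k_neighbors Number of neighbors; must be below the number of cells.
#' @param columns Feature columns to use.
#' @return Numeric vector of outlier scores, one per row of `features`.
#' @export
score_outliers <- function(features, k_neighbors = 10,
                           columns = c("cd138", "cd56", "cd45", "area",
                                       "nuclear_eccentricity")) {
  n <- nrow(features)
  if (n < k_neighbors + 1) {
    stop("need at least k_neighbors + 1 = ", k_neighbors + 1, " cells")
  }
  x <- as.matrix(features[, columns, drop = FALSE])
  int_cols <- intersect(columns, c("dapi", "cd138", "cd56", "cd45"))
  for (ch in int_cols) x[, ch] <- log1p(x[, ch])
  for (j in seq_len(ncol(x))) {
    med <- stats::median(x[, j])
    sc <- stats::mad(x[, j])
    if (sc == 0) sc <- 1
    x[, j] <- (x[, j] - med) / sc
  }
  scores <- numeric(n)
  sq <- rowSums(x^2)
  chunk <- max(1L, floor(2e7 / n))
  for (a in seq(1L, n, by = chunk)) {
    b <- min(a + chunk - 1L, n)
    # squared distances of cells a..b to all cells
    d2 <- outer(sq[a:b], sq, "+") - 2 * tcrossprod(x[a:b, , drop = FALSE], x)
    d2[d2 < 0] <- 0
    for (i in seq_len(b - a + 1L)) {
      di <- sqrt(d2[i, -(a + i - 1L)])
      scores[a + i - 1L] <- mean(sort(di, partial = k_neighbors)[1:k_neighbors])
    }
  }
  scores
}

#' Classify DAPI+ cells into plasma-cell morphotypes
#'
#' Assigns each cell exactly one subtype. Channel positivity is a strict `>`
#' comparison against the calibrated cutoffs. Because the morphology-defined
#' categories overlap the marker combinations (a binucleated CD138+CD56+
#' cell), enumeration requires a partition; precedence among CD138+ cells is
#' apoptotic > cluster > binucleated > marker combination, and the positivity
#' triple is retained alongside so no information is lost. CD138- cells
#' larger than the surrounding WBCs (area above the `size_quantile` of
#' CD45+CD138- cells) with eccentric nuclei are CD138- candidate plasma
#' cells; CD56+ cells without CD138 or plasma-cell morphology are CD56+
#' non-plasma cells; the remainder are common WBCs (CD45+) or other rare.
#'
#' @param features Cell feature `data.frame` (DAPI+ gated).
#' @param thresholds A [calibrate_thresholds()] result.
#' @param size_quantile Quantile of CD45+CD138- cell area defining "larger
#'   than surrounding WBCs"; default 0.95. If a sample has no CD45+CD138-
#'   cells the reference falls back to all CD138- cells.
#' @param ecc_cutoff Nuclear-eccentricity cutoff for candidate plasma cells;
#'   default 0.6.
#' @param apoptosis_cutoff Apoptosis-score cutoff; default 0.7.
#' @return A `data.frame` with one row per cell: `cell_id`, `sample_id`,
#'   positivity flags `cd138_pos`/`cd56_pos`/`cd45_pos`, morphology flags
#'   `flag_apoptotic`/`flag_cluster`/`flag_binucleated`, and `subtype`.
#' @export
classify_cells <- function(features, thresholds, size_quantile = 0.95,
                           ecc_cutoff = 0.6, apoptosis_cutoff = 0.7) {
  if (!inherits(thresholds, "channel_thresholds")) {
    stop("thresholds must be calibrated with calibrate_thresholds()")
  }
  cd138 <- features$cd138 > threshold_for(thresholds, "cd138")
  cd56 <- features$cd56 > threshold_for(thresholds, "cd56")
  cd45 <- features$cd45 > threshold_for(thresholds, "cd45")

  # per-sample WBC size reference
  size_cut <- rep(NA_real_, nrow(features))
  for (s in unique(features$sample_id)) {
    in_s <- features$sample_id == s
    ref <- in_s & cd45 & !cd138
    if (!any(ref)) ref <- in_s & !cd138
    if (!any(ref)) ref <- in_s
    size_cut[in_s] <- stats::quantile(features$area[ref], size_quantile,
                                      names = FALSE)
  }
  large <- features$area > size_cut
  eccentric <- features$nuclear_eccentricity > ecc_cutoff
  apoptotic <- cd138 & features$apoptosis_score > apoptosis_cutoff
  binucleated <- cd138 & features$nucleus_count >= 2

  # a cluster is >= 2 CD138+ cells sharing a cluster id
  clustered <- rep(FALSE, nrow(features))
  has_cl <- which(!is.na(features$cluster_id) & cd138)
  if (length(has_cl)) {
    tab <- table(features$cluster_id[has_cl])
    clustered[has_cl] <- tab[features$cluster_id[has_cl]] >= 2
  }

  subtype <- character(nrow(features))
  marker <- ifelse(cd56 & cd45, "CD138+CD56+CD45+",
            ifelse(cd56, "CD138+CD56+",
            ifelse(cd45, "CD138+CD45+", "CD138+")))
  pos <- which(cd138)
  subtype[pos] <- ifelse(apoptotic[pos], "apoptotic PC",
                  ifelse(clustered[pos], "PC cluster",
                  ifelse(binucleated[pos], "binucleated PC", marker[pos])))
  neg <- which(!cd138)
  subtype[neg] <- ifelse(large[neg] & eccentric[neg], "CD138- candidate PC",
                  ifelse(cd56[neg], "CD56+ non-PC",
                  ifelse(cd45[neg], "common WBC", "other rare")))

  data.frame(cell_id = features$cell_id, sample_id = features$sample_id,
             cd138_pos = cd138, cd56_pos = cd56, cd45_pos = cd45,
             flag_apoptotic = apoptotic, flag_cluster = clustered,
             flag_binucleated = binucleated,
             subtype = factor(subtype, levels = subtype_levels()),
             stringsAsFactors = FALSE)
}

#' Enumerate subtypes as counts and cells/mL
#'
#' Each cell category is reported as a raw count and as cells per mL of the
#' blood-volume equivalent analyzed; the union of CD138+ subtypes is
#' additionally reported as `total CD138+`.
#'
#' @param classes Classification `data.frame` from [classify_cells()].
#' @param ml_equivalent Blood-volume equivalent (mL); must be positive.
#' @return A `data.frame` with columns `subtype`, `count`, `cells_per_ml`;
#'   the final row is `total CD138+`.
#' @examples
#' # 10 CD138+ cells over a 2 mL equivalent -> 5 cells/mL
#' @export
enumerate_subtypes <- function(classes, ml_equivalent) {
  if (ml_equivalent <= 0) stop("ml_equivalent must be > 0")
  counts <- table(factor(classes$subtype, levels = subtype_levels()))
  total_cd138 <- sum(counts[cd138_subtypes()])
  out <- data.frame(subtype = c(names(counts), "total CD138+"),
                    count = c(as.integer(counts), total_cd138),
                    stringsAsFactors = FALSE)
  out$cells_per_ml <- out$count / ml_equivalent
  out
}

#' Stratify a sample by circulating CD138+ cell burden
#'
#' Labels a sample myeloma-like when its CD138+ cells/mL of peripheral blood
#' strictly exceed the threshold (default more than 3 cells/mL).
#'
#' @param cells_per_ml CD138+ cells per mL.
#' @param threshold Non-negative threshold; default 3.
#' @return `"myeloma-like"` or `"normal-like"` (vectorized).
#' @export
stratify_by_ctc_threshold <- function(cells_per_ml, threshold = 3) {
  if (threshold < 0) stop("threshold must be >= 0")
  ifelse(cells_per_ml > threshold, "myeloma-like", "normal-like")
}
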