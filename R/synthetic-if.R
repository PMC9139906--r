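#' Morphotype vocabulary
#'
#' The eight plasma-cell candidate subtypes (marker combinations of CD138,
#' CD56, CD45 plus morphology-defined categories), the two common classes,
#' and an "other rare" bucket used by the classifier.
#'
#' @return Character vector of subtype labels.
#' @export
subtype_levels <- function() {
  c("CD138+", "CD138+CD56+", "CD138+CD45+", "CD138+CD56+CD45+",
    "CD138- candidate PC", "apoptotic PC", "PC cluster", "binucleated PC",
    "CD56+ non-PC", "common WBC", "other rare")
}

# subtypes counted as CD138-positive for enumeration
cd138_subtypes <- function() {
  c("CD138+", "CD138+CD56+", "CD138+CD45+", "CD138+CD56+CD45+",
    "apoptotic PC", "PC cluster", "binucleated PC")
}

#' Specify a synthetic immunofluorescence cohort
#'
#' Describes per-sample slides of DAPI+ nucleated cells with four-channel
#' intensities (DAPI, CD138, CD56, CD45) and morphometrics, with rare
#' plasma-cell subtypes spiked at configurable frequencies. The default slide
#' is scaled down to 50,000 cells (real slides hold about 3 million).
#'
#' @param n_samples Number of samples (slides).
#' @param cells_per_sample Cells per slide; default 50000.
#' @param ml_equivalent_per_sample Blood-volume equivalent per slide (mL),
#'   used for cells/mL normalization; default 1.
#' @param subtype_frequencies Named numeric vector of per-cell frequencies
#'   over subtypes from [subtype_levels()] (excluding `"common WBC"`, which
#'   absorbs the remainder). Rare plasma-cell subtype frequencies must sum to
#'   below 0.01.
#' @param channel_models Named list per channel (`dapi`, `cd138`, `cd56`,
#'   `cd45`) of `list(neg = c(meanlog, sdlog), pos = c(meanlog, sdlog))`
#'   log-normal intensity models. Positive location must exceed negative.
#' @param morpho_models List with WBC and PC area models (normal, um^2),
#'   eccentricity models, and flag probabilities; see defaults.
#' @param compartment `"PB"` or `"BMA"` recorded on every cell.
#' @param seed Integer seed.
#' @return An object of class `"if_cohort_spec"`.
#' @export
if_cohort_spec <- function(n_samples = 1L,
                           cells_per_sample = 50000L,
                           ml_equivalent_per_sample = 1,
                           subtype_frequencies = c("CD138+CD56+" = 1e-4),
                           channel_models = default_channel_models(),
                           morpho_models = default_morpho_models(),
                           compartment = "PB",
                           seed = 1L) {
  if (cells_per_sample < 1) stop("cells_per_sample must be >= 1")
  if (any(subtype_frequencies < 0)) stop("frequencies must be >= 0")
  if (sum(subtype_frequencies) >= 1) {
    stop("subtype frequencies must sum to below 1")
  }
  unknown <- setdiff(names(subtype_frequencies), subtype_levels())
  if (length(unknown)) {
    stop("unknown subtype(s): ", paste(unknown, collapse = ", "))
  }
  rare <- setdiff(names(subtype_frequencies), c("common WBC", "CD56+ non-PC"))
  if (length(rare) && sum(subtype_frequencies[rare]) >= 0.01) {
    stop("rare-subtype frequencies must sum to below 0.01")
  }
  for (ch in c("dapi", "cd138", "cd56", "cd45")) {
    m <- channel_models[[ch]]
    if (is.null(m)) stop("channel_models missing channel: ", ch)
    if (m$pos[1] <= m$neg[1]) {
      stop("positive location must exceed negative location for ", ch)
    }
  }
  stopifnot(compartment %in% c("PB", "BMA"))
  structure(list(n_samples = as.integer(n_samples),
                 cells_per_sample = as.integer(cells_per_sample),
                 ml_equivalent_per_sample = ml_equivalent_per_sample,
                 subtype_frequencies = subtype_frequencies,
                 channel_models = channel_models,
                 morpho_models = morpho_models,
                 compartment = compartment,
                 seed = as.integer(seed)),
            class = "if_cohort_spec")
}

#' Default log-normal channel intensity models
#'
#' Negative populations sit at location log(50) with log-scale 0.25
#' (about 25% coefficient of variation, typical of stable immunofluorescence
#' staining); positive populations are separated tenfold in location with the
#' same spread. DAPI is positive for every cell (all cells are nucleated and
#' pass the DAPI gate).
#'
#' @return Named list of per-channel `neg`/`pos` `c(meanlog, sdlog)` pairs.
#' @export
default_channel_models <- function() {
  neg <- c(log(50), 0.25)
  pos <- c(log(50) + log(10), 0.25)
  list(dapi = list(neg = neg, pos = pos),
       cd138 = list(neg = neg, pos = pos),
       cd56 = list(neg = neg, pos = pos),
       cd45 = list(neg = neg, pos = pos))
}

#' Default morphometric models
#'
#' WBC area about 60 um^2 (sd 12), plasma-cell area about 150 um^2 (sd 30);
#' nuclear eccentricity modest for WBCs, high (eccentric nuclei) for
#' plasma-cell candidates.
#'
#' @return List of model parameters used by [simulate_if_cohort()].
#' @export
default_morpho_models <- function() {
  list(wbc_area = c(mean = 60, sd = 12),
       pc_area = c(mean = 150, sd = 30),
       wbc_ecc = c(mean = 0.35, sd = 0.1),
       pc_ecc = c(mean = 0.75, sd = 0.08),
       apoptosis_background = c(0, 0.3),
       apoptosis_positive = c(0.75, 1))
}

# which channels are positive for each truth subtype
subtype_channel_map <- function(subtype) {
  switch(subtype,
    "CD138+" = c("cd138"),
    "CD138+CD56+" = c("cd138", "cd56"),
    "CD138+CD45+" = c("cd138", "cd45"),
    "CD138+CD56+CD45+" = c("cd138", "cd56", "cd45"),
    "CD138- candidate PC" = character(0),
    "apoptotic PC" = c("cd138"),
    "PC cluster" = c("cd138"),
    "binucleated PC" = c("cd138"),
    "CD56+ non-PC" = c("cd56"),
    "common WBC" = c("cd45"),
    "other rare" = character(0),
    stop("unknown subtype: ", subtype))
}

pc_like_subtypes <- function() {
  c("CD138+", "CD138+CD56+", "CD138+CD45+", "CD138+CD56+CD45+",
    "CD138- candidate PC", "apoptotic PC", "PC cluster", "binucleated PC")
}

#' Simulate an immunofluorescence cohort with ground truth
#'
#' Generates one feature row per segmented DAPI+ cell: sample id,
#' compartment, four channel mean intensities, area, nuclear eccentricity,
#' nucleus count, cluster id and apoptosis score, with rare subtypes spiked
#' at the spec frequencies. Morphology flags are generated by the truth
#' subtype: binucleated plasma cells carry two nuclei, cluster cells share a
#' cluster id pairwise, apoptotic cells carry a high apoptosis score.
#' Intensities are rounded to 3 decimals (areas 2, scores 4) so written
#' tables round-trip exactly.
#'
#' @param spec An [if_cohort_spec()].
#' @return List with `features` (`data.frame`, one row per cell) and `truth`
#'   (`data.frame` of `cell_id`, `sample_id`, `subtype`).
#' @examples
#' sp <- if_cohort_spec(cells_per_sample = 500, seed = 7)
#' sim <- simulate_if_cohort(sp)
#' table(sim$truth$subtype)
#' @export
simulate_if_cohort <- function(spec) {
  stopifnot(inherits(spec, "if_cohort_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(spec$seed)

  out_feat <- vector("list", spec$n_samples)
  out_truth <- vector("list", spec$n_samples)
  mm <- spec$morpho_models
  for (s in seq_len(spec$n_samples)) {
    sample_id <- sprintf("S%02d", s)
    n <- spec$cells_per_sample
    freqs <- spec$subtype_frequencies
    p <- c(freqs, "common WBC" = 1 - sum(freqs))
    subtype <- sample(names(p), n, replace = TRUE, prob = p)

    inten <- matrix(0, n, 4,
                    dimnames = list(NULL, c("dapi", "cd138", "cd56", "cd45")))
    for (ch in colnames(inten)) {
      m <- spec$channel_models[[ch]]
      pos <- if (ch == "dapi") rep(TRUE, n) else {
        vapply(subtype, function(st) ch %in% subtype_channel_map(st),
               logical(1))
      }
      x <- numeric(n)
      x[pos] <- stats::rlnorm(sum(pos), m$pos[1], m$pos[2])
      x[!pos] <- stats::rlnorm(sum(!pos), m$neg[1], m$neg[2])
      inten[, ch] <- x
    }

    pc_like <- subtype %in% pc_like_subtypes()
    area <- ifelse(pc_like,
                   stats::rnorm(n, mm$pc_area["mean"], mm$pc_area["sd"]),
                   stats::rnorm(n, mm$wbc_area["mean"], mm$wbc_area["sd"]))
    area <- pmax(area, 10)
    ecc <- ifelse(pc_like,
                  stats::rnorm(n, mm$pc_ecc["mean"], mm$pc_ecc["sd"]),
                  stats::rnorm(n, mm$wbc_ecc["mean"], mm$wbc_ecc["sd"]))
    ecc <- pmin(pmax(ecc, 0), 0.99)
    # CD138- candidates are defined by large size and eccentric nuclei
    cand <- subtype == "CD138- candidate PC"
    ecc[cand] <- pmin(pmax(ecc[cand], 0.65), 0.99)

    nucleus_count <- ifelse(subtype == "binucleated PC", 2L, 1L)
    apop <- subtype == "apoptotic PC"
    apoptosis <- stats::runif(n, mm$apoptosis_background[1],
                              mm$apoptosis_background[2])
    apoptosis[apop] <- stats::runif(sum(apop), mm$apoptosis_positive[1],
                                    mm$apoptosis_positive[2])

    cluster_id <- rep(NA_character_, n)
    cl <- which(subtype == "PC cluster")
    if (length(cl)) {
      # consecutive cluster cells share an id pairwise (odd leftover joins
      # the last pair so every cluster has >= 2 members when possible)
      grp <- ceiling(seq_along(cl) / 2)
      if (length(cl) %% 2 == 1 && length(cl) > 1) grp[length(cl)] <- max(grp) - 1
      cluster_id[cl] <- sprintf("%s_cl%02d", sample_id, grp)
    }

    frame_id <- sample.int(2304L, n, replace = TRUE)
    cell_id <- sprintf("%s_c%06d", sample_id, seq_len(n))
    out_feat[[s]] <- data.frame(
      cell_id = cell_id, sample_id = sample_id,
      compartment = spec$compartment, frame_id = frame_id,
      dapi = round(inten[, "dapi"], 3), cd138 = round(inten[, "cd138"], 3),
      cd56 = round(inten[, "cd56"], 3), cd45 = round(inten[, "cd45"], 3),
      area = round(area, 2), nuclear_eccentricity = round(ecc, 4),
      nucleus_count = nucleus_count, cluster_id = cluster_id,
      apoptosis_score = round(apoptosis, 4),
      stringsAsFactors = FALSE)
    out_truth[[s]] <- data.frame(cell_id = cell_id, sample_id = sample_id,
                                 subtype = subtype, stringsAsFactors = FALSE)
  }
  list(features = do.call(rbind, out_feat),
       truth = do.call(rbind, out_truth))
}
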