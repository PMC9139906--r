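# a feature table with hand-set intensities against known thresholds
manual_features <- function(n = 1, cd138 = 10, cd56 = 10, cd45 = 10,
                            area = 60, ecc = 0.3, nuc = 1L, apop = 0,
                            cluster = NA_character_) {
  data.frame(cell_id = sprintf("c%02d", seq_len(n)), sample_id = "S",
             compartment = "PB", frame_id = 1L,
             dapi = 500, cd138 = cd138, cd56 = cd56, cd45 = cd45,
             area = area, nuclear_eccentricity = ecc, nucleus_count = nuc,
             cluster_id = cluster, apoptosis_score = apop,
             stringsAsFactors = FALSE)
}

# fixed thresholds (cutoff 100 on every channel) without calibration
fixed_thresholds <- function(cutoff = 100) {
  out <- data.frame(channel = c("dapi", "cd138", "cd56", "cd45"),
                    cutoff = cutoff, location = NA_real_, scale = NA_real_,
                    method = "manual", stringsAsFactors = FALSE)
  class(out) <- c("channel_thresholds", "data.frame")
  out
}

test_that("constant channels fall back to epsilon cutoffs with a warning", {
  feats <- manual_features(200)
  set.seed(1)
  for (ch in c("dapi", "cd56", "cd45")) {
    feats[[ch]] <- round(stats::rlnorm(200, log(50), 0.3), 3)
  }
  # cd138 stays constant: its MAD is zero
  expect_warning(th <- calibrate_thresholds(feats), "MAD is zero.*cd138")
  cls <- classify_cells(feats, th)
  # strict '>' comparison: no cell positive on the constant channel
  expect_false(any(cls$cd138_pos))
})

test_that("calibration separates a 10x two-population mixture", {
  sp <- if_cohort_spec(cells_per_sample = 50000,
                       subtype_frequencies = c("CD138+CD56+" = 1e-4),
                       seed = 17)
  sim <- simulate_if_cohort(sp)
  th <- calibrate_thresholds(sim$features)
  cls <- classify_cells(sim$features, th)
  truth_pos <- sim$truth$subtype == "CD138+CD56+"
  call_pos <- cls$subtype == "CD138+CD56+"
  expect_lt(mean(truth_pos != call_pos), 0.01)
})

test_that("calibration requires enough cells and positive k_mad", {
  feats <- manual_features(50)
  expect_error(calibrate_thresholds(feats), "100")
  expect_error(calibrate_thresholds(manual_features(200), k_mad = 0),
               "k_mad")
})

test_that("classification is invariant to a global intensity gain", {
  sp <- if_cohort_spec(cells_per_sample = 5000,
                       subtype_frequencies = c("CD138+CD56+" = 2e-3,
                                               "CD138+" = 2e-3),
                       seed = 19)
  sim <- simulate_if_cohort(sp)
  cls1 <- classify_cells(sim$features, calibrate_thresholds(sim$features))
  scaled <- sim$features
  for (ch in c("dapi", "cd138", "cd56", "cd45")) {
    scaled[[ch]] <- scaled[[ch]] * 2
  }
  cls2 <- classify_cells(scaled, calibrate_thresholds(scaled))
  expect_identical(as.character(cls1$subtype), as.character(cls2$subtype))
})

test_that("identical cells all score zero for outlierness", {
  feats <- manual_features(50)
  expect_equal(score_outliers(feats, 5), rep(0, 50))
})

test_that("a spiked bright large cell has the maximum outlier score", {
  sp <- if_cohort_spec(cells_per_sample = 10000,
                       subtype_frequencies = c("CD138+CD56+" = 0), seed = 23)
  feats <- simulate_if_cohort(sp)$features
  spike <- manual_features(1, cd138 = 5000, cd56 = 10, cd45 = 10,
                           area = 180, ecc = 0.8)
  spike$cell_id <- "spike"
  feats <- rbind(feats, spike)
  sc <- score_outliers(feats, 10)
  expect_equal(which.max(sc), nrow(feats))
})

test_that("outlier scores match a brute-force kNN oracle", {
  sp <- if_cohort_spec(cells_per_sample = 200,
                       subtype_frequencies = c("CD138+" = 5e-3), seed = 29)
  feats <- simulate_if_cohort(sp)$features
  k <- 7
  sc <- score_outliers(feats, k)
  # oracle: full distance matrix on the same standardized features
  x <- cbind(log1p(feats$cd138), log1p(feats$cd56), log1p(feats$cd45),
             feats$area, feats$nuclear_eccentricity)
  for (j in seq_len(ncol(x))) {
    s <- stats::mad(x[, j]); if (s == 0) s <- 1
    x[, j] <- (x[, j] - stats::median(x[, j])) / s
  }
  d <- as.matrix(stats::dist(x))
  oracle <- vapply(seq_len(nrow(x)), function(i) {
    mean(sort(d[i, -i])[seq_len(k)])
  }, numeric(1))
  expect_equal(sc, oracle, tolerance = 1e-10)
  # duplicating the dataset preserves score ranks
  sc2 <- score_outliers(rbind(feats, feats), k)
  expect_equal(rank(sc2[seq_len(nrow(feats))]),
               rank(sc2[nrow(feats) + seq_len(nrow(feats))]))
  expect_error(score_outliers(feats[1:5, ], 10), "at least")
})

test_that("marker combinations map to their subtypes", {
  th <- fixed_thresholds()
  # CD138+CD56+ with CD45 below cutoff and no morphology flags
  r <- classify_cells(manual_features(1, cd138 = 500, cd56 = 500,
                                      cd45 = 10), th)
  expect_equal(as.character(r$subtype), "CD138+CD56+")
  r <- classify_cells(manual_features(1, cd138 = 500), th)
  expect_equal(as.character(r$subtype), "CD138+")
  r <- classify_cells(manual_features(1, cd138 = 500, cd45 = 500), th)
  expect_equal(as.character(r$subtype), "CD138+CD45+")
  r <- classify_cells(manual_features(1, cd138 = 500, cd56 = 500,
                                      cd45 = 500), th)
  expect_equal(as.character(r$subtype), "CD138+CD56+CD45+")
  # CD45 only at typical size: common WBC
  r <- classify_cells(manual_features(1, cd45 = 500), th)
  expect_equal(as.character(r$subtype), "common WBC")
})

test_that("morphology precedence is apoptotic > cluster > binucleated > markers", {
  th <- fixed_thresholds()
  r <- classify_cells(manual_features(1, cd138 = 500, cd56 = 500,
                                      apop = 0.9, nuc = 2L), th)
  expect_equal(as.character(r$subtype), "apoptotic PC")
  two <- manual_features(2, cd138 = 500, nuc = 2L, cluster = "cl1")
  r <- classify_cells(two, th)
  expect_equal(as.character(r$subtype), c("PC cluster", "PC cluster"))
  r <- classify_cells(manual_features(1, cd138 = 500, nuc = 2L), th)
  expect_equal(as.character(r$subtype), "binucleated PC")
  # a lone cell with a cluster id is not a cluster
  r <- classify_cells(manual_features(1, cd138 = 500, cluster = "cl1"), th)
  expect_equal(as.character(r$subtype), "CD138+")
})

test_that("large eccentric CD138- cells are candidate plasma cells", {
  th <- fixed_thresholds()
  feats <- rbind(manual_features(200, cd45 = 500),  # WBC background
                 manual_features(1, cd138 = 10, area = 200, ecc = 0.8))
  feats$cell_id <- sprintf("c%03d", seq_len(nrow(feats)))
  r <- classify_cells(feats, th)
  expect_equal(as.character(r$subtype[201]), "CD138- candidate PC")
  # same cell with a round nucleus is not a candidate
  feats$nuclear_eccentricity[201] <- 0.3
  r <- classify_cells(feats, th)
  expect_false(as.character(r$subtype[201]) == "CD138- candidate PC")
})

test_that("every cell gets exactly one subtype and markers stay consistent", {
  sp <- if_cohort_spec(cells_per_sample = 5000,
                       subtype_frequencies = c("CD138+CD56+" = 1e-3,
                                               "CD138+" = 1e-3,
                                               "binucleated PC" = 1e-3,
                                               "CD56+ non-PC" = 2e-3),
                       seed = 31)
  sim <- simulate_if_cohort(sp)
  cls <- classify_cells(sim$features, calibrate_thresholds(sim$features))
  expect_equal(nrow(cls), nrow(sim$features))
  expect_false(any(is.na(cls$subtype)))
  expect_equal(sum(table(cls$subtype)), nrow(cls))
  cd138_named <- startsWith(as.character(cls$subtype), "CD138+")
  expect_true(all(cls$cd138_pos[cd138_named]))
  cand <- cls$subtype == "CD138- candidate PC"
  expect_false(any(cls$cd138_pos[cand]))
})

test_that("enumeration normalizes counts to cells per mL", {
  th <- fixed_thresholds()
  cls <- classify_cells(manual_features(10, cd138 = 500), th)
  en <- enumerate_subtypes(cls, ml_equivalent = 2)
  expect_equal(en$cells_per_ml[en$subtype == "CD138+"], 5)
  expect_equal(en$cells_per_ml[en$subtype == "total CD138+"], 5)
  expect_error(enumerate_subtypes(cls, 0), "ml_equivalent")
  # zero rare cells -> all rare rates zero
  cls0 <- classify_cells(manual_features(200, cd45 = 500), th)
  en0 <- enumerate_subtypes(cls0, 1)
  expect_equal(en0$count[en0$subtype == "total CD138+"], 0)
})

test_that("recovered spike rate falls in the binomial 95% interval", {
  sp <- if_cohort_spec(cells_per_sample = 50000,
                       subtype_frequencies = c("CD138+CD56+" = 1e-4),
                       seed = 37)
  sim <- simulate_if_cohort(sp)
  cls <- classify_cells(sim$features, calibrate_thresholds(sim$features))
  en <- enumerate_subtypes(cls, ml_equivalent = 1)
  k <- en$count[en$subtype == "CD138+CD56+"]
  lo <- stats::qbinom(0.025, 50000, 1e-4)
  hi <- stats::qbinom(0.975, 50000, 1e-4)
  expect_gte(k, lo)
  expect_lte(k, hi)
})

test_that("the >3 cells/mL threshold stratifies strictly", {
  expect_equal(stratify_by_ctc_threshold(4), "myeloma-like")
  expect_equal(stratify_by_ctc_threshold(196), "myeloma-like")
  expect_equal(stratify_by_ctc_threshold(3), "normal-like")
  expect_equal(stratify_by_ctc_threshold(0), "normal-like")
  expect_error(stratify_by_ctc_threshold(1, threshold = -1), "threshold")
})
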