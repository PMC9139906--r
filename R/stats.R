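#' Exact two-sided rank-sum test
#'
#' Exact Wilcoxon rank-sum (Mann-Whitney) test for two independent groups,
#' suited to the very small cohorts of rare-cell enumeration studies. The
#' statistic is the midrank sum W of the first group; the two-sided p-value
#' is the probability, over group assignments of the pooled values, that
#' `|W - E[W]|` is at least the observed deviation. With pooled size up to
#' `max_exact` every `choose(n, n_a)` assignment is enumerated; beyond that
#' a seeded Monte-Carlo permutation approximation is used. Ties are handled
#' by midranks. The p-value lies in (0, 1] and is symmetric in the two
#' groups.
#'
#' With 4 vs 4 observations and complete separation the exact p-value is
#' 2/70, printed as 0.029.
#'
#' @param a,b Numeric vectors (both non-empty).
#' @param max_exact Largest pooled size for full enumeration; default 12.
#' @param n_perm Monte-Carlo permutations for larger inputs; default 1e5.
#' @param seed Seed for the permutation path.
#' @return An object of class `"htest"` with `statistic` (W), `p.value`,
#'   and `method` recording the path taken.
#' @examples
#' exact_rank_sum_test(c(4, 17, 30, 196), c(0, 0, 1, 3))$p.value # 2/70
#' @export
exact_rank_sum_test <- function(a, b, max_exact = 12, n_perm = 1e5,
                                seed = 1L) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)  # midranks
  w_obs <- sum(r[seq_len(na)])
  ew <- na * (n + 1) / 2
  dev_obs <- abs(w_obs - ew)
  eps <- 1e-9
  if (n <= max_exact) {
    idx <- utils::combn(n, na)
    w_all <- colSums(matrix(r[idx], nrow = na))
    p <- mean(abs(w_all - ew) >= dev_obs - eps)
    method <- "exact rank-sum (full enumeration)"
  } else {
    old <- get0(".Random.seed", envir = globalenv())
    on.exit(restore_seed(old))
    set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      w <- sum(r[sample.int(n, na)])
      if (abs(w - ew) >= dev_obs - eps) hits <- hits + 1L
    }
    p <- (hits + 1) / (n_perm + 1)
    method <- "rank-sum (Monte-Carlo permutation)"
  }
  structure(list(statistic = c(W = w_obs), p.value = min(p, 1),
                 method = method,
                 data.name = paste(deparse(substitute(a)), "vs",
                                   deparse(substitute(b)))),
            class = "htest")
}

#' Round half away from zero
#'
#' Percentage tables use half-away-from-zero rounding to one decimal, the
#' convention that reproduces the cohort's printed worked percentages
#' (e.g. 36/44 = 81.8, 19/22 = 86.4).
#'
#' @param x Numeric.
#' @param digits Decimal places; default 1.
#' @return Rounded numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Altered-cell percentages by morphotype and compartment
#'
#' Joins classifications to copy-number profiles on `cell_id` and tabulates,
#' per morphotype and compartment, the number of sequenced cells, the number
#' altered, and the percentage (one decimal, half away from zero). Sequenced
#' cells without a classification are reported under the morphotype
#' `"unjoined"` rather than dropped.
#'
#' @param classifications `data.frame` from [classify_cells()] with a
#'   `compartment` column (joined from features/metadata if needed).
#' @param cn_summary `data.frame` with `cell_id` and logical `altered`
#'   (e.g. `summary(fit_cnv(...))`).
#' @return `data.frame`: `morphotype`, `compartment`, `n_sequenced`,
#'   `n_altered`, `pct_altered`.
#' @export
percent_altered_by_morphotype <- function(classifications, cn_summary) {
  cls <- classifications
  if (!"compartment" %in% names(cls)) cls$compartment <- "all"
  m <- merge(cn_summary[, c("cell_id", "altered")],
             cls[, c("cell_id", "subtype", "compartment")],
             by = "cell_id", all.x = TRUE)
  m$morphotype <- as.character(m$subtype)
  m$morphotype[is.na(m$morphotype)] <- "unjoined"
  m$compartment[is.na(m$compartment)] <- "unjoined"
  agg <- stats::aggregate(list(n_sequenced = m$altered,
                               n_altered = m$altered),
                          by = list(morphotype = m$morphotype,
                                    compartment = m$compartment),
                          FUN = length)
  alt <- stats::aggregate(list(n_altered = m$altered),
                          by = list(morphotype = m$morphotype,
                                    compartment = m$compartment),
                          FUN = sum)
  out <- merge(agg[, c("morphotype", "compartment", "n_sequenced")], alt,
               by = c("morphotype", "compartment"))
  out$pct_altered <- round_half_away(100 * out$n_altered / out$n_sequenced)
  out <- out[order(out$morphotype, out$compartment), ]
  rownames(out) <- NULL
  out
}

#' Ploidy-class fractions of altered cells
#'
#' Per group, the percentage of altered cells at each baseline ploidy
#' (one decimal, half away from zero); fractions per group sum to 100 up to
#' rounding.
#'
#' @param cn_summary `data.frame` with `baseline_ploidy`, logical `altered`,
#'   and any grouping columns.
#' @param group Character vector of grouping column names; default none
#'   (one overall group).
#' @return `data.frame`: grouping columns, `ploidy`, `n_cells`, `pct`.
#' @export
ploidy_distribution <- function(cn_summary, group = character(0)) {
  d <- cn_summary[cn_summary$altered, , drop = FALSE]
  if (!nrow(d)) {
    out <- data.frame(ploidy = integer(0), n_cells = integer(0),
                      pct = numeric(0))
    return(out)
  }
  if (!length(group)) {
    d$.grp <- "all"
    group <- ".grp"
  }
  keys <- c(group, "baseline_ploidy")
  agg <- stats::aggregate(list(n_cells = d$cell_id), by = d[, keys,
                          drop = FALSE], FUN = length)
  tot <- stats::aggregate(list(total = agg$n_cells),
                          by = agg[, group, drop = FALSE], FUN = sum)
  out <- merge(agg, tot, by = group)
  out$pct <- round_half_away(100 * out$n_cells / out$total)
  names(out)[names(out) == "baseline_ploidy"] <- "ploidy"
  out$total <- NULL
  out <- out[do.call(order, out[, c(group, "ploidy"), drop = FALSE]), ]
  if (".grp" %in% names(out)) out$.grp <- NULL
  rownames(out) <- NULL
  out
}

#' Sequencing-outcome summary
#'
#' Per patient and compartment: cells sequenced and cells altered, plus
#' cohort totals per diagnosis. Cohort totals equal the sums of per-patient
#' counts by construction.
#'
#' @param meta `data.frame` with `cell_id`, `patient_id`, `compartment`,
#'   and optionally `diagnosis`.
#' @param cn_summary `data.frame` with `cell_id` and logical `altered`.
#' @return List with `by_sample` (`patient_id`, `compartment`,
#'   `n_sequenced`, `n_altered`) and `totals` (`diagnosis`, `n_sequenced`,
#'   `n_altered`).
#' @export
sequencing_outcome_summary <- function(meta, cn_summary) {
  if (!nrow(cn_summary)) {
    return(list(by_sample = data.frame(patient_id = character(0),
                                       compartment = character(0),
                                       n_sequenced = integer(0),
                                       n_altered = integer(0)),
                totals = data.frame(diagnosis = character(0),
                                    n_sequenced = integer(0),
                                    n_altered = integer(0))))
  }
  if (!"diagnosis" %in% names(meta)) meta$diagnosis <- "all"
  m <- merge(cn_summary[, c("cell_id", "altered")],
             meta[, c("cell_id", "patient_id", "compartment", "diagnosis")],
             by = "cell_id")
  by_sample <- stats::aggregate(
    list(n_sequenced = m$altered, n_altered = m$altered),
    by = list(patient_id = m$patient_id, compartment = m$compartment),
    FUN = length)
  alt <- stats::aggregate(list(n_altered = m$altered),
                          by = list(patient_id = m$patient_id,
                                    compartment = m$compartment), FUN = sum)
  by_sample <- merge(by_sample[, c("patient_id", "compartment",
                                   "n_sequenced")], alt,
                     by = c("patient_id", "compartment"))
  by_sample <- by_sample[order(by_sample$patient_id,
                               by_sample$compartment), ]
  totals <- stats::aggregate(list(n_sequenced = m$altered),
                             by = list(diagnosis = m$diagnosis), FUN = length)
  talt <- stats::aggregate(list(n_altered = m$altered),
                           by = list(diagnosis = m$diagnosis), FUN = sum)
  totals <- merge(totals, talt, by = "diagnosis")
  rownames(by_sample) <- rownames(totals) <- NULL
  list(by_sample = by_sample, totals = totals)
}
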