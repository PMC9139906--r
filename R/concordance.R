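#' The 12-event clinical cytogenetics locus panel
#'
#' The common myeloma cytogenetic events probed by clinical interphase FISH:
#' copy-number probes for CCND1 (11q13), RB1 (13q14), 13q34, TP53 (17p13),
#' CKS1B (1q21), CDKN2C (1p32), FGFR3 (4p16), IGH (14q32) and the chr17
#' centromere (CEP17), plus the three canonical IGH translocations t(4;14),
#' t(11;14), t(14;16). Intervals are hg19-approximate arm/band-scale
#' hardcoded coordinates; a BED-like panel file (see [read_locus_panel()])
#' is the override mechanism. Translocations carry no interval and are never
#' evaluable from low-pass copy-number data.
#'
#' @return `data.frame` with columns `event_name`, `chrom`, `start`, `end`
#'   (0-based half-open; `NA` for translocations) and `direction`
#'   (`gain`/`loss`/`translocation`).
#' @export
default_locus_panel <- function() {
  data.frame(
    event_name = c("CCND1_11q13_gain", "RB1_13q14_loss", "13q34_loss",
                   "TP53_17p13_loss", "CKS1B_1q21_gain", "CDKN2C_1p32_loss",
                   "FGFR3_4p16_gain", "IGH_14q32_gain", "CEP17_gain",
                   "t(4;14)", "t(11;14)", "t(14;16)"),
    chrom = c("chr11", "chr13", "chr13", "chr17", "chr1", "chr1", "chr4",
              "chr14", "chr17", NA, NA, NA),
    start = c(53700000, 19500000, 109600000, 0, 142600000, 49000000, 0,
              95000000, 22200000, NA, NA, NA),
    end = c(135006516, 115169878, 115169878, 22200000, 155300000, 61300000,
            11300000, 107349540, 25800000, NA, NA, NA),
    direction = c("gain", "loss", "loss", "loss", "gain", "loss", "gain",
                  "gain", "gain", "translocation", "translocation",
                  "translocation"),
    stringsAsFactors = FALSE)
}

# weighted median; w > 0, x numeric
weighted_median <- function(x, w) {
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1]
  x[i]
}

#' Call one cytogenetic event on one cell
#'
#' The observed copy number at a locus is the bin-length-weighted median
#' integer copy number over bins overlapping the locus interval (the
#' weighted median resists boundary bins). Matching interphase-FISH copy
#' counting, presence is judged against absolute 2 copies: a gain event is
#' present when the observed copy number exceeds 2, a loss event when it is
#' below 2. With `relative_to_ploidy = TRUE` the comparison baseline is the
#' cell's fitted ploidy instead. Translocation events cannot be detected
#' from low-pass copy-number data and return `"not_evaluable"`.
#'
#' @param profile A `cn_profile` (element of a [fit_cnv()] result).
#' @param locus One row of a locus panel (`data.frame` or list with
#'   `event_name`, `chrom`, `start`, `end`, `direction`).
#' @param bins Bin table aligned with the profile.
#' @param relative_to_ploidy Judge events against the cell's baseline ploidy
#'   rather than 2; default `FALSE`.
#' @return List (`event_call`): `cell_id`, `event_name`, `status`
#'   (`present`/`absent`/`not_evaluable`), `observed_cn` (`NA` for
#'   translocations).
#' @export
call_event <- function(profile, locus, bins, relative_to_ploidy = FALSE) {
  if (locus$direction == "translocation") {
    return(list(cell_id = profile$cell_id, event_name = locus$event_name,
                status = "not_evaluable", observed_cn = NA_real_))
  }
  ov_start <- pmax(bins$start, locus$start)
  ov_end <- pmin(bins$end, locus$end)
  hit <- bins$chrom == locus$chrom & ov_end > ov_start
  if (!any(hit)) {
    stop("locus ", locus$event_name, " overlaps no genome bins")
  }
  cn_obs <- weighted_median(profile$cn[hit], (ov_end - ov_start)[hit])
  base <- if (relative_to_ploidy) profile$baseline_ploidy else 2
  present <- if (locus$direction == "gain") cn_obs > base else cn_obs < base
  list(cell_id = profile$cell_id, event_name = locus$event_name,
       status = if (present) "present" else "absent",
       observed_cn = cn_obs)
}

#' Call the full panel on every cell
#'
#' @param fit A `cnv_fit` (or list of `cn_profile`s).
#' @param panel Locus panel; default [default_locus_panel()].
#' @param bins Bin table; taken from the fit when omitted.
#' @param relative_to_ploidy Passed to [call_event()].
#' @return `data.frame` of event calls: `cell_id`, `event_name`, `status`,
#'   `observed_cn`.
#' @export
call_events <- function(fit, panel = default_locus_panel(), bins = NULL,
                        relative_to_ploidy = FALSE) {
  profiles <- if (inherits(fit, "cnv_fit")) fit$profiles else fit
  if (is.null(bins)) {
    if (!inherits(fit, "cnv_fit")) stop("bins must be supplied")
    bins <- fit$bins
  }
  rows <- list()
  for (p in profiles) {
    for (j in seq_len(nrow(panel))) {
      rows[[length(rows) + 1L]] <-
        call_event(p, panel[j, ], bins, relative_to_ploidy)
    }
  }
  out <- data.frame(
    cell_id = vapply(rows, `[[`, character(1), "cell_id"),
    event_name = vapply(rows, `[[`, character(1), "event_name"),
    status = vapply(rows, `[[`, character(1), "status"),
    observed_cn = vapply(rows, `[[`, numeric(1), "observed_cn"),
    stringsAsFactors = FALSE)
  out
}

#' Aggregate event calls per patient, compartment and cohort
#'
#' Counts cells with a `present` call per event and patient, per event and
#' compartment, and per event over the cohort; cohort totals equal the sum
#' of per-patient (and per-compartment) counts by construction.
#'
#' @param calls Event-call `data.frame` from [call_events()].
#' @param meta `data.frame` with `cell_id`, `patient_id`, `compartment`.
#' @return List of three `data.frame`s: `by_patient`, `by_compartment`,
#'   `cohort` (columns `event_name`, grouping key, `n_cells`).
#' @export
aggregate_events <- function(calls, meta) {
  m <- merge(calls, meta[, intersect(c("cell_id", "patient_id",
                                       "compartment"), names(meta))],
             by = "cell_id")
  pres <- m[m$status == "present", ]
  count_by <- function(keys) {
    if (!nrow(pres)) {
      out <- data.frame(event_name = character(0))
      for (k in keys) out[[k]] <- character(0)
      out$n_cells <- integer(0)
      return(out)
    }
    agg <- stats::aggregate(list(n_cells = pres$cell_id),
                            by = pres[, c("event_name", keys), drop = FALSE],
                            FUN = length)
    agg[do.call(order, agg[, c("event_name", keys), drop = FALSE]), ,
        drop = FALSE]
  }
  by_patient <- count_by("patient_id")
  by_compartment <- count_by("compartment")
  cohort <- if (nrow(pres)) {
    agg <- stats::aggregate(list(n_cells = pres$cell_id),
                            by = pres[, "event_name", drop = FALSE],
                            FUN = length)
    agg[order(agg$event_name), , drop = FALSE]
  } else {
    data.frame(event_name = character(0), n_cells = integer(0))
  }
  rownames(by_patient) <- rownames(by_compartment) <- rownames(cohort) <- NULL
  list(by_patient = by_patient, by_compartment = by_compartment,
       cohort = cohort)
}

#' Co-occurrence intersection sizes of present events
#'
#' UpSet-style counting: for every observed combination of present events,
#' the number of cells carrying exactly that combination. Combination counts
#' sum to the number of cells with at least one present event.
#'
#' @param calls Event-call `data.frame` from [call_events()].
#' @return `data.frame` with `combination` (event names sorted, joined by
#'   `"+"`), `degree` (number of events) and `n_cells`, sorted by
#'   decreasing count then combination; empty when no cell has a present
#'   event.
#' @export
cooccurrence_sets <- function(calls) {
  pres <- calls[calls$status == "present", ]
  if (!nrow(pres)) {
    return(data.frame(combination = character(0), degree = integer(0),
                      n_cells = integer(0)))
  }
  combos <- vapply(split(pres$event_name, pres$cell_id), function(ev) {
    paste(sort(unique(ev)), collapse = "+")
  }, character(1))
  tab <- table(combos)
  out <- data.frame(combination = names(tab),
                    degree = lengths(strsplit(names(tab), "+", fixed = TRUE)),
                    n_cells = as.integer(tab), stringsAsFactors = FALSE)
  out <- out[order(-out$n_cells, out$combination), ]
  rownames(out) <- NULL
  out
}

#' Report discordances between single-cell calls and clinical FISH
#'
#' For one patient, compares the events present in at least one sequenced
#' cell against the clinical panel result: `cell_only` lists events carried
#' by cells but clinically negative, `clinical_only` lists clinically
#' positive events with no present cell. Events that are not evaluable from
#' copy-number data (translocations) are excluded from both lists. Output is
#' deterministic (sorted).
#'
#' @param calls Event-call `data.frame` for the patient's cells.
#' @param fish A `fish_panel_result` (see [simulate_fish_panel()] /
#'   [read_fish_panel()]).
#' @return List with `patient_id`, `cell_only`, `clinical_only` (sorted
#'   character vectors).
#' @export
discordance_report <- function(calls, fish) {
  stopifnot(inherits(fish, "fish_panel_result"))
  unknown <- setdiff(unique(calls$event_name), names(fish$status))
  if (length(unknown)) {
    stop("event name(s) missing from FISH panel: ",
         paste(sort(unknown), collapse = ", "))
  }
  not_evaluable <- unique(calls$event_name[calls$status == "not_evaluable"])
  cell_present <- unique(calls$event_name[calls$status == "present"])
  clinical_pos <- names(fish$status)[fish$status == "positive"]
  list(patient_id = fish$patient_id,
       cell_only = sort(setdiff(cell_present, clinical_pos)),
       clinical_only = sort(setdiff(setdiff(clinical_pos, cell_present),
                                    not_evaluable)))
}
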