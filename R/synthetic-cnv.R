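#' Define a clone for copy-number simulation
#'
#' A clone is a flat genome at an integer baseline ploidy with a list of
#' copy-number events layered on top, drawn by a fraction of simulated cells.
#' Myeloma-typical architectures (hyperdiploid trisomies of odd-numbered
#' chromosomes, focal or arm-level losses) are expressed this way.
#'
#' @param clone_id Character label.
#' @param ploidy Integer baseline ploidy, 2 to 5. Autosomes start at this
#'   copy number; sex chromosomes are simulated at copy number 2 (female-like)
#'   so that unmodeled patient sex does not confound ploidy fitting.
#' @param events A `data.frame` with columns `chrom`, `start`, `end`
#'   (0-based half-open) and `cn` (integer copy number replacing the baseline
#'   over the interval), or `NULL` for none.
#' @param fraction Fraction of simulated cells drawn from this clone.
#' @return An object of class `"clone_spec"`.
#' @export
clone_spec <- function(clone_id, ploidy = 2L, events = NULL, fraction = 1) {
  ploidy <- as.integer(ploidy)
  if (ploidy < 2L || ploidy > 5L) stop("ploidy must be an integer in 2..5")
  if (!is.null(events)) {
    stopifnot(is.data.frame(events),
              all(c("chrom", "start", "end", "cn") %in% names(events)))
    if (any(events$cn < 0)) stop("event copy numbers must be >= 0")
    lens <- hg19_chrom_lengths()
    unknown <- setdiff(events$chrom, names(lens))
    if (length(unknown)) {
      stop("clone event references unknown chromosome(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(events$start < 0) ||
        any(events$end > lens[events$chrom] + 0.5) ||
        any(events$end <= events$start)) {
      stop("event intervals must lie within chromosome bounds")
    }
  }
  if (fraction < 0 || fraction > 1) stop("fraction must be in [0, 1]")
  structure(list(clone_id = as.character(clone_id), ploidy = ploidy,
                 events = events, fraction = fraction),
            class = "clone_spec")
}

#' Specify a single-cell copy-number simulation
#'
#' Bundles clones and count-noise parameters for [simulate_cnv_cells()].
#' Defaults emulate low-pass single-cell whole-genome sequencing after
#' whole-genome amplification: roughly 500,000 mapped reads per cell over
#' 5,000 genome bins, negative-binomial count overdispersion and a
#' multiplicative quadratic GC bias.
#'
#' @param clone_specs List of [clone_spec()] objects; fractions must sum to 1.
#' @param n_cells Number of cells to simulate.
#' @param reads_per_cell Expected total mapped reads per cell (default 5e5).
#' @param n_bins Number of genome bins (default 5000); must not exceed
#'   `reads_per_cell`.
#' @param dispersion Negative-binomial overdispersion; variance is
#'   `mu + dispersion * mu^2`. `0` gives Poisson counts.
#' @param gc_bias_coefficients Numeric length-3 vector `c(c0, c1, c2)` of a
#'   quadratic in GC fraction; the multiplicative bias curve is normalized to
#'   mean 1 across bins. Default `c(1, 0, 0)` (no bias).
#' @param seed Integer seed.
#' @return An object of class `"cnv_sim_spec"`.
#' @export
cnv_sim_spec <- function(clone_specs, n_cells, reads_per_cell = 5e5,
                         n_bins = 5000L, dispersion = 0,
                         gc_bias_coefficients = c(1, 0, 0), seed = 1L) {
  if (!length(clone_specs)) stop("at least one clone_spec is required")
  if (inherits(clone_specs, "clone_spec")) clone_specs <- list(clone_specs)
  stopifnot(all(vapply(clone_specs, inherits, TRUE, "clone_spec")))
  fr <- vapply(clone_specs, `[[`, numeric(1), "fraction")
  if (abs(sum(fr) - 1) > 1e-8) stop("clone fractions must sum to 1")
  if (reads_per_cell < n_bins) stop("reads_per_cell must be >= n_bins")
  if (dispersion < 0) stop("dispersion must be >= 0")
  stopifnot(length(gc_bias_coefficients) == 3)
  structure(list(clone_specs = clone_specs, n_cells = as.integer(n_cells),
                 reads_per_cell = reads_per_cell, n_bins = as.integer(n_bins),
                 dispersion = dispersion,
                 gc_bias_coefficients = gc_bias_coefficients,
                 seed = as.integer(seed)),
            class = "cnv_sim_spec")
}

#' True integer copy number of a clone over a bin table
#'
#' Autosomal bins carry the clone's baseline ploidy, overridden by any event
#' covering the bin midpoint; sex-chromosome bins are copy number 2.
#'
#' @param clone A [clone_spec()].
#' @param bins Bin table from [make_bin_table()].
#' @return Integer vector of per-bin copy number.
#' @export
clone_cn_profile <- function(clone, bins) {
  cn <- ifelse(bins$chrom %in% autosome_names(), clone$ploidy, 2L)
  ev <- clone$events
  if (!is.null(ev)) {
    mid <- (bins$start + bins$end) / 2
    for (i in seq_len(nrow(ev))) {
      hit <- bins$chrom == ev$chrom[i] & mid >= ev$start[i] & mid < ev$end[i]
      cn[hit] <- as.integer(ev$cn[i])
    }
  }
  as.integer(cn)
}

#' Simulate single-cell bin-count profiles
#'
#' Draws each cell from a clone (multinomially by clone fraction), then draws
#' per-bin read counts with expectation proportional to
#' `true CN x bin width x GC-bias factor`, scaled so the expected per-cell
#' total equals `reads_per_cell`. Counts are negative-binomial with the
#' spec's dispersion (Poisson at dispersion 0).
#'
#' @param spec A [cnv_sim_spec()].
#' @param bins Bin table from [make_bin_table()].
#' @return A list with `counts` (integer matrix, cells x bins, rownames
#'   cell ids), `truth` (`data.frame` of `cell_id`, `clone_id`, `ploidy`),
#'   and `true_cn` (integer matrix of per-bin true copy number, cells x bins).
#' @examples
#' bins <- make_bin_table(200, seed = 1)
#' sp <- cnv_sim_spec(clone_spec("diploid"), n_cells = 3,
#'                    reads_per_cell = 2e4, n_bins = 200)
#' sim <- simulate_cnv_cells(sp, bins)
#' rowSums(sim$counts)
#' @export
simulate_cnv_cells <- function(spec, bins) {
  stopifnot(inherits(spec, "cnv_sim_spec"))
  if (nrow(bins) != spec$n_bins) {
    stop("bin table has ", nrow(bins), " bins but spec declares ",
         spec$n_bins)
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(spec$seed)

  co <- spec$gc_bias_coefficients
  gcf <- co[1] + co[2] * bins$gc + co[3] * bins$gc^2
  gcf <- pmax(gcf, 1e-6)
  gcf <- gcf / mean(gcf)
  width <- bins$end - bins$start

  cn_by_clone <- lapply(spec$clone_specs, clone_cn_profile, bins = bins)
  clone_ids <- vapply(spec$clone_specs, `[[`, character(1), "clone_id")
  fr <- vapply(spec$clone_specs, `[[`, numeric(1), "fraction")
  pick <- sample.int(length(clone_ids), spec$n_cells, replace = TRUE,
                     prob = fr)

  counts <- matrix(0L, spec$n_cells, spec$n_bins)
  true_cn <- matrix(0L, spec$n_cells, spec$n_bins)
  for (i in seq_len(spec$n_cells)) {
    cn <- cn_by_clone[[pick[i]]]
    w <- cn * width * gcf
    mu <- spec$reads_per_cell * w / sum(w)
    counts[i, ] <- if (spec$dispersion == 0) {
      stats::rpois(spec$n_bins, mu)
    } else {
      stats::rnbinom(spec$n_bins, mu = mu, size = 1 / spec$dispersion)
    }
    true_cn[i, ] <- cn
  }
  cell_id <- sprintf("cell_%03d", seq_len(spec$n_cells))
  rownames(counts) <- rownames(true_cn) <- cell_id
  truth <- data.frame(
    cell_id = cell_id,
    clone_id = clone_ids[pick],
    ploidy = vapply(spec$clone_specs, `[[`, integer(1), "ploidy")[pick],
    stringsAsFactors = FALSE)
  list(counts = counts, truth = truth, true_cn = true_cn)
}

#' Derive a clinical FISH panel result from clone truth
#'
#' Emulates an interphase-FISH readout with a clinical positivity cut-off:
#' a copy-number event at a panel locus is reported positive when the
#' clone-fraction-weighted proportion of cells carrying it (absolute copies,
#' gain > 2 or loss < 2 at the locus midpoint) reaches the cut-off.
#' Translocation events are not modeled and always report negative.
#'
#' @param clone_specs List of [clone_spec()] objects (fractions sum to 1).
#' @param locus_panel Locus panel `data.frame`, e.g. [default_locus_panel()].
#' @param positivity_cutoff Clinical cut-off fraction in (0, 1); default 0.20.
#' @param patient_id Label stored on the result.
#' @return An object of class `"fish_panel_result"`: list with `patient_id`
#'   and `status`, a named character vector over panel events with values
#'   `"positive"`/`"negative"`.
#' @export
simulate_fish_panel <- function(clone_specs, locus_panel = default_locus_panel(),
                                positivity_cutoff = 0.20,
                                patient_id = "synthetic") {
  if (!length(clone_specs)) stop("at least one clone_spec is required")
  if (inherits(clone_specs, "clone_spec")) clone_specs <- list(clone_specs)
  if (positivity_cutoff <= 0 || positivity_cutoff >= 1) {
    stop("positivity_cutoff must be in (0, 1)")
  }
  fr <- vapply(clone_specs, `[[`, numeric(1), "fraction")
  status <- setNames(rep("negative", nrow(locus_panel)),
                     locus_panel$event_name)
  for (j in seq_len(nrow(locus_panel))) {
    if (locus_panel$direction[j] == "translocation") next
    mid <- (locus_panel$start[j] + locus_panel$end[j]) / 2
    carried <- vapply(clone_specs, function(cl) {
      cn <- cl$ploidy
      if (!(locus_panel$chrom[j] %in% autosome_names())) cn <- 2L
      ev <- cl$events
      if (!is.null(ev)) {
        hit <- ev$chrom == locus_panel$chrom[j] & ev$start <= mid &
          ev$end > mid
        if (any(hit)) cn <- ev$cn[which(hit)[1]]
      }
      if (locus_panel$direction[j] == "gain") cn > 2 else cn < 2
    }, logical(1))
    if (sum(fr[carried]) >= positivity_cutoff) status[j] <- "positive"
  }
  structure(list(patient_id = patient_id, status = status),
            class = "fish_panel_result")
}
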