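# Tabular I/O: TSV with '#'-prefixed comment lines, UTF-8, NA for missing,
# BED-like files for genomic intervals. All genomic coordinates are 0-based
# half-open internally and at the BED boundary.

read_table_checked <- function(path, required, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  x <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                         stringsAsFactors = FALSE, quote = "",
                         check.names = FALSE, na.strings = "NA")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols)) {
    stop("schema error in ", path, ": missing required column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  x
}

write_table_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
}

#' Read a cell feature table
#'
#' TSV with one row per segmented DAPI+ cell; `#` comment lines allowed.
#' Required columns: `cell_id`, `sample_id`, `dapi`, `cd138`, `cd56`,
#' `cd45`, `area`, `nuclear_eccentricity`, `nucleus_count`,
#' `apoptosis_score` (plus optional `compartment`, `frame_id`,
#' `cluster_id`).
#'
#' @param path File path.
#' @param sep Field separator; `"\t"` (default) or `","` for CSV.
#' @return `data.frame` of cell features.
#' @export
read_cell_features <- function(path, sep = "\t") {
  req <- c("cell_id", "sample_id", "dapi", "cd138", "cd56", "cd45", "area",
           "nuclear_eccentricity", "nucleus_count", "apoptosis_score")
  x <- read_table_checked(path, req, sep)
  for (ch in c("dapi", "cd138", "cd56", "cd45")) {
    bad <- which(x[[ch]] < 0)
    if (length(bad)) {
      stop("validation error in ", path, ": negative ", ch,
           " intensity at row ", bad[1])
    }
  }
  if ("cluster_id" %in% names(x)) x$cluster_id <- as.character(x$cluster_id)
  x
}

#' Write a cell feature table
#' @param path File path.
#' @param features `data.frame` as returned by [simulate_if_cohort()] or
#'   [read_cell_features()].
#' @export
write_cell_features <- function(path, features) {
  write_table_tsv(features, path)
  invisible(path)
}

#' Write cell classifications
#' @param path File path.
#' @param classes `data.frame` from [classify_cells()].
#' @export
write_classifications <- function(path, classes) {
  out <- classes
  out$subtype <- as.character(out$subtype)
  write_table_tsv(out, path)
  invisible(path)
}

#' Read cell classifications
#' @param path File path.
#' @return `data.frame` with `subtype` as a factor over [subtype_levels()].
#' @export
read_classifications <- function(path) {
  x <- read_table_checked(path, c("cell_id", "sample_id", "subtype"))
  x$subtype <- factor(x$subtype, levels = subtype_levels())
  x
}

#' Read a per-cell bin-count matrix
#'
#' TSV whose first column is `cell_id` and remaining columns are genome bins
#' in bin-table order. All counts must be non-negative integers; when a bin
#' table is supplied its bin count must agree with the matrix.
#'
#' @param path File path.
#' @param bins Optional bin table for schema validation.
#' @return Integer matrix, cells x bins, cell ids as rownames.
#' @export
read_bin_counts <- function(path, bins = NULL) {
  x <- read_table_checked(path, "cell_id")
  ids <- x$cell_id
  m <- as.matrix(x[, setdiff(names(x), "cell_id"), drop = FALSE])
  if (!is.numeric(m)) stop("validation error in ", path,
                           ": non-numeric counts")
  neg <- which(rowSums(m < 0) > 0)
  if (length(neg)) {
    stop("validation error in ", path, ": negative count at row ", neg[1],
         " (cell ", ids[neg[1]], ")")
  }
  if (!is.null(bins) && ncol(m) != nrow(bins)) {
    stop("schema error: count matrix has ", ncol(m),
         " bins but bin table declares ", nrow(bins))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- ids
  m
}

#' Write a per-cell bin-count matrix
#' @param path File path.
#' @param counts Integer matrix, cells x bins (rownames are cell ids).
#' @export
write_bin_counts <- function(path, counts) {
  df <- data.frame(cell_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df) <- c("cell_id", sprintf("bin_%d", seq_len(ncol(counts))))
  write_table_tsv(df, path)
  invisible(path)
}

#' Read a genome bin table (BED-like)
#'
#' Columns `chrom`, `start`, `end`, `gc`; 0-based half-open coordinates.
#' @param path File path.
#' @return `data.frame` bin table.
#' @export
read_bin_table <- function(path) {
  x <- read_table_checked(path, c("chrom", "start", "end", "gc"))
  bad <- which(x$end <= x$start)
  if (length(bad)) {
    stop("validation error in ", path, ": empty interval at row ", bad[1])
  }
  x
}

#' Write a genome bin table (BED-like TSV)
#' @param path File path.
#' @param bins Bin table from [make_bin_table()].
#' @export
write_bin_table <- function(path, bins) {
  write_table_tsv(bins, path)
  invisible(path)
}

#' Write per-cell copy-number profiles
#'
#' Long-format TSV with one row per segment, carrying the per-cell fit
#' alongside: `cell_id`, `ploidy_scale`, `baseline_ploidy`, `altered`,
#' `quality`, `chrom`, `start_bin`, `end_bin`, `n_bins`, `mean_ratio`, `cn`.
#'
#' @param path File path.
#' @param fit A `cnv_fit` from [fit_cnv()].
#' @export
write_cn_profiles <- function(path, fit) {
  stopifnot(inherits(fit, "cnv_fit"))
  rows <- lapply(fit$profiles, function(p) {
    seg <- p$segments
    data.frame(cell_id = p$cell_id, ploidy_scale = p$ploidy_scale,
               baseline_ploidy = p$baseline_ploidy, altered = p$altered,
               quality = p$quality, seg, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$mean_ratio <- round(out$mean_ratio, 6)
  out$quality <- round(out$quality, 8)
  write_table_tsv(out, path)
  invisible(path)
}

#' Read per-cell copy-number profiles written by [write_cn_profiles()]
#' @param path File path.
#' @return `data.frame` in the long segment format.
#' @export
read_cn_profiles <- function(path) {
  read_table_checked(path, c("cell_id", "ploidy_scale", "baseline_ploidy",
                             "altered", "chrom", "start_bin", "end_bin",
                             "n_bins", "mean_ratio", "cn"))
}

#' Read a clinical FISH panel result
#'
#' TSV with columns `patient_id`, `event_name`, `status`
#' (`positive`/`negative`/`not_tested`). Event names must come from the
#' supplied locus panel.
#'
#' @param path File path.
#' @param panel Locus panel for vocabulary validation; default
#'   [default_locus_panel()].
#' @return A `fish_panel_result` (single patient per file).
#' @export
read_fish_panel <- function(path, panel = default_locus_panel()) {
  x <- read_table_checked(path, c("patient_id", "event_name", "status"))
  unknown <- setdiff(x$event_name, panel$event_name)
  if (length(unknown)) {
    stop("validation error in ", path, ": unknown event name(s) ",
         paste(sort(unknown), collapse = ", "))
  }
  bad <- which(!x$status %in% c("positive", "negative", "not_tested"))
  if (length(bad)) {
    stop("validation error in ", path, ": unknown status at row ", bad[1])
  }
  if (length(unique(x$patient_id)) != 1) {
    stop("FISH panel file must contain exactly one patient")
  }
  structure(list(patient_id = x$patient_id[1],
                 status = stats::setNames(x$status, x$event_name)),
            class = "fish_panel_result")
}

#' Write a clinical FISH panel result
#' @param path File path.
#' @param fish A `fish_panel_result`.
#' @export
write_fish_panel <- function(path, fish) {
  stopifnot(inherits(fish, "fish_panel_result"))
  write_table_tsv(data.frame(patient_id = fish$patient_id,
                             event_name = names(fish$status),
                             status = unname(fish$status),
                             stringsAsFactors = FALSE), path)
  invisible(path)
}

#' Read a cytogenetic locus panel (BED-like)
#'
#' Five columns: `chrom`, `start`, `end`, `event_name`, `direction`
#' (`gain`/`loss`/`translocation`); header optional, `#` comments allowed,
#' 0-based half-open coordinates. Translocation rows may use `.` or `NA`
#' for coordinates.
#'
#' @param path File path.
#' @return Locus panel `data.frame` in [default_locus_panel()] layout.
#' @export
read_locus_panel <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 10)
  first <- first[!startsWith(first, "#")][1]
  has_header <- grepl("chrom", first, fixed = TRUE)
  x <- utils::read.table(path, header = has_header, sep = "\t",
                         comment.char = "#", stringsAsFactors = FALSE,
                         na.strings = c("NA", "."))
  if (!has_header) {
    if (ncol(x) < 5) stop("locus panel needs 5 columns (BED + direction)")
    names(x)[1:5] <- c("chrom", "start", "end", "event_name", "direction")
  }
  bad <- which(!x$direction %in% c("gain", "loss", "translocation"))
  if (length(bad)) {
    stop("validation error in ", path, ": bad direction at row ", bad[1])
  }
  cn_rows <- x$direction != "translocation"
  if (any(cn_rows & (is.na(x$start) | is.na(x$end)))) {
    stop("copy-number loci require coordinates")
  }
  x[, c("event_name", "chrom", "start", "end", "direction")]
}

#' Write a cytogenetic locus panel (BED-like)
#' @param path File path.
#' @param panel Locus panel `data.frame`.
#' @export
write_locus_panel <- function(path, panel) {
  out <- panel[, c("chrom", "start", "end", "event_name", "direction")]
  write_table_tsv(out, path)
  invisible(path)
}

#' Load and validate a YAML configuration
#'
#' Accepts the generator/pipeline settings as a YAML map. Recognized keys
#' are validated for type; unknown keys are kept as-is.
#'
#' @param path YAML file path.
#' @return Named list of settings.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  num_keys <- c("seed", "n_bins", "n_cells", "reads_per_cell", "dispersion",
                "k_mad", "min_seg_bins", "min_event_bins",
                "similarity_threshold", "positivity_cutoff")
  for (k in intersect(num_keys, names(cfg))) {
    if (!is.numeric(cfg[[k]])) stop("config key '", k, "' must be numeric")
  }
  cfg
}
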