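#' hg19-like chromosome lengths
#'
#' Returns the chromosome lengths (bp) of an hg19-like human genome:
#' 22 autosomes plus X and Y. Hardcoded so the pipeline needs no reference
#' download; only realistic proportions matter for binned low-pass analysis.
#'
#' @return Named integer-valued numeric vector of chromosome lengths,
#'   names `"chr1"`..`"chr22"`, `"chrX"`, `"chrY"`.
#' @export
hg19_chrom_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

#' Names of the autosomes
#' @return Character vector `"chr1"`..`"chr22"`.
#' @keywords internal
autosome_names <- function() paste0("chr", 1:22)

#' Build a genome bin table
#'
#' Partitions an hg19-like genome into `n_bins` bins, allocated to
#' chromosomes proportionally to their length (largest-remainder rounding,
#' at least one bin each) and equal-width within a chromosome up to integer
#' rounding. A GC fraction is drawn per bin from a seeded AR(1) latent chain
#' so that GC content is autocorrelated along the genome, mapped into
#' (0.2, 0.8).
#'
#' @param n_bins Total number of bins; must be at least 24 (one per
#'   chromosome).
#' @param seed Integer seed for the GC draw.
#' @return A `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open), and `gc`. Bins partition each chromosome exactly.
#' @examples
#' bins <- make_bin_table(500, seed = 1)
#' tapply(bins$end - bins$start, bins$chrom, sum)[1] # chr1 length
#' @export
make_bin_table <- function(n_bins, seed = 1L) {
  min_bins <- length(hg19_chrom_lengths())
  if (n_bins < min_bins) {
    stop("n_bins must be at least ", min_bins,
         " (one bin per chromosome)", call. = FALSE)
  }
  lens <- hg19_chrom_lengths()
  # largest-remainder allocation, each chromosome >= 1 bin
  raw <- n_bins * lens / sum(lens)
  k <- stats::setNames(pmax(1L, floor(raw)), names(lens))
  rem <- n_bins - sum(k)
  if (rem > 0) {
    ord <- order(raw - floor(raw), decreasing = TRUE)
    k[ord[seq_len(rem)]] <- k[ord[seq_len(rem)]] + 1L
  } else if (rem < 0) {
    # over-allocated by the 1-bin floor; trim from chromosomes with most bins
    for (i in seq_len(-rem)) {
      j <- which.max(k)
      k[j] <- k[j] - 1L
    }
  }
  chrom <- rep(names(lens), k)
  start <- end <- numeric(sum(k))
  pos <- 1L
  for (cn in names(lens)) {
    b <- round(seq(0, lens[[cn]], length.out = k[[cn]] + 1L))
    idx <- pos:(pos + k[[cn]] - 1L)
    start[idx] <- b[-length(b)]
    end[idx] <- b[-1L]
    pos <- pos + k[[cn]]
  }
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(restore_seed(old))
  set.seed(seed)
  # AR(1) latent chain -> logistic map into (0.2, 0.8)
  n <- length(chrom)
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  rho <- 0.9
  innov <- stats::rnorm(n, sd = sqrt(1 - rho^2))
  for (i in seq_len(n)[-1]) z[i] <- rho * z[i - 1] + innov[i]
  gc <- 0.2 + 0.6 * stats::plogis(z)
  data.frame(chrom = chrom, start = start, end = end, gc = gc,
             stringsAsFactors = FALSE)
}

# Restore (or remove) the global RNG state after a seeded generator call.
restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
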