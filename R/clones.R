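#' Group altered cells into clones by copy-number similarity
#'
#' Similarity between two cells is the fraction of genome bins at identical
#' integer copy number. Altered cells are clustered by average-linkage
#' hierarchical clustering on `1 - similarity`, cut so cells within
#' `1 - similarity_threshold` of each other (on the linkage scale) share a
#' clone. Normal cells are assigned the reserved label `"normal"`. The clone
#' consensus profile is the per-bin modal copy number; per-clone cell counts
#' are reported by compartment when metadata is supplied, so clones shared
#' between blood and bone marrow are visible.
#'
#' @param fit A `cnv_fit` from [fit_cnv()], or a list of `cn_profile`s.
#' @param similarity_threshold Fraction in (0, 1]; default 0.95.
#' @param meta Optional `data.frame` with `cell_id` and `compartment`
#'   columns.
#' @return An object of class `"clone_assignment"`: list with `assignment`
#'   (`data.frame` of `cell_id`, `clone`), `consensus` (integer matrix,
#'   clones x bins), and `counts` (`data.frame` of clone cell counts, by
#'   compartment when available). With no altered cells the assignment is
#'   empty (not an error).
#' @export
group_clones <- function(fit, similarity_threshold = 0.95, meta = NULL) {
  if (similarity_threshold <= 0 || similarity_threshold > 1) {
    stop("similarity_threshold must be in (0, 1]")
  }
  profiles <- if (inherits(fit, "cnv_fit")) fit$profiles else fit
  altered <- vapply(profiles, function(p) isTRUE(p$altered), logical(1))
  normal_ids <- vapply(profiles[!altered], `[[`, character(1), "cell_id")
  alt <- profiles[altered]
  if (!length(alt)) {
    assignment <- data.frame(cell_id = normal_ids,
                             clone = rep("normal", length(normal_ids)),
                             stringsAsFactors = FALSE)
    return(structure(list(assignment = assignment,
                          consensus = NULL,
                          counts = data.frame()),
                     class = "clone_assignment"))
  }
  cn <- do.call(rbind, lapply(alt, `[[`, "cn"))
  ids <- vapply(alt, `[[`, character(1), "cell_id")
  n <- length(alt)
  if (n == 1) {
    grp <- 1L
  } else {
    d <- matrix(0, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        d[i, j] <- d[j, i] <- mean(cn[i, ] != cn[j, ])
      }
    }
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = 1 - similarity_threshold)
  }
  # label clones by decreasing size, ties by first occurrence
  sizes <- table(grp)
  ord <- order(-as.integer(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(seq_along(ord), names(sizes)[ord])
  clone <- sprintf("clone_%d", relabel[as.character(grp)])
  assignment <- data.frame(
    cell_id = c(ids, normal_ids),
    clone = c(clone, rep("normal", length(normal_ids))),
    stringsAsFactors = FALSE)

  clones <- sort(unique(clone))
  consensus <- t(vapply(clones, function(cl) {
    sub <- cn[clone == cl, , drop = FALSE]
    apply(sub, 2, function(col) {
      tab <- table(col)
      as.integer(names(tab)[which.max(tab)])
    })
  }, integer(ncol(cn))))
  rownames(consensus) <- clones

  counts <- as.data.frame(table(clone = assignment$clone),
                          stringsAsFactors = FALSE)
  names(counts) <- c("clone", "n_cells")
  if (!is.null(meta)) {
    m <- merge(assignment, meta[, c("cell_id", "compartment")],
               by = "cell_id", all.x = TRUE)
    byc <- as.data.frame(table(clone = m$clone, compartment = m$compartment),
                         stringsAsFactors = FALSE)
    names(byc) <- c("clone", "compartment", "n_cells")
    counts <- byc[byc$n_cells > 0 | TRUE, ]
  }
  structure(list(assignment = assignment, consensus = consensus,
                 counts = counts),
            class = "clone_assignment")
}

#' @export
print.clone_assignment <- function(x, ...) {
  k <- setdiff(unique(x$assignment$clone), "normal")
  cat("Clone assignment:", length(k), "clone(s),",
      sum(x$assignment$clone != "normal"), "altered cells,",
      sum(x$assignment$clone == "normal"), "normal\n")
  invisible(x)
}
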