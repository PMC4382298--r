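# Parametric Analysis of Gene set Enrichment (PAGE): per-term Z-scores and
# the terms x studies Z matrix with size and ontology-depth filters.

# Coerce a differential_result (or a named numeric vector) to a named
# fold-change vector.
fold_change_vector <- function(diff) {
  if (inherits(diff, "differential_result") || is.data.frame(diff)) {
    stats::setNames(diff$log2_fc, diff$gene)
  } else if (is.numeric(diff) && !is.null(names(diff))) {
    diff
  } else {
    stop("expected a differential_result or a named numeric vector of fold changes")
  }
}

#' PAGE Z-score of one gene set
#'
#' The parametric gene-set statistic: with mu and delta the mean and sample
#' standard deviation (n - 1 denominator) of the log2 fold changes over all
#' measured genes, and Sm the mean fold change over the m member genes,
#' `Z = (Sm - mu) * sqrt(m) / delta`. Under a null of exchangeable genes, Z
#' is approximately standard normal for moderate m, so it measures the
#' treatment-induced modulation of the whole set without requiring any
#' individual gene to be significant.
#'
#' @param diff a `differential_result` (see [differential_stats()]) or a
#'   named numeric vector of log2 fold changes over all measured genes.
#' @param members character vector of member gene IDs; all must be measured.
#' @return the Z-score, a single number.
#' @export
page_zscore <- function(diff, members) {
  fc <- fold_change_vector(diff)
  if (length(fc) < 2L) stop("need at least two measured genes")
  members <- unique(as.character(members))
  if (length(members) < 1L) stop("empty member set")
  idx <- match(members, names(fc))
  if (anyNA(idx)) {
    stop("member genes not measured in this study: ",
         paste(utils::head(members[is.na(idx)], 5L), collapse = ", "))
  }
  mu <- mean(fc)
  delta <- stats::sd(fc)
  if (delta == 0) {
    stop("degenerate input: all genes have identical fold change (delta = 0)")
  }
  (mean(fc[idx]) - mu) * sqrt(length(idx)) / delta
}

#' PAGE Z-score matrix across studies
#'
#' Applies the collection-level filters and computes the full terms x
#' studies Z matrix. Terms whose ontology depth lies outside `depth_range`
#' are dropped entirely. Within each study a term's cell is computed only if
#' its effective size — the number of member genes actually measured on that
#' study's platform — lies in `[min_size, max_size]`; otherwise the cell is
#' missing (`NA`, never 0: 0 is a valid Z). Rows missing in every study are
#' dropped.
#'
#' @param diffs named list of `differential_result` objects (or named
#'   fold-change vectors), one per study; names become column names.
#' @param collection a [gene_set_collection()] with non-missing depths.
#' @param min_size,max_size effective-set-size filter bounds.
#' @param depth_range inclusive `(low, high)` ontology-depth filter.
#' @return a matrix of class `z_score_matrix` with attributes
#'   `effective_size` (same shape, integer) and `universe_size` (named,
#'   measured genes per study).
#' @export
page_matrix <- function(diffs, collection, min_size = 10, max_size = 1000,
                        depth_range = c(3, 5)) {
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!is.list(diffs) || length(diffs) < 1L) stop("need at least one study")
  if (is.null(names(diffs))) {
    names(diffs) <- vapply(diffs, function(d) {
      attr(d, "study_id") %||% ""
    }, "")
    if (any(names(diffs) == "")) {
      names(diffs) <- paste0("study_", seq_along(diffs))
    }
  }
  min_size <- assert_count(min_size, "min_size")
  max_size <- assert_count(max_size, "max_size")
  depth <- collection$info$depth
  if (anyNA(depth)) {
    stop("collection has terms with missing ontology depth; supply term metadata")
  }
  keep <- depth >= depth_range[1] & depth <= depth_range[2]
  if (!any(keep)) stop("all terms filtered out: no term within depth range")
  sets <- collection$sets[keep]
  term_ids <- collection$info$term_id[keep]

  n_terms <- length(sets)
  n_studies <- length(diffs)
  z <- matrix(NA_real_, n_terms, n_studies,
              dimnames = list(term_ids, names(diffs)))
  eff <- matrix(0L, n_terms, n_studies,
                dimnames = list(term_ids, names(diffs)))
  universe <- stats::setNames(integer(n_studies), names(diffs))

  prev_genes <- NULL
  idx_list <- NULL
  for (s in seq_len(n_studies)) {
    fc <- fold_change_vector(diffs[[s]])
    genes <- names(fc)
    universe[s] <- length(fc)
    if (length(fc) < 2L) stop("study ", names(diffs)[s], ": fewer than two measured genes")
    # membership indices are reused when studies share one platform
    if (is.null(prev_genes) || !identical(genes, prev_genes)) {
      idx_list <- lapply(sets, function(m) {
        i <- match(m, genes)
        i[!is.na(i)]
      })
      prev_genes <- genes
    }
    mu <- mean(fc)
    delta <- stats::sd(fc)
    if (delta == 0) {
      stop("study ", names(diffs)[s],
           ": degenerate input (all fold changes identical)")
    }
    m_eff <- lengths(idx_list)
    eff[, s] <- as.integer(m_eff)
    compute <- which(m_eff >= min_size & m_eff <= max_size)
    if (length(compute)) {
      sm <- vapply(idx_list[compute], function(i) mean(fc[i]), 0)
      z[compute, s] <- (sm - mu) * sqrt(m_eff[compute]) / delta
    }
  }
  present <- rowSums(!is.na(z)) > 0L
  if (!any(present)) {
    stop("all terms filtered out: no term passes the effective-size filter in any study")
  }
  z <- z[present, , drop = FALSE]
  eff <- eff[present, , drop = FALSE]
  structure(z, effective_size = eff, universe_size = universe,
            class = c("z_score_matrix", "matrix", "array"))
}

#' @export
print.z_score_matrix <- function(x, ...) {
  cat("z_score_matrix:", nrow(x), "terms x", ncol(x), "studies;",
      sum(is.na(x)), "missing cells\n")
  invisible(x)
}
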