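# Cross-study consensus signature: term-wise one-sample t-tests on PAGE
# Z-scores, Benjamini-Hochberg correction, and the dual median-Z /
# adjusted-p filters.

#' Benjamini-Hochberg step-up adjustment
#'
#' Standard step-up FDR adjustment: with p-values sorted ascending,
#' `adjusted_(i) = min over j >= i of p_(j) * m / j`, capped at 1, original
#' order restored. Thin validated wrapper around [stats::p.adjust()].
#'
#' @param pvals numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the original order.
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || length(pvals) == 0L) {
    stop("'pvals' must be a non-empty numeric vector")
  }
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Median Z-score per term over a study subset
#'
#' @param zmat a [page_matrix()] result (or any terms x studies matrix with
#'   `NA` missingness).
#' @param study_subset column names or indices; defaults to all studies.
#' @return named numeric vector of per-term medians over non-missing cells
#'   (even counts use the mean-of-middle-two convention); `NA` for terms
#'   missing everywhere in the subset.
#' @export
median_z <- function(zmat, study_subset = NULL) {
  zmat <- as.matrix(zmat)
  if (!is.null(study_subset)) {
    zmat <- zmat[, study_subset, drop = FALSE]
  }
  if (ncol(zmat) == 0L) stop("study subset is empty")
  apply(zmat, 1L, function(r) {
    r <- r[!is.na(r)]
    if (length(r) == 0L) NA_real_ else stats::median(r)
  })
}

#' Consensus signature across studies
#'
#' Identifies terms coherently modulated across studies. Terms with Z-scores
#' in fewer than `min_studies` studies are excluded before testing. Each
#' remaining term's non-missing Z values are submitted to a two-sided
#' one-sample t-test against mean 0; BH correction is applied across exactly
#' the tested terms. A term passes when its adjusted p-value is below
#' `p_adj_max` AND its median Z across studies is at least `z_median_min` in
#' absolute value — the second filter guarantees that at least half of the
#' studies individually show a strong set-level effect.
#'
#' Zero-variance rows are degenerate for the t-test: a constant non-zero Z
#' row is maximal evidence of a consistent effect and gets `p = 0` (flagged
#' in column `degenerate`); a constant zero row carries no evidence and is
#' excluded.
#'
#' @param zmat a [page_matrix()] result.
#' @param p_adj_max BH-adjusted p threshold (default 0.00285).
#' @param z_median_min median-Z magnitude threshold (default 2.58).
#' @param min_studies minimum number of studies with a Z-score (default 2).
#' @return a data.frame of class `signature_table`, one row per tested term:
#'   `term_id`, `median_z`, `n_studies`, `t`, `p`, `p_adj`, `pass`,
#'   `direction` (`"up"`/`"down"`), `degenerate`; sorted by direction (up
#'   first) then decreasing median Z. Thresholds are carried as attributes.
#' @export
consensus_signature <- function(zmat, p_adj_max = 0.00285,
                                z_median_min = 2.58, min_studies = 2) {
  zmat <- as.matrix(zmat)
  if (ncol(zmat) < 2L) stop("need a Z matrix with at least two studies")
  assert_number(p_adj_max, "p_adj_max", 0, 1)
  assert_number(z_median_min, "z_median_min", min = 0)
  min_studies <- assert_count(min_studies, "min_studies", min = 2L)
  if (min_studies > ncol(zmat)) {
    stop("min_studies (", min_studies,
         ") exceeds the number of studies (", ncol(zmat), ")")
  }
  n <- rowSums(!is.na(zmat))
  tested <- n >= min_studies
  zt <- zmat[tested, , drop = FALSE]
  n <- n[tested]
  if (nrow(zt) == 0L) stop("no term has Z-scores in at least min_studies studies")
  mean_z <- rowMeans(zt, na.rm = TRUE)
  ss <- rowSums((zt - mean_z)^2, na.rm = TRUE)
  sd_z <- sqrt(ss / (n - 1))
  med <- median_z(zt)
  degenerate <- sd_z == 0
  # constant-zero rows: no evidence, excluded from testing
  keep <- !(degenerate & mean_z == 0)
  zt <- zt[keep, , drop = FALSE]
  n <- n[keep]; mean_z <- mean_z[keep]; sd_z <- sd_z[keep]
  med <- med[keep]; degenerate <- degenerate[keep]
  if (nrow(zt) == 0L) stop("no testable term remains")
  t_stat <- mean_z / (sd_z / sqrt(n))
  p <- 2 * stats::pt(-abs(t_stat), n - 1)
  t_stat[degenerate] <- sign(mean_z[degenerate]) * Inf
  p[degenerate] <- 0
  p_adj <- bh_adjust(p)
  pass <- p_adj < p_adj_max & abs(med) >= z_median_min & n >= min_studies
  direction <- ifelse(med > 0, "up", ifelse(med < 0, "down", NA_character_))
  out <- data.frame(term_id = rownames(zt), median_z = med,
                    n_studies = as.integer(n), t = t_stat, p = p,
                    p_adj = p_adj, pass = pass, direction = direction,
                    degenerate = degenerate,
                    stringsAsFactors = FALSE, row.names = NULL)
  ord <- order(factor(out$direction, levels = c("up", "down")), -out$median_z)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "thresholds") <- list(p_adj_max = p_adj_max,
                                  z_median_min = z_median_min,
                                  min_studies = min_studies)
  class(out) <- c("signature_table", "data.frame")
  out
}

#' @export
print.signature_table <- function(x, ...) {
  th <- attr(x, "thresholds")
  cat("signature_table:", nrow(x), "tested terms,", sum(x$pass),
      "passing (p_adj <", th$p_adj_max, ", |median Z| >=",
      th$z_median_min, ")\n")
  print.data.frame(utils::head(as.data.frame(x), 10L), digits = 4)
  if (nrow(x) > 10L) cat("  ...", nrow(x) - 10L, "more rows\n")
  invisible(x)
}
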