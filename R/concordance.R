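# Concordance between two median-Z signature vectors: Spearman correlation
# with four significance/confidence schemes, including Gaussian null models
# that carry the correlation induced by overlapping gene sets.

# Align two vectors by names when both are named, then drop pairs missing in
# either vector. All four schemes funnel through this helper so missingness
# is handled identically everywhere.
pair_complete <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) {
    common <- intersect(names(a), names(b))
    a <- a[common]; b <- b[common]
  } else if (length(a) != length(b)) {
    stop("vectors must have equal length (or shared names)")
  }
  keep <- !is.na(a) & !is.na(b)
  list(a = as.numeric(a[keep]), b = as.numeric(b[keep]),
       names = if (!is.null(names(a))) names(a)[keep] else NULL,
       n_dropped = sum(!keep))
}

check_rankable <- function(x, what) {
  if (length(unique(x)) < 2L) {
    stop("undefined correlation: ", what, " is constant after rank transform")
  }
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks (midranks for ties), after aligning
#' the two vectors by names (when both are named) and dropping pairs with a
#' missing entry in either vector.
#'
#' @param a,b numeric vectors; at least 3 complete pairs must remain.
#' @return the correlation, a single number in `[-1, 1]`.
#' @export
spearman_cor <- function(a, b) {
  pc <- pair_complete(a, b)
  if (length(pc$a) < 3L) stop("need at least 3 complete pairs")
  check_rankable(pc$a, "first vector")
  check_rankable(pc$b, "second vector")
  stats::cor(pc$a, pc$b, method = "spearman")
}

#' Permutation test for Spearman concordance
#'
#' Scheme 1: shuffle the association between the components of the two
#' vectors, recomputing the correlation on each permuted set. The Monte
#' Carlo p-value uses the add-one estimator
#' `p = (1 + #{r* >= r_obs}) / (n_perm + 1)`, whose smallest attainable
#' value at 999 permutations is 0.001.
#'
#' @param a,b numeric vectors (aligned as in [spearman_cor()]).
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed.
#' @param alternative `"greater"` (default; positive concordance) or
#'   `"two.sided"`.
#' @return a `concordance_result` with the observed r and Monte Carlo p.
#' @export
permutation_test <- function(a, b, n_perm = 999, seed = NULL,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n_perm <- assert_count(n_perm, "n_perm")
  pc <- pair_complete(a, b)
  if (length(pc$a) < 3L) stop("need at least 3 complete pairs")
  check_rankable(pc$a, "first vector")
  check_rankable(pc$b, "second vector")
  r_obs <- stats::cor(pc$a, pc$b, method = "spearman")
  ra <- rank(pc$a); rb <- rank(pc$b)
  n <- length(ra)
  r_star <- with_seed_(seed, {
    vapply(seq_len(n_perm),
           function(k) stats::cor(ra, rb[sample.int(n)]), 0)
  })
  exceed <- if (alternative == "greater") sum(r_star >= r_obs) else
    sum(abs(r_star) >= abs(r_obs))
  new_concordance_result(r = r_obs, scheme = "permutation",
                         n_terms = n, n_resamples = n_perm, seed = seed,
                         p = (1 + exceed) / (n_perm + 1),
                         alternative = alternative,
                         n_dropped = pc$n_dropped)
}

#' Pair bootstrap confidence interval for Spearman concordance
#'
#' Scheme 2: sample terms with replacement; each sampled term contributes
#' its pair of Z-scores; the percentile interval of the resampled Spearman r
#' is returned. Resamples whose rank vectors are degenerate (constant) are
#' redrawn and counted.
#'
#' @param a,b numeric vectors (aligned as in [spearman_cor()]).
#' @param n_boot number of bootstrap resamples (default 1000).
#' @param seed optional integer seed.
#' @param level confidence level (default 0.95).
#' @return a `concordance_result` with the observed r, percentile CI and the
#'   number of redrawn degenerate resamples (`n_redrawn`).
#' @export
pair_bootstrap <- function(a, b, n_boot = 1000, seed = NULL, level = 0.95) {
  n_boot <- assert_count(n_boot, "n_boot")
  assert_number(level, "level", 0, 1, open_min = TRUE, open_max = TRUE)
  pc <- pair_complete(a, b)
  if (length(pc$a) < 3L) stop("need at least 3 complete pairs")
  check_rankable(pc$a, "first vector")
  check_rankable(pc$b, "second vector")
  r_obs <- stats::cor(pc$a, pc$b, method = "spearman")
  n <- length(pc$a)
  n_redrawn <- 0L
  r_star <- with_seed_(seed, {
    vapply(seq_len(n_boot), function(k) {
      repeat {
        idx <- sample.int(n, n, replace = TRUE)
        xa <- pc$a[idx]; xb <- pc$b[idx]
        if (length(unique(xa)) > 1L && length(unique(xb)) > 1L) {
          return(stats::cor(xa, xb, method = "spearman"))
        }
        n_redrawn <<- n_redrawn + 1L
        if (n_redrawn > 100L * n_boot) {
          stop("too many degenerate bootstrap resamples")
        }
      }
    }, 0)
  })
  ci <- unname(stats::quantile(r_star, c((1 - level) / 2, 1 - (1 - level) / 2)))
  new_concordance_result(r = r_obs, scheme = "pair_bootstrap",
                         n_terms = n, n_resamples = n_boot, seed = seed,
                         ci = ci, level = level, n_dropped = pc$n_dropped,
                         extra = list(n_redrawn = n_redrawn))
}

#' Overlap-induced correlation matrix of gene-set Z-scores
#'
#' Two gene sets that share member genes have correlated PAGE Z-scores even
#' under the null; the predicted null correlation is
#' `overlap(i, j) / sqrt(size_i * size_j)` with nominal set sizes. The raw
#' matrix is not guaranteed positive semidefinite for arbitrary overlap
#' patterns, so eigenvalues below `1e-8` are clipped and the matrix rescaled
#' back to unit diagonal; whether repair was applied and the smallest
#' original eigenvalue are recorded.
#'
#' @param collection a [gene_set_collection()].
#' @param term_list character vector of term IDs (default: all terms).
#' @return a symmetric matrix of class `overlap_correlation_matrix` with
#'   unit diagonal, dimnames = term IDs, and attributes `repaired` (logical)
#'   and `min_eigenvalue` (smallest eigenvalue before repair).
#' @export
overlap_correlation <- function(collection, term_list = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  term_list <- term_list %||% collection$info$term_id
  sets <- subset_terms(collection, term_list)$sets
  genes <- unique(unlist(sets, use.names = FALSE))
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(sets), lengths(sets)),
    j = match(unlist(sets, use.names = FALSE), genes),
    x = 1, dims = c(length(sets), length(genes)))
  O <- as.matrix(Matrix::tcrossprod(M))
  sizes <- lengths(sets)
  R <- O / sqrt(outer(sizes, sizes))
  diag(R) <- 1
  dimnames(R) <- list(names(sets), names(sets))
  eg <- eigen(R, symmetric = TRUE)
  min_ev <- min(eg$values)
  repaired <- min_ev < 1e-8
  if (repaired) {
    lam <- pmax(eg$values, 1e-8)
    R <- eg$vectors %*% (lam * t(eg$vectors))
    R <- stats::cov2cor(R)
    R <- (R + t(R)) / 2
    dimnames(R) <- list(names(sets), names(sets))
  }
  structure(R, repaired = repaired, min_eigenvalue = min_ev,
            class = c("overlap_correlation_matrix", "matrix", "array"))
}

# Cholesky factor (upper) of a correlation matrix, with one eigenvalue-clip
# repair attempt before giving up.
chol_with_repair <- function(corr) {
  U <- tryCatch(chol(corr), error = function(e) NULL)
  if (!is.null(U)) return(U)
  eg <- eigen(corr, symmetric = TRUE)
  lam <- pmax(eg$values, 1e-8)
  R <- stats::cov2cor(eg$vectors %*% (lam * t(eg$vectors)))
  R <- (R + t(R)) / 2
  tryCatch(chol(R), error = function(e) {
    stop("Cholesky decomposition failed even after eigenvalue repair ",
         "(dim = ", nrow(corr), ", min eigenvalue = ",
         format(min(eg$values), digits = 3), "): ", conditionMessage(e))
  })
}

# Subset an overlap-correlation matrix to the kept, aligned terms.
align_corr <- function(corr, pc) {
  corr <- as.matrix(corr)
  if (!is.null(pc$names) && !is.null(dimnames(corr))) {
    missing <- setdiff(pc$names, rownames(corr))
    if (length(missing)) {
      stop("correlation matrix lacks terms: ",
           paste(utils::head(missing, 5L), collapse = ", "))
    }
    corr <- corr[pc$names, pc$names, drop = FALSE]
  } else if (nrow(corr) != length(pc$a)) {
    stop("correlation matrix dimension (", nrow(corr),
         ") does not match the number of complete term pairs (",
         length(pc$a), ")")
  }
  corr
}

#' Model-based permutation test under overlap-induced correlation
#'
#' Scheme 3: each iteration draws two independent zero-mean Gaussian vectors
#' whose common covariance is the overlap-induced correlation matrix
#' (via its Cholesky factor), and records their Spearman correlation. The
#' observed r is referred to this null sample with the add-one estimator.
#' With an identity matrix this reduces to the ordinary independence null.
#'
#' @param a,b numeric vectors (aligned as in [spearman_cor()]).
#' @param corr an [overlap_correlation()] matrix covering the common terms.
#' @param n_sim number of simulated null datasets (default 999).
#' @param seed optional integer seed.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return a `concordance_result` with the observed r and model-based p.
#' @export
model_permutation <- function(a, b, corr, n_sim = 999, seed = NULL,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  n_sim <- assert_count(n_sim, "n_sim")
  pc <- pair_complete(a, b)
  if (length(pc$a) < 3L) stop("need at least 3 complete pairs")
  check_rankable(pc$a, "first vector")
  check_rankable(pc$b, "second vector")
  corr <- align_corr(corr, pc)
  r_obs <- stats::cor(pc$a, pc$b, method = "spearman")
  U <- chol_with_repair(corr)
  n <- length(pc$a)
  r_star <- with_seed_(seed, {
    za <- crossprod(U, matrix(stats::rnorm(n * n_sim), n, n_sim))
    zb <- crossprod(U, matrix(stats::rnorm(n * n_sim), n, n_sim))
    vapply(seq_len(n_sim),
           function(k) stats::cor(za[, k], zb[, k], method = "spearman"), 0)
  })
  exceed <- if (alternative == "greater") sum(r_star >= r_obs) else
    sum(abs(r_star) >= abs(r_obs))
  new_concordance_result(r = r_obs, scheme = "model_permutation",
                         n_terms = n, n_resamples = n_sim, seed = seed,
                         p = (1 + exceed) / (n_sim + 1),
                         alternative = alternative, n_dropped = pc$n_dropped,
                         extra = list(psd_repaired = isTRUE(attr(corr, "repaired"))))
}

#' Model-based bootstrap under overlap-induced correlation
#'
#' Scheme 4: like the model-based permutation, but both Gaussian vectors are
#' drawn around the componentwise average `(a + b) / 2` of the two observed
#' vectors, giving a sampling distribution for the observed correlation; the
#' percentile interval is returned. With zero mean vectors it reduces to the
#' scheme-3 null.
#'
#' @inheritParams model_permutation
#' @param n_sim number of simulated datasets (default 1000).
#' @param level confidence level (default 0.95).
#' @return a `concordance_result` with the observed r and percentile CI.
#' @export
model_bootstrap <- function(a, b, corr, n_sim = 1000, seed = NULL,
                            level = 0.95) {
  n_sim <- assert_count(n_sim, "n_sim")
  assert_number(level, "level", 0, 1, open_min = TRUE, open_max = TRUE)
  pc <- pair_complete(a, b)
  if (length(pc$a) < 3L) stop("need at least 3 complete pairs")
  check_rankable(pc$a, "first vector")
  check_rankable(pc$b, "second vector")
  corr <- align_corr(corr, pc)
  r_obs <- stats::cor(pc$a, pc$b, method = "spearman")
  U <- chol_with_repair(corr)
  n <- length(pc$a)
  mu <- (pc$a + pc$b) / 2
  r_star <- with_seed_(seed, {
    za <- mu + crossprod(U, matrix(stats::rnorm(n * n_sim), n, n_sim))
    zb <- mu + crossprod(U, matrix(stats::rnorm(n * n_sim), n, n_sim))
    vapply(seq_len(n_sim),
           function(k) stats::cor(za[, k], zb[, k], method = "spearman"), 0)
  })
  ci <- unname(stats::quantile(r_star, c((1 - level) / 2, 1 - (1 - level) / 2)))
  new_concordance_result(r = r_obs, scheme = "model_bootstrap",
                         n_terms = n, n_resamples = n_sim, seed = seed,
                         ci = ci, level = level, n_dropped = pc$n_dropped,
                         extra = list(psd_repaired = isTRUE(attr(corr, "repaired"))))
}
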