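# S3 containers for the pipeline's domain objects.

#' Gene-set collection
#'
#' A named collection of gene sets (GO-term style) together with term
#' metadata. Ontology depth is carried as supplied metadata; no DAG traversal
#' is performed anywhere in the package.
#'
#' @param sets named list of character vectors of member gene IDs. Duplicate
#'   members within a set are dropped.
#' @param depth integer vector of ontology depths (recycled), or `NA` when
#'   unknown (e.g. a bare GMT file without a metadata table).
#' @param term_names optional character vector of human-readable term names;
#'   defaults to the term IDs.
#' @param seed optional integer recording the generating seed for synthetic
#'   collections.
#' @return an object of class `gene_set_collection` with components `sets`
#'   (named list), `info` (data.frame: `term_id`, `name`, `depth`) and `seed`.
#' @export
gene_set_collection <- function(sets, depth = NA_integer_,
                                term_names = NULL, seed = NULL) {
  if (!is.list(sets) || length(sets) == 0L || is.null(names(sets)) ||
      anyDuplicated(names(sets))) {
    stop("'sets' must be a non-empty list with unique names")
  }
  sets <- lapply(sets, function(m) unique(as.character(m)))
  if (any(lengths(sets) == 0L)) stop("every gene set must be non-empty")
  depth <- suppressWarnings(as.integer(depth))
  depth <- rep_len(depth, length(sets))
  if (any(!is.na(depth) & depth < 1L)) stop("ontology depth must be >= 1")
  term_names <- as.character(term_names %||% names(sets))
  info <- data.frame(term_id = names(sets), name = rep_len(term_names, length(sets)),
                     depth = depth, stringsAsFactors = FALSE)
  structure(list(sets = sets, info = info, seed = seed),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("gene_set_collection:", length(x$sets), "terms,",
      length(unique(unlist(x$sets, use.names = FALSE))), "distinct genes\n")
  cat("  set sizes:", min(sz), "-", max(sz),
      " depth:", paste(sort(unique(x$info$depth)), collapse = ","), "\n")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Sizes of the sets in a collection
#' @param collection a [gene_set_collection()].
#' @return named integer vector of member counts.
#' @export
term_sizes <- function(collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lengths(collection$sets)
}

#' Restrict a collection to a subset of terms
#' @param collection a [gene_set_collection()].
#' @param term_ids character vector of term IDs to keep (order preserved).
#' @return a [gene_set_collection()].
#' @export
subset_terms <- function(collection, term_ids) {
  stopifnot(inherits(collection, "gene_set_collection"))
  missing <- setdiff(term_ids, collection$info$term_id)
  if (length(missing)) {
    stop("terms not in collection: ", paste(missing, collapse = ", "))
  }
  idx <- match(term_ids, collection$info$term_id)
  gene_set_collection(collection$sets[idx],
                      depth = collection$info$depth[idx],
                      term_names = collection$info$name[idx],
                      seed = collection$seed)
}

#' One study's expression matrix with group labels
#'
#' The unit the source studies call a "tissue"/"dataset": a genes x samples
#' matrix of linear-scale signal intensities with control/treated labels.
#'
#' @param signal numeric matrix, rows = genes (unique rownames), columns =
#'   samples; strictly positive linear intensities.
#' @param groups character vector of length `ncol(signal)` with values
#'   `"control"` / `"treated"`; both groups must be present.
#' @param study_id single string identifying the study.
#' @param tissue optional species/tissue label.
#' @return an object of class `expression_study`.
#' @export
expression_study <- function(signal, groups, study_id, tissue = NA_character_) {
  if (!is.matrix(signal) || !is.numeric(signal)) {
    stop("'signal' must be a numeric matrix")
  }
  if (is.null(rownames(signal)) || anyDuplicated(rownames(signal))) {
    stop("'signal' needs unique gene rownames")
  }
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    stop("intensities must be finite and > 0 (linear scale)")
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(signal) ||
      !all(groups %in% c("control", "treated"))) {
    stop("'groups' must label every column as control or treated")
  }
  if (!all(c("control", "treated") %in% groups)) {
    stop("both control and treated samples are required")
  }
  if (is.null(colnames(signal))) colnames(signal) <- paste0("S", seq_len(ncol(signal)))
  structure(list(study_id = as.character(study_id)[1L],
                 tissue = as.character(tissue)[1L],
                 signal = signal, groups = groups),
            class = "expression_study")
}

#' @export
print.expression_study <- function(x, ...) {
  cat("expression_study '", x$study_id, "': ", nrow(x$signal), " genes, ",
      sum(x$groups == "control"), " control vs ",
      sum(x$groups == "treated"), " treated\n", sep = "")
  invisible(x)
}

#' Probe-level signal table with gene annotation
#'
#' @param signal numeric matrix, rows = probes (unique rownames = probe IDs),
#'   columns = samples; positive linear intensities.
#' @param annotation data.frame with columns `probe_id`, `gene_id`; a probe
#'   annotated to several genes appears on several rows, a probe absent from
#'   the table has no annotation.
#' @param groups control/treated label per column; at least two samples per
#'   group.
#' @param study_id single string.
#' @param tissue optional label.
#' @return an object of class `probe_table`.
#' @export
probe_table <- function(signal, annotation, groups, study_id = "study",
                        tissue = NA_character_) {
  if (!is.matrix(signal) || !is.numeric(signal) ||
      is.null(rownames(signal)) || anyDuplicated(rownames(signal))) {
    stop("'signal' must be a numeric matrix with unique probe rownames")
  }
  if (any(!is.finite(signal)) || any(signal <= 0)) {
    stop("intensities must be finite and > 0")
  }
  if (!is.data.frame(annotation) ||
      !all(c("probe_id", "gene_id") %in% names(annotation))) {
    stop("'annotation' needs columns probe_id, gene_id")
  }
  groups <- as.character(groups)
  if (length(groups) != ncol(signal) ||
      !all(groups %in% c("control", "treated"))) {
    stop("'groups' must label every column as control or treated")
  }
  if (sum(groups == "control") < 2L || sum(groups == "treated") < 2L) {
    stop("at least two samples per group are required")
  }
  annotation <- unique(data.frame(probe_id = as.character(annotation$probe_id),
                                  gene_id = as.character(annotation$gene_id),
                                  stringsAsFactors = FALSE))
  structure(list(signal = signal, annotation = annotation, groups = groups,
                 study_id = as.character(study_id)[1L],
                 tissue = as.character(tissue)[1L]),
            class = "probe_table")
}

# internal: classed concordance result record
new_concordance_result <- function(r, scheme, n_terms, n_resamples, seed,
                                   p = NULL, ci = NULL, level = NULL,
                                   alternative = NULL, n_dropped = 0L,
                                   extra = list()) {
  structure(c(list(r = r, scheme = scheme, n_terms = n_terms,
                   n_resamples = n_resamples, seed = seed, p = p,
                   ci = ci, level = level, alternative = alternative,
                   n_dropped = n_dropped), extra),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("concordance_result [", x$scheme, "]\n", sep = "")
  cat("  Spearman r =", format(x$r, digits = 4),
      "on", x$n_terms, "terms (", x$n_dropped, "dropped as missing )\n")
  if (!is.null(x$p)) {
    cat("  Monte Carlo p =", format(x$p, digits = 4),
        "(", x$alternative, ",", x$n_resamples, "resamples )\n")
  }
  if (!is.null(x$ci)) {
    cat("  ", format(100 * x$level), "% CI [",
        format(x$ci[1], digits = 4), ", ", format(x$ci[2], digits = 4),
        "] (", x$n_resamples, " resamples)\n", sep = "")
  }
  invisible(x)
}
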