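# File formats: GMT gene-set files, TSV signal/result matrices, JSON
# records. All writes are atomic (write-temp-then-rename).

#' Read a GMT gene-set file
#'
#' One term per tab-separated line: `term_id`, description, then one or more
#' member gene IDs. Duplicate members within a line are deduplicated with a
#' warning; duplicate term IDs are an error.
#'
#' @param path GMT file path.
#' @param meta_path optional term-metadata TSV (columns `term_id`, `name`,
#'   `depth`) supplying ontology depth.
#' @return a [gene_set_collection()]; depth is `NA` unless metadata is given.
#' @export
read_gmt <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1L], " in ", path,
         ": need term_id, description and at least one member")
  }
  ids <- vapply(fields, `[[`, "", 1L)
  if (anyDuplicated(ids)) {
    stop("duplicate term_id in ", path, ": ",
         ids[duplicated(ids)][1L])
  }
  descs <- vapply(fields, `[[`, "", 2L)
  members <- lapply(fields, function(f) f[-(1:2)])
  n_dup <- sum(vapply(members, function(m) length(m) - length(unique(m)), 0L))
  if (n_dup > 0L) {
    warning("deduplicated ", n_dup, " repeated member(s) within GMT lines")
    members <- lapply(members, unique)
  }
  names(members) <- ids
  depth <- NA_integer_
  nm <- descs
  if (!is.null(meta_path)) {
    meta <- read_term_metadata(meta_path)
    idx <- match(ids, meta$term_id)
    depth <- meta$depth[idx]
    nm <- ifelse(is.na(idx), descs, meta$name[idx])
  }
  gene_set_collection(members, depth = depth, term_names = nm)
}

#' Write a collection as GMT
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(seq_along(collection$sets), function(i) {
    paste(c(collection$info$term_id[i], collection$info$name[i],
            collection$sets[[i]]), collapse = "\t")
  }, "")
  atomic_write(function(p) writeLines(lines, p), path)
}

#' Read a term-metadata table (term_id, name, depth)
#' @param path TSV path with a header row.
#' @return data.frame with columns `term_id`, `name`, `depth`.
#' @export
read_term_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  meta <- utils::read.delim(path, colClasses = "character",
                            stringsAsFactors = FALSE)
  need <- c("term_id", "name", "depth")
  if (!all(need %in% names(meta))) {
    stop("term metadata must have columns: ", paste(need, collapse = ", "))
  }
  meta$depth <- as.integer(meta$depth)
  meta
}

#' Write a term-metadata table
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_term_metadata <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  atomic_write(function(p) {
    utils::write.table(collection$info, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

#' Write an expression study as a TSV signal matrix
#'
#' Layout: header row 1 = `gene_id` + sample IDs; row 2 = `group` +
#' control/treated labels; then one row per gene with linear intensities.
#'
#' @param study an [expression_study()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_study_tsv <- function(study, path) {
  stopifnot(inherits(study, "expression_study"))
  atomic_write(function(p) {
    con <- file(p, "w")
    on.exit(close(con))
    writeLines(c(paste(c("gene_id", colnames(study$signal)), collapse = "\t"),
                 paste(c("group", study$groups), collapse = "\t")), con)
    body <- apply(study$signal, 1L, function(r) {
      paste(sprintf("%.10g", r), collapse = "\t")
    })
    writeLines(paste(rownames(study$signal), body, sep = "\t"), con)
  }, path)
}

#' Read an expression study from a TSV signal matrix
#' @param path TSV path (layout of [write_study_tsv()]).
#' @param study_id study identifier; defaults to the file name.
#' @param tissue optional label.
#' @return an [expression_study()].
#' @export
read_study_tsv <- function(path, study_id = NULL, tissue = NA_character_) {
  if (!file.exists(path)) stop("file not found: ", path)
  head2 <- readLines(path, n = 2L)
  if (length(head2) < 2L) stop("truncated study file: ", path)
  samples <- strsplit(head2[1L], "\t", fixed = TRUE)[[1L]][-1L]
  groups <- strsplit(head2[2L], "\t", fixed = TRUE)[[1L]][-1L]
  dat <- utils::read.table(path, skip = 2L, sep = "\t", header = FALSE,
                           colClasses = c("character",
                                          rep("numeric", length(samples))),
                           stringsAsFactors = FALSE)
  signal <- as.matrix(dat[, -1L, drop = FALSE])
  dimnames(signal) <- list(dat[[1L]], samples)
  expression_study(signal, groups,
                   study_id %||% sub("\\.tsv$", "", basename(path)), tissue)
}

#' Write a differential result as TSV
#' @param diff a `differential_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_differential_tsv <- function(diff, path) {
  atomic_write(function(p) {
    utils::write.table(as.data.frame(diff), p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }, path)
}

#' Read a differential result from TSV
#' @param path TSV written by [write_differential_tsv()].
#' @param study_id optional study identifier.
#' @return a `differential_result` data.frame.
#' @export
read_differential_tsv <- function(path, study_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(gene = "character"))
  attr(d, "study_id") <- study_id %||% sub("\\.tsv$", "", basename(path))
  class(d) <- c("differential_result", "data.frame")
  d
}

#' Write a Z-score matrix as TSV (NA marks missing cells)
#' @param zmat a [page_matrix()] result.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_zscore_matrix <- function(zmat, path) {
  atomic_write(function(p) {
    df <- data.frame(term_id = rownames(zmat),
                     as.data.frame(unclass(zmat)[, , drop = FALSE]),
                     check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA")
  }, path)
}

#' Read a Z-score matrix from TSV
#' @param path TSV written by [write_zscore_matrix()].
#' @return a numeric matrix of class `z_score_matrix` (terms x studies).
#' @export
read_zscore_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                         colClasses = c(term_id = "character"))
  z <- as.matrix(d[, -1L, drop = FALSE])
  rownames(z) <- d$term_id
  structure(z, class = c("z_score_matrix", "matrix", "array"))
}

#' Write a signature table as TSV
#'
#' Rows keep the table's grouped-by-direction ordering.
#' @param sig a [consensus_signature()] table.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_signature_table <- function(sig, path) {
  atomic_write(function(p) {
    utils::write.table(as.data.frame(sig), p, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }, path)
}

#' Write the synthetic-truth record as JSON
#' @param truth a `synthetic_truth` object from [simulate_studies()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_truth <- function(truth, path) {
  stopifnot(inherits(truth, "synthetic_truth"))
  atomic_write(function(p) {
    jsonlite::write_json(
      list(term_effects = truth$term_effects,
           study_penetrance = truth$study_penetrance,
           gene_effects = lapply(truth$gene_effects, as.list),
           seed = truth$seed),
      p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}

#' Write a concordance result as JSON
#' @param result a `concordance_result`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_concordance <- function(result, path) {
  stopifnot(inherits(result, "concordance_result"))
  atomic_write(function(p) {
    jsonlite::write_json(Filter(Negate(is.null), unclass(result)),
                         p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }, path)
}
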