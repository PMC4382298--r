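# End-to-end orchestration: simulate (or load) -> differential -> PAGE ->
# signature -> median Z -> concordance, with a reproducible run manifest.

#' Pipeline configuration
#'
#' Collects every stage parameter. By default the pipeline runs on synthetic
#' data generated from `simulation`; alternatively `studies` may name
#' gene-level TSV files (layout of [write_study_tsv()]) together with a
#' `gmt` / `term_metadata` pair describing the collection.
#'
#' @param outdir output directory (created if needed).
#' @param seed global integer seed, fanned out to per-stage streams by
#'   stable labels (see [stage_seed()]).
#' @param simulation a [simulation_config()]; its seed is overridden by
#'   `seed` so one pipeline seed governs everything.
#' @param studies optional named character vector of study TSV paths; when
#'   given, `gmt` (and `term_metadata`) must be given too and no data are
#'   simulated.
#' @param gmt,term_metadata optional collection file paths for `studies`
#'   mode.
#' @param min_size,max_size,depth_range PAGE filters (see [page_matrix()]).
#' @param p_adj_max,z_median_min,min_studies signature thresholds (see
#'   [consensus_signature()]).
#' @param gene_p_max,gene_min_studies gene-level consensus parameters (see
#'   [gene_consensus()]).
#' @param group_a,group_b study IDs for the two concordance groups; default
#'   first half vs second half. Concordance is skipped when either group is
#'   empty or fewer than 4 studies exist.
#' @param concordance_scheme one of `"model_permutation"`, `"permutation"`,
#'   `"pair_bootstrap"`, `"model_bootstrap"`.
#' @param n_resamples resampling count for the concordance stage.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            simulation = simulation_config(seed = seed),
                            studies = NULL, gmt = NULL, term_metadata = NULL,
                            min_size = 10, max_size = 1000,
                            depth_range = c(3, 5),
                            p_adj_max = 0.00285, z_median_min = 2.58,
                            min_studies = 2,
                            gene_p_max = 0.05, gene_min_studies = NULL,
                            group_a = NULL, group_b = NULL,
                            concordance_scheme = c("model_permutation",
                                                   "permutation",
                                                   "pair_bootstrap",
                                                   "model_bootstrap"),
                            n_resamples = 999) {
  seed <- assert_count(seed, "seed", min = 0L)
  if (!is.null(studies) && is.null(gmt)) {
    stop("'studies' mode requires a 'gmt' file")
  }
  simulation$seed <- seed
  cfg <- list(outdir = outdir, seed = seed, simulation = simulation,
              studies = studies, gmt = gmt, term_metadata = term_metadata,
              min_size = assert_count(min_size, "min_size"),
              max_size = assert_count(max_size, "max_size"),
              depth_range = depth_range,
              p_adj_max = assert_number(p_adj_max, "p_adj_max", 0, 1),
              z_median_min = assert_number(z_median_min, "z_median_min", min = 0),
              min_studies = assert_count(min_studies, "min_studies", min = 2L),
              gene_p_max = assert_number(gene_p_max, "gene_p_max", 0, 1),
              gene_min_studies = gene_min_studies,
              group_a = group_a, group_b = group_b,
              concordance_scheme = match.arg(concordance_scheme),
              n_resamples = assert_count(n_resamples, "n_resamples"))
  structure(cfg, class = "pipeline_config")
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline aborted at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes, in order: input (simulate or load) -> per-study differential
#' statistics -> PAGE Z matrix -> consensus signature -> median Z ->
#' gene-level consensus -> concordance between two study groups. Every
#' intermediate is written to `config$outdir`; a `manifest.json` records the
#' package version, seed, parameters and MD5 checksums of all outputs, so a
#' rerun with the same configuration is verifiably identical. A failing
#' stage aborts with the stage name; outputs of earlier stages are kept.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `signature`, `zmat`, `concordance` (or
#'   `NULL`), `manifest` and `files` (named vector of output paths).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  outdir <- config$outdir
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  path <- function(f) file.path(outdir, f)
  files <- character()

  # --- input stage -----------------------------------------------------
  collection <- NULL
  truth <- NULL
  if (is.null(config$studies)) {
    run_stage("simulate", {
      collection <- simulate_collection(config$simulation)
      sim <- simulate_studies(collection, config$simulation)
      studies <- sim$studies
      truth <- sim$truth
      write_gmt(collection, path("collection.gmt"))
      write_term_metadata(collection, path("term_metadata.tsv"))
      write_truth(truth, path("truth.json"))
      for (s in names(studies)) {
        write_study_tsv(studies[[s]], path(paste0(s, ".tsv")))
      }
      files <- c(files, "collection.gmt", "term_metadata.tsv", "truth.json",
                 paste0(names(studies), ".tsv"))
    })
  } else {
    run_stage("load", {
      collection <- read_gmt(config$gmt, config$term_metadata)
      studies <- lapply(seq_along(config$studies), function(i) {
        read_study_tsv(config$studies[i],
                       study_id = names(config$studies)[i])
      })
      names(studies) <- vapply(studies, `[[`, "", "study_id")
    })
  }

  # --- differential stage ----------------------------------------------
  diffs <- run_stage("differential", {
    d <- lapply(studies, differential_stats)
    for (s in names(d)) write_differential_tsv(d[[s]], path(paste0("diff_", s, ".tsv")))
    files <- c(files, paste0("diff_", names(d), ".tsv"))
    d
  })

  # --- PAGE stage -------------------------------------------------------
  zmat <- run_stage("page", {
    z <- page_matrix(diffs, collection, min_size = config$min_size,
                     max_size = config$max_size,
                     depth_range = config$depth_range)
    write_zscore_matrix(z, path("zscore_matrix.tsv"))
    files <- c(files, "zscore_matrix.tsv")
    z
  })

  # --- signature stage --------------------------------------------------
  sig <- run_stage("signature", {
    s <- consensus_signature(zmat, p_adj_max = config$p_adj_max,
                             z_median_min = config$z_median_min,
                             min_studies = config$min_studies)
    write_signature_table(s, path("signature.tsv"))
    files <- c(files, "signature.tsv")
    s
  })

  # --- median-Z stage ---------------------------------------------------
  run_stage("median_z", {
    med <- median_z(zmat)
    atomic_write(function(p) {
      utils::write.table(
        data.frame(term_id = names(med), median_z = med,
                   stringsAsFactors = FALSE),
        p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    }, path("median_z.tsv"))
    files <- c(files, "median_z.tsv")
  })

  # --- gene-consensus stage --------------------------------------------
  run_stage("gene_consensus", {
    gc <- gene_consensus(diffs, p_max = config$gene_p_max,
                         min_studies = config$gene_min_studies)
    atomic_write(function(p) {
      utils::write.table(gc, p, sep = "\t", quote = FALSE, row.names = FALSE)
    }, path("gene_consensus.tsv"))
    files <- c(files, "gene_consensus.tsv")
  })

  # --- concordance stage ------------------------------------------------
  conc <- NULL
  ids <- colnames(zmat)
  group_a <- config$group_a %||% ids[seq_len(length(ids) %/% 2)]
  group_b <- config$group_b %||% setdiff(ids, group_a)
  if (length(ids) >= 4L && length(group_a) >= 2L && length(group_b) >= 2L) {
    conc <- run_stage("concordance", {
      # compare on the signature's terms when enough pass, else on all terms
      terms <- if (sum(sig$pass) >= 10L) sig$term_id[sig$pass] else rownames(zmat)
      med_a <- median_z(zmat[terms, , drop = FALSE], group_a)
      med_b <- median_z(zmat[terms, , drop = FALSE], group_b)
      cseed <- stage_seed(config$seed, "concordance")
      res <- switch(config$concordance_scheme,
        permutation = permutation_test(med_a, med_b,
                                       n_perm = config$n_resamples,
                                       seed = cseed),
        pair_bootstrap = pair_bootstrap(med_a, med_b,
                                        n_boot = config$n_resamples,
                                        seed = cseed),
        model_permutation = model_permutation(
          med_a, med_b, overlap_correlation(collection, terms),
          n_sim = config$n_resamples, seed = cseed),
        model_bootstrap = model_bootstrap(
          med_a, med_b, overlap_correlation(collection, terms),
          n_sim = config$n_resamples, seed = cseed))
      write_concordance(res, path("concordance.json"))
      files <- c(files, "concordance.json")
      res
    })
  }

  # --- manifest ---------------------------------------------------------
  files <- sort(unique(files))
  sums <- tools::md5sum(vapply(files, path, ""))
  manifest <- list(
    package = "crsignature",
    version = as.character(utils::packageVersion("crsignature")),
    seed = config$seed,
    parameters = list(
      simulation = if (is.null(config$studies)) unclass(config$simulation),
      min_size = config$min_size, max_size = config$max_size,
      depth_range = config$depth_range,
      p_adj_max = config$p_adj_max, z_median_min = config$z_median_min,
      min_studies = config$min_studies,
      gene_p_max = config$gene_p_max,
      concordance_scheme = config$concordance_scheme,
      n_resamples = config$n_resamples,
      group_a = group_a, group_b = group_b),
    inputs = if (!is.null(config$studies)) {
      as.list(tools::md5sum(c(config$studies, config$gmt,
                              config$term_metadata)))
    },
    files = stats::setNames(as.list(unname(sums)), files))
  atomic_write(function(p) {
    jsonlite::write_json(manifest, p, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null")
  }, path("manifest.json"))

  invisible(list(signature = sig, zmat = zmat, concordance = conc,
                 manifest = manifest,
                 files = stats::setNames(vapply(c(files, "manifest.json"), path, ""),
                                         c(files, "manifest.json"))))
}
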