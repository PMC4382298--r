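# Synthetic multi-study expression data with known embedded signature truth.

#' Configuration for the synthetic-data generator
#'
#' Defaults describe the study design the pipeline is built around: eight
#' studies ("tissues") of five control vs five treated arrays, a collection
#' of 1000 gene sets of 10-30 members over 20000 genes with modest chained
#' pairwise overlap, log-normal-like intensities, and a 10% fraction of sets
#' carrying a coherent 0.5 log2-unit shift. See the methods vignette for the
#' rationale behind each value.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_terms number of gene sets.
#' @param set_size_range integer `(min, max)` member counts; min >= 2.
#' @param overlap_fraction proportion in `[0, 1)`: adjacent term pairs
#'   (1-2, 2-3, ...) share `round(overlap_fraction * min(size_i, size_j))`
#'   genes; all other pairs are disjoint.
#' @param n_studies number of studies sharing the collection.
#' @param n_control,n_treated samples per group per study.
#' @param baseline_log2_mean,baseline_log2_sd per-gene baseline intensity
#'   distribution, log2 scale.
#' @param noise_sd within-group log2 noise standard deviation (> 0).
#' @param effect_size log2 shift applied to member genes of a realized signal
#'   term in the treated group; 0 disables all signal.
#' @param signal_term_fraction proportion of terms carrying an effect.
#' @param study_penetrance probability that a signal term's effect is
#'   realized in any given study.
#' @param seed integer seed; all randomness of both generator calls flows
#'   from it through stage-labelled streams.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 20000, n_terms = 1000,
                              set_size_range = c(10, 30),
                              overlap_fraction = 0.1,
                              n_studies = 8, n_control = 5, n_treated = 5,
                              baseline_log2_mean = 6, baseline_log2_sd = 1.5,
                              noise_sd = 0.25, effect_size = 0.5,
                              signal_term_fraction = 0.1,
                              study_penetrance = 1, seed = 1L) {
  cfg <- list(
    n_genes = assert_count(n_genes, "n_genes"),
    n_terms = assert_count(n_terms, "n_terms"),
    set_size_range = c(assert_count(set_size_range[1], "set_size_range[1]", min = 2L),
                       assert_count(set_size_range[2], "set_size_range[2]", min = 2L)),
    overlap_fraction = assert_number(overlap_fraction, "overlap_fraction",
                                     0, 1, open_max = TRUE),
    n_studies = assert_count(n_studies, "n_studies"),
    n_control = assert_count(n_control, "n_control"),
    n_treated = assert_count(n_treated, "n_treated"),
    baseline_log2_mean = assert_number(baseline_log2_mean, "baseline_log2_mean"),
    baseline_log2_sd = assert_number(baseline_log2_sd, "baseline_log2_sd", min = 0),
    noise_sd = assert_number(noise_sd, "noise_sd", min = 0, open_min = TRUE),
    effect_size = assert_number(effect_size, "effect_size", min = 0),
    signal_term_fraction = assert_number(signal_term_fraction,
                                         "signal_term_fraction", 0, 1),
    study_penetrance = assert_number(study_penetrance, "study_penetrance", 0, 1),
    seed = assert_count(seed, "seed", min = 0L)
  )
  if (cfg$set_size_range[1] > cfg$set_size_range[2]) {
    stop("set_size_range must be non-decreasing")
  }
  structure(cfg, class = "simulation_config")
}

#' Simulate an overlapping gene-set collection
#'
#' Builds `n_terms` sets over the gene universe `1..n_genes`. Consecutive
#' term pairs (the designated pairs) share exactly
#' `round(overlap_fraction * min(size_i, size_j))` genes, drawn from disjoint
#' blocks so that every non-designated pair is exactly disjoint. Each term is
#' assigned an ontology depth drawn uniformly from {3, 4, 5}.
#'
#' @param config a [simulation_config()].
#' @return a [gene_set_collection()] whose `seed` records `config$seed` and
#'   which carries the designed pairwise overlaps in component
#'   `designed_overlaps` (data.frame: `term_a`, `term_b`, `overlap`).
#' @export
simulate_collection <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_terms
  smin <- config$set_size_range[1]; smax <- config$set_size_range[2]
  with_seed_(stage_seed(config$seed, "collection"), {
    sizes <- if (smin == smax) rep(smin, n) else
      sample(seq.int(smin, smax), n, replace = TRUE)
    depths <- sample(3:5, n, replace = TRUE)
  })
  ids <- sprintf("T%04d", seq_len(n))
  ov <- if (n > 1L) {
    as.integer(round(config$overlap_fraction * pmin(sizes[-n], sizes[-1L])))
  } else integer()
  # term i must accommodate its shares with both neighbours
  if (n > 2L) {
    bad <- which(ov[-length(ov)] + ov[-1L] > sizes[2:(n - 1L)])
    if (length(bad)) {
      i <- bad[1L] + 1L
      stop("infeasible overlap/size combination: term ", ids[i],
           " cannot hold its shared genes with both ", ids[i - 1L],
           " and ", ids[i + 1L])
    }
  }
  if (n > 1L && any(ov > pmin(sizes[-n], sizes[-1L]))) {
    stop("infeasible overlap: designated pair overlap exceeds a set size")
  }
  needed <- sum(sizes) - sum(ov)
  if (needed > config$n_genes) {
    stop("n_genes = ", config$n_genes, " too small: the requested sets need ",
         needed, " distinct genes")
  }
  genes <- as.character(seq_len(config$n_genes))
  sets <- vector("list", n)
  ptr <- 0L
  for (i in seq_len(n)) {
    shared_prev <- if (i > 1L && ov[i - 1L] > 0L) {
      # the block a term shares with its successor starts right after the
      # block it shares with its predecessor, keeping non-adjacent pairs
      # disjoint
      off <- if (i > 2L) ov[i - 2L] else 0L
      sets[[i - 1L]][(off + 1L):(off + ov[i - 1L])]
    } else character()
    n_new <- sizes[i] - length(shared_prev)
    fresh <- genes[ptr + seq_len(n_new)]
    ptr <- ptr + n_new
    sets[[i]] <- c(shared_prev, fresh)
  }
  names(sets) <- ids
  out <- gene_set_collection(sets, depth = depths,
                             term_names = paste("synthetic term", seq_len(n)),
                             seed = config$seed)
  out$designed_overlaps <- if (n > 1L) {
    data.frame(term_a = ids[-n], term_b = ids[-1L], overlap = ov,
               stringsAsFactors = FALSE)
  } else {
    data.frame(term_a = character(), term_b = character(),
               overlap = integer(), stringsAsFactors = FALSE)
  }
  out
}

#' Simulate expression studies with embedded gene-set signal
#'
#' For each study, per-gene log2 signals are drawn as baseline +
#' Normal(0, noise_sd^2); each signal term realized in that study shifts all
#' of its member genes by `direction * effect_size` in the treated group
#' (shifts from multiple realized terms add on shared genes). Matrices are
#' returned on the linear (anti-logged) scale, mirroring MAS5-style input.
#'
#' @param collection a [gene_set_collection()] over genes contained in the
#'   simulated universe `1..config$n_genes`.
#' @param config a [simulation_config()].
#' @return a list with components `studies` (list of [expression_study()])
#'   and `truth` (class `synthetic_truth`: `term_effects` data.frame with
#'   `term_id`, `direction`, `magnitude`; `study_penetrance`; `gene_effects`,
#'   a per-study named list of realized non-zero log2 shifts; `seed`).
#' @export
simulate_studies <- function(collection, config) {
  stopifnot(inherits(collection, "gene_set_collection"),
            inherits(config, "simulation_config"))
  genes <- as.character(seq_len(config$n_genes))
  members_all <- unlist(collection$sets, use.names = FALSE)
  if (!all(members_all %in% genes)) {
    stop("collection genes must be a subset of the simulated gene universe")
  }
  ids <- collection$info$term_id
  n_terms <- length(ids)
  n_sig <- round(config$signal_term_fraction * n_terms)
  nsamp <- config$n_control + config$n_treated
  treated_cols <- config$n_control + seq_len(config$n_treated)
  member_idx <- lapply(collection$sets, function(m) match(m, genes))

  with_seed_(stage_seed(config$seed, "studies"), {
    direction <- integer(n_terms)
    if (config$effect_size > 0 && n_sig > 0) {
      sig <- sample.int(n_terms, n_sig)
      direction[sig] <- sample(c(-1L, 1L), n_sig, replace = TRUE)
    }
    studies <- vector("list", config$n_studies)
    gene_effects <- vector("list", config$n_studies)
    study_ids <- sprintf("study_%d", seq_len(config$n_studies))
    for (s in seq_len(config$n_studies)) {
      realized <- which(direction != 0L &
                          stats::runif(n_terms) <= config$study_penetrance)
      delta <- numeric(config$n_genes)
      for (t in realized) {
        delta[member_idx[[t]]] <- delta[member_idx[[t]]] +
          direction[t] * config$effect_size
      }
      baseline <- stats::rnorm(config$n_genes, config$baseline_log2_mean,
                               config$baseline_log2_sd)
      logm <- baseline + matrix(stats::rnorm(config$n_genes * nsamp,
                                             sd = config$noise_sd),
                                config$n_genes, nsamp)
      logm[, treated_cols] <- logm[, treated_cols] + delta
      signal <- 2^logm
      dimnames(signal) <- list(genes,
                               paste0(study_ids[s], "_s", seq_len(nsamp)))
      studies[[s]] <- expression_study(
        signal,
        groups = rep(c("control", "treated"),
                     c(config$n_control, config$n_treated)),
        study_id = study_ids[s],
        tissue = paste0("synthetic_tissue_", s))
      nz <- which(delta != 0)
      gene_effects[[s]] <- stats::setNames(delta[nz], genes[nz])
    }
    names(studies) <- study_ids
    names(gene_effects) <- study_ids
  })

  truth <- structure(
    list(term_effects = data.frame(
           term_id = ids,
           direction = direction,
           magnitude = ifelse(direction == 0L, 0, config$effect_size),
           stringsAsFactors = FALSE),
         study_penetrance = config$study_penetrance,
         gene_effects = gene_effects,
         seed = config$seed),
    class = "synthetic_truth")
  list(studies = studies, truth = truth)
}
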