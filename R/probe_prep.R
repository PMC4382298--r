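# Probe-to-gene collapsing, per-study differential statistics and the
# cross-study gene-level consensus.

#' Collapse a probe table to one row per gene
#'
#' Reproduces the standard microarray preprocessing rule: probes without a
#' gene annotation are removed; probes annotated to more than one gene are
#' removed; when several probes remain for one gene, the probe with the
#' largest mean intensity across all arrays of the study is kept. Ties in
#' mean intensity are broken by the lexicographically smallest probe ID so
#' the result is deterministic.
#'
#' @param probes a [probe_table()].
#' @return an [expression_study()] with one row per surviving gene.
#' @export
collapse_probes <- function(probes) {
  stopifnot(inherits(probes, "probe_table"))
  ann <- probes$annotation
  ann <- ann[ann$probe_id %in% rownames(probes$signal), , drop = FALSE]
  n_genes_per_probe <- table(ann$probe_id)
  unique_probes <- names(n_genes_per_probe)[n_genes_per_probe == 1L]
  ann <- ann[ann$probe_id %in% unique_probes, , drop = FALSE]
  if (nrow(ann) == 0L) {
    stop("no annotatable probes: every probe has zero or multiple gene annotations")
  }
  means <- rowMeans(probes$signal)[ann$probe_id]
  ord <- order(ann$gene_id, -means, ann$probe_id)
  keep <- ord[!duplicated(ann$gene_id[ord])]
  signal <- probes$signal[ann$probe_id[keep], , drop = FALSE]
  rownames(signal) <- ann$gene_id[keep]
  signal <- signal[order(rownames(signal)), , drop = FALSE]
  expression_study(signal, probes$groups, probes$study_id, probes$tissue)
}

#' Per-gene differential expression statistics
#'
#' Computes, per gene, the log2 fold change (mean log2 treated minus mean
#' log2 control) and a two-sided Welch two-sample t-test on log2 signals.
#' The computation is vectorised over genes. Degenerate genes with zero
#' variance in both groups get `t = 0, p = 1` when the means agree and the
#' `p = 0` convention (flagged in column `degenerate`) when they differ.
#'
#' @param study an [expression_study()] with at least two samples per group.
#' @return a data.frame of class `differential_result` with columns `gene`,
#'   `log2_fc`, `t`, `df`, `p`, `direction` (-1/0/+1), `degenerate`; the
#'   study ID is carried in attribute `study_id`.
#' @export
differential_stats <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  x <- log2(study$signal)
  ctrl <- x[, study$groups == "control", drop = FALSE]
  trt <- x[, study$groups == "treated", drop = FALSE]
  n1 <- ncol(ctrl); n2 <- ncol(trt)
  if (n1 < 2L || n2 < 2L) stop("need >= 2 samples per group")
  m1 <- rowMeans(ctrl); m2 <- rowMeans(trt)
  v1 <- rowSums((ctrl - m1)^2) / (n1 - 1)
  v2 <- rowSums((trt - m2)^2) / (n2 - 1)
  fc <- m2 - m1
  se2 <- v1 / n1 + v2 / n2
  t <- fc / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * stats::pt(-abs(t), df)
  degen <- se2 == 0
  if (any(degen)) {
    zero_diff <- degen & fc == 0
    t[zero_diff] <- 0; p[zero_diff] <- 1
    t[degen & !zero_diff] <- sign(fc[degen & !zero_diff]) * Inf
    p[degen & !zero_diff] <- 0
    df[degen] <- NA_real_
  }
  out <- data.frame(gene = rownames(x), log2_fc = fc, t = t, df = df, p = p,
                    direction = as.integer(sign(fc)),
                    degenerate = degen,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "study_id") <- study$study_id
  class(out) <- c("differential_result", "data.frame")
  out
}

#' Cross-study consensus of differentially expressed genes
#'
#' Flags genes that are significant (`p < p_max`) in at least `min_studies`
#' studies with the same direction of change in every study where they are
#' significant — the "significant and consistently differentially expressed
#' in the majority of tissues" rule. Genes measured in fewer than
#' `min_studies` studies are excluded.
#'
#' @param results list (>= 2) of `differential_result` data.frames; gene
#'   universes may differ between studies.
#' @param p_max per-study significance threshold.
#' @param min_studies minimum number of significant studies; defaults to
#'   `ceiling(n_studies * 5/8)`, generalising a 5-of-8 majority rule.
#' @return data.frame with columns `gene`, `n_significant`,
#'   `consensus_direction`, sorted by decreasing `n_significant`.
#' @export
gene_consensus <- function(results, p_max = 0.05, min_studies = NULL) {
  if (!is.list(results) || length(results) < 2L) {
    stop("need at least two studies")
  }
  lapply(results, function(r) {
    if (!all(c("gene", "p", "direction") %in% names(r))) {
      stop("each result needs columns gene, p, direction")
    }
  })
  n_studies <- length(results)
  min_studies <- if (is.null(min_studies)) ceiling(n_studies * 5 / 8) else
    assert_count(min_studies, "min_studies")
  if (min_studies > n_studies) {
    stop("min_studies (", min_studies, ") exceeds the number of studies (",
         n_studies, ")")
  }
  assert_number(p_max, "p_max", 0, 1)
  long <- do.call(rbind, lapply(results, function(r) {
    data.frame(gene = as.character(r$gene), p = r$p,
               direction = as.integer(r$direction), stringsAsFactors = FALSE)
  }))
  n_measured <- table(long$gene)
  sig <- long[long$p < p_max, , drop = FALSE]
  if (nrow(sig) == 0L) {
    return(data.frame(gene = character(), n_significant = integer(),
                      consensus_direction = integer(),
                      stringsAsFactors = FALSE))
  }
  n_sig <- tapply(sig$p, sig$gene, length)
  dir_min <- tapply(sig$direction, sig$gene, min)
  dir_max <- tapply(sig$direction, sig$gene, max)
  genes <- names(n_sig)
  ok <- n_sig >= min_studies &
    as.integer(n_measured[genes]) >= min_studies &
    dir_min == dir_max & dir_min != 0L
  out <- data.frame(gene = genes[ok],
                    n_significant = as.integer(n_sig[ok]),
                    consensus_direction = as.integer(dir_min[ok]),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(-out$n_significant, out$gene), , drop = FALSE]
}
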