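---
title: "Methods: cross-tissue gene-set signatures and their conservation"
author: "crsignature"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cross-tissue gene-set signatures and their conservation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crsignature)
```

## The problem

Caloric restriction (CR) — reduced calorie intake without malnutrition —
changes gene expression in essentially every tissue, but few individual
genes respond consistently across tissues: platforms differ, tissues differ,
and single-gene effects are small relative to array noise. The question this
package addresses is whether a *tissue-independent* transcriptional response
exists at the level of gene functional categories, and whether that response
is conserved across species and across genetic models of delayed aging.

The analysis unit is a *study*: one tissue's expression matrix with
control and treated (CR) sample groups, on the linear intensity scale
produced by standard microarray summarization (e.g. MAS5). Several studies
share a gene-set collection (GO-term style: named sets with an ontology
depth), and the pipeline asks which sets move coherently across all
studies, then how strongly two groups of studies agree.

## Stage 1: probe collapsing and per-gene statistics

Probe-level matrices are reduced to one row per gene
(`collapse_probes()`): probes with no gene annotation are dropped, probes
annotated to multiple genes are dropped, and among a gene's remaining
probes the one with the largest mean intensity across all arrays of the
study is kept. Ties are broken by the lexicographically smallest probe ID,
making the reduction deterministic. The operation is idempotent.

Per-gene differential statistics (`differential_stats()`) are a Welch
two-sample t-test on log2 intensities, with the log2 fold change defined as
mean(log2 treated) − mean(log2 control). Welch's unequal-variance form is
the conservative default for small, possibly heteroscedastic array groups.
Degenerate genes with zero variance in both groups get `p = 1` when the
group means agree and the flagged convention `p = 0` when they differ.
Gene-level consensus across studies (`gene_consensus()`) keeps genes
significant (`p < 0.05` by default) in a majority of studies — the default
majority is `ceiling(n_studies * 5/8)` — with the same direction of change
in *every* study where they are significant. Direction consistency is
deliberately required only among the significant studies; a
non-significant, noisy opposite sign elsewhere does not disqualify a gene.

## Stage 2: the PAGE Z-score

For a set of $m$ measured member genes, with $\mu$ and $\delta$ the mean
and sample standard deviation (with the $n-1$ denominator) of the log2 fold
changes of *all* measured genes and $S_m$ the mean fold change of the
members, the parametric gene-set enrichment statistic is

$$Z = \frac{(S_m - \mu)\,\sqrt{m}}{\delta}.$$

By the central limit theorem $Z$ is approximately standard normal under a
null of exchangeable genes, so a single strong set-level shift is visible
even when no individual member reaches significance. The choice of the
$n-1$ denominator is immaterial at realistic universe sizes but is fixed so
that results are exactly reproducible; fold changes enter on the log2
scale, matching the fold-change convention of the differential stage.

`page_matrix()` assembles the terms × studies matrix with two filters:

* **ontology depth**: only terms of depth 3–5 are considered, excluding
  near-root umbrella categories ("metabolism") and very specific leaves;
  depth is consumed as supplied metadata, never recomputed from a DAG;
* **effective size**: within each study, a term is scored only if the
  number of its members actually measured on that study's platform lies in
  [10, 1000]. The per-study *effective* size governs the filter because
  platforms differ in transcript representation; a term can legitimately be
  scored in one study and missing in another.

Missing cells are explicit `NA`, never 0 — 0 is a valid Z-score.

## Stage 3: the consensus signature

Terms with Z-scores in at least `min_studies` (default 2) studies are
tested with a two-sided one-sample t-test of their Z values against 0;
Benjamini–Hochberg correction is applied across exactly the tested terms. A
term enters the signature when

* its BH-adjusted p-value is below 0.00285, and
* its median Z across studies is ≥ 2.58 or ≤ −2.58.

The second filter guarantees that at least half of the studies individually
show a strong set-level response, preventing one extreme study from
carrying the t-test. Both thresholds and the study minimum are exposed as
parameters; the defaults are the conventional operating point of this
analysis. The test screens both tails, so up- and downregulated sets are
found without constraining the direction.

A constant, non-zero Z row has zero variance and an undefined t statistic;
it is the strongest possible evidence of a consistent effect, so it is
assigned `p = 0` and flagged `degenerate` rather than silently dropped. A
constant zero row carries no evidence and is excluded from testing.

## Stage 4: concordance between study groups

Agreement between two groups of studies (e.g. mouse CR tissues vs CR in
other species) is measured by the Spearman correlation of their per-term
median-Z vectors, usually restricted to the signature's terms. Terms
missing in either vector are dropped identically in all schemes. Four
significance/confidence schemes are provided:

1. **permutation** (`permutation_test()`): shuffle the pairing of the two
   vectors; one-sided add-one Monte Carlo p. With 999 permutations the
   smallest attainable p is $1/1000 = 0.001$.
2. **pair bootstrap** (`pair_bootstrap()`): resample terms with
   replacement; percentile confidence interval for the correlation.
3. **model-based permutation** (`model_permutation()`): overlapping gene
   sets have correlated Z-scores even under the null — the predicted null
   correlation between two sets is
   $\mathrm{overlap}(i,j)/\sqrt{\mathrm{size}_i\,\mathrm{size}_j}$
   (`overlap_correlation()`). Each iteration draws two *independent*
   zero-mean Gaussian vectors with this term-by-term covariance (via its
   Cholesky factor) and records their Spearman correlation; the observed r
   is referred to that null. This is the scheme of record: plain
   permutation destroys the overlap structure and can be anticonservative
   on GO-style collections.
4. **model-based bootstrap** (`model_bootstrap()`): as scheme 3 but both
   Gaussian vectors are centred on the componentwise average of the two
   observed vectors, yielding a sampling distribution and percentile CI.

Design choices worth recording:

* p-values are one-sided for positive concordance by default (the
  scientific hypothesis is conservation, i.e. positive r); a two-sided
  alternative is a flag.
* the add-one estimator never returns 0 and makes the p floor explicit.
* nominal set sizes (within the analyzed universe) enter the overlap
  formula, since one matrix must serve both vectors regardless of
  per-study platforms.
* the overlap formula does not guarantee a positive semidefinite matrix
  for arbitrary overlap patterns (identical sets make it exactly
  singular). Eigenvalues below 1e-8 are clipped and the matrix rescaled to
  unit diagonal; whether repair occurred and the smallest original
  eigenvalue are kept as attributes.
* both simulated vectors are drawn fresh in schemes 3–4 (neither observed
  vector is held fixed), treating the two study groups symmetrically.

## The synthetic-data generator

Real multi-tissue CR compendia are not redistributable, so validation runs
on synthetic data with known truth (`simulate_collection()`,
`simulate_studies()`). The generator emulates: log-normal-like intensities
(baseline log2 mean 6, sd 1.5 — the scale of MAS5 signals), two groups per
study, several studies sharing one collection, a subset of terms with
coherent per-gene shifts partially shared across studies, and pairwise
overlapping sets. Defaults were chosen once as a realistic operating point
and are not tuned per analysis:

| parameter | default | why |
|---|---|---|
| `n_studies`, `n_control`, `n_treated` | 8, 5, 5 | an eight-tissue design at n = 5 per group, the typical size of the source studies |
| `n_genes` | 20000 | order of a mammalian array's annotated transcripts |
| `n_terms`, `set_size_range` | 1000, (10, 30) | enough terms for meaningful FDR behaviour; sizes above the min-size filter but small enough to keep sets disjoint where designed |
| `overlap_fraction` | 0.1 | modest sharing, typical of depth-filtered sibling terms; larger values are exercised explicitly in tests |
| `noise_sd` | 0.25 | within-group log2 scatter of a well-run array experiment |
| `effect_size` | 0.5 | a half log2 unit, a moderate pathway-level shift |
| `signal_term_fraction` | 0.1 | a minority of categories respond |
| `study_penetrance` | 1 | the default asks whether a fully shared effect is recovered; partial penetrance is available |

Overlap is *chained*: consecutive term pairs share
`round(overlap_fraction × min(size_i, size_j))` genes drawn from disjoint
blocks, so every non-adjacent pair is exactly disjoint. This pairwise-only
structure is sufficient to exercise the overlap-correlation model while
keeping the designed overlap of every pair exact. Signals are generated in
log2 space and anti-logged, matching the linear-intensity input contract.
Shifts from multiple realized terms add on shared genes, and the truth
object records every realized per-gene shift, so that each shift is
attributable to at least one non-null term.

What the generator does *not* emulate: probe-level artifacts beyond
multi-annotation (no CEL/MAS5 noise model), platform-specific gene
universes (all synthetic studies measure all genes), batch effects, and
correlated biological replicates. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated model, not
performance on any particular real compendium.

## Reproducibility and numerical conventions

One global seed is fanned out to per-stage streams via a stable label hash
(`stage_seed()`), so each stage is independently reproducible. All file
writes are atomic (write-temp-then-rename), and `run_pipeline()` writes a
manifest with parameters and MD5 checksums of every artifact; reruns with
the same configuration produce byte-identical manifests. TSV with `NA`
missing markers is used throughout; gene IDs are opaque strings.

Problem sizes used in the validation suite: the null-calibration check
runs 20 replicates of the full 8-study default configuration; the
overlap-correlation model is validated on 5000 simulated null datasets
over a 5000-gene universe; scheme calibration uses 500 replicates of a
40-term overlapping collection with 199 model simulations each. These
sizes give Monte Carlo standard errors comfortably below the tolerances
they are checked against.

## Known limitations

* GO depth must be supplied; collections without metadata cannot pass the
  depth filter.
* The one-sample t-test across studies treats studies as independent
  replicates; shared platforms or labs violate this silently.
* The overlap-correlation model captures only pairwise set overlap, not
  higher-order structure of the GO DAG.
* Spearman correlation against a heavily tied vector (e.g. a ±1 direction
  vector) is bounded away from 1 by the midrank convention — for a
  balanced binary vector the ceiling is √3/2 ≈ 0.866 — which matters when
  interpreting concordance against discretised references.
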