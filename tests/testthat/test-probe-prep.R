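make_probes <- function(signal, ann, groups = rep(c("control", "treated"), each = 2)) {
  probe_table(signal, ann, groups)
}

test_that("collapse keeps the highest-mean probe and drops un/multi-annotated probes", {
  sig <- rbind(p1 = c(100, 100, 100, 100),
               p2 = c(200, 200, 200, 200),
               p3 = c(50, 50, 50, 50),
               p4 = c(300, 300, 300, 300),
               p5 = c(10, 10, 10, 10),
               p6 = c(20, 20, 20, 20))
  colnames(sig) <- paste0("S", 1:4)
  ann <- data.frame(
    probe_id = c("p1", "p2", "p4", "p4", "p5", "p6"),
    gene_id  = c("g1", "g1", "g2", "g3", "g2", "g3"))
  # p3 unannotated, p4 multi-annotated -> both removed; g1 via p2 (mean 200)
  st <- collapse_probes(make_probes(sig, ann))
  expect_setequal(rownames(st$signal), c("g1", "g2", "g3"))
  expect_equal(unname(st$signal["g1", ]), rep(200, 4))
  expect_equal(unname(st$signal["g2", ]), rep(10, 4))
  expect_equal(unname(st$signal["g3", ]), rep(20, 4))
})

test_that("mean-intensity ties break on the lexicographically smallest probe id", {
  sig <- rbind(pB = c(5, 5, 7, 7), pA = c(7, 7, 5, 5))
  colnames(sig) <- paste0("S", 1:4)
  ann <- data.frame(probe_id = c("pA", "pB"), gene_id = c("g1", "g1"))
  st <- collapse_probes(make_probes(sig, ann))
  expect_equal(unname(st$signal["g1", ]), c(7, 7, 5, 5))
})

test_that("collapse is an error with no annotatable probes and idempotent otherwise", {
  sig <- matrix(runif(16, 1, 10), 4, 4,
                dimnames = list(paste0("p", 1:4), paste0("S", 1:4)))
  ann_multi <- data.frame(probe_id = rep(paste0("p", 1:4), each = 2),
                          gene_id = paste0("g", 1:8))
  expect_error(collapse_probes(make_probes(sig, ann_multi)),
               "no annotatable probes")
  ann_unique <- data.frame(probe_id = paste0("p", 1:4),
                           gene_id = paste0("g", 1:4))
  st1 <- collapse_probes(make_probes(sig, ann_unique))
  # re-collapsing its own output (identity annotation) changes nothing
  ident <- data.frame(probe_id = rownames(st1$signal),
                      gene_id = rownames(st1$signal))
  st2 <- collapse_probes(make_probes(st1$signal, ident))
  expect_identical(st1$signal, st2$signal)
})

test_that("differential_stats matches the textbook Welch computation", {
  st <- make_study(n_genes = 40, n_per_group = 4, seed = 8)
  d <- differential_stats(st)
  x <- log2(st$signal)
  for (i in c(1, 7, 23, 40)) {
    o <- brute_welch(x[i, 1:4], x[i, 5:8])
    expect_equal(d$t[i], o$t, tolerance = 1e-10)
    expect_equal(d$p[i], o$p, tolerance = 1e-10)
    # and against stats::t.test as a second, independent route
    tt <- t.test(x[i, 5:8], x[i, 1:4])
    expect_equal(d$t[i], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(d$p[i], tt$p.value, tolerance = 1e-10)
    expect_equal(d$log2_fc[i], mean(x[i, 5:8]) - mean(x[i, 1:4]),
                 tolerance = 1e-12)
  }
})

test_that("a printed 4-vs-4 Welch instance reproduces the hand computation", {
  ctrl <- c(7.9, 8.1, 8.0, 8.2)
  trt <- c(8.6, 8.9, 8.4, 8.7)
  sig <- rbind(g1 = 2^c(ctrl, trt))
  colnames(sig) <- paste0("S", 1:8)
  st <- expression_study(sig, rep(c("control", "treated"), each = 4), "w")
  d <- differential_stats(st)
  o <- brute_welch(ctrl, trt)
  expect_equal(d$t, o$t, tolerance = 1e-10)
  expect_equal(d$p, o$p, tolerance = 1e-10)
  expect_equal(d$log2_fc, 0.60, tolerance = 1e-10)
})

test_that("identical groups give fold change 0 / p 1; exact doubling gives log2 FC 1", {
  vals <- c(3, 5, 4, 6)
  sig <- rbind(g1 = c(vals, vals), g2 = c(vals, 2 * vals))
  colnames(sig) <- paste0("S", 1:8)
  st <- expression_study(sig, rep(c("control", "treated"), each = 4), "t")
  d <- differential_stats(st)
  expect_equal(d$log2_fc[1], 0)
  expect_equal(d$p[1], 1)
  expect_equal(d$t[1], 0)
  expect_equal(d$log2_fc[2], 1, tolerance = 1e-12)
})

test_that("degenerate zero-variance genes follow the stated conventions", {
  sig <- rbind(same = c(4, 4, 4, 4, 4, 4, 4, 4),
               diff = c(4, 4, 4, 4, 8, 8, 8, 8))
  colnames(sig) <- paste0("S", 1:8)
  st <- expression_study(sig, rep(c("control", "treated"), each = 4), "d")
  d <- differential_stats(st)
  expect_equal(d$t[1], 0); expect_equal(d$p[1], 1)
  expect_false(d$degenerate[1] && d$p[1] != 1)
  expect_equal(d$p[2], 0)
  expect_true(d$degenerate[2])
  expect_equal(d$direction[2], 1L)
})

test_that("differential stats are invariant to column order and global rescaling", {
  st <- make_study(n_genes = 30, seed = 5)
  d0 <- differential_stats(st)
  perm <- c(3, 1, 4, 2, 7, 5, 8, 6)
  st_perm <- expression_study(st$signal[, perm], st$groups[perm], st$study_id)
  d1 <- differential_stats(st_perm)
  expect_equal(d1$t, d0$t, tolerance = 1e-12)
  expect_equal(d1$p, d0$p, tolerance = 1e-12)
  st_scaled <- expression_study(st$signal * 7.3, st$groups, st$study_id)
  d2 <- differential_stats(st_scaled)
  expect_equal(d2$log2_fc, d0$log2_fc, tolerance = 1e-10)
  expect_equal(d2$p, d0$p, tolerance = 1e-10)
})

test_that("gene consensus applies the majority and direction-consistency rules", {
  genes <- "g1"
  mk <- function(p, dir, id) fake_diff(genes, p, dir, id)
  # significant same-direction in 5 of 8 -> included with n_significant = 5
  res5 <- c(lapply(1:5, function(i) mk(0.01, 1L, paste0("s", i))),
            lapply(6:8, function(i) mk(0.5, -1L, paste0("s", i))))
  out <- gene_consensus(res5, p_max = 0.05, min_studies = 5)
  expect_identical(out$gene, "g1")
  expect_identical(out$n_significant, 5L)
  expect_identical(out$consensus_direction, 1L)
  # one of the 5 significant flips sign -> excluded
  res_flip <- res5
  res_flip[[5]] <- mk(0.01, -1L, "s5")
  expect_identical(nrow(gene_consensus(res_flip, min_studies = 5)), 0L)
  # significant in only 4 of 8 -> excluded at min_studies = 5
  res4 <- c(lapply(1:4, function(i) mk(0.01, 1L, paste0("s", i))),
            lapply(5:8, function(i) mk(0.5, 1L, paste0("s", i))))
  expect_identical(nrow(gene_consensus(res4, min_studies = 5)), 0L)
  # default threshold generalises the 5-of-8 rule
  out_def <- gene_consensus(res5)
  expect_identical(out_def$n_significant, 5L)
  expect_error(gene_consensus(res5, min_studies = 9), "exceeds")
})

test_that("genes measured in too few studies are excluded even if always significant", {
  res <- c(list(fake_diff("g1", 0.001, 1L, "s1"),
                fake_diff("g1", 0.001, 1L, "s2")),
           lapply(3:8, function(i) fake_diff("g2", 0.5, 1L, paste0("s", i))))
  expect_identical(nrow(gene_consensus(res, min_studies = 5)), 0L)
})
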