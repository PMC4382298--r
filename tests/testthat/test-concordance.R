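test_that("spearman_cor reproduces exact small cases and the midrank oracle", {
  expect_equal(spearman_cor(1:10, 1:10), 1)
  expect_equal(spearman_cor(c(1, 2, 3), c(3, 1, 2)), -0.5)  # 1 - 6*6/(3*8)
  withr::with_seed(3, {
    for (k in 1:10) {
      n <- sample(5:40, 1)
      a <- sample(1:8, n, replace = TRUE)  # heavy ties
      b <- a + sample(-2:2, n, replace = TRUE)
      if (length(unique(a)) < 2 || length(unique(b)) < 2) next
      expect_equal(spearman_cor(a, b), brute_spearman(a, b),
                   tolerance = 1e-12)
    }
  })
  expect_error(spearman_cor(rep(1, 5), 1:5), "constant")
  expect_error(spearman_cor(1:2, 2:1), "3 complete pairs")
})

test_that("vectors are aligned by names and missing pairs dropped identically everywhere", {
  a <- c(t1 = 1, t2 = 2, t3 = NA, t4 = 4, t5 = 5, t6 = 2.5)
  b <- c(t6 = 3, t5 = 5, t4 = 4, t3 = 3, t2 = NA, t1 = 1)
  # complete common pairs: t1, t4, t5, t6
  expect_equal(spearman_cor(a, b),
               cor(c(1, 4, 5, 2.5), c(1, 4, 5, 3), method = "spearman"))
  pt <- permutation_test(a, b, n_perm = 99, seed = 1)
  bt <- pair_bootstrap(a, b, n_boot = 99, seed = 1)
  expect_identical(pt$n_terms, 4L); expect_identical(pt$n_dropped, 2L)
  expect_identical(bt$n_terms, 4L); expect_identical(bt$n_dropped, 2L)
  corr <- diag(4); dimnames(corr) <- list(names(a)[c(1, 4, 5, 6)],
                                          names(a)[c(1, 4, 5, 6)])
  mp <- model_permutation(a, b, corr, n_sim = 99, seed = 1)
  expect_identical(mp$n_terms, 4L); expect_identical(mp$n_dropped, 2L)
})

test_that("permutation p has the add-one floor and is seed-reproducible", {
  withr::with_seed(10, {
    a <- rnorm(40); b <- a + rnorm(40, sd = 0.05)
  })
  r1 <- permutation_test(a, b, n_perm = 999, seed = 7)
  r2 <- permutation_test(a, b, n_perm = 999, seed = 7)
  expect_equal(r1$p, 0.001)      # floor of the add-one rule at 999 resamples
  expect_identical(r1$p, r2$p)
  expect_gte(r1$p, 1 / 1000)
  r3 <- permutation_test(a, sample(b), n_perm = 99, seed = 1)
  expect_gt(r3$p, 0.001)
})

test_that("permutation p-values are approximately uniform under independence", {
  withr::with_seed(21, {
    ps <- vapply(1:300, function(k) {
      a <- rnorm(25); b <- rnorm(25)
      permutation_test(a, b, n_perm = 199)$p
    }, 0)
  })
  ks <- suppressWarnings(ks.test(ps, "punif"))
  expect_lt(unname(ks$statistic), 0.08)
})

test_that("pair bootstrap: identical vectors give CI [1,1]; CIs are seed-stable", {
  a <- c(5, 1, 9, 3, 7, 2, 8)
  r <- pair_bootstrap(a, a, n_boot = 200, seed = 2)
  expect_equal(r$ci, c(1, 1))
  expect_equal(r$r, 1)
  r1 <- pair_bootstrap(a, rev(a) + a, n_boot = 500, seed = 3)
  r2 <- pair_bootstrap(a, rev(a) + a, n_boot = 500, seed = 3)
  expect_identical(r1$ci, r2$ci)
  expect_true(r1$ci[1] <= r1$r && r1$r <= r1$ci[2] + 1e-12)
})

test_that("bootstrap CIs approximately cover a known population concordance", {
  # bivariate normal with rho = 0.6; population Spearman = 6/pi*asin(rho/2)
  rho <- 0.6
  true_rs <- 6 / pi * asin(rho / 2)
  withr::with_seed(14, {
    cover <- vapply(1:120, function(k) {
      x <- rnorm(60); y <- rho * x + sqrt(1 - rho^2) * rnorm(60)
      ci <- pair_bootstrap(x, y, n_boot = 300)$ci
      ci[1] <= true_rs && true_rs <= ci[2]
    }, NA)
  })
  expect_gte(mean(cover), 0.88)
  expect_lte(mean(cover), 0.995)
})

test_that("overlap correlation matches the printed formula on known sets", {
  col <- toy_collection()
  oc <- overlap_correlation(col)
  expect_equal(oc["A", "B"], 5 / sqrt(10 * 20), tolerance = 1e-12)
  expect_equal(oc["A", "B"], 0.353553, tolerance = 1e-5)
  expect_equal(oc["C", "D"], 1)        # identical sets
  expect_equal(oc["A", "C"], 0)        # disjoint
  expect_equal(diag(oc), c(A = 1, B = 1, C = 1, D = 1))
  expect_true(isSymmetric(unclass(oc)))
  # C == D makes the raw matrix singular: repair must have been applied
  # while a disjoint collection needs none
  oc2 <- overlap_correlation(gene_set_collection(
    list(x = as.character(1:5), y = as.character(6:10)), depth = 3))
  expect_false(attr(oc2, "repaired"))
  expect_equal(unclass(oc2), diag(2), ignore_attr = TRUE)
})

test_that("model permutation with identity correlation matches the plain permutation null", {
  withr::with_seed(30, {
    a <- rnorm(30); b <- rnorm(30)
    corr <- diag(30)
    mp <- model_permutation(a, b, corr, n_sim = 2000, seed = 31)
    # draw the two null samples and compare their distributions
    null_perm <- vapply(1:2000, function(k) {
      cor(a, sample(b), method = "spearman")
    }, 0)
  })
  null_model <- withr::with_seed(32, {
    vapply(1:2000, function(k) {
      cor(rnorm(30), rnorm(30), method = "spearman")
    }, 0)
  })
  ks <- suppressWarnings(ks.test(null_model, null_perm))
  expect_lt(unname(ks$statistic), 0.05)
  expect_true(mp$p > 0 && mp$p <= 1)
})

test_that("model permutation: r_obs = 0 gives p near 0.5; runs are seed-reproducible", {
  col <- toy_collection()
  sets <- lapply(1:20, function(i) as.character((i * 7):(i * 7 + 9)))
  names(sets) <- sprintf("S%02d", 1:20)
  colm <- gene_set_collection(sets, depth = 4)
  corr <- overlap_correlation(colm)
  # an exactly exchangeable pair with r_obs ~ 0
  a <- c(seq(-2, 2, length.out = 20))
  b <- a[c(seq(2, 20, 2), seq(19, 1, -2))]
  stopifnot(abs(cor(a, b, method = "spearman")) < 0.1)
  r1 <- model_permutation(a, b, corr, n_sim = 999, seed = 5)
  r2 <- model_permutation(a, b, corr, n_sim = 999, seed = 5)
  expect_identical(r1$p, r2$p)
  expect_gt(r1$p, 0.3); expect_lt(r1$p, 0.7)
})

test_that("model bootstrap centres near r_obs for structured data and reduces to the null at mean zero", {
  withr::with_seed(40, a <- sort(rnorm(40, sd = 3)))
  corr <- diag(40)
  r <- model_bootstrap(a, a, corr, n_sim = 500, seed = 41)
  expect_equal(r$r, 1)
  expect_true(r$ci[1] > 0.5)          # strongly structured: CI near r_obs = 1
  # near-zero vectors: the mean washes out and the CI spans the
  # independence-null spread
  eps_a <- seq(0, 1e-9, length.out = 40)
  eps_b <- rev(eps_a)
  r0 <- model_bootstrap(eps_a, eps_b, corr, n_sim = 500, seed = 42)
  expect_lt(r0$ci[1], -0.1)
  expect_gt(r0$ci[2], 0.1)
  r0b <- model_bootstrap(eps_a, eps_b, corr, n_sim = 500, seed = 42)
  expect_identical(r0$ci, r0b$ci)
})

test_that("a non-PSD overlap pattern is repaired enough for Cholesky", {
  corr <- matrix(0.9, 3, 3); diag(corr) <- 1
  corr[1, 3] <- corr[3, 1] <- 0  # violates PSD ordering constraints
  a <- c(1, 2, 3); b <- c(2, 1, 3)
  expect_error(chol(corr))
  r <- model_permutation(c(a, 4, 5), c(b, 5, 4),
                         {
                           m <- diag(5); m[1:3, 1:3] <- corr; m
                         }, n_sim = 99, seed = 1)
  expect_true(is.finite(r$p))
})
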