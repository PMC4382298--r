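# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive (loops, explicit formulas) so they cannot share a bug
# with the vectorised implementation paths they check.

# PAGE statistic from first principles: explicit mean, n-1 sd, set mean.
brute_page <- function(fc, members) {
  n <- length(fc)
  mu <- sum(fc) / n
  delta <- sqrt(sum((fc - mu)^2) / (n - 1))
  sm <- 0
  for (g in members) sm <- sm + fc[[g]]
  sm <- sm / length(members)
  (sm - mu) * sqrt(length(members)) / delta
}

# Midranks by counting, then Pearson by the explicit sum formulas.
brute_midrank <- function(x) {
  vapply(x, function(xi) sum(x < xi) + (sum(x == xi) + 1) / 2, 0)
}

brute_spearman <- function(a, b) {
  ra <- brute_midrank(a); rb <- brute_midrank(b)
  n <- length(ra)
  num <- sum((ra - mean(ra)) * (rb - mean(rb)))
  den <- sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  num / den
}

# BH step-up by the textbook definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Welch two-sample t from the textbook formulas on log2 values.
brute_welch <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  v1 <- sum((x - mean(x))^2) / (n1 - 1)
  v2 <- sum((y - mean(y))^2) / (n2 - 1)
  t <- (mean(y) - mean(x)) / sqrt(v1 / n1 + v2 / n2)
  df <- (v1 / n1 + v2 / n2)^2 /
    ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# A small study with explicit per-group log2 means; noise added on top.
make_study <- function(n_genes = 50, n_per_group = 4, delta = NULL,
                       noise_sd = 0.2, seed = 1, study_id = "toy") {
  withr::with_seed(seed, {
    genes <- as.character(seq_len(n_genes))
    base <- rnorm(n_genes, 8, 1)
    delta <- delta %||% numeric(n_genes)
    logm <- base + matrix(rnorm(n_genes * 2 * n_per_group, sd = noise_sd),
                          n_genes, 2 * n_per_group)
    trt <- n_per_group + seq_len(n_per_group)
    logm[, trt] <- logm[, trt] + delta
    sig <- 2^logm
    rownames(sig) <- genes
    expression_study(sig, rep(c("control", "treated"), each = n_per_group),
                     study_id)
  })
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A tiny hand-built collection with known overlaps.
toy_collection <- function() {
  gene_set_collection(
    list(A = as.character(1:10),
         B = as.character(6:25),    # overlap with A = 5, sizes 10 & 20
         C = as.character(26:40),
         D = as.character(26:40)),  # identical to C
    depth = c(3, 4, 5, 4))
}

# Hand-built differential_result rows for consensus-rule tests.
fake_diff <- function(genes, p, direction, study_id = "s") {
  d <- data.frame(gene = genes, log2_fc = direction * 1, t = 0,
                  df = 6, p = p, direction = as.integer(direction),
                  degenerate = FALSE, stringsAsFactors = FALSE)
  attr(d, "study_id") <- study_id
  class(d) <- c("differential_result", "data.frame")
  d
}
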