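# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Derive a stage-specific seed from a global seed
#'
#' A single pipeline seed is fanned out to independent per-stage streams by a
#' stable label hash, so each stage is reproducible on its own regardless of
#' execution order. Results stay below 2^31 - 1.
#'
#' @param seed integer global seed.
#' @param label character stage label, e.g. `"studies"`.
#' @return an integer seed.
#' @export
stage_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed),
            is.character(label), length(label) == 1L)
  m <- 2147483647
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% m
  as.integer((abs(as.numeric(seed)) + h) %% m)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state;
# seed = NULL uses (and advances) the current stream.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

# Write-temp-then-rename so a crashed run never leaves a truncated output.
# `writer` is a function(path) performing the actual write.
atomic_write <- function(writer, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tmp <- tempfile(pattern = paste0(".", basename(path), "."), tmpdir = dir)
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) {
    stop("atomic write failed: could not rename temporary file onto '",
         path, "'")
  }
  invisible(path)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
      x != round(x) || x < min) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

assert_number <- function(x, name, min = -Inf, max = Inf,
                          open_min = FALSE, open_max = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open_min) x > min else x >= min) &&
    (if (open_max) x < max else x <= max)
  if (!ok) {
    stop("'", name, "' must be a single number in ",
         if (open_min) "(" else "[", min, ", ", max,
         if (open_max) ")" else "]", call. = FALSE)
  }
  as.numeric(x)
}
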