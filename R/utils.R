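# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed without disturbing the caller's
# random stream. All exported stochastic operations funnel through this so
# that identical (inputs, seed) pairs give bit-identical output.
with_seed <- function(seed, code) {
  if (!is.null(old <- .GlobalEnv$.Random.seed)) {
    on.exit(assign(".Random.seed", old, envir = .GlobalEnv), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE))
      rm(".Random.seed", envir = .GlobalEnv), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Spawn `n` reproducible sub-seeds from one master seed; keeps modules
# independently re-runnable within a pipeline run. Seeds stay < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stopf("'%s' must be a single finite number", name)
  }
  if (positive && x <= 0) stopf("'%s' must be > 0 (got %g)", name, x)
  if (nonneg && x < 0) stopf("'%s' must be >= 0 (got %g)", name, x)
  invisible(x)
}
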