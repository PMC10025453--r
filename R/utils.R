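#' Derive a child RNG seed from a master seed and context tags
#'
#' Folds integer tags into the master seed so that independent pipeline
#' stages (per-fold scoring, null draws per module size, repeats) get
#' distinct, reproducible streams. Result is always in [1, 2^31 - 2].
#'
#' @param seed master integer seed
#' @param ... integer tags identifying the context
#' @return a single integer seed
#' @keywords internal
derive_seed <- function(seed, ...) {
  m <- 2147483629
  s <- as.numeric(seed) %% m
  for (a in c(...)) {
    s <- (s * 31 + (as.numeric(a) %% m)) %% m
  }
  as.integer(s + 1)
}

# Run expr with a local RNG state so callers' streams are not disturbed.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
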