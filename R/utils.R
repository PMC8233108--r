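#' Derive a stage seed from a master seed
#'
#' All stochastic stages draw their seeds from one master seed through a
#' Lehmer-style integer recurrence, so that a pipeline run is reproducible
#' from a single integer while stages remain statistically decoupled.
#'
#' @param master integer master seed.
#' @param ... one or more small non-negative integers identifying the stage
#'   (and, optionally, sub-stage indices such as the gamma level and run
#'   number).
#' @return a single integer in `[1, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  ks <- c(...)
  s <- (abs(as.numeric(master)) %% 2147483647)
  for (k in ks) {
    s <- (s * 48271 + as.numeric(k) + 1) %% 2147483647
  }
  as.integer(s + 1)
}

# Evaluate `expr` under `set.seed(seed)` without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Upper-triangle index pairs (i < j) of an n x n matrix.
upper_pairs <- function(n) {
  which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
}

stop_param <- function(...) stop(..., call. = FALSE)
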