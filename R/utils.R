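# Internal helpers shared across modules.

#' @import data.table
#' @importFrom stats rpois rbinom runif rgamma setNames cor
#' @importFrom utils head tail write.table read.table
NULL

# Stop with a consistent parameter-error class so callers/tests can
# distinguish misuse from runtime failures.
param_error <- function(...) {
  stop(errorCondition(paste0(...), class = c("radmap_param_error", "error")))
}

stage_error <- function(stage, ...) {
  stop(errorCondition(paste0("[", stage, "] ", ...),
                      class = c("radmap_stage_error", "error")))
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) param_error(...)
  invisible(TRUE)
}

# round() in base R is round-half-even; the printed summary statistics
# this package reproduces use conventional round-half-away-from-zero.
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Seeded evaluation that restores the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

# Derive a stream-specific child seed from a master seed, kept < 2^31.
child_seed <- function(seed, stream) {
  (as.double(seed) * 1103515245 + stream * 12345) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a
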