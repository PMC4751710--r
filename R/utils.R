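## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Sets the seed, runs `expr`, and restores the caller's RNG state so that
#' seeded sampling inside the package never perturbs user-level randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

## Derive a child seed from a base seed and an index, kept below 2^31.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647)
}

stop_input <- function(...) {
  stop(errorCondition(paste0(...), class = c("trackenrich_input_error", "error")))
}

stop_io <- function(...) {
  stop(errorCondition(paste0(...), class = c("trackenrich_io_error", "error")))
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x) && x == floor(x)
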