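# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the global RNG seeded to `seed`, then restores the
#' previous RNG state so library code never perturbs a caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  eval.parent(substitute(expr))
}

abort_if <- function(cond, ...) {
  if (cond) stop(..., call. = FALSE)
}

# 0-based half-open interval -> IRanges (1-based closed)
as_iranges0 <- function(start, end) {
  IRanges::IRanges(start = start + 1L, end = as.integer(end))
}

# IRanges -> 0-based half-open data.frame columns
from_iranges0 <- function(ir) {
  data.frame(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
}
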