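# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the RNG seeded to `seed` (when non-NULL) and restores the
#' caller's `.Random.seed` afterwards, so seeded package functions never
#' perturb the session RNG stream.
#'
#' @param seed Integer seed or `NULL` (use the current RNG state).
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# round-half-away-from-zero; base round() uses banker's rounding, which would
# turn e.g. 0.5-valued implied cell counts downward half the time.
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# Derive a stream of sub-seeds from one master seed, keeping every value a
# valid 32-bit R integer.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) {
    return(rep(list(NULL), n))
  }
  with_seed(seed, as.list(sample.int(.Machine$integer.max, n)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)
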