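#' Derive a reproducible sub-stream seed
#'
#' Mixes a global seed with an arbitrary sequence of string/integer tags into a
#' new 32-bit seed. Every stage of the pipeline (cohort generation, fold
#' assignment, hyperparameter sampling, per-fold model fits, bootstrap draws)
#' derives its own stream this way, so parallel or reordered execution cannot
#' change results.
#'
#' @param seed integer global seed.
#' @param ... tags (coerced to character) identifying the sub-stream.
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, ...) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  m <- 2147483647  # 2^31 - 1, Mersenne prime; products stay < 2^53
  h <- (abs(seed) %% m)
  for (tag in c(...)) {
    for (code in utf8ToInt(as.character(tag))) {
      h <- (h * 69069 + code) %% m
    }
  }
  as.integer(h)
}

#' Evaluate an expression with a local RNG seed
#'
#' Saves and restores `.Random.seed` so library code never disturbs the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
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

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
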