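#' @keywords internal
"_PACKAGE"

#' Evaluate an expression under a local, restorable RNG state
#'
#' All stochastic operations in the package route their randomness through
#' this helper so that (a) identical seeds give bitwise-identical output and
#' (b) calling a seeded function never disturbs the caller's RNG stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a global seed
#'
#' Stable arithmetic hash of the stage name mixed with the global seed, kept
#' below 2^31 so it is a valid R integer. Toggling one pipeline stage does not
#' shift the randomness of any other stage.
#'
#' @param global_seed integer global seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
stage_seed <- function(global_seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 131 + code) %% 1999999973
  as.integer((as.numeric(global_seed) %% 1999999973 + h) %% 2147483629L)
}

# shared input checks ---------------------------------------------------------

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}
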