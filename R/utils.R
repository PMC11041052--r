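#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random-number stream seeded to `seed`, then
#' restores the previous stream so callers' randomness is unaffected.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assertFlag <- function(x, nm) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop(nm, " must be TRUE or FALSE", call. = FALSE)
  x
}

.assertCount <- function(x, nm, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    stop(nm, " must be an integer >= ", min, call. = FALSE)
  as.integer(x)
}
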