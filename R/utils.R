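`%||%` <- function(x, y) if (is.null(x)) y else x

#' Run code with a temporary RNG seed
#'
#' Evaluates `expr` under `set.seed(seed)` and restores the caller's
#' `.Random.seed` afterwards, so seeded package internals never disturb the
#' global random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ..., class = NULL) {
  msg <- sprintf(fmt, ...)
  cond <- structure(
    class = c(class, "stpra_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

assert_probability <- function(x, what = "probability") {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stopf("%s must lie in [0, 1]; got %s", what,
          paste(format(x), collapse = ", "), class = "stpra_domain_error")
  }
  invisible(x)
}
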