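# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so stochastic stages (ICA restarts,
#' simulation) are pure functions of their seed argument.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Laplace with unit variance by default (scale b: var = 2 b^2).
rlaplace <- function(n, scale = 1 / sqrt(2)) {
  u <- stats::runif(n) - 0.5
  -scale * sign(u) * log(1 - 2 * abs(u))
}

plaplace <- function(q, scale = 1 / sqrt(2)) {
  ifelse(q < 0, 0.5 * exp(q / scale), 1 - 0.5 * exp(-q / scale))
}

geomMean <- function(x) exp(mean(log(x)))

# Trapezoidal integral of y over x.
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stable content hash (md5 of serialized text) for provenance headers.
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(paste(deparse(x), collapse = "\n"), f)
  unname(tools::md5sum(f))
}

# Prefix errors from a pipeline stage with the stage name.
stageCall <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

assertFiniteNumeric <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop(sprintf("%s must be finite numeric", what), call. = FALSE)
  invisible(x)
}
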