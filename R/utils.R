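clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Truncated normal draws
#'
#' Samples from N(mean, sd^2) truncated at `mean +- trunc * sd` by inverse-CDF
#' sampling (exact, no rejection loop).
#'
#' @param n number of draws.
#' @param mean,sd location and scale.
#' @param trunc truncation half-width in standard deviations.
#' @return numeric vector of length `n`.
#' @keywords internal
rtruncnorm <- function(n, mean = 0, sd = 1, trunc = 2) {
  lo <- stats::pnorm(-trunc)
  u <- stats::runif(n, lo, 1 - lo)
  mean + sd * stats::qnorm(u)
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is left untouched. With seed = NULL the expression runs on the
# current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
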