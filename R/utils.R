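#' @useDynLib dynsyn, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif rexp optimize pnorm sd var cor qnorm
#' @importFrom graphics hist
#' @importFrom utils write.csv read.csv modifyList
NULL

# error function (not in base R under this name)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf,
                             strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (x < lower || (strict_lower && x <= lower) || x > upper)
    stop(sprintf("'%s' = %g out of range [%g, %g]%s", name, x, lower, upper,
                 if (strict_lower) " (strict lower)" else ""), call. = FALSE)
  invisible(x)
}

#' Derive a child seed from a global seed
#'
#' A counter-based scheme: every stochastic component of an experiment draws
#' its own seed as a deterministic function of the global seed and a small
#' integer index, so adding a component never perturbs the random streams of
#' the others. The result is always a valid 32-bit integer seed.
#'
#' @param seed integer global seed.
#' @param index non-negative integer counter identifying the component.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, index = 0L) {
  s <- (as.double(seed) %% 2147483647) + 1
  # two rounds of a Lehmer-style mix, kept in double precision (< 2^53)
  for (k in c(48271, 69621)) {
    s <- (s * k + as.double(index) * 2654435761 %% 2147483647) %% 2147483647
  }
  as.integer(s %% 2147483646) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
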