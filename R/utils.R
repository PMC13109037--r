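#' Round half away from zero
#'
#' Deterministic commercial rounding, used for edge counts and for snapping
#' the selected density to the grid resolution. Base `round()` uses
#' round-half-to-even, which would drift edge counts at exact .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so seeded internals (null models,
#' modularity restarts) do not perturb the caller's RNG stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Truncated normal draws by inverse-CDF sampling
#'
#' @param n number of draws.
#' @param mean,sd location and scale of the parent normal.
#' @param lower,upper truncation bounds.
#' @return numeric vector of length n in [lower, upper].
#' @keywords internal
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd < 0) stop("sd must be >= 0")
  if (sd == 0) {
    if (mean < lower || mean > upper) stop("degenerate truncated normal outside bounds")
    return(rep(mean, n))
  }
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

# Stop with a formatted message (no call in the condition).
abort <- function(...) stop(sprintf(...), call. = FALSE)
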