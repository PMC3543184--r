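# Internal helpers shared across modules.

ARRAYS_ALL <- LETTERS[1:8]          # A = unfractionated reference, B..H = pooled fractions
ARRAYS_FRAC <- LETTERS[2:8]         # B..H
FRACTIONS_ENGAGED <- LETTERS[4:8]   # D..H: at least one complete ribosome

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

#' Trapezoidal area under a sampled curve over a time window
#'
#' Composite trapezoid rule on an (x, y) sample, restricted to `[lo, hi]`.
#' Window edges that fall between sample points are handled by linear
#' interpolation, so the result is exact for piecewise-linear curves.
#'
#' @param x strictly increasing sample positions.
#' @param y sampled values, same length as `x`.
#' @param lo,hi integration window; defaults to the full range of `x`.
#' @return Scalar area.
#' @keywords internal
#' @noRd
trapezoid_area <- function(x, y, lo = min(x), hi = max(x)) {
  stopifnot(length(x) == length(y), !is.unsorted(x, strictly = TRUE))
  if (hi <= lo) return(0)
  lo <- max(lo, min(x)); hi <- min(hi, max(x))
  keep <- x > lo & x < hi
  xs <- c(lo, x[keep], hi)
  ys <- c(stats::approx(x, y, xout = lo)$y, y[keep],
          stats::approx(x, y, xout = hi)$y)
  sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
}

# Truncated-normal sampler on [lo, hi] by inverse-CDF; vectorised in n.
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd <= 0) return(pmin(pmax(rep(mean, n), lo), hi))
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# Evaluate `expr` under a private RNG stream seeded with `seed`, restoring
# the caller's RNG state afterwards. `seed = NULL` leaves the RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Small stable content hash (polynomial rolling hash over the serialized
# object), used to stamp outputs so reruns with the same configuration are
# identifiable. All intermediates stay below 2^53 so arithmetic is exact.
config_hash <- function(x) {
  b <- as.double(serialize(x, NULL, version = 2))
  h <- 0
  for (v in b) h <- (h * 31 + v) %% 2147483647
  sprintf("%08x", as.integer(h))
}
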