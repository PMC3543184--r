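#' Polysome absorbance profile container
#'
#' A sampled A254 absorbance curve over elution time, divided into 11 elution
#' fractions by 12 ordered boundary times, with a role assigned to each
#' fraction: free RNA (1), 30S subunit (2), 50S subunit (3), monosome (4) and
#' polysomes of increasing size (5--11). Fraction roles are experimental
#' inputs (assigned via rRNA quantification), not inferred from the trace.
#'
#' @param time Strictly increasing elution times.
#' @param absorbance Nonnegative A254 values, same length as `time`.
#' @param boundaries 12 strictly increasing times inside the sampled range.
#' @param roles Character vector of length 11 naming each fraction's role;
#'   defaults to the standard layout
#'   `free_RNA, subunit_30S, subunit_50S, monosome, polysome...`.
#' @return A `polysome_profile` object.
#' @export
polysome_profile <- function(time, absorbance, boundaries,
                             roles = default_fraction_roles()) {
  if (is.unsorted(time, strictly = TRUE)) {
    stop("time must be strictly increasing", call. = FALSE)
  }
  stopifnot(length(time) == length(absorbance))
  if (any(absorbance < 0)) stop("absorbance must be >= 0", call. = FALSE)
  if (length(boundaries) != 12 || is.unsorted(boundaries, strictly = TRUE)) {
    stop("boundaries must be 12 strictly increasing times", call. = FALSE)
  }
  if (boundaries[1] < min(time) || boundaries[12] > max(time)) {
    stop("boundaries must lie within the sampled time range", call. = FALSE)
  }
  if (length(roles) != 11) stop("roles must cover 11 fractions", call. = FALSE)
  structure(list(time = time, absorbance = absorbance,
                 boundaries = boundaries, roles = roles),
            class = "polysome_profile")
}

#' @rdname polysome_profile
#' @export
default_fraction_roles <- function() {
  c("free_RNA", "subunit_30S", "subunit_50S", "monosome",
    paste0("polysome_", 5:11))
}

#' @export
print.polysome_profile <- function(x, ...) {
  cat(sprintf("polysome_profile: %d samples, 11 fractions over [%.2f, %.2f]\n",
              length(x$time), x$boundaries[1], x$boundaries[12]))
  invisible(x)
}

#' Calibrate ribosome numbers against elution time
#'
#' Fits, per replicate, the log-linear relation `ln(t) = a ln(P) + b` between
#' the elution time `t` of a resolved peak and its polysome size `P` (number
#' of loaded ribosomes). The slope `a` is averaged over replicates; the
#' intercept `b` is anchored per replicate at the monosome peak so the line
#' passes through `(P = 1, monosome_time)`, i.e. `b = ln(monosome_time)`.
#'
#' @param monosome_time Elution time of the monosome peak, one per replicate.
#' @param resolved_peaks List (one element per replicate) of data frames with
#'   columns `psize` and `time` for at least two resolved peaks.
#' @return A `ribosome_calibration` with elements `a` (scalar slope),
#'   `b` (per-replicate intercepts), `slopes` (per-replicate slopes) and
#'   `monosome_time`.
#' @export
#' @examples
#' pk <- data.frame(psize = c(1, 2, 4, 8), time = 10 * sqrt(c(1, 2, 4, 8)))
#' cal <- fit_ribosome_calibration(10, list(pk))
#' cal$a   # 0.5
fit_ribosome_calibration <- function(monosome_time, resolved_peaks) {
  if (is.data.frame(resolved_peaks)) resolved_peaks <- list(resolved_peaks)
  K <- length(resolved_peaks)
  stopifnot(length(monosome_time) == K)
  if (any(monosome_time <= 0)) {
    stop("monosome elution times must be positive", call. = FALSE)
  }
  slopes <- vapply(resolved_peaks, function(pk) {
    if (!all(c("psize", "time") %in% names(pk))) {
      stop("resolved_peaks need columns psize and time", call. = FALSE)
    }
    if (length(unique(pk$psize)) < 2) {
      stop("calibration impossible: need >= 2 distinct resolved peaks",
           call. = FALSE)
    }
    if (any(pk$psize <= 0) || any(pk$time <= 0)) {
      stop("peak sizes and times must be positive", call. = FALSE)
    }
    unname(stats::coef(stats::lm(log(time) ~ log(psize), data = pk))[2])
  }, numeric(1))
  structure(list(a = mean(slopes), b = log(monosome_time),
                 slopes = slopes, monosome_time = monosome_time),
            class = "ribosome_calibration")
}

#' @export
print.ribosome_calibration <- function(x, ...) {
  cat(sprintf("ribosome_calibration: a = %.4f (slopes %s), b = %s\n",
              x$a, paste(sprintf("%.3f", x$slopes), collapse = ", "),
              paste(sprintf("%.3f", x$b), collapse = ", ")))
  invisible(x)
}

#' Ribosome-number range for an elution window
#'
#' Inverts the calibration `ln(t) = a ln(P) + b` at the two boundary times of
#' an elution window, giving the range of polysome sizes eluting in it. The
#' representative value is the arithmetic midpoint of the bounds, reported to
#' one decimal; for the monosome window it is exactly 1 by definition.
#'
#' @param cal A [fit_ribosome_calibration()] result.
#' @param boundary_times Length-2 numeric `(t_low, t_high)`.
#' @param replicate Which replicate's intercept to use (default 1).
#' @param monosome If `TRUE`, force the representative value to 1.
#' @return Named numeric `(min, max, representative)`.
#' @export
#' @examples
#' cal <- fit_ribosome_calibration(10, list(
#'   data.frame(psize = c(1, 4), time = c(10, 20))))
#' ribosomes_for_fraction(cal, c(10, 20))  # P in [1, 4]
ribosomes_for_fraction <- function(cal, boundary_times, replicate = 1,
                                   monosome = FALSE) {
  stopifnot(inherits(cal, "ribosome_calibration"),
            length(boundary_times) == 2)
  if (cal$a == 0) stop("calibration slope a = 0: inversion undefined",
                       call. = FALSE)
  if (boundary_times[1] >= boundary_times[2] || any(boundary_times <= 0)) {
    stop("boundary_times must be positive with t_low < t_high", call. = FALSE)
  }
  b <- cal$b[replicate]
  p <- exp((log(boundary_times) - b) / cal$a)
  p <- sort(p)
  # midpoint is pre-rounded at 10 decimals so representative values are
  # stable against last-bit noise from the log/exp inversion
  rep_val <- if (monosome) 1 else round(round(mean(p), 10), 1)
  c(min = p[1], max = p[2], representative = rep_val)
}

#' Per-fraction ribosome numbers for the pooled fractions D--H
#'
#' Applies [ribosomes_for_fraction()] to the elution windows of the pooled
#' microarray fractions: D = elution fraction 4 (monosome), E, F, G = elution
#' fractions 5--7, H = pooled elution fractions 8--11. The monosome fraction
#' D has representative ribosome number exactly 1.
#'
#' @param cal A [fit_ribosome_calibration()] result.
#' @param profile A [polysome_profile()] supplying the boundary times.
#' @param replicate Replicate index for the intercept.
#' @return Data frame with columns `fraction`, `min`, `max`,
#'   `representative`, rows D..H with increasing, non-overlapping ranges.
#' @export
fraction_ribosome_table <- function(cal, profile, replicate = 1) {
  stopifnot(inherits(profile, "polysome_profile"))
  b <- profile$boundaries
  windows <- list(D = b[c(4, 5)], E = b[c(5, 6)], F = b[c(6, 7)],
                  G = b[c(7, 8)], H = b[c(8, 12)])
  rows <- lapply(names(windows), function(f) {
    v <- ribosomes_for_fraction(cal, windows[[f]], replicate,
                                monosome = (f == "D"))
    data.frame(fraction = f, min = v["min"], max = v["max"],
               representative = v["representative"], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Percentage of ribosomes engaged in translation
#'
#' Integrates the absorbance trace by the composite trapezoid rule and
#' reports the area over elution fractions 4--11 (complete ribosomes bound to
#' mRNA) as a percentage of the area over fractions 2--11 (all ribosomal
#' material: subunits, monosomes and polysomes). Fraction 1 (free RNA) is
#' excluded. The result is invariant under uniform rescaling of absorbance.
#'
#' @param profile A [polysome_profile()].
#' @return Percentage in `[0, 100]`.
#' @export
engaged_ribosome_fraction <- function(profile) {
  stopifnot(inherits(profile, "polysome_profile"))
  b <- profile$boundaries
  total <- trapezoid_area(profile$time, profile$absorbance, b[2], b[12])
  if (total <= 0) {
    stop("zero absorbance area over fractions 2-11: engaged fraction undefined",
         call. = FALSE)
  }
  engaged <- trapezoid_area(profile$time, profile$absorbance, b[4], b[12])
  100 * engaged / total
}

#' Fraction boundaries implied by a calibration
#'
#' Elution-fraction boundaries derived from `ln(t) = a ln(P) + b`: the
#' monosome window spans polysome sizes 0.75--1.4, single-ribosome-resolved
#' polysome fractions span 1.4--2.9, 2.9--5.4 and 5.4--9.6, and the heaviest
#' material (9.6--17.9 ribosomes) is split geometrically over the last four
#' elution fractions. Times before the monosome window are divided equally
#' into the free-RNA and subunit fractions.
#'
#' @param a,b Calibration slope and intercept (single replicate).
#' @return Numeric vector of 12 boundary times.
#' @keywords internal
#' @export
calibration_boundaries <- function(a, b) {
  tp <- function(p) exp(a * log(p) + b)
  pre <- tp(0.75)
  p_geo <- 9.6 * (17.9 / 9.6)^(0:4 / 4)
  c(0, pre / 3, 2 * pre / 3, pre, tp(c(1.4, 2.9, 5.4)), tp(p_geo))
}

#' Simulate a polysome absorbance profile
#'
#' Builds an A254 trace as a sum of Gaussian peaks placed at the elution
#' times implied by the calibration `ln(t) = a ln(P) + b`: 30S and 50S
#' subunit peaks in elution fractions 2 and 3, the monosome at `t = exp(b)`,
#' and polysome peaks at increasing sizes. Peak areas are scaled so that the
#' configured share of the total ribosomal absorbance (fractions 2--11) lies
#' in the translating fractions 4--11.
#'
#' @param calibration_a Positive slope (larger polysomes elute later).
#' @param calibration_b Intercept; `exp(calibration_b)` is the monosome
#'   elution time.
#' @param config A [synthetic_config()]; `engaged_fraction` sets the target
#'   polysomal area share, `seed` perturbs nothing (the profile is
#'   deterministic given the calibration).
#' @return A [polysome_profile()] with attributes `resolved_peaks` (exact
#'   `(psize, time)` pairs on the calibration line, suitable for
#'   [fit_ribosome_calibration()]), `monosome_time` and `engaged_target`.
#' @export
synthesize_profile <- function(calibration_a, calibration_b, config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (!is.numeric(calibration_a) || calibration_a <= 0) {
    stop("calibration_a must be positive (larger polysomes elute later)",
         call. = FALSE)
  }
  a <- calibration_a; b <- calibration_b
  bounds <- calibration_boundaries(a, b)
  tp <- function(p) exp(a * log(p) + b)
  engaged <- config$engaged_fraction

  centers2 <- function(i) (bounds[i] + bounds[i + 1]) / 2
  peak_t <- c(centers2(1),                 # free RNA
              centers2(2), centers2(3),    # 30S, 50S
              tp(1),                       # monosome
              tp(c(2, 4, 7, 12, 16)))      # polysomes
  # areas: free RNA fixed; subunits share (1 - engaged); translating peaks
  # share engaged, with decreasing weight for heavier complexes
  w_poly <- c(0.35, 0.20, 0.15, 0.12, 0.10, 0.08)
  area <- c(0.30,
            (1 - engaged) * c(0.45, 0.55),
            engaged * w_poly / sum(w_poly))
  sigma <- 0.45

  tmax <- bounds[12] + 1
  time <- seq(0, tmax, by = 0.02)
  absorb <- rep(0, length(time))
  for (i in seq_along(peak_t)) {
    absorb <- absorb + area[i] * stats::dnorm(time, peak_t[i], sigma)
  }

  prof <- polysome_profile(time, absorb, bounds)
  attr(prof, "resolved_peaks") <- data.frame(
    psize = c(1, 2, 4, 7, 12, 16),
    time = tp(c(1, 2, 4, 7, 12, 16)))
  attr(prof, "monosome_time") <- tp(1)
  attr(prof, "engaged_target") <- 100 * engaged
  prof
}
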