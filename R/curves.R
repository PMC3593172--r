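#' Time-stamped curves
#'
#' Concentration and signal-intensity curves share a minimal structure: a
#' strictly increasing, uniformly spaced time grid (seconds) and non-negative
#' values, tagged with the circuit location / image ROI they were measured at.
#'
#' @param times Numeric vector of sample times in seconds, uniform grid.
#' @param values Numeric vector of samples, same length as `times`.
#' @param location Label of the circuit location (e.g. `"aorta"`).
#' @return An object of class `concentration_curve` (values in mmol/L) or
#'   `signal_curve` (values in arbitrary units, au).
#' @examples
#' concentration_curve(0:10, dgamma(0:10, 3), "aorta")
#' @export
concentration_curve <- function(times, values, location = "unknown") {
  new_curve(times, values, location, "concentration_curve")
}

#' @rdname concentration_curve
#' @param roi Label of the image region of interest.
#' @param baseline_n Number of leading pre-contrast samples that form the
#'   baseline segment (used for baseline subtraction).
#' @export
signal_curve <- function(times, values, roi = "unknown", baseline_n = 0L) {
  x <- new_curve(times, values, roi, "signal_curve")
  x$baseline_n <- as.integer(baseline_n)
  x
}

new_curve <- function(times, values, location, class) {
  times <- as.numeric(times)
  values <- as.numeric(values)
  if (length(times) != length(values)) {
    stop("`times` and `values` must have the same length", call. = FALSE)
  }
  if (length(times) < 2L) stop("a curve needs at least two samples", call. = FALSE)
  dt <- diff(times)
  if (any(dt <= 0)) stop("`times` must be strictly increasing", call. = FALSE)
  if (diff(range(dt)) > 1e-9 * dt[1L]) {
    stop("`times` must be a uniform grid", call. = FALSE)
  }
  if (any(values < -1e-9)) stop("curve values must be non-negative", call. = FALSE)
  structure(
    list(times = times, values = pmax(values, 0), location = location,
         dt = dt[1L]),
    class = c(class, "phantom_curve")
  )
}

#' @export
print.phantom_curve <- function(x, ...) {
  unit <- if (inherits(x, "signal_curve")) "au" else "mmol/L"
  cat(sprintf("<%s> %s: %d samples, dt = %g s, t = [%g, %g] s\n",
              class(x)[1L], x$location, length(x$times), x$dt,
              x$times[1L], x$times[length(x$times)]))
  cat(sprintf("  peak %0.4g %s at t = %g s\n", max(x$values), unit,
              x$times[which.max(x$values)]))
  invisible(x)
}

#' @export
as.data.frame.phantom_curve <- function(x, ...) {
  val <- if (inherits(x, "signal_curve")) "si_au" else "conc_mmol_per_L"
  out <- data.frame(time_s = x$times, value = x$values)
  names(out)[2L] <- val
  out
}

#' Tracer mass carried past a curve's location
#'
#' Integrates concentration times flow, giving the total amount of contrast
#' agent (mmol) transported past the sampling point over the curve duration.
#'
#' @param curve A [concentration_curve()].
#' @param flow Flow past the location in L/min.
#' @return Mass in mmol.
#' @export
curve_mass <- function(curve, flow) {
  stopifnot(inherits(curve, "concentration_curve"))
  # mmol/L * mL/s * s / 1000 = mmol
  sum(curve$values) * curve$dt * flow_ml_s(flow) / 1000
}

#' First moment (mean transit time) of a curve
#'
#' @param curve A curve with non-zero area.
#' @return Time in seconds.
#' @export
first_moment <- function(curve) {
  a <- sum(curve$values)
  if (a <= 0) stop("curve has zero area; first moment undefined", call. = FALSE)
  sum(curve$times * curve$values) / a
}

#' Washout time of a bolus curve
#'
#' First time after the peak at which the curve falls below
#' `threshold_fraction` of its peak value and stays below it for the rest of
#' the record. In the open-circuit phantom this is the waiting time before a
#' new injection can be performed.
#'
#' @param curve A curve with a non-zero peak.
#' @param threshold_fraction Fraction of the peak (default 0.01, i.e. 1%).
#' @return Time in seconds (curve time coordinate), or `NA_real_` if the
#'   curve never washes out below the threshold within its duration.
#' @export
washout_time <- function(curve, threshold_fraction = 0.01) {
  stopifnot(threshold_fraction > 0, threshold_fraction <= 1)
  pk <- max(curve$values)
  if (pk <= 0) stop("curve has no peak; washout time undefined", call. = FALSE)
  ipk <- which.max(curve$values)
  if (threshold_fraction >= 1) return(curve$times[ipk])
  below <- curve$values < threshold_fraction * pk
  below[seq_len(ipk)] <- FALSE
  # first index after the peak from which the curve stays below for good
  stays <- rev(cumprod(rev(below))) > 0
  if (!any(stays)) return(NA_real_)
  curve$times[which(stays)[1L]]
}

#' Full width at half maximum of a bolus curve
#'
#' Width of the (baseline-subtracted, for signal curves) peak at half its
#' height, with linear interpolation between samples.
#'
#' @param curve A curve with a single dominant peak.
#' @return Width in seconds.
#' @export
curve_fwhm <- function(curve) {
  v <- curve$values
  if (inherits(curve, "signal_curve") && curve$baseline_n > 0L) {
    v <- v - mean(v[seq_len(curve$baseline_n)])
  }
  pk <- max(v)
  if (pk <= 0) stop("curve has no peak; FWHM undefined", call. = FALSE)
  ipk <- which.max(v)
  half <- pk / 2
  cross <- function(idx) {
    # linear interpolation of the half-max crossing between idx and idx+1
    t0 <- curve$times[idx]
    curve$dt * (half - v[idx]) / (v[idx + 1L] - v[idx]) + t0
  }
  i_up <- which(v[seq_len(ipk - 1L)] < half & v[2L:ipk] >= half)
  i_dn <- which(v[ipk:(length(v) - 1L)] >= half & v[(ipk + 1L):length(v)] < half)
  if (length(i_up) == 0L || length(i_dn) == 0L) {
    stop("curve does not cross half maximum on both sides of the peak",
         call. = FALSE)
  }
  t_up <- cross(max(i_up))
  t_dn <- cross(ipk - 1L + min(i_dn))
  t_dn - t_up
}

flow_ml_s <- function(flow_l_min) flow_l_min * 1000 / 60
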