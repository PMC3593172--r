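#' Saturation-recovery sequence parameters
#'
#' Saturation-recovery gradient-echo readout triggered once per heartbeat.
#' TR, TE and the flip angle enter the simplified signal model only through
#' the overall `scale * sin(flip)` factor; T2* decay at TE = 1 ms is
#' neglected.
#'
#' @param TR Repetition time in ms.
#' @param TE Echo time in ms.
#' @param flip Flip angle in degrees.
#' @param SR_delay Saturation-recovery delay TD in ms.
#' @param RR Heartbeat interval in s (1.0 s = 60 bpm triggering).
#' @return A `sequence_params` object.
#' @export
sequence_params <- function(TR = 3.0, TE = 1.0, flip = 15, SR_delay = 120,
                            RR = 1.0) {
  vals <- c(TR = TR, TE = TE, flip = flip, SR_delay = SR_delay, RR = RR)
  if (any(vals <= 0)) stop("all sequence parameters must be positive",
                           call. = FALSE)
  structure(as.list(vals), class = "sequence_params")
}

#' Signal model parameters
#'
#' Linear relaxivity model `R1 = R10 + r1 * c` feeding an ideal
#' saturation-recovery readout `SI = scale * sin(flip) * (1 - exp(-TD * R1))`.
#' Defaults are plausible 3T values for gadobutrol in water; `scale` and
#' `r1` are normally set by [calibrate_signal_model()] against a measured
#' dose-series peak table.
#'
#' @param r1 Relaxivity in L mmol^-1 s^-1.
#' @param R10 Baseline longitudinal relaxation rate of water in s^-1.
#' @param scale Scanner calibration constant in au.
#' @return A `signal_model_params` object.
#' @export
signal_model_params <- function(r1 = 5.0, R10 = 0.33, scale = 1) {
  if (r1 <= 0 || R10 <= 0 || scale <= 0) {
    stop("r1, R10 and scale must be positive", call. = FALSE)
  }
  structure(list(r1 = r1, R10 = R10, scale = scale),
            class = "signal_model_params")
}

#' Longitudinal relaxation rate at a gadolinium concentration
#'
#' @param c Concentration in mmol/L (vectorised).
#' @param params A [signal_model_params()].
#' @return R1 in s^-1.
#' @examples
#' concentration_to_R1(1, signal_model_params(r1 = 5, R10 = 0.33))  # 5.33
#' @export
concentration_to_R1 <- function(c, params) {
  stopifnot(all(c >= 0))
  params$R10 + params$r1 * c
}

#' Saturation-recovery signal intensity
#'
#' Ideal saturation followed by a single readout after the recovery delay:
#' `SI = scale * sin(flip) * (1 - exp(-TD * R1))`, strictly increasing and
#' saturating in R1.
#'
#' @param R1 Longitudinal relaxation rate in s^-1 (vectorised).
#' @param seq A [sequence_params()].
#' @param params A [signal_model_params()].
#' @return Signal intensity in au.
#' @export
sr_signal <- function(R1, seq = sequence_params(), params = signal_model_params()) {
  stopifnot(all(R1 > 0))
  td <- seq$SR_delay / 1000  # ms -> s
  params$scale * sin(seq$flip * pi / 180) * (1 - exp(-td * R1))
}

#' Convert a concentration curve to a continuous signal curve
#'
#' @param curve A [concentration_curve()].
#' @param seq A [sequence_params()].
#' @param params A [signal_model_params()].
#' @return A [signal_curve()] on the same time grid (baseline offset from
#'   the water R10 included).
#' @export
concentration_to_signal <- function(curve, seq = sequence_params(),
                                    params = signal_model_params()) {
  stopifnot(inherits(curve, "concentration_curve"))
  si <- sr_signal(concentration_to_R1(curve$values, params), seq, params)
  signal_curve(curve$times, si, roi = curve$location)
}

#' Invert the signal equation back to concentration
#'
#' Exact inversion of the saturation-recovery signal model:
#' `R1 = -log(1 - SI / (scale sin(flip))) / TD`, then
#' `c = (R1 - R10) / r1`. Used by the quantification pipeline to remove
#' T1 saturation from measured curves before deconvolution; in this
#' digital twin the signal model is known exactly, so the inversion is
#' bias-free up to noise. Pre-contrast noise can map to slightly negative
#' concentrations, which are kept (they average to zero in the fit).
#'
#' @param curve A [signal_curve()] of raw (not baseline-subtracted)
#'   intensities.
#' @param seq A [sequence_params()].
#' @param params The [signal_model_params()] the curve was generated (or
#'   calibrated) with.
#' @return A curve in mmol/L on the same grid (negative noise excursions
#'   clipped at a small margin below zero are truncated by the container).
#' @export
signal_to_concentration <- function(curve, seq = sequence_params(),
                                    params = signal_model_params()) {
  stopifnot(inherits(curve, "signal_curve"))
  plateau <- params$scale * sin(seq$flip * pi / 180)
  td <- seq$SR_delay / 1000
  frac <- pmin(pmax(curve$values / plateau, 0), 1 - 1e-9)
  r1 <- -log(1 - frac) / td
  conc <- (r1 - params$R10) / params$r1
  out <- concentration_curve(curve$times, pmax(conc, 0), curve$location)
  out$baseline_n <- curve$baseline_n
  out
}

#' Heartbeat sampling with additive noise
#'
#' Resamples a continuous signal curve once per RR interval (the simulated
#' ECG trigger) and adds seeded Gaussian noise on the magnitude signal.
#' The global RNG state is left untouched.
#'
#' @param curve A [signal_curve()] on a fine grid.
#' @param seq A [sequence_params()] (RR gives the sampling interval).
#' @param sigma Noise standard deviation in au (0 = noiseless resampling).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param baseline_n Number of leading samples marked as pre-contrast
#'   baseline on the output curve.
#' @return A [signal_curve()] sampled at `0, RR, 2 RR, ...`.
#' @export
sample_and_noise <- function(curve, seq = sequence_params(), sigma = 0,
                             seed = NULL, baseline_n = NULL) {
  stopifnot(inherits(curve, "signal_curve"), sigma >= 0)
  tt <- seq(curve$times[1L], curve$times[length(curve$times)], by = seq$RR)
  vv <- stats::approx(curve$times, curve$values, xout = tt)$y
  if (sigma > 0) {
    vv <- vv + with_seed(seed, stats::rnorm(length(vv), 0, sigma))
    vv <- pmax(vv, 0)  # magnitude signal
  }
  if (is.null(baseline_n)) baseline_n <- curve$baseline_n
  signal_curve(tt, vv, roi = curve$location, baseline_n = baseline_n)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Peak signal intensity above baseline
#'
#' Maximum of the baseline-subtracted curve; the baseline is the mean of
#' the first five pre-contrast samples (or fewer if the baseline segment is
#' shorter). Curves without a baseline segment are treated as already
#' baseline-free.
#'
#' @param curve A [signal_curve()].
#' @return Peak enhancement in au.
#' @export
peak_si <- function(curve) {
  stopifnot(inherits(curve, "signal_curve"))
  if (length(curve$values) == 0L) stop("empty curve", call. = FALSE)
  b <- 0
  if (!is.null(curve$baseline_n) && curve$baseline_n > 0L) {
    b <- mean(curve$values[seq_len(min(5L, curve$baseline_n))])
  }
  max(curve$values - b)
}

#' Linearly extrapolated ("expected") peak signal intensity
#'
#' Extrapolates the peak measured at a low, non-saturating reference dose
#' linearly to another dose: `reference_peak * dose / reference_dose`.
#'
#' @param reference_peak Peak SI at the reference dose, in au.
#' @param reference_dose Reference dose in mmol/kg.
#' @param dose Target dose in mmol/kg.
#' @return Expected peak SI in au.
#' @examples
#' expected_peak(665, 0.0005, 0.001)  # 1330
#' @export
expected_peak <- function(reference_peak, reference_dose, dose) {
  if (any(reference_dose <= 0)) {
    stop("reference_dose must be positive", call. = FALSE)
  }
  reference_peak * dose / reference_dose
}

#' Saturation ratio
#'
#' Expected (linearly extrapolated) peak SI divided by the observed peak
#' SI, reported to two decimals. Values above 1 indicate T1 saturation of
#' the signal at the observed concentration.
#'
#' @param expected Expected peak SI in au.
#' @param observed Observed peak SI in au.
#' @return Dimensionless ratio, rounded to 2 decimals.
#' @examples
#' saturation_ratio(13300, 8365)  # 1.59
#' @export
saturation_ratio <- function(expected, observed) {
  if (any(observed <= 0)) stop("observed peak must be positive", call. = FALSE)
  round(expected / observed, 2)
}

#' Default noise level for a calibrated signal model
#'
#' Chosen so the pre-contrast baseline has SNR of about 50, giving a
#' controllable noise floor for the reproducibility experiments.
#'
#' @param seq A [sequence_params()].
#' @param params A calibrated [signal_model_params()].
#' @param snr Target baseline signal-to-noise ratio.
#' @return Noise standard deviation in au.
#' @export
default_noise_sigma <- function(seq = sequence_params(),
                                params = signal_model_params(), snr = 50) {
  sr_signal(params$R10, seq, params) / snr
}
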