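#' Simulate one imaging acquisition on the digital phantom
#'
#' Full chain for a single injection: circuit transit, myocardial uptake,
#' saturation-recovery signal conversion, heartbeat sampling and noise.
#'
#' @param config A [circuit_config()].
#' @param protocol An [injection_protocol()].
#' @param seq A [sequence_params()].
#' @param model A [signal_model_params()].
#' @param sigma Noise SD in au; `NULL` uses [default_noise_sigma()].
#' @param seed Integer seed for the noise (offset per ROI); `NULL` for
#'   noiseless curves.
#' @param duration,dt,onset Simulation window, circuit grid step and
#'   injection onset in s.
#' @return List of sampled [signal_curve()]s `aorta`, `myo_right`,
#'   `myo_left`, plus the underlying concentration curves in `conc`.
#' @export
simulate_acquisition <- function(config, protocol, seq = sequence_params(),
                                 model = signal_model_params(), sigma = NULL,
                                 seed = NULL, duration = 180, dt = 0.05,
                                 onset = 10) {
  conc <- simulate_phantom(config, protocol, duration = duration, dt = dt,
                           onset = onset)
  if (is.null(sigma)) sigma <- default_noise_sigma(seq, model)
  if (is.null(seed)) sigma <- 0
  nb <- NULL
  sample1 <- function(curve, seed_offset) {
    si <- concentration_to_signal(curve, seq, model)
    if (is.null(nb)) nb <<- sum(seq(si$times[1L], si$times[length(si$times)],
                                    by = seq$RR) < onset)
    sample_and_noise(si, seq, sigma = sigma,
                     seed = if (is.null(seed)) NULL else seed + seed_offset,
                     baseline_n = nb)
  }
  list(aorta = sample1(conc$aorta, 0L),
       myo_right = sample1(conc$myo_right, 1L),
       myo_left = sample1(conc$myo_left, 2L),
       conc = conc, sigma = sigma, onset = onset)
}

is_calibrated <- function(model) isTRUE(attr(model, "calibrated"))

require_calibrated <- function(model) {
  if (!inherits(model, "signal_model_params") || !is_calibrated(model)) {
    stop(paste("this experiment needs a calibrated signal model;",
               "run calibrate_signal_model() first"), call. = FALSE)
  }
  invisible(model)
}

#' Measured dose-series peak table of the hardware phantom
#'
#' Reference peak signal intensities measured on the hardware phantom's
#' contrast-dose series (cardiac output 3 L/min, both myocardial
#' compartments at 10 mL/mL/min), shipped as a plain-text fixture. Aortic
#' peaks cover 0.0005-0.1 mmol/kg; myocardial peaks 0.001-0.01 mmol/kg.
#'
#' @return Data frame with columns `dose_mmol_kg`, `aif_peak_au`,
#'   `myo_peak_au` (NA where not measured).
#' @export
reference_peak_table <- function() {
  path <- system.file("extdata", "reference_dose_series_peaks.csv",
                      package = "perfusiontwin", mustWork = TRUE)
  utils::read.csv(path, comment.char = "#")
}

#' Calibrate the signal model against a measured dose series
#'
#' Simulates the aortic concentration peaks for the doses in the reference
#' table and fits the calibration constant `scale` and (optionally) the
#' relaxivity `r1` so the modelled baseline-subtracted peaks match the
#' measured ones, minimising squared log error. With `fit_r1 = TRUE`, `r1`
#' is profiled on a log grid with `scale` solved in closed form.
#'
#' If the measured peaks are consistent with a purely linear signal (no
#' saturation), `r1` is unidentifiable; the fit then flags
#' `r1_identifiable = FALSE` and keeps the default relaxivity.
#'
#' @param printed_peaks Data frame as from [reference_peak_table()].
#' @param cardiac_output,perfusion Experimental conditions of the dose
#'   series (L/min and mL/mL/min).
#' @param seq A [sequence_params()].
#' @param R10 Baseline water relaxation rate, s^-1.
#' @param r1_default Relaxivity used when `r1` is not identifiable.
#' @param fit_r1 Fit the relaxivity as well as the scale.
#' @param body_weight Subject weight in kg.
#' @param duration,dt,onset Simulation window parameters in s.
#' @return A calibrated [signal_model_params()] with attribute
#'   `"calibration"` (simulated peak table, residuals, identifiability).
#' @export
calibrate_signal_model <- function(printed_peaks = reference_peak_table(),
                                   cardiac_output = 3, perfusion = 10,
                                   seq = sequence_params(), R10 = 0.33,
                                   r1_default = 5.0, fit_r1 = TRUE,
                                   body_weight = 60, duration = 90,
                                   dt = 0.05, onset = 10) {
  doses <- printed_peaks$dose_mmol_kg
  peaks <- printed_peaks$aif_peak_au
  if (length(doses) < 2L || any(!is.finite(peaks)) || any(peaks <= 0)) {
    stop("calibration needs at least two positive measured peaks",
         call. = FALSE)
  }
  pf <- perfusion_to_flow(perfusion)
  cfg <- circuit_config(cardiac_output = cardiac_output,
                        perfusion_flow_right = pf, perfusion_flow_left = pf)
  td <- seq$SR_delay / 1000
  rr_grid <- seq2 <- NULL
  c_peaks <- vapply(doses, function(d) {
    sim <- simulate_circuit(cfg, injection_protocol(dose = d,
                                                    body_weight = body_weight),
                            duration = duration, dt = dt, onset = onset)
    a <- sim$aorta
    tt <- seq(a$times[1L], a$times[length(a$times)], by = seq$RR)
    max(stats::approx(a$times, a$values, xout = tt)$y)
  }, 0)

  # model: peak = K * (1 - exp(-td * r1 * c_peak)), K = scale*sin(flip)*e^-td*R10
  sse_for <- function(lr1) {
    f <- 1 - exp(-td * exp(lr1) * c_peaks)
    r <- log(peaks) - log(f)
    sum((r - mean(r))^2)
  }
  lin_r <- log(peaks) - log(c_peaks)
  sse_lin <- sum((lin_r - mean(lin_r))^2)  # r1 -> 0 limit (pure linearity)

  r1 <- r1_default
  r1_identifiable <- FALSE
  if (fit_r1) {
    opt <- stats::optimize(sse_for, interval = log(c(0.05, 500)), tol = 1e-10)
    improved <- (sse_lin - opt$objective) > 1e-6 * max(sse_lin, 1e-12)
    at_bound <- opt$minimum < log(0.05) + 1e-3 || opt$minimum > log(500) - 1e-3
    if (improved && !at_bound) {
      r1 <- exp(opt$minimum)
      r1_identifiable <- TRUE
    }
  }
  f <- 1 - exp(-td * r1 * c_peaks)
  K <- exp(mean(log(peaks) - log(f)))
  scale <- K / (sin(seq$flip * pi / 180) * exp(-td * R10))
  model <- signal_model_params(r1 = r1, R10 = R10, scale = scale)
  fitted <- K * f
  attr(model, "calibrated") <- TRUE
  attr(model, "calibration") <- list(
    table = data.frame(dose_mmol_kg = doses, c_peak_mmol_L = c_peaks,
                       measured_au = peaks, fitted_au = fitted),
    r1_identifiable = r1_identifiable,
    sse_log = if (fit_r1) sse_for(log(r1)) else NA_real_,
    conditions = list(cardiac_output = cardiac_output, perfusion = perfusion)
  )
  model
}

#' Contrast-dose sensitivity experiment
#'
#' Injects a series of doses under fixed conditions (default: cardiac
#' output 3 L/min, both compartments at 10 mL/mL/min), records aortic and
#' myocardial peak enhancement, the linearly extrapolated expected peaks
#' (aorta anchored at the lowest dose, myocardium at 0.001 mmol/kg) and
#' the saturation ratios. Optionally runs the dual-bolus quantification
#' arm at selected doses with noisy replicates.
#'
#' @param model A calibrated [signal_model_params()].
#' @param doses Doses in mmol/kg.
#' @param cardiac_output L/min.
#' @param perfusion Both-compartment perfusion rate in mL/mL/min.
#' @param aif_anchor_dose,myo_anchor_dose Reference doses for the linear
#'   extrapolation.
#' @param quantify_doses Doses at which to run Fermi quantification
#'   (`NULL` to skip).
#' @param n_replicates Noisy replicates per quantified dose.
#' @param base_seed Seed; replicate r uses `base_seed + r - 1`.
#' @param sigma Noise SD in au (`NULL` = default noise model); peaks are
#'   measured noiselessly.
#' @param seq A [sequence_params()].
#' @param duration Simulation window, s.
#' @return An `experiment_result` with elements `table` (per-dose peaks
#'   and ratios) and `quantification` (per-dose perfusion mean +- SD).
#' @export
run_dose_series <- function(model, doses = c(0.0005, 0.001, 0.0025, 0.005,
                                             0.01, 0.1),
                            cardiac_output = 3, perfusion = 10,
                            aif_anchor_dose = 0.0005, myo_anchor_dose = 0.001,
                            quantify_doses = c(0.0025, 0.005, 0.01),
                            n_replicates = 6, base_seed = 20260101,
                            sigma = NULL, seq = sequence_params(),
                            duration = 180) {
  require_calibrated(model)
  pf <- perfusion_to_flow(perfusion)
  cfg <- circuit_config(cardiac_output = cardiac_output,
                        perfusion_flow_right = pf, perfusion_flow_left = pf)
  acqs <- lapply(doses, function(d) {
    simulate_acquisition(cfg, injection_protocol(dose = d), seq, model,
                         seed = NULL, duration = duration)
  })
  aif_peaks <- vapply(acqs, function(a) peak_si(a$aorta), 0)
  myo_peaks <- vapply(acqs, function(a) peak_si(a$myo_left), 0)
  aif_ref <- aif_peaks[match(aif_anchor_dose, doses)]
  myo_ref <- myo_peaks[match(myo_anchor_dose, doses)]
  tab <- data.frame(
    dose_mmol_kg = doses,
    aif_peak_au = aif_peaks,
    aif_expected_au = expected_peak(aif_ref, aif_anchor_dose, doses),
    myo_peak_au = myo_peaks,
    myo_expected_au = expected_peak(myo_ref, myo_anchor_dose, doses)
  )
  tab$aif_saturation_ratio <- saturation_ratio(tab$aif_expected_au, aif_peaks)
  tab$myo_saturation_ratio <- saturation_ratio(tab$myo_expected_au, myo_peaks)

  quant <- NULL
  if (!is.null(quantify_doses) && length(quantify_doses) > 0L) {
    rows <- lapply(quantify_doses, function(d) {
      est <- replicate_estimates(model, cfg, dose = d, side = "left",
                                 n = n_replicates, base_seed = base_seed,
                                 sigma = sigma, seq = seq,
                                 duration = duration)
      data.frame(dose_mmol_kg = d, truth_ml_ml_min = perfusion,
                 mean_perfusion = mean(est), sd_perfusion = stats::sd(est),
                 n = length(est))
    })
    quant <- do.call(rbind, rows)
  }
  experiment_result("dose_series", table = tab, quantification = quant,
                    seed = base_seed,
                    conditions = list(cardiac_output = cardiac_output,
                                      perfusion = perfusion))
}

# Dual-bolus perfusion estimates over n noise replicates at one condition.
# The clean prebolus AIF and main-bolus myocardial curves are simulated
# once; replicates differ only in the seeded noise. Measured SI curves are
# inverted back to concentration through the calibrated signal model
# before deconvolution (the twin's myocardial concentrations are high
# enough that assuming SI-concentration linearity would bias the fit).
replicate_estimates <- function(model, cfg, dose, side = "left", n = 6,
                                base_seed = 1, sigma = NULL,
                                seq = sequence_params(), duration = 180,
                                dt = 0.05, onset = 10,
                                correct_saturation = TRUE) {
  if (is.null(sigma)) sigma <- default_noise_sigma(seq, model)
  pre <- injection_protocol(dose = dose)  # carries prebolus_fraction
  pre_proto <- injection_protocol(dose = dose * pre$prebolus_fraction)
  sim_pre <- simulate_circuit(cfg, pre_proto, duration = duration, dt = dt,
                              onset = onset, side = side)
  conc_main <- simulate_phantom(cfg, injection_protocol(dose = dose),
                                duration = duration, dt = dt, onset = onset)
  aif_si <- concentration_to_signal(sim_pre$aorta, seq, model)
  myo_si <- concentration_to_signal(
    if (side == "left") conc_main$myo_left else conc_main$myo_right,
    seq, model)
  nb <- sum(seq(0, duration, by = seq$RR) < onset)
  vapply(seq_len(n), function(r) {
    s <- base_seed + (r - 1L)
    aif_r <- sample_and_noise(aif_si, seq, sigma, seed = s, baseline_n = nb)
    myo_r <- sample_and_noise(myo_si, seq, sigma, seed = s + 500000L,
                              baseline_n = nb)
    if (correct_saturation) {
      aif_r <- signal_to_concentration(aif_r, seq, model)
      myo_r <- signal_to_concentration(myo_r, seq, model)
    }
    acq <- dual_bolus_acquisition(aif_r, myo_r,
                                  dose_ratio = 1 / pre$prebolus_fraction)
    estimate_perfusion(quantify_dual_bolus(acq))
  }, 0)
}

#' Myocardial perfusion-rate sensitivity experiment
#'
#' Varies the left-compartment perfusion rate at fixed cardiac output and
#' dose, runs the dual-bolus Fermi quantification on noisy replicates, and
#' compares the recovered perfusion to the gold-standard rates set on the
#' circuit (one-way ANOVA across rates).
#'
#' @param model A calibrated [signal_model_params()].
#' @param rates Gold-standard perfusion rates in mL/mL/min.
#' @param cardiac_output L/min.
#' @param dose Main-bolus dose in mmol/kg (10% prebolus).
#' @param right_perfusion Fixed right-compartment rate in mL/mL/min.
#' @param n_replicates Noisy replicates per rate.
#' @param base_seed Seed; rate i, replicate r uses
#'   `base_seed + 100 * (i - 1) + (r - 1)`.
#' @param sigma Noise SD in au (`NULL` = default noise model).
#' @param seq A [sequence_params()].
#' @param duration Simulation window, s.
#' @return An `experiment_result`: `table` (rate, truth, mean, SD),
#'   `anova` (F, p) and the raw `estimates`.
#' @export
run_perfusion_series <- function(model, rates = c(1, 2.5, 5, 7.5, 10),
                                 cardiac_output = 3, dose = 0.01,
                                 right_perfusion = 10, n_replicates = 6,
                                 base_seed = 20260101, sigma = NULL,
                                 seq = sequence_params(), duration = 180) {
  require_calibrated(model)
  est <- lapply(seq_along(rates), function(i) {
    cfg <- circuit_config(
      cardiac_output = cardiac_output,
      perfusion_flow_right = perfusion_to_flow(right_perfusion),
      perfusion_flow_left = perfusion_to_flow(rates[i]))
    replicate_estimates(model, cfg, dose = dose, side = "left",
                        n = n_replicates,
                        base_seed = base_seed + 100L * (i - 1L),
                        sigma = sigma, seq = seq, duration = duration)
  })
  tab <- data.frame(
    truth_ml_ml_min = rates,
    mean_perfusion = vapply(est, mean, 0),
    sd_perfusion = vapply(est, stats::sd, 0),
    n = vapply(est, length, 0L)
  )
  aov <- if (length(rates) >= 2L && n_replicates >= 2L) one_way_anova(est)
  else NULL
  experiment_result("perfusion_series", table = tab, anova = aov,
                    estimates = est, seed = base_seed,
                    conditions = list(cardiac_output = cardiac_output,
                                      dose = dose))
}

#' Cardiac-output sensitivity experiment
#'
#' Repeats the same injection at different cardiac outputs (noiseless) and
#' summarises the aortic peak, its full width at half maximum, the
#' myocardial peak, and the myocardial-to-aortic peak ratio. Higher
#' cardiac output dilutes the bolus faster: shorter, lower-amplitude
#' aortic curves.
#'
#' @param model A calibrated [signal_model_params()].
#' @param cardiac_outputs L/min values to compare.
#' @param dose Dose in mmol/kg.
#' @param perfusion Both-compartment perfusion rate in mL/mL/min.
#' @param seq A [sequence_params()].
#' @param duration Simulation window, s.
#' @return An `experiment_result` with per-cardiac-output summary table.
#' @export
run_cardiac_output_series <- function(model, cardiac_outputs = c(3, 4),
                                      dose = 0.01, perfusion = 5,
                                      seq = sequence_params(),
                                      duration = 180) {
  require_calibrated(model)
  pf <- perfusion_to_flow(perfusion)
  rows <- lapply(cardiac_outputs, function(co) {
    cfg <- circuit_config(cardiac_output = co, perfusion_flow_right = pf,
                          perfusion_flow_left = pf)
    acq <- simulate_acquisition(cfg, injection_protocol(dose = dose), seq,
                                model, seed = NULL, duration = duration)
    aif_pk <- peak_si(acq$aorta)
    myo_pk <- peak_si(acq$myo_left)
    data.frame(cardiac_output = co,
               aif_peak_au = aif_pk,
               aif_fwhm_s = curve_fwhm(acq$aorta),
               myo_peak_au = myo_pk,
               myo_aif_peak_ratio = myo_pk / aif_pk,
               aorta_conc_peak = max(acq$conc$aorta$values))
  })
  experiment_result("cardiac_output_series", table = do.call(rbind, rows),
                    conditions = list(dose = dose, perfusion = perfusion))
}

#' Reproducibility experiment
#'
#' Repeats the same acquisition with independent noise realisations
#' (optionally in two seed families standing in for different
#' operators/days) and computes pairwise Pearson adjusted R^2 between the
#' replicate aortic and myocardial signal curves.
#'
#' @param model A calibrated [signal_model_params()].
#' @param cardiac_output L/min.
#' @param dose mmol/kg.
#' @param right_perfusion,left_perfusion Compartment rates in mL/mL/min
#'   (`right_perfusion` may be a vector of conditions).
#' @param n_replicates Replicates per condition and family.
#' @param seed_families Number of independent seed families.
#' @param base_seed Seed.
#' @param sigma Noise SD in au (`NULL` = default noise model).
#' @param seq A [sequence_params()].
#' @param duration Simulation window, s.
#' @return An `experiment_result`; `table` has one row per condition x ROI
#'   with the minimum and mean pairwise adjusted R^2.
#' @export
run_reproducibility <- function(model, cardiac_output = 4, dose = 0.01,
                                right_perfusion = c(1, 5),
                                left_perfusion = 10, n_replicates = 6,
                                seed_families = 2, base_seed = 20260101,
                                sigma = NULL, seq = sequence_params(),
                                duration = 180) {
  require_calibrated(model)
  if (is.null(sigma)) sigma <- default_noise_sigma(seq, model)
  rows <- list()
  for (rp in right_perfusion) {
    cfg <- circuit_config(
      cardiac_output = cardiac_output,
      perfusion_flow_right = perfusion_to_flow(rp),
      perfusion_flow_left = perfusion_to_flow(left_perfusion))
    clean <- simulate_acquisition(cfg, injection_protocol(dose = dose), seq,
                                  model, seed = NULL, duration = duration)
    for (roi in c("aorta", "myo_right", "myo_left")) {
      si <- concentration_to_signal(clean$conc[[if (roi == "aorta") "aorta"
                                                else roi]], seq, model)
      for (fam in seq_len(seed_families)) {
        reps <- lapply(seq_len(n_replicates), function(r) {
          sample_and_noise(si, seq, sigma,
                           seed = base_seed + 100000L * fam + (r - 1L),
                           baseline_n = 0L)
        })
        pairs <- utils::combn(n_replicates, 2L)
        r2 <- apply(pairs, 2L, function(p) {
          pearson_r2(reps[[p[1L]]], reps[[p[2L]]])$adj_r2
        })
        rows[[length(rows) + 1L]] <- data.frame(
          right_perfusion = rp, roi = roi, family = fam,
          min_adj_r2 = min(r2), mean_adj_r2 = mean(r2))
      }
    }
  }
  experiment_result("reproducibility", table = do.call(rbind, rows),
                    seed = base_seed,
                    conditions = list(cardiac_output = cardiac_output,
                                      dose = dose, sigma = sigma))
}

#' Squared Pearson correlation between two curves
#'
#' @param a,b Curves (or numeric vectors) of equal length >= 3.
#' @return List with `r2`, `adj_r2` (`1 - (1 - R^2)(n - 1)/(n - 2)`) and
#'   the regression `p` value.
#' @export
pearson_r2 <- function(a, b) {
  x <- if (inherits(a, "phantom_curve")) a$values else as.numeric(a)
  y <- if (inherits(b, "phantom_curve")) b$values else as.numeric(b)
  n <- length(x)
  if (n != length(y) || n < 3L) {
    stop("pearson_r2 needs two equal-length inputs with n >= 3", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: an input has zero variance", call. = FALSE)
  }
  r <- stats::cor(x, y)
  r2 <- r^2
  tstat <- abs(r) * sqrt((n - 2) / max(1 - r2, .Machine$double.eps))
  list(r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / (n - 2),
       p = 2 * stats::pt(tstat, df = n - 2, lower.tail = FALSE))
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA across groups of measurements.
#'
#' @param groups List of numeric vectors (>= 2 groups, each >= 2 values).
#' @return List with the `F` statistic, `p` value and degrees of freedom.
#' @export
one_way_anova <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    stop("one_way_anova needs at least two groups", call. = FALSE)
  }
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("every group needs at least two samples", call. = FALSE)
  }
  all_x <- unlist(groups)
  grand <- mean(all_x)
  ss_between <- sum(sizes * (vapply(groups, mean, 0) - grand)^2)
  ss_within <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1L
  df2 <- length(all_x) - length(groups)
  if (ss_within == 0 && ss_between == 0) {
    stop("degenerate groups: no variance at all", call. = FALSE)
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(F = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df = c(df1, df2))
}

experiment_result <- function(protocol, ...) {
  structure(c(list(protocol = protocol), list(...)),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("<experiment_result> protocol: %s\n", x$protocol))
  if (!is.null(x$table)) print(x$table, row.names = FALSE)
  if (!is.null(x$quantification)) {
    cat("quantification:\n")
    print(x$quantification, row.names = FALSE)
  }
  if (!is.null(x$anova)) {
    cat(sprintf("ANOVA: F(%d, %d) = %0.4g, p = %0.3g\n", x$anova$df[1L],
                x$anova$df[2L], x$anova$F, x$anova$p))
  }
  invisible(x)
}
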