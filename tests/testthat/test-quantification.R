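test_that("Fermi impulse response is a delayed, normalised, decaying step", {
  p <- fermi_params(F = 0.12, k = 0.25, tau_d = 3, tau_0 = 5)
  expect_equal(fermi_h(c(0, 1, 2.999), p), c(0, 0, 0))
  expect_equal(fermi_h(3, p), 0.12)           # h(tau_d) = F, the read-off
  expect_lt(fermi_h(200, p), 1e-15)
  tt <- seq(3, 60, 0.5)
  expect_true(all(diff(fermi_h(tt, p)) < 0))
  expect_error(fermi_params(F = -1, k = 0.1), "non-negative")
})

test_that("model_tissue equals the brute-force rectangle-rule convolution", {
  # impulse identity: q is h sampled on the grid
  n <- 60
  imp <- signal_curve(0:(n - 1), c(1, numeric(n - 1)), roi = "imp")
  p <- fermi_params(F = 0.2, k = 0.3, tau_d = 2, tau_0 = 4)
  expect_equal(model_tissue(imp, p)$values, fermi_h(0:(n - 1), p),
               tolerance = 1e-12)

  set.seed(3)
  for (i in 1:5) {
    n <- sample(10:50, 1)
    dt <- sample(c(0.5, 1, 2), 1)
    x <- stats::runif(n)
    aif <- signal_curve(seq(0, by = dt, length.out = n), x, roi = "a")
    p <- fermi_params(stats::runif(1, 0, 1), stats::runif(1, 0, 1),
                      stats::runif(1, 0, 5), stats::runif(1, 0, 10))
    got <- model_tissue(aif, p)$values
    h <- fermi_h((0:(n - 1)) * dt, p)
    brute <- numeric(n)
    for (ii in 1:n) {
      for (jj in 1:ii) brute[ii] <- brute[ii] + dt * x[jj] * h[ii - jj + 1]
    }
    expect_equal(got, pmax(brute, 0), tolerance = 1e-10)
    # linearity in the arterial input
    aif2 <- signal_curve(aif$times, 3.7 * x, roi = "a")
    expect_equal(model_tissue(aif2, p)$values, 3.7 * got, tolerance = 1e-9)
  }
})

test_that("noiseless Fermi tissue curves return their own parameters", {
  aif <- gamma_aif()
  truth <- fermi_params(F = 0.1, k = 0.3, tau_d = 2, tau_0 = 4)
  tis <- model_tissue(aif, truth)
  fit <- fit_fermi(aif, tis)
  expect_true(fit$converged)
  for (nm in c("F", "k", "tau_d", "tau_0")) {
    expect_equal(fit$params[[nm]], truth[[nm]], tolerance = 1e-4)
  }
  expect_lt(fit$residual_rms, 1e-6)
})

test_that("perfusion of a simulated mono-exponential myocardium is recovered", {
  cfg <- default_config(left = 5)
  sim <- simulate_phantom(cfg, injection_protocol(dose = 0.01),
                          duration = 180)
  rr <- seq(0, 180, 1)
  aif <- signal_curve(rr, stats::approx(sim$aorta$times, sim$aorta$values,
                                        rr)$y, roi = "aorta")
  tis <- signal_curve(rr, stats::approx(sim$myo_left$times,
                                        sim$myo_left$values, rr)$y,
                      roi = "myo")
  fit <- fit_fermi(aif, tis)
  expect_equal(fit$perfusion, 5, tolerance = 0.10)
})

test_that("the estimate is scale invariant and robust to a 2 s delay", {
  aif <- gamma_aif()
  tis <- model_tissue(aif, fermi_params(F = 0.08, k = 0.12, tau_d = 1,
                                        tau_0 = 3))
  base <- fit_fermi(aif, tis)$perfusion

  scl <- function(cur, a) signal_curve(cur$times, a * cur$values, roi = "s")
  both <- fit_fermi(scl(aif, 137), scl(tis, 137))$perfusion
  expect_equal(both, base, tolerance = 1e-6)

  shifted <- signal_curve(tis$times,
                          c(0, 0, tis$values[1:(length(tis$values) - 2)]),
                          roi = "sh")
  expect_equal(fit_fermi(aif, shifted)$perfusion, base, tolerance = 0.05)
})

test_that("degenerate tissue curves are handled", {
  aif <- gamma_aif()
  zero <- signal_curve(aif$times, numeric(length(aif$times)), roi = "z")
  fit <- fit_fermi(aif, zero)
  expect_lt(fit$params$F, 1e-8)
})

test_that("dual-bolus assembly rescales the prebolus input", {
  tt <- 0:90
  pre <- signal_curve(tt, c(rep(10, 10),
                            10 + 1325 * pmax(0, stats::dgamma(tt[-(1:10)] - 15,
                                                              4, 0.5)) /
                              max(stats::dgamma(tt, 4, 0.5))),
                      roi = "aorta", baseline_n = 10)
  acq <- dual_bolus_acquisition(pre, pre, dose_ratio = 10)
  up <- assemble_aif(acq)
  expect_equal(max(up$values), 10 * peak_si(pre), tolerance = 1e-9)

  one <- assemble_aif(dual_bolus_acquisition(pre, pre, dose_ratio = 1))
  expect_equal(max(one$values), peak_si(pre), tolerance = 1e-9)

  zero <- signal_curve(tt, numeric(91), roi = "z")
  expect_equal(max(assemble_aif(dual_bolus_acquisition(zero, zero,
                                                       10))$values), 0)

  coarse <- signal_curve(seq(0, 90, 2), numeric(46), roi = "c")
  expect_error(dual_bolus_acquisition(pre, coarse, 10),
               "sampling interval")
})

test_that("perfusion read-off converts the onset height to mL/mL/min", {
  fit <- structure(list(params = fermi_params(F = 10 / 60, k = 0.2),
                        perfusion = 10, converged = TRUE,
                        residual_rms = 0, n_iter = 5L),
                   class = "fermi_fit")
  expect_equal(estimate_perfusion(fit), 10)
  fit$converged <- FALSE
  expect_error(estimate_perfusion(fit), "did not converge")
})
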