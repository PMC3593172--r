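test_that("relaxivity model is linear in concentration", {
  p <- signal_model_params(r1 = 5, R10 = 0.33)
  expect_equal(concentration_to_R1(0, p), 0.33)
  expect_equal(concentration_to_R1(1, p), 5.33)
  expect_equal(concentration_to_R1(2, p) - p$R10,
               2 * (concentration_to_R1(1, p) - p$R10))
})

test_that("saturation-recovery signal saturates monotonically", {
  sq <- sequence_params()
  p <- signal_model_params(scale = 1000)
  plateau <- 1000 * sin(15 * pi / 180)
  expect_equal(sr_signal(1e6, sq, p), plateau, tolerance = 1e-9)
  # linear regime: SI ~ scale sin(flip) TD R1 within 1% when TD R1 < 0.02
  r1_small <- 0.02 / 0.120
  expect_equal(sr_signal(r1_small, sq, p) / (plateau * 0.120 * r1_small), 1,
               tolerance = 0.011)
  # strictly increasing and concave in concentration
  cc <- seq(0, 12, 0.1)
  si <- sr_signal(concentration_to_R1(cc, p), sq, p)
  expect_true(all(diff(si) > 0))
  expect_true(all(diff(diff(si)) < 0))
})

test_that("signal equation inverts back to concentration", {
  sq <- sequence_params()
  p <- signal_model_params(r1 = 4.4, R10 = 0.4, scale = 25000)
  tt <- 0:80
  conc <- concentration_curve(tt, 2 * pmax(0, stats::dgamma(tt - 8, 3, 0.4)),
                              "aorta")
  back <- signal_to_concentration(concentration_to_signal(conc, sq, p), sq, p)
  expect_equal(back$values, conc$values, tolerance = 1e-9)
})

test_that("heartbeat sampling is seeded, reproducible and leaves the RNG alone", {
  sq <- sequence_params()
  cur <- gamma_aif()
  clean <- sample_and_noise(cur, sq, sigma = 0)
  expect_equal(clean$values, cur$values[cur$times %% 1 == 0],
               tolerance = 1e-12)

  a <- sample_and_noise(cur, sq, sigma = 10, seed = 42)
  b <- sample_and_noise(cur, sq, sigma = 10, seed = 42)
  expect_identical(a$values, b$values)
  expect_false(identical(a$values, clean$values))

  set.seed(99); before <- stats::runif(1)
  set.seed(99); invisible(sample_and_noise(cur, sq, sigma = 10, seed = 1))
  expect_identical(stats::runif(1), before)

  # realised noise SD close to sigma (chi-square bounds for n = 300)
  long <- signal_curve(0:299, rep(500, 300), roi = "flat")
  noisy <- sample_and_noise(long, sq, sigma = 10, seed = 7)
  expect_gt(stats::sd(noisy$values - 500), 8.5)
  expect_lt(stats::sd(noisy$values - 500), 11.5)
})

test_that("peak enhancement is measured above the pre-contrast baseline", {
  flat <- signal_curve(0:20, rep(120, 21), roi = "f", baseline_n = 10)
  expect_equal(peak_si(flat), 0)
  two <- signal_curve(0:1, c(100, 100), roi = "f", baseline_n = 2)
  expect_equal(peak_si(two), 0)
  bump <- signal_curve(0:20, c(rep(100, 10), 100 + 11:1), roi = "b",
                       baseline_n = 10)
  expect_equal(peak_si(bump), 11)
})

test_that("expected peaks and saturation ratios reproduce the dose arithmetic", {
  expect_equal(expected_peak(665, 0.0005, 0.001), 1330)
  expect_equal(expected_peak(665, 0.0005, 0.01), 13300)
  expect_equal(expected_peak(123, 0.004, 0.004), 123)
  expect_error(expected_peak(665, 0, 0.01), "positive")

  expect_equal(saturation_ratio(13300, 8365), 1.59)
  expect_equal(saturation_ratio(133000, 17894), 7.43)
  expect_equal(saturation_ratio(512, 512), 1)
  expect_error(saturation_ratio(100, 0), "positive")
})

test_that("calibration matches the measured dose series and flags degeneracy", {
  mod <- calibrated_model()
  cal <- attr(mod, "calibration")
  expect_true(attr(mod, "calibrated"))
  expect_true(cal$r1_identifiable)
  # simulated reference-dose peak within 2% of the measured 665 au
  expect_equal(cal$table$fitted_au[cal$table$dose_mmol_kg == 5e-4], 665,
               tolerance = 0.02)
  # fitted peaks track the measured ones over a 27-fold saturating range
  expect_true(all(abs(log(cal$table$fitted_au / cal$table$measured_au)) <
                    log(1.15)))

  # a perfectly linear measured table leaves the relaxivity unidentified
  lin <- data.frame(dose_mmol_kg = c(5e-4, 1e-3, 2.5e-3, 5e-3),
                    aif_peak_au = c(500, 1000, 2500, 5000))
  lin_mod <- calibrate_signal_model(lin, duration = 60)
  expect_false(attr(lin_mod, "calibration")$r1_identifiable)
  expect_equal(lin_mod$r1, 5.0)  # default retained
})

test_that("acquisitions are bit-identical for identical seeds and configs", {
  mod <- calibrated_model()
  cfg <- default_config()
  pr <- injection_protocol(dose = 0.001)
  a <- simulate_acquisition(cfg, pr, model = mod, seed = 11, duration = 60)
  b <- simulate_acquisition(cfg, pr, model = mod, seed = 11, duration = 60)
  expect_identical(a$aorta$values, b$aorta$values)
  expect_identical(a$myo_left$values, b$myo_left$values)
  c2 <- simulate_acquisition(cfg, pr, model = mod, seed = 12, duration = 60)
  expect_false(identical(a$aorta$values, c2$aorta$values))
})
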