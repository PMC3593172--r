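# Shared fixtures, built in code. The calibrated signal model is cached per
# test session (calibration re-simulates the six-dose aortic series).

.twin_cache <- new.env(parent = emptyenv())

calibrated_model <- function() {
  if (is.null(.twin_cache$model)) {
    .twin_cache$model <- calibrate_signal_model()
  }
  .twin_cache$model
}

default_config <- function(right = 10, left = 10, cardiac_output = 3) {
  circuit_config(cardiac_output = cardiac_output,
                 perfusion_flow_right = perfusion_to_flow(right),
                 perfusion_flow_left = perfusion_to_flow(left))
}

# smooth gamma-variate test AIF on a 1 s grid, arbitrary units
gamma_aif <- function(n = 150, onset = 10, amplitude = 1000) {
  tt <- seq(0, n)
  signal_curve(tt, amplitude * pmax(0, stats::dgamma(tt - onset,
                                                     shape = 4,
                                                     scale = 2.5)),
               roi = "test_aif")
}
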