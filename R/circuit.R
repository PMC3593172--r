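#' Compartment specification
#'
#' One segment of the phantom's water circuit. Boxes (atria, ventricles) are
#' treated as well-mixed chambers (CSTRs); silicone/PVC tubes (vena cava,
#' pulmonary artery/vein, aorta, coronaries) as plug-flow delays.
#'
#' @param name Unique label within a circuit.
#' @param volume Inner volume in mL.
#' @param kind `"mixed"` (well-mixed chamber) or `"plug"` (plug-flow tube).
#' @return A `compartment` object.
#' @examples
#' compartment("aorta", 36, "plug")
#' @export
compartment <- function(name, volume, kind = c("mixed", "plug")) {
  kind <- match.arg(kind)
  if (!is.numeric(volume) || length(volume) != 1L || volume <= 0) {
    stop("compartment volume must be a single positive number (mL)",
         call. = FALSE)
  }
  structure(list(name = name, volume = volume, kind = kind),
            class = "compartment")
}

#' Circuit configuration
#'
#' The default cascade reproduces the physiologically sized hardware
#' phantom: vena cava (26 mL tube), right atrium (105 mL box), right
#' ventricle (120 mL box), pulmonary artery/vein (88 mL tube), left atrium
#' (105 mL box), left ventricle (120 mL box) and aorta (36 mL tube, up to
#' the coronary take-off), followed by a 5.8 mL coronary tube feeding each
#' myocardial compartment (45 mL distribution volume).
#'
#' @param cardiac_output Main pump flow in L/min (hardware range 2-11).
#' @param perfusion_flow_right,perfusion_flow_left Myocardial flows in
#'   L/min (hardware range 0.035-0.45; 0.45 L/min over 45 mL is
#'   10 mL/mL/min).
#' @param cascade Ordered list of [compartment()]s from injection point to
#'   AIF sampling point.
#' @param coronary Coronary [compartment()] (traversed at the myocardial
#'   perfusion flow).
#' @param distribution_volume Myocardial distribution volume V_d in mL.
#' @param mode `"open"` (washout to waste; all validated behaviour) or
#'   `"closed"` (recirculation flag; untested against hardware data).
#' @param tube_dispersion_n Number of serial mixing segments per tube;
#'   1 = pure delay (default), larger values soften the bolus front.
#' @return A `circuit_config` object.
#' @examples
#' cfg <- circuit_config(cardiac_output = 3,
#'                       perfusion_flow_right = 0.45,
#'                       perfusion_flow_left = 0.45)
#' @export
circuit_config <- function(cardiac_output = 3,
                           perfusion_flow_right = 0.45,
                           perfusion_flow_left = 0.45,
                           cascade = default_cascade(),
                           coronary = compartment("coronary", 5.8, "plug"),
                           distribution_volume = 45,
                           mode = c("open", "closed"),
                           tube_dispersion_n = 1L) {
  mode <- match.arg(mode)
  stopifnot(is.list(cascade), length(cascade) >= 1L)
  for (comp in cascade) {
    if (!inherits(comp, "compartment")) {
      stop("`cascade` must be a list of compartment() objects", call. = FALSE)
    }
  }
  nm <- vapply(cascade, `[[`, "", "name")
  if (anyDuplicated(c(nm, coronary$name))) {
    stop("compartment names must be unique within a circuit", call. = FALSE)
  }
  if (cardiac_output <= 0) stop("cardiac_output must be positive", call. = FALSE)
  if (cardiac_output < 2 || cardiac_output > 11) {
    warning("cardiac_output outside the hardware's 2-11 L/min range")
  }
  for (pf in c(perfusion_flow_right, perfusion_flow_left)) {
    if (pf <= 0) stop("perfusion flows must be positive", call. = FALSE)
    if (pf < 0.035 || pf > 0.45) {
      warning("perfusion flow outside the hardware's 0.035-0.45 L/min range")
    }
  }
  if (perfusion_flow_right + perfusion_flow_left >= cardiac_output) {
    stop("combined myocardial flow must be below the cardiac output",
         call. = FALSE)
  }
  if (distribution_volume <= 0) {
    stop("distribution_volume must be positive", call. = FALSE)
  }
  structure(
    list(cascade = cascade, coronary = coronary,
         cardiac_output = cardiac_output,
         perfusion_flow_right = perfusion_flow_right,
         perfusion_flow_left = perfusion_flow_left,
         distribution_volume = distribution_volume,
         mode = mode, tube_dispersion_n = as.integer(tube_dispersion_n)),
    class = "circuit_config"
  )
}

#' @rdname circuit_config
#' @export
default_cascade <- function() {
  list(
    compartment("vena_cava", 26, "plug"),
    compartment("right_atrium", 105, "mixed"),
    compartment("right_ventricle", 120, "mixed"),
    compartment("pulmonary", 88, "plug"),
    compartment("left_atrium", 105, "mixed"),
    compartment("left_ventricle", 120, "mixed"),
    compartment("aorta", 36, "plug")
  )
}

#' Contrast injection protocol
#'
#' Body-weight-adjusted gadobutrol bolus delivered by a power injector
#' through a three-way stopcock just before the vena cava, followed by a
#' saline flush. A dual-bolus acquisition precedes the main bolus with a
#' diluted prebolus carrying `prebolus_fraction` of the dose.
#'
#' @param dose Dose in mmol/kg body weight.
#' @param body_weight Subject weight in kg (the phantom is sized for 60 kg).
#' @param agent_concentration Stock agent concentration in mmol/mL
#'   (gadobutrol: 1.0).
#' @param injection_rate Injector flow in mL/s.
#' @param flush_volume Saline flush in mL.
#' @param prebolus_fraction Prebolus dose as a fraction of `dose`.
#' @param inter_bolus_gap Pause between prebolus and main bolus in s (the
#'   injector is programmed to wait for complete washout).
#' @return An `injection_protocol` object.
#' @examples
#' injection_protocol(dose = 0.01)
#' @export
injection_protocol <- function(dose,
                               body_weight = 60,
                               agent_concentration = 1.0,
                               injection_rate = 4,
                               flush_volume = 20,
                               prebolus_fraction = 0.10,
                               inter_bolus_gap = 300) {
  if (!is.numeric(dose) || length(dose) != 1L || !is.finite(dose) || dose < 0) {
    stop("invalid protocol: dose must be a single finite number >= 0",
         call. = FALSE)
  }
  if (injection_rate <= 0) {
    stop("invalid protocol: injection_rate must be positive", call. = FALSE)
  }
  if (prebolus_fraction < 0 || prebolus_fraction > 1) {
    stop("invalid protocol: prebolus_fraction must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(dose = dose, body_weight = body_weight,
         agent_concentration = agent_concentration,
         injection_rate = injection_rate, flush_volume = flush_volume,
         prebolus_fraction = prebolus_fraction,
         inter_bolus_gap = inter_bolus_gap),
    class = "injection_protocol"
  )
}

#' Concentration at the circuit inlet
#'
#' Rectangular concentration pulse produced by injecting the agent at
#' `injection_rate` into the main flow at the stopcock: while the injector
#' runs, the mixed concentration is
#' `rate * agent_concentration / (Q_main + rate)`. The agent leaves the
#' injector in `injected volume / rate` seconds (0.15 s at 0.01 mmol/kg),
#' during which the contrast-laden parcel occupies `(Q_main + rate)` times
#' that volume of circuit water; carried downstream at `Q_main`, it passes
#' a fixed point in `(Q_main + rate) / Q_main` times the injector time, so
#' the returned pulse is stretched by that factor and
#' `integral C Q_main dt` equals dose times body weight exactly. The pulse
#' is rasterised onto the simulation grid area-preservingly, so sub-sample
#' pulses (very low doses) keep the correct mass. The flush is a
#' continuation of the main flow.
#'
#' @param protocol An [injection_protocol()].
#' @param config A [circuit_config()].
#' @param duration Simulated duration in s.
#' @param dt Simulation grid step in s (0.05 s resolves clinical-dose
#'   pulses of 0.15 s).
#' @param onset Injection start time in s (pre-contrast baseline period).
#' @return A [concentration_curve()] at location `"inlet"`.
#' @export
inlet_concentration <- function(protocol, config, duration = 180,
                                dt = 0.05, onset = 10) {
  stopifnot(inherits(protocol, "injection_protocol"),
            inherits(config, "circuit_config"))
  times <- seq(0, duration, by = dt)
  v_inj <- protocol$dose * protocol$body_weight / protocol$agent_concentration
  q_main <- flow_ml_s(config$cardiac_output)
  # injector time stretched by the parcel-volume factor (see Details)
  t_inj <- v_inj / protocol$injection_rate *
    (q_main + protocol$injection_rate) / q_main
  conc <- protocol$injection_rate * protocol$agent_concentration /
    (q_main + protocol$injection_rate) * 1000  # mmol/mL -> mmol/L
  # area-preserving rasterisation of the rectangle [onset, onset + t_inj)
  lo <- pmax(times, onset)
  hi <- pmin(times + dt, onset + t_inj)
  values <- conc * pmax(hi - lo, 0) / dt
  concentration_curve(times, values, "inlet")
}

#' Propagate a concentration curve through one compartment
#'
#' A well-mixed chamber obeys `dC/dt = (Q/V) (C_in - C)` with `C(0) = 0`
#' (exact exponential update per step, trapezoidal input); a plug-flow tube
#' delays its input by the transit time `V/Q`. Both conserve tracer mass.
#'
#' @param curve Input [concentration_curve()].
#' @param comp A [compartment()].
#' @param flow Flow through the compartment in L/min.
#' @param n_segments For plug tubes only: number of serial mixing segments
#'   used to soften the front; 1 (default) is a pure delay.
#' @return The outflow [concentration_curve()], located at `comp$name`.
#' @export
propagate <- function(curve, comp, flow, n_segments = 1L) {
  stopifnot(inherits(curve, "concentration_curve"),
            inherits(comp, "compartment"))
  if (!is.numeric(flow) || length(flow) != 1L || flow <= 0) {
    stop("invalid flow: must be a single positive number (L/min)",
         call. = FALSE)
  }
  q <- flow_ml_s(flow)
  out <- curve$values
  if (comp$kind == "plug" && n_segments <= 1L) {
    delay <- comp$volume / q
    out <- stats::approx(curve$times, curve$values,
                         xout = curve$times - delay,
                         yleft = 0, rule = 1)$y
    out[is.na(out)] <- 0
  } else {
    n <- if (comp$kind == "mixed") 1L else as.integer(n_segments)
    k <- q / (comp$volume / n)          # per-segment rate constant, 1/s
    a <- exp(-k * curve$dt)
    for (i in seq_len(n)) {
      mid <- (out + c(0, out[-length(out)])) / 2
      out <- as.numeric(stats::filter((1 - a) * mid, a, method = "recursive"))
    }
  }
  concentration_curve(curve$times, out, comp$name)
}

#' Simulate bolus transit through the whole circuit
#'
#' Chains [propagate()] over the cascade at the cardiac output, returning
#' the arterial input function sampled in the proximal aorta (before the
#' coronary take-off) and the myocardial inflow after the coronary tube,
#' which is traversed at the compartment's perfusion flow and therefore
#' adds a perfusion-dependent arrival delay.
#'
#' @inheritParams inlet_concentration
#' @param side `"left"` or `"right"` myocardial compartment for the
#'   returned inflow curve.
#' @return List with elements `aorta` and `myo_inflow`
#'   ([concentration_curve()]s).
#' @export
simulate_circuit <- function(config, protocol, duration = 180,
                             dt = 0.05, onset = 10, side = c("left", "right")) {
  side <- match.arg(side)
  cur <- inlet_concentration(protocol, config, duration = duration,
                             dt = dt, onset = onset)
  for (comp in config$cascade) {
    cur <- propagate(cur, comp, config$cardiac_output,
                     n_segments = config$tube_dispersion_n)
  }
  aorta <- cur
  aorta$location <- "aorta"
  pf <- if (side == "left") config$perfusion_flow_left else
    config$perfusion_flow_right
  myo_in <- propagate(aorta, config$coronary, pf,
                      n_segments = config$tube_dispersion_n)
  myo_in$location <- paste0("myo_inflow_", side)
  list(aorta = aorta, myo_inflow = myo_in)
}

#' Myocardial compartment concentration
#'
#' The myocardial space acts as a single well-mixed compartment of volume
#' `V_d` perfused at `perfusion_flow`; its impulse response is the
#' mono-exponential `(F/V_d) exp(-(F/V_d) t)`. The compartment is uniform,
#' so the concentration at the imaging plane equals the compartment
#' concentration.
#'
#' @param myo_inflow Inflow [concentration_curve()] (aortic curve after the
#'   coronary tube).
#' @param perfusion_flow Myocardial flow in L/min.
#' @param V_d Distribution volume in mL (45 in the hardware).
#' @return A [concentration_curve()] at the imaging plane.
#' @export
myocardial_curve <- function(myo_inflow, perfusion_flow, V_d = 45) {
  if (!is.numeric(V_d) || length(V_d) != 1L || V_d <= 0) {
    stop("invalid config: V_d must be positive", call. = FALSE)
  }
  out <- propagate(myo_inflow, compartment("myocardium", V_d, "mixed"),
                   perfusion_flow)
  out$location <- sub("myo_inflow", "myocardium", myo_inflow$location)
  out
}

#' Simulate the full phantom: AIF plus both myocardial compartments
#'
#' Convenience wrapper running [simulate_circuit()] and [myocardial_curve()]
#' for both myocardial compartments.
#'
#' @inheritParams simulate_circuit
#' @return List with concentration curves `aorta`, `myo_right`, `myo_left`.
#' @export
simulate_phantom <- function(config, protocol, duration = 180,
                             dt = 0.05, onset = 10) {
  left <- simulate_circuit(config, protocol, duration, dt, onset, "left")
  right_in <- propagate(left$aorta, config$coronary,
                        config$perfusion_flow_right,
                        n_segments = config$tube_dispersion_n)
  list(
    aorta = left$aorta,
    myo_right = myocardial_curve(right_in, config$perfusion_flow_right,
                                 config$distribution_volume),
    myo_left = myocardial_curve(left$myo_inflow, config$perfusion_flow_left,
                                config$distribution_volume)
  )
}

#' Convert a myocardial flow to a perfusion rate
#'
#' Perfusion is flow per millilitre of distribution volume:
#' `flow * 1000 / V_d`. The hardware's 0.035-0.45 L/min over 45 mL spans
#' 0.8-10 mL/mL/min.
#'
#' @param flow Myocardial flow in L/min.
#' @param V_d Distribution volume in mL.
#' @return Perfusion rate in mL/mL/min.
#' @examples
#' flow_to_perfusion(0.45, 45)  # 10
#' @export
flow_to_perfusion <- function(flow, V_d = 45) {
  if (!is.numeric(V_d) || any(V_d <= 0)) {
    stop("invalid config: V_d must be positive", call. = FALSE)
  }
  flow * 1000 / V_d
}

#' @rdname flow_to_perfusion
#' @param perfusion Perfusion rate in mL/mL/min.
#' @export
perfusion_to_flow <- function(perfusion, V_d = 45) {
  if (!is.numeric(V_d) || any(V_d <= 0)) {
    stop("invalid config: V_d must be positive", call. = FALSE)
  }
  perfusion * V_d / 1000
}

#' Stroke volume from cardiac output and heart rate
#'
#' @param cardiac_output Cardiac output in L/min.
#' @param heart_rate Simulated heart rate in beats per minute.
#' @return Stroke volume in mL, rounded to the nearest integer.
#' @examples
#' stroke_volume(4, 60)  # 67
#' @export
stroke_volume <- function(cardiac_output, heart_rate = 60) {
  if (any(heart_rate <= 0)) stop("heart_rate must be positive", call. = FALSE)
  round(cardiac_output * 1000 / heart_rate)
}
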