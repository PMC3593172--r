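# perfusiontwin

A digital twin of a hardware flow phantom for first-pass myocardial
perfusion MR. Hardware phantoms of this kind pump water through a
physiologically sized replica of the thoracic circulation (vena cava,
four cardiac chambers, pulmonary vessels, aorta) and through two
"myocardial" compartments whose perfusion flows are set and measured
exactly — giving quantitative perfusion imaging something it otherwise
lacks: a true gold standard. `perfusiontwin` reproduces that whole
measurement chain in software, for people developing or stress-testing
perfusion quantification methods:

1. **Indicator dilution** — a gadobutrol bolus (dose in mmol/kg for a
   60 kg subject, injected at 4 mL/s with a 20 mL flush) is mixed and
   diluted through the compartment cascade; chambers are well-mixed
   (`dC/dt = (Q/V)(C_in − C)`), vessels are plug-flow delays. The aortic
   curve is the arterial input function (AIF); the myocardium is a single
   well-mixed compartment of distribution volume `V_d = 45` mL with
   mono-exponential impulse response `(F/V_d) e^{−(F/V_d)t}`, so
   0.035–0.45 L/min maps to perfusion of 0.8–10 mL/mL/min.
2. **MR signal** — saturation-recovery gradient echo,
   `SI = s·sin(α)·(1 − e^{−T_D(R10 + r1·c)})` (T_D = 120 ms, α = 15°),
   sampled once per heartbeat at 60 bpm with seeded Gaussian noise.
   `calibrate_signal_model()` anchors `s` and `r1` to a measured
   dose-series peak table shipped with the package.
3. **Quantification** — dual-bolus Fermi-constrained deconvolution: a 10%
   prebolus provides an unsaturated AIF that is rescaled by the dose
   ratio; the tissue impulse response
   `h(t) = θ(t−τ_d)·F·(1+e^{−kτ_0})/(1+e^{k(t−τ_d−τ_0)})` is fitted by
   bounded least squares and perfusion is read off as `60·F` mL/mL/min at
   the delay-corrected onset.
4. **Experiments** — the standard phantom characterisation protocols:
   contrast-dose series (saturation ratios), perfusion-rate series
   (recovery vs gold standard, ANOVA), cardiac-output sensitivity and
   reproducibility (pairwise adjusted R²), plus a synthetic transverse
   image renderer with ROI extraction.

## Worked example

```r
library(perfusiontwin)

## calibrate the signal model against the measured dose-series peaks
model <- calibrate_signal_model()

## dose sensitivity: saturation ratios (expected / observed peak)
run_dose_series(model, quantify_doses = NULL)$table
#>  dose_mmol_kg aif_peak_au aif_expected_au aif_saturation_ratio myo_saturation_ratio
#>        0.0005       660.7           660.7                 1.00                 0.99
#>        0.0010      1296.2          1321.5                 1.02                 1.00
#>        0.0025      3060.2          3303.7                 1.08                 1.04
#>        0.0050      5579.0          6607.3                 1.18                 1.10
#>        0.0100      9357.5         13214.7                 1.41                 1.24
#>        0.1000     17249.6        132146.7                 7.66                 4.92

## perfusion recovery: simulate dual-bolus acquisitions at known rates,
## quantify them blind, compare to the gold standard
res <- run_perfusion_series(model, rates = c(1, 5, 10),
                            n_replicates = 6, base_seed = 20260101)
res$table
#>  truth_ml_ml_min mean_perfusion sd_perfusion n
#>                1          0.946       0.0051 6
#>                5          4.627       0.0234 6
#>               10          8.904       0.0572 6
res$anova$p
#> 1.1e-30
```

Reading: the AIF is linear at the lowest doses (ratio ≈ 1) and saturates
progressively above 0.0025 mmol/kg; the dual-bolus Fermi pipeline
recovers the gold-standard rates with small replicate scatter and a
rate-dependent negative bias (largest around 7.5–10 mL/mL/min) that is a
property of fitting a Fermi response to an idealised mono-exponential
compartment — the vignette
(`vignettes/perfusion-twin-methods.Rmd`) quantifies this and the other
deliberate departures from the hardware.

Single acquisitions are also first-class:

```r
cfg <- circuit_config(cardiac_output = 3,
                      perfusion_flow_right = perfusion_to_flow(10),
                      perfusion_flow_left = perfusion_to_flow(5))
acq <- simulate_acquisition(cfg, injection_protocol(dose = 0.01),
                            model = model, seed = 7)
stack <- render_image_series(list(aorta = acq$aorta,
                                  myo_right = acq$myo_right,
                                  myo_left = acq$myo_left))
extract_roi(stack, "myo_left")   # ROI mean time-intensity curve
```

## Acceptance script

`scripts/acceptance.R` replays the headline recovery experiments end to
end — calibrate, simulate the dual-bolus acquisitions at gold-standard
rates 10 and 5 mL/mL/min and at dose 0.01 mmol/kg, fit the Fermi model,
average over six noise replicates — and writes the resulting mean
perfusion estimates as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
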