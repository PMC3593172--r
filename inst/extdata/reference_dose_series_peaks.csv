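# Measured peak signal intensities (au) from the hardware perfusion
# phantom's contrast-dose series: cardiac output 3 L/min, right and left
# myocardial perfusion 10 mL/mL/min, gadobutrol at 4 mL/s with 20 mL flush.
# Myocardial peaks were only acquired for 0.001-0.01 mmol/kg.
dose_mmol_kg,aif_peak_au,myo_peak_au
0.0005,665,NA
0.001,1335,125
0.0025,3308,327
0.005,5369,628
0.01,8365,1245
0.1,17894,NA
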