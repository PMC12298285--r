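# atquant

Antithrombin (AT) activity quantification from photon-counting absorbance
traces, as acquired by a chromogenic anti-Xa assay on a digital-microfluidic
point-of-care device — together with a virtual instrument that simulates the
whole detection chain so the pipeline can be exercised and validated without
hardware.

**Who it is for:** developers and validators of photometric point-of-care
coagulation assays who need a tested reference implementation of the signal
chain from raw PMT counts to reported activity, and a ground-truth simulator
to probe it with.

## The model

AT neutralizes factor Xa 1:1; residual Xa cleaves a chromogenic substrate,
releasing yellow p-nitroaniline (pNA, absorbing at 405 nm), so the color
develops *faster* when AT activity is *lower*. The device reads the droplet
in a double-pass reflection–transmission geometry,

$$I_\mathrm{out} = I_\mathrm{in}\,e^{-\alpha l}\,r,$$

with $l$ twice the chamber gap and $r$ the electrode reflectance. All
detector constants cancel in the photon-count ratio, so the absorbance
change over the measurement window is simply

$$\Delta A = \log_{10}\frac{N(t_0)}{N(t_1)}, \qquad t_0 = 0\ \mathrm{s},\ t_1 = 60\ \mathrm{s},$$

after subtraction of the PMT dark-current mean. Activity follows by
inverting a linear calibration of rate on activity fraction
($y = a + b\,x$, $b < 0$; linearity acceptance $R^2 \ge 0.985$), fitted per
sample matrix (plasma, or 1:9-diluted whole blood). Method-validation
statistics — repeatability CV (acceptance ≤ 10%), two-sample KS
consistency, per-sample relative differences — are included.

## Worked example

Simulate a calibration set and an unknown sample at 82% activity, then run
the full pipeline — dark characterization, subtraction, rate, inverse
prediction:

```r
library(atquant)

cal_set <- simulate_calibration_set(noise_sd = 5e-4, seed = 11)
cal <- fit_calibration(cal_set$activity, cal_set$rate)
print(cal)
#> Calibration (plasma, n = 32): dA/min = 0.038089 - 0.026281 * activity
#>   R^2 = 0.9977 (bound 0.985) -> linearity PASS; Pearson r = -0.9988

run  <- simulate_run(kinetics_params(at_activity_fraction = 0.82),
                     noise = instrument_noise(seed = 12))
dark <- characterize_dark_current(simulate_dark_trace(instrument_noise(seed = 13)))
print(dark)
#> Dark current: 384470.25 +/- 571.82 counts/bin (mean +/- SD, n = 30)

rate <- compute_rate(subtract_dark(run$trace, dark))
print(rate)
#> delta A = 0.0166046 AU over [0, 60] s  ->  0.0166046 AU/min

print(invert_calibration(cal, rate$rate_per_min))
#> AT activity: 81.8% (rate 0.016605 AU/min, plasma calibration)
```

The fitted line recovers the generating plasma calibration
(intercept 0.0382, slope −0.02616) well within its standard errors; the
dark model recovers the instrument's characterized dark current
(384,460.71 ± 559.22 counts/bin); and the simulated 82%-activity sample
reads back as 81.8% after traversing the entire noisy chain —
count-level Poisson shot noise, Gaussian dark counts, dark subtraction,
the count-ratio law, and calibration inversion.

The same stages are scriptable through `run_pipeline()`
(`simulate | qc | process | calibrate | quantify | compare`) or the thin
CLI wrapper in `inst/cli/atquant.R`.

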