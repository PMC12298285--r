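---
title: "Methods: photon-count photometry and AT activity quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: photon-count photometry and AT activity quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atquant)
```

## The assay and its observable

Antithrombin (AT) is a serine-protease inhibitor; its activity, expressed as
a percentage of a calibrator (normal range roughly 80–120%), is measured by
a chromogenic anti-Xa assay. Factor Xa is supplied in excess; AT (potentiated
by heparin) neutralizes it in a 1:1 complex, and the *residual* Xa cleaves a
chromogenic peptide substrate, releasing yellow p-nitroaniline (pNA), which
absorbs at 405 nm. The faster the color develops, the *lower* the AT
activity — the calibration slope is negative.

On the digital-microfluidic device this package models, absorbance is not
read by a spectrophotometer but by photon counting: a 405 nm
bandpass-filtered beam crosses the droplet, reflects off the bottom
electrode, crosses the droplet a second time, and a photomultiplier tube
(PMT) counts transmitted photons in 1000 ms bins. For this
reflection–transmission geometry the modified Beer–Lambert law is

$$ I_\mathrm{out} = I_\mathrm{in}\, e^{-\alpha l}\, r, $$

with $\alpha$ the solution absorption coefficient, $l$ the *total*
(double-pass) path — twice the chamber gap — and $r$ the electrode
reflectance. Because $r$, the detector area, and the photon energy
$hf = hc/\lambda$ are constants, they all cancel in the ratio of two photon
counts, giving the package's central identity:

$$ \Delta A = A(t_1) - A(t_0) = \log_{10} \frac{N(t_0)}{N(t_1)}. $$

The assay observable is $\Delta A/\mathrm{min}$ over the window
$t_0 = 0$ s to $t_1 = 60$ s. Activity is then obtained by inverting a
linear calibration $y = a + b\,x$ of rate $y$ on activity fraction $x$
(classical calibration: the line is fitted in the forward direction and
inverted algebraically, not refitted as activity-on-rate).

`delta_absorbance()` is deliberately strict: zero or negative counts raise
an error rather than being clamped, because a silent clamp would bias
$\Delta A$ systematically upward in low-signal droplets.

## Units: activity is a fraction

All calibration math takes activity as a *fraction* (1.0 = 100%). With
activity in percent, the plasma calibration
$y = 0.0382 - 0.02616\,x$ would predict negative rates for every activity
above 1.46%, which is physically impossible; as a fraction the line spans
exactly the clinically relevant 0–146% range before the rate crosses zero.
Reported results carry both `activity_fraction` and `activity_percent`.

## Trace processing and QC

* **Dark current.** The PMT registers counts with the source blocked; a
  30-bin dark acquisition is summarized as mean ± sample SD (the
  characterized instrument values are 384,460.71 ± 559.22 counts/bin) and
  the scalar mean is subtracted from every bin. A scalar suffices because
  the dark CV is ~0.15%; negative corrected counts are retained with a
  warning (clamping would bias low-signal rates), and rate computation
  rejects nonpositive endpoint counts.
* **Saturation.** Counts saturate when the lamp voltage strictly exceeds
  2.45 V; the threshold itself is usable, and the default operating voltage
  is 2.44 V. Saturated traces are rejected before rate computation. No PMT
  nonlinearity is modeled below the threshold.
* **Source stability.** Empty-chip traces are summarized as CV% with an
  acceptance bound of 0.5% (the characterized source runs at CV ≈ 0.1%,
  mean ≈ 2.44×10⁷ counts/bin).
* **Temperature.** Source counts drift linearly with ambient temperature
  (≈7704.5 counts/°C on an intercept of 2.358×10⁷ — about 0.03%/°C).
  Because the count *ratio* is what matters, this drift is negligible over
  a 60 s window, so `correct_temperature()` exists but is off by default in
  the pipeline.
* **Endpoint selection.** `compute_rate()` takes the bin nearest each
  window endpoint (ties to the earlier bin) without interpolation: with
  1000 ms bins the worst-case timing error is 0.5 s over a 60 s window,
  i.e. below 1% of the rate.

Statistics conventions: sample SD (n − 1) throughout; repeatability is
CV% = 100·SD/mean with the pharmacopoeial acceptance CV ≤ 10%; calibration
linearity acceptance is R² ≥ 0.985; relative differences against a
reference instrument are 100·|ref − test|/ref, displayed rounded half-up to
one decimal (full precision is always retained — published comparison
tables are not always internally consistent under a single rounding
convention, so worked examples use entries robust to the choice). The
two-sample Kolmogorov–Smirnov consistency check uses the asymptotic
p-value; with ~30 samples per arm the exact small-sample correction is
immaterial.

## The virtual instrument

No public photon-trace data exist for this device class, so the package
carries a forward simulator that stands in for the hardware, with ground
truth retained at every stage:

1. **Kinetics** (`simulate_reaction`): residual enzyme after instantaneous
   stoichiometric 1:1 inhibition, $E_\mathrm{res} = \max(0, E_0 - \kappa
   a)$, drives Michaelis–Menten substrate turnover, integrated with
   `deSolve::ode` (lsoda, tolerances 1e-10). A `second_order` mode runs
   complexation and turnover concurrently for kinetics exploration; it is
   not used in validation.
2. **Optics** (`concentration_to_absorbance`): $A(t) = \varepsilon\,
   [\mathrm{pNA}](t)\, l_\mathrm{total} +$ static interferent $+$ drift
   $\cdot t/60$.
3. **Counting** (`simulate_trace`): expected transmitted counts are the
   temperature-adjusted source mean times $10^{-A(t)}$; recorded counts
   are Poisson draws around that expectation, plus Gaussian dark counts.

Parameter choices, made once:

* **Rate scale.** No rate constants are published for this reagent set, so
  kinetics defaults (kcat = 1.0992 µM s⁻¹ per enzyme unit, Km = 50 µM,
  substrate 2000 µM, inhibition capacity 0.6848 enzyme units per activity
  fraction) were chosen so the simulated observable reproduces the plasma
  calibration scale: ≈0.038 AU/min at 0% activity, ≈0.012 AU/min at 100%,
  zero just past 146%. The substrate is ~40× Km so the first minute is
  within 1% of zero-order, matching the linearity of the real assay.
* **pNA absorptivity** defaults to the standard literature value
  9.9×10³ M⁻¹cm⁻¹ (990 M⁻¹mm⁻¹); configurable.
* **Chamber gap.** The physical gap is not published; the default is
  0.3 mm (typical for two-plate electrowetting chips). Absolute
  absorbances therefore carry an arbitrary scale, but every ΔA-level
  quantity is gap-independent once the simulator and the processor share a
  configuration.
* **Dark counts are Gaussian, not Poisson**: the characterized dark SD
  (559) is far below Poisson for its mean (√384461 ≈ 620 would be the
  shot-noise floor of the *photon* part alone, and the measured dispersion
  reflects the full electronics chain), so the measured moments are used
  directly.
* **Whole blood** adds a static hemoglobin baseline (default 1.2 AU
  undiluted, scaled by 1/dilution) and scales the kinetic amplitude to the
  diluted regime; the standard plan is 1 part blood + 9 parts diluent
  on-chip (factor 10). Activity is always read against a calibration built
  in the same matrix and dilution regime, so no ×10 back-multiplication is
  applied — activity is a relative quantity. The true mapping from
  hemoglobin content to baseline absorbance in this geometry is not
  published; it is a free parameter here.
* **Interferents.** Icteric and hemolyzed samples are modeled as *static*
  additive absorbance — which provably cancels in ΔA, reproducing the
  observation that such samples read correctly. Lipemic (chylous) samples
  are modeled as a slow absorbance *drift*, which adds its own magnitude
  to the measured rate and so degrades accuracy; this is the simulator's
  deliberate representation of the one failure mode this assay class shows.
* **RNG.** One seed per simulated acquisition, default 20250630; identical
  seeds reproduce traces bit-for-bit at the count level.

What the simulator does *not* emulate: droplet transport and mixing
dynamics, evaporation, spectral width of the 10 nm bandpass
(monochromatic approximation), PMT dead time, and spatial beam effects.
Passing tests therefore validate the *signal chain* — counts to activity —
under realistic noise magnitudes, not the fluidics or optics hardware.

## Validation design and problem sizes

The test suite works at desk scale: calibration recovery uses the standard
4-level (25/50/75/100%) × 8-replicate design with rate noise SD 5×10⁻⁴
AU/min (about 2% of the mid-range rate, consistent with the observed 3%
repeatability CVs); temperature recovery uses 5 temperatures with count
noise SD 5000; dark recovery uses 30 bins; the long-run recovery property
uses 200 seeded replicates and requires the fitted slope and intercept
within ±3 SE of truth in ≥99% of them. Poisson-law checks use 400–500 bins
and a 3× Monte-Carlo-error band. The noiseless end-to-end identity
(simulate → process vs. the analytic double-pass Beer–Lambert value) is
held to 1e-8 AU/min; pure-algebra identities (reflectance cancellation,
round-trip inversion) to 1e-10 or tighter.

`scripts/acceptance.R` re-runs the recovery computations from scratch
against the installed package with a caller-supplied seed and writes the
recovered quantities as JSON.

## Known limitations

* Absolute α and absolute absorbance depend on the unpublished chamber
  gap; only ratio-level quantities are meaningful across devices.
* The asymptotic KS p-value is anticonservative below ~n = 10 per arm.
* The instantaneous-inhibition default ignores the finite AT–Xa
  complexation rate; if complexation were slow on the 60 s scale the early
  rate would be biased toward lower apparent activity. The `second_order`
  mode exists to explore this.
* Clinical regressions on real patient samples (and their R², Pearson and
  KS figures) require the physical device; the package validates the
  computational pipeline by parameter recovery on synthetic data at the
  instrument's characterized noise levels instead.
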