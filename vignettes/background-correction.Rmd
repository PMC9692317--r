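---
title: "Histogram-subtraction background correction for millisecond SP-ICP-MS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Histogram-subtraction background correction for millisecond SP-ICP-MS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6, fig.height = 3.5)
library(spicpms)
library(ggplot2)
```

## The problem

In single-particle ICP-MS a dilute nanoparticle suspension is nebulised into
the plasma and the detector is read out in short, contiguous dwell-time
windows (here 1–20 ms). Each particle that reaches the plasma vaporises into
a burst of ions much shorter than one window, so a particle shows up as a
single window whose count is the sum of the particle pulse and whatever the
dissolved background contributed to that window. Dissolved analyte and
isobaric interferents produce counts in *every* window, Poisson-distributed
with a mean that grows linearly with the dwell time.

For an element like titanium measured at m/z 48 the dissolved background is
substantial, and for realistic TiO~2~ size distributions the low-intensity
end of the particle signals overlaps the high-intensity wing of the
background. The classical discriminator — flag windows above
`mean + n * sd` of a blank — is then ambiguous: a small `n` keeps
false-positive background windows, a large `n` throws away genuine small
particles, and the threshold itself inflates with dwell time because the
background's standard deviation does. `nsigma_threshold()` and
`poisson_threshold()` implement these classical rules for comparison.

## The correction

Everything happens on *frequency–intensity distributions*: histograms, with
bin width one count, of how many windows registered each integer count value
(`build_distribution()`). Given a sample histogram and a blank histogram
acquired with the same number of windows `N` at the same dwell time:

1. **Raw difference.** Subtract the blank from the sample bin by bin
   (`subtract_distributions()`). Frequencies sum to zero; the mass of the
   negative range equals the mass of the positive range, and both equal the
   number of windows whose background draw was displaced upward by a
   particle. That negative mass is the particle count
   (`particle_count()`): `N_NP`.
2. **Background count.** `N_bgd = N - N_NP`.
3. **Rescale the blank.** The sample contains only `N_bgd` background draws,
   so each blank frequency is multiplied by `N_bgd / N`
   (`scale_background()`). Frequencies are kept fractional here — rounding
   would break the identity that they sum to `N_bgd`.
4. **Corrected difference.** Subtract the rescaled blank from the sample
   (`corrected_sample()`). In expectation only particle signal remains.
   Where small particles hide inside the background body a small negative
   residual survives; it is reported in the diagnostics (and is visibly
   smaller than the raw difference's negative range), never silently
   clipped away from the record.
5. **Transition intensity and net pulses.** The largest intensity with a
   negative corrected frequency (`transition_intensity()`) separates the
   background-dominated from the particle-dominated range; with several sign
   changes the largest negative intensity governs (the conservative
   reading). Windows strictly above it are particle candidates. Each
   candidate's net intensity is its gross count minus the *modal* blank
   intensity (`modal_background()`), the fractional corrected frequency
   rounded half-up to a non-negative integer giving its multiplicity. Net
   values below one count are indistinguishable from background and
   dropped.

`run_correction()` executes the chain once, in this order, and returns all
intermediate objects. The particle count is not iterated to a fixed point:
the single pass mirrors how the procedure is defined, and on all simulated
data the first pass is already consistent (`N_NP + N_bgd = N` holds exactly
by construction).

```{r worked}
sample <- intensity_distribution(c(0, 1, 2), c(5, 3, 2))
blank <- intensity_distribution(c(0, 1), c(6, 4))
run_correction(sample, blank)
```

This ten-window example can be traced by hand: the raw difference is
{0: −1, 1: −1, 2: +2}, so `N_NP = 2` and `N_bgd = 8`; the blank rescaled by
8/10 is {0: 4.8, 1: 3.2}; the corrected difference {0: +0.2, 1: −0.2, 2: +2}
puts the transition at 1 count; the two windows at 2 counts are particles
with net intensity 2 − 0 = 2.

### Interpretation choices

Two points in the procedure are genuinely open and were fixed as follows.

* **"Mean intensity at the maximum" of the blank distribution** is read as
  the modal intensity (argmax of the histogram, smallest intensity on ties).
  The alternative reading — the mean of the signals sitting in the modal
  bin — is numerically identical for integer bins. The gap between the mode
  and the transition intensity is surfaced as a diagnostic warning when it
  exceeds 2 counts; for well-separated particle populations a large gap is
  expected and harmless, because the transition point then sits at the upper
  edge of the background rather than at its body.
* **Fractional corrected frequencies** are carried as real numbers through
  the whole chain and rounded (half-up, floored at zero) only when pulses
  are enumerated into the per-particle net intensity list. Premature
  rounding breaks the conservation identities that the tests pin down.

## From counts to diameters

The calibration chain is indirect, because monodisperse TiO~2~ standards are
not available:

* `particle_mass()` / `particle_size()` convert between diameter and mass of
  an equivalent sphere, `m = d^3 * pi * rho / 6`, with TiO~2~ density
  4.23 g/cm³.
* `transport_efficiency()` measures the fraction of nebulised material that
  reaches the detector from a particle-number standard (a 60 nm silver
  dispersion of known concentration; silver density 10.49 g/cm³ is the
  standard literature value, stored on the standard object and overridable).
* `mass_per_window()` turns a dissolved-standard concentration into the
  element mass actually reaching the detector per window,
  `m = eta_TE * V * t_dt * C`, and `fit_sensitivity()` regresses the mean
  blank-subtracted intensity on that mass, through the origin — a zero
  concentration must map to zero detected mass, so the transformed
  calibration line has no intercept. The slope is the sensitivity in counts
  per gram of element.
* `intensity_to_size()` divides net counts by the sensitivity, scales the
  element mass by the TiO~2~/Ti mass ratio (1.67 by convention;
  `tio2_ti_mass_ratio(exact = TRUE)` gives the full-precision 1.6685
  computed from standard atomic weights), and inverts the sphere formula.
  Ionisation efficiency is taken as 100% and no correction factor is
  exposed.
* `lod_size()` is `intensity_to_size(1)`: after the correction the smallest
  resolvable particle is the one whose whole-particle signal equals one
  count. It depends on the instrument sensitivity only, not on the
  background level.

All internal masses are grams, diameters nm, densities g/cm³, flow rates
mL/min, dwell times ms, concentrations µg/L; the conversions live in one
place in the calibration module.

`size_distribution()` maps the net pulses through the calibration, floors
the result at the size LOD, rounds to the nearest nm (net intensities are
integer counts, so sizes are naturally discrete — no further binning is
imposed), trims rare high-size tail bins whose frequency falls below 10
(`tail_filter()`, configurable; interior bins are never removed), and
reports the modal diameter (`max_position`) and the largest surviving
diameter (`right_wing`).

## What the simulator emulates

`simulate_sample()` generates paired sample/blank traces with full ground
truth so every claim above can be checked against known inputs:

* per-window background counts are Poisson with mean
  `background_rate * dwell_time` — the default 4 counts/ms reproduces a
  typical dissolved-Ti background of ~40 counts at 10 ms;
* particle events arrive as a Poisson process (default ~500 events per
  60 s run) with lognormal diameters (default median 150 nm, geometric SD
  1.3, a realistic mildly polydisperse consumer-product population);
* each event's total ion count is Poisson around the calibration response
  to the particle's Ti mass, and occupies a rectangular transient of
  duration `transient_duration` (default 0.5 ms, a typical single-particle
  transient) placed uniformly in time; counts are split multinomially
  across the windows the transient overlaps, so short dwell times fragment
  pulses exactly as observed on real traces;
* coincidences are allowed — two events in one window simply add — and a
  warning fires when the expected event rate exceeds 0.1 per window;
* dilution divides the event rate and leaves the background untouched, and
  a dilution series shares one blank realisation, as one deionised-water
  run would serve a real series.

The default calibration (`default_calibration()`) uses transport efficiency
5.7% and flow rate 0.28 mL/min — typical measured values for a pneumatic
introduction system — and a sensitivity that makes a median 150 nm particle
produce about 200 counts, the pulse height seen on millisecond
time-resolved traces of TiO~2~ suspensions. With that sensitivity particle
pulses sit well clear of the background body, which is the regime in which
the particle count from the negative difference mass is unbiased. Note that
an instrument whose sensitivity puts one count at a 71 nm sphere would give
a median 150 nm particle only ~9 counts — inside the background
fluctuations at 16 ms — and there the negative-mass estimate genuinely
underestimates the particle number; the correction separates the
distributions it can separate, it does not create resolution.

What the simulator does **not** emulate: plasma ionisation physics, flicker
(1/f) noise, detector dead time, incomplete vaporisation of large
particles, and matrix-dependent background drift. Passing tests therefore
demonstrate the correctness of the data processing on idealised Poisson
statistics, not the accuracy of any particular instrument's calibration.

```{r figure}
cfg <- sim_config(dwell_time = 16, total_time = 60, seed = 11,
                  calibration = default_calibration(16))
pair <- suppressWarnings(simulate_pair(cfg))
res <- correct_trace(pair$sample, pair$blank)
autoplot(res)
```

## Numerical and statistical choices

* **Population (not sample) standard deviation** in `summary_stats()`:
  traces hold thousands of windows, the distinction is immaterial, and the
  population form keeps hand-checkable test values exact.
* **Strict inequality at thresholds**: a window exactly at `mean + n*sd`
  (or at the transition intensity) is indistinguishable from background and
  is not counted as a particle.
* **Mode tie-break**: smallest intensity, a deterministic and conservative
  background estimate (a Poisson histogram with integer mean has an exact
  pmf tie at `lambda - 1` and `lambda`).
* **Negative-frequency tolerance**: transition detection treats frequencies
  above −1e−9 as zero so that floating-point dust from the rescaling never
  creates a phantom sign change.
* **Problem sizes in the tests**: simulation-based checks use 60–240 s
  acquisitions (3,750–60,000 windows) with 500–1,200 particles. These match
  the acquisition lengths the method is used with in practice while keeping
  the whole suite under a minute.
* **Sub-stream seeding**: every component of a simulated run (blank,
  background, events, each dilution member) draws from its own seed derived
  from the configuration seed, so regenerating one component never perturbs
  another and all fixtures are bit-reproducible.

## Known limitations

* The particle count inherits a noise floor from the histogram subtraction:
  with `N` windows and background-level bin counts of order `B`, pure
  counting noise contributes folded-Gaussian mass of order `sqrt(B)` per
  overlapping bin to the negative range. On a dilution series this appears
  as a positive intercept in recovered counts versus inverse dilution; the
  proportionality itself (the slope) is recovered cleanly.
* The modal diameter of a finely quantised size distribution is a noisy
  statistic at a few hundred particles: with 1-nm bins and ~500 lognormal
  particles the peak bins hold only a handful of counts each, and the
  argmax wanders over the flat top of the distribution (and the mode of a
  lognormal with GSD 1.3 sits ~7% below its median to begin with). The
  median of the net sizes is the stable location summary; the modal
  position is reported because it is the conventional headline number for
  size distributions.
* Window-wise operation is by design: at microsecond dwell times, where
  every pulse fragments, the method would need the cross-window peak
  reassembly that dedicated microsecond-mode software performs, which is
  out of scope here.
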