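# spicpms

Background-signal correction and particle sizing for millisecond
single-particle ICP-MS (SP-ICP-MS).

## The problem

In SP-ICP-MS a dilute nanoparticle suspension is nebulised into the plasma
and the detector is read out in contiguous dwell-time windows of a few
milliseconds. Each nanoparticle vaporises into an ion burst shorter than one
window, so particles appear as single high-count windows riding on a
continuous, Poisson-distributed background from the dissolved element and
isobaric interferents. For TiO₂ in consumer products measured at m/z 48 the
background is high and the small-particle signals overlap its upper wing, so
the classical discriminator — flag windows above `mean + n·σ` of a blank —
either keeps false-positive background windows (small *n*) or discards real
particles (large *n*), and the threshold inflates with dwell time.

This package implements a histogram-based alternative. Build the
frequency–intensity distributions (windows per integer count value) of the
sample and of a matched blank with equal window count *N*, then:

1. `N_I^s − N_I^bgd` per intensity *I* — the negative mass of this signed
   difference is the particle count, `N_NP = Σ |N_I^{s−bgd}|` over the
   negative range (it equals the positive mass exactly);
2. `N_bgd = N − N_NP`;
3. rescale the blank by the background fraction,
   `N_corr,I^bgd = N_I^bgd · N_bgd / N` (kept fractional);
4. subtract again: `N_I^s − N_corr,I^bgd` — in expectation only particle
   signal remains;
5. the largest intensity with a negative corrected frequency is the
   background/particle transition `I_t`; windows strictly above it are
   particles, each netted by the modal blank intensity.

Net pulses are converted to equivalent spherical diameters through an
indirect calibration: transport efficiency `η_TE` from a particle-number
standard, detected mass per window `m = η_TE · V · t_dt · C` for dissolved
standards, a through-origin sensitivity fit (counts per gram of element),
the TiO₂/Ti mass ratio (1.67) and the spherical inversion
`d = (6 m_NP / (π ρ))^{1/3}` with ρ = 4.23 g/cm³. The size limit of
detection is the diameter whose whole-particle signal equals one count —
after correction it depends on instrument sensitivity only, not on the
background.

A fully ground-truthed simulator (Poisson background linear in dwell time,
Poisson particle arrivals, lognormal sizes, sub-dwell rectangular transients
that split multinomially across window boundaries, dilution series) is
included for validating the whole chain, along with the classical n·σ and
Poisson decision thresholds for comparison.

## Worked example

Simulate a 60 s acquisition at 16 ms dwell (3,750 windows, background
4 counts/ms, ~500 lognormal particles with median 150 nm), run the
correction, and size the pulses:

```r
library(spicpms)

cfg <- sim_config(dwell_time = 16, total_time = 60, seed = 11,
                  calibration = default_calibration(16))
pair <- simulate_pair(cfg)
res <- correct_trace(pair$sample, pair$blank)
res
#> <sp_correction>
#>   windows (N):           3750
#>   particles (N_NP):      531
#>   background (N_bgd):    3219
#>   transition intensity:  90 counts
#>   modal background:      66 counts
#>   residual negative:     -163
#>   warning: modal background (66) and transition intensity (90) differ by more than 2 counts

nrow(pair$truth) # true number of generated particles
#> [1] 504

sizes <- size_distribution(res, cfg$calibration, min_frequency = 0)
glance(sizes)
#> # A tibble: 1 × 5
#>   n_particles max_position right_wing lod_size dwell_time
#>         <int>        <int>      <int>    <dbl>      <dbl>
#> 1         481          159        288     25.6         16

median(intensity_to_size(res$net_intensities, cfg$calibration))
#> [1] 152.4595
```

The correction recovers 531 particles against a ground truth of 504 — within
counting statistics, the residual being the histogram-subtraction noise
floor. The background body (modal intensity 66 counts ≈ 4 counts/ms × 16 ms)
is removed from every pulse; the transition at 90 counts marks the upper
edge of the background fluctuations. The median recovered diameter,
152.5 nm, sits on the generating median of 150 nm; `max_position` is the
conventional (but at 500 particles noisy) modal diameter, and `autoplot(res)`
or `autoplot(sizes)` draw the corrected distributions. The 25.6 nm LOD is a
property of the simulated instrument's sensitivity (one count ↔ 25.6 nm
sphere); an instrument with one count at a 71 nm sphere reports
`lod_size = 71`.

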