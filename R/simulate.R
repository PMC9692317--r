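# Synthetic time-resolved traces with known ground truth.
#
# Phenomenology reproduced: (i) Poisson background counts whose mean scales
# linearly with dwell time; (ii) particle events arriving as a Poisson
# process, each a rectangular transient of sub-dwell duration whose total ion
# count is Poisson around the calibration response to the particle's element
# mass; (iii) transients that straddle a window boundary split their counts
# multinomially in proportion to overlap; (iv) coincident events add within a
# window; (v) dilution scales the event rate, never the background.

#' Particle size models for the simulator
#'
#' `size_lognormal()` draws diameters from a lognormal distribution given its
#' median (nm) and geometric standard deviation; `size_monodisperse()` always
#' returns the same diameter.
#'
#' @param median Median diameter, nm.
#' @param gsd Geometric standard deviation (> 1 for a spread).
#' @param diameter Fixed diameter, nm.
#' @return A list of class `sp_size_model`.
#' @export
size_lognormal <- function(median = 150, gsd = 1.3) {
  if (median <= 0 || gsd < 1) abort("median must be > 0 and gsd >= 1")
  structure(
    list(type = "lognormal", median = median, gsd = gsd),
    class = "sp_size_model"
  )
}

#' @rdname size_lognormal
#' @export
size_monodisperse <- function(diameter = 150) {
  if (diameter <= 0) abort("diameter must be > 0")
  structure(
    list(type = "monodisperse", median = diameter, gsd = 1),
    class = "sp_size_model"
  )
}

draw_sizes <- function(model, n) {
  if (n == 0) return(numeric())
  switch(model$type,
    monodisperse = rep(model$median, n),
    lognormal = rlnorm(n, meanlog = log(model$median), sdlog = log(model$gsd)),
    abort("unknown size model")
  )
}

#' Default calibration used by the simulator
#'
#' Transport efficiency 5.7% and flow rate 0.28 mL/min (typical measured
#' values for a pneumatic introduction system), TiO2 constants, and a
#' sensitivity chosen so that a median 150 nm TiO2 particle produces about
#' 200 detector counts - the pulse height observed on millisecond
#' time-resolved traces of TiO2 suspensions, and high enough that particle
#' pulses sit clear of a typical dissolved background.
#'
#' @param dwell_time Dwell time in ms the calibration is bound to.
#' @param counts_at_150nm Detector counts produced by a 150 nm TiO2 particle.
#' @return An [calibration_model()].
#' @export
default_calibration <- function(dwell_time = 10, counts_at_150nm = 200) {
  ti_mass_150 <- particle_mass(150, 4.23) / tio2_ti_mass_ratio()
  calibration_model(
    transport_efficiency = 0.057,
    flow_rate = 0.28,
    dwell_time = dwell_time,
    sensitivity = counts_at_150nm / ti_mass_150
  )
}

#' Simulation configuration
#'
#' Bundles every generator parameter. Defaults describe a typical
#' millisecond acquisition: dissolved background of 4 counts/ms, 60 s run,
#' ~500 particle events, lognormal sizes with median 150 nm and GSD 1.3,
#' 0.5 ms rectangular transients.
#'
#' @param background_rate Background count rate, counts per ms (lambda). The
#'   per-window background is Poisson(lambda * dwell_time).
#' @param dwell_time Dwell time, ms.
#' @param total_time Total acquisition time, s. `n_windows` overrides it.
#' @param n_windows Number of dwell windows (optional; default
#'   `round(total_time * 1000 / dwell_time)`).
#' @param particle_rate Expected particle events per second before dilution.
#' @param size_model A [size_lognormal()] or [size_monodisperse()].
#' @param transient_duration Transient length tau, ms (rectangular profile).
#' @param calibration An [calibration_model()] mapping particle mass to
#'   expected counts.
#' @param dilution_factor Dilution of the particle suspension (>= 1); scales
#'   the event rate down, leaves the background untouched.
#' @param seed Integer seed; every draw in the run derives from it.
#' @return A list of class `sp_sim_config`.
#' @export
sim_config <- function(background_rate = 4,
                       dwell_time = 10,
                       total_time = 60,
                       n_windows = NULL,
                       particle_rate = 500 / 60,
                       size_model = size_lognormal(150, 1.3),
                       transient_duration = 0.5,
                       calibration = default_calibration(dwell_time),
                       dilution_factor = 1,
                       seed = 1L) {
  if (background_rate < 0) abort("background_rate must be >= 0")
  check_dwell(dwell_time)
  if (particle_rate < 0) abort("particle_rate must be >= 0")
  if (transient_duration <= 0) abort("transient_duration must be > 0")
  if (dilution_factor < 1) abort("dilution_factor must be >= 1")
  stopifnot(inherits(size_model, "sp_size_model"))
  assert_complete_calibration(calibration)
  n_windows <- n_windows %||% round(total_time * 1000 / dwell_time)
  if (n_windows < 1) abort("need at least one window")
  structure(
    list(
      background_rate = background_rate,
      dwell_time = dwell_time,
      n_windows = as.integer(n_windows),
      total_time = n_windows * dwell_time / 1000,
      particle_rate = particle_rate,
      size_model = size_model,
      transient_duration = transient_duration,
      calibration = calibration,
      dilution_factor = dilution_factor,
      seed = as.integer(seed)
    ),
    class = "sp_sim_config"
  )
}

# Deterministic sub-stream seeds: every component of a run (blank, background,
# events, per-factor runs) gets its own seed derived from the config seed, so
# adding draws to one component never perturbs another.
derive_seeds <- function(seed, n) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Simulate a particle-free background trace
#'
#' Independent Poisson counts with mean `background_rate * dwell_time` in
#' every window: the dissolved-element background accumulates linearly with
#' dwell time.
#'
#' @param config An [sim_config()].
#' @param seed Optional seed override (defaults to a sub-stream of
#'   `config$seed` distinct from the sample's).
#' @return An [sp_trace].
#' @export
simulate_background <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sp_sim_config"))
  seed <- seed %||% derive_seeds(config$seed, 2)[2]
  counts <- withr::with_seed(
    seed,
    rpois(config$n_windows, config$background_rate * config$dwell_time)
  )
  sp_trace(counts, dwell_time = config$dwell_time, label = "simulated blank")
}

#' Simulate a sample trace with known ground truth
#'
#' Particle events arrive as a Poisson process at
#' `particle_rate / dilution_factor`; each event draws a diameter from the
#' size model, a total ion count Poisson around the calibration response to
#' its element mass, and a uniformly placed rectangular transient of duration
#' `transient_duration` whose counts are split multinomially across the
#' windows it overlaps. Background counts per [simulate_background()] are
#' added everywhere. A warning is raised when the expected events per window
#' exceed 0.1 (time-unresolved coincidences become likely).
#'
#' @param config An [sim_config()].
#' @return A list with elements `trace` ([sp_trace]) and `truth`, a tibble
#'   with one row per generated event: `event`, `diameter` (nm),
#'   `total_counts`, `start_time` (s), `first_window`, `n_windows_touched`.
#' @export
simulate_sample <- function(config) {
  stopifnot(inherits(config, "sp_sim_config"))
  seeds <- derive_seeds(config$seed, 2)
  rate <- config$particle_rate / config$dilution_factor
  expected_per_window <- rate * config$dwell_time / 1000
  if (expected_per_window > 0.1) {
    warn(sprintf(
      "expected %.3g particle events per window: time-unresolved coincidences likely",
      expected_per_window
    ))
  }

  t_dt <- config$dwell_time
  tau <- config$transient_duration
  n_win <- config$n_windows
  total_ms <- n_win * t_dt
  cal <- config$calibration

  out <- withr::with_seed(seeds[1], {
    counts <- rpois(n_win, config$background_rate * t_dt)
    n_events <- rpois(1, rate * config$total_time)
    if (n_events > 0) {
      diameters <- draw_sizes(config$size_model, n_events)
      ti_mass <- particle_mass(diameters, cal$particle_density) / cal$molar_ratio
      totals <- rpois(n_events, cal$sensitivity * ti_mass)
      starts <- runif(n_events, 0, max(total_ms - tau, 0))
      first_win <- integer(n_events)
      n_touched <- integer(n_events)
      for (e in seq_len(n_events)) {
        w0 <- floor(starts[e] / t_dt)
        w1 <- min(floor((starts[e] + tau) / t_dt), n_win - 1)
        wins <- w0:w1
        # overlap of [start, start + tau) with each window [w t, (w+1) t)
        overlap <- pmin((wins + 1) * t_dt, starts[e] + tau) - pmax(wins * t_dt, starts[e])
        overlap[overlap < 0] <- 0
        split <- if (length(wins) == 1) {
          totals[e]
        } else {
          drop(rmultinom(1, totals[e], prob = overlap / sum(overlap)))
        }
        touched <- split > 0 | (length(wins) == 1)
        counts[wins + 1] <- counts[wins + 1] + split
        first_win[e] <- w0
        n_touched[e] <- max(1L, sum(touched))
      }
      truth <- tibble(
        event = seq_len(n_events),
        diameter = diameters,
        total_counts = totals,
        start_time = starts / 1000,
        first_window = first_win,
        n_windows_touched = n_touched
      )
    } else {
      truth <- tibble(
        event = integer(), diameter = numeric(), total_counts = integer(),
        start_time = numeric(), first_window = integer(),
        n_windows_touched = integer()
      )
    }
    list(counts = counts, truth = truth)
  })

  list(
    trace = sp_trace(out$counts, dwell_time = t_dt, label = "simulated sample"),
    truth = out$truth
  )
}

#' Simulate a matched sample/blank pair
#'
#' The blank shares the background parameters but is an independent
#' realisation drawn from its own sub-stream, as a separate deionised-water
#' acquisition would be.
#'
#' @param config An [sim_config()].
#' @return A list `sample` ([sp_trace]), `blank` ([sp_trace]), `truth`.
#' @export
simulate_pair <- function(config) {
  s <- simulate_sample(config)
  list(sample = s$trace, blank = simulate_background(config), truth = s$truth)
}

#' Simulate a dilution series
#'
#' One sample per dilution factor, all sharing the same background
#' parameters and one common blank realisation (a single deionised-water
#' run, as matched blanks are acquired in practice). Expected particle
#' counts scale as 1/factor; the background is untouched by dilution.
#'
#' @param config An [sim_config()] (its `dilution_factor` is ignored).
#' @param factors Numeric vector of dilution factors, all >= 1.
#' @return A list with `blank` ([sp_trace]) and `runs`, a list of
#'   `list(factor, trace, truth)` in the order of `factors`.
#' @export
simulate_dilution_series <- function(config, factors = c(1, 2, 5, 10)) {
  stopifnot(inherits(config, "sp_sim_config"))
  if (any(factors < 1)) abort("dilution factors must be >= 1")
  seeds <- derive_seeds(config$seed, length(factors) + 1)
  blank <- simulate_background(config, seed = seeds[1])
  runs <- purrr::map2(factors, seeds[-1], function(f, s) {
    cfg <- config
    cfg$dilution_factor <- f
    cfg$seed <- s
    sim <- simulate_sample(cfg)
    list(factor = f, trace = sim$trace, truth = sim$truth)
  })
  list(blank = blank, runs = runs)
}
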