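# Units used throughout: diameters nm, densities g/cm^3, masses g,
# flow rates mL/min, dwell times ms, acquisition times s, dissolved
# concentrations ug/L. Conversions are centralised here.
NM_PER_CM <- 1e7
L_PER_ML <- 1e-3
S_PER_MIN <- 60
S_PER_MS <- 1e-3
G_PER_UG <- 1e-6

# standard atomic weights (IUPAC 2021, conventional)
AW_TI <- 47.867
AW_O <- 15.999

#' TiO2/Ti mass conversion factor
#'
#' Ratio of the molar mass of TiO2 to that of Ti, used to convert the Ti mass
#' inferred from a pulse into the mass of the whole oxide particle. The
#' conventional rounded value 1.67 is the default; `exact = TRUE` returns the
#' full-precision ratio from standard atomic weights.
#'
#' @param exact Return the unrounded ratio?
#' @return Numeric scalar (1.67, or ~1.66848 when `exact`).
#' @export
tio2_ti_mass_ratio <- function(exact = FALSE) {
  r <- (AW_TI + 2 * AW_O) / AW_TI
  if (exact) r else round(r, 2)
}

#' Mass of a single spherical nanoparticle
#'
#' `m = d^3 * pi * rho / 6` for an equivalent sphere, with the diameter in nm
#' and the density in g/cm^3.
#'
#' @param diameter Diameter in nm (vectorised, >= 0).
#' @param density Bulk density in g/cm^3 (> 0). Default is TiO2.
#' @return Mass in grams.
#' @examples
#' particle_mass(60, 10.49) # a 60 nm silver particle, ~1.19e-15 g
#' @export
particle_mass <- function(diameter, density = 4.23) {
  if (any(diameter < 0)) abort("negative diameter")
  if (any(density <= 0)) abort("density must be > 0")
  (diameter / NM_PER_CM)^3 * pi * density / 6
}

#' Equivalent spherical diameter from particle mass
#'
#' Inverse of [particle_mass()]: `d = (6 m / (pi rho))^(1/3)`, returned in nm.
#'
#' @param mass Particle mass in grams (vectorised, >= 0).
#' @inheritParams particle_mass
#' @return Diameter in nm.
#' @export
particle_size <- function(mass, density = 4.23) {
  if (any(mass < 0)) abort("negative mass")
  if (any(density <= 0)) abort("density must be > 0")
  (6 * mass / (pi * density))^(1 / 3) * NM_PER_CM
}

#' Describe a particle-number standard
#'
#' A monodisperse reference dispersion of known diameter, density and mass
#' concentration, used to measure the transport efficiency of the introduction
#' system (classically a 60 nm silver standard).
#'
#' @param diameter Nominal diameter in nm.
#' @param density Bulk density in g/cm^3 (10.49 for silver).
#' @param mass_concentration Mass concentration of the dispersion in ug/L.
#' @param element Element label.
#' @return A list of class `sp_standard`.
#' @export
particle_standard <- function(diameter, density = 10.49, mass_concentration,
                              element = "Ag") {
  if (diameter <= 0) abort("diameter must be > 0")
  if (density <= 0) abort("density must be > 0")
  if (mass_concentration <= 0) abort("mass_concentration must be > 0")
  structure(
    list(
      diameter = diameter, density = density,
      mass_concentration = mass_concentration, element = element
    ),
    class = "sp_standard"
  )
}

#' Transport efficiency from a particle-number standard
#'
#' Fraction of nebulised particles that reach the detector: the ratio of the
#' number of particle events counted on the time-resolved spectrum to the
#' number of particles introduced, where the latter follows from the
#' standard's mass concentration, the sample flow rate, the acquisition time
#' and the mass of one particle.
#'
#' @param n_detected Number of particle events counted.
#' @param standard A [particle_standard()].
#' @param flow_rate Sample flow rate in mL/min.
#' @param acquisition_time Acquisition time in s.
#' @return Transport efficiency as a dimensionless fraction.
#' @export
transport_efficiency <- function(n_detected, standard, flow_rate,
                                 acquisition_time) {
  stopifnot(inherits(standard, "sp_standard"))
  if (n_detected <= 0 || flow_rate <= 0 || acquisition_time <= 0) {
    abort("n_detected, flow_rate and acquisition_time must all be > 0")
  }
  volume_l <- flow_rate * L_PER_ML / S_PER_MIN * acquisition_time
  mass_g <- standard$mass_concentration * G_PER_UG * volume_l
  n_introduced <- mass_g / particle_mass(standard$diameter, standard$density)
  if (n_introduced <= 0) abort("zero introduced particles")
  n_detected / n_introduced
}

#' Assemble a calibration model
#'
#' Holds everything needed to turn a net pulse intensity into an equivalent
#' spherical diameter: the transport efficiency, the sample flow rate, the
#' dwell time, the sensitivity (counts per gram of analyte element reaching
#' the detector, the slope of the transformed calibration curve), the
#' oxide/element mass ratio and the particle bulk density. Defaults carry the
#' TiO2 constants (mass ratio 1.67, density 4.23 g/cm^3).
#'
#' @param transport_efficiency Dimensionless fraction in (0, 1].
#' @param flow_rate Sample flow rate, mL/min.
#' @param dwell_time Dwell time, ms.
#' @param sensitivity Counts per gram of detected element (NA until fitted).
#' @param molar_ratio Oxide-to-element mass conversion factor (>= 1).
#' @param particle_density Particle bulk density, g/cm^3.
#' @return A list of class `sp_calibration`.
#' @export
calibration_model <- function(transport_efficiency, flow_rate, dwell_time,
                              sensitivity = NA_real_,
                              molar_ratio = tio2_ti_mass_ratio(),
                              particle_density = 4.23) {
  if (transport_efficiency <= 0 || transport_efficiency > 1) {
    abort("transport_efficiency must be in (0, 1]")
  }
  if (flow_rate <= 0) abort("flow_rate must be > 0")
  check_dwell(dwell_time)
  if (!is.na(sensitivity) && sensitivity <= 0) abort("sensitivity must be > 0")
  if (molar_ratio < 1) abort("molar_ratio must be >= 1")
  if (particle_density <= 0) abort("particle_density must be > 0")
  structure(
    list(
      transport_efficiency = transport_efficiency,
      flow_rate = flow_rate,
      dwell_time = dwell_time,
      sensitivity = sensitivity,
      molar_ratio = molar_ratio,
      particle_density = particle_density
    ),
    class = "sp_calibration"
  )
}

assert_complete_calibration <- function(cal) {
  stopifnot(inherits(cal, "sp_calibration"))
  if (is.na(cal$sensitivity)) {
    abort("incomplete calibration: sensitivity has not been fitted or set")
  }
  invisible(cal)
}

#' @export
print.sp_calibration <- function(x, ...) {
  cat("<sp_calibration>\n")
  cat(sprintf("  transport efficiency: %.3g (%.2g%%)\n",
              x$transport_efficiency, 100 * x$transport_efficiency))
  cat(sprintf("  flow rate:            %g mL/min\n", x$flow_rate))
  cat(sprintf("  dwell time:           %g ms\n", x$dwell_time))
  cat(sprintf("  sensitivity:          %s counts/g\n",
              if (is.na(x$sensitivity)) "<unfitted>" else format(x$sensitivity, digits = 4)))
  cat(sprintf("  oxide/element ratio:  %g\n", x$molar_ratio))
  cat(sprintf("  particle density:     %g g/cm^3\n", x$particle_density))
  if (!is.na(x$sensitivity)) {
    cat(sprintf("  size LOD (1 count):   %.1f nm\n", lod_size(x)))
  }
  invisible(x)
}

#' Detected element mass per dwell window for a dissolved standard
#'
#' The mass of analyte element reaching the detector in one dwell window when
#' nebulising a dissolved standard of concentration `C`:
#' `m = eta_TE * V * t_dt * C`, with the units reconciled internally
#' (flow mL/min, dwell ms, concentration ug/L, mass in g).
#'
#' @param concentration Dissolved standard concentration in ug/L (vectorised).
#' @param cal An [calibration_model()] (sensitivity not required).
#' @return Mass in grams per dwell window.
#' @examples
#' cal <- calibration_model(0.057, 0.28, 10)
#' mass_per_window(1, cal) # ~2.66e-15 g
#' @export
mass_per_window <- function(concentration, cal) {
  stopifnot(inherits(cal, "sp_calibration"))
  if (any(concentration < 0)) abort("concentration must be >= 0")
  cal$transport_efficiency *
    (cal$flow_rate * L_PER_ML / S_PER_MIN) *
    (cal$dwell_time * S_PER_MS) *
    (concentration * G_PER_UG)
}

#' Fit the sensitivity from a dissolved-standard dilution series
#'
#' Transforms the conventional intensity-vs-concentration calibration curve
#' into intensity vs detected mass per window (via [mass_per_window()]) and
#' fits an ordinary least-squares line through the origin after blank
#' subtraction. The slope is the sensitivity in counts per gram of detected
#' element.
#'
#' @param points A data frame with columns `concentration` (ug/L) and
#'   `intensity` (mean counts per window). A row with concentration 0 is used
#'   as the blank; otherwise intensities are assumed already blank-corrected.
#' @param cal A partial [calibration_model()] supplying transport efficiency,
#'   flow rate and dwell time.
#' @return The calibration with `sensitivity` filled in. The fit (slope
#'   standard error, R^2, residuals) is attached as attribute `"fit"` and
#'   surfaced by [tidy()] / [glance()].
#' @export
fit_sensitivity <- function(points, cal) {
  stopifnot(inherits(cal, "sp_calibration"))
  points <- as_tibble(points)
  if (!all(c("concentration", "intensity") %in% names(points))) {
    abort("points needs columns 'concentration' and 'intensity'")
  }
  if (length(unique(points$concentration)) < 2) {
    abort("need at least 2 distinct concentrations")
  }
  blank <- points$intensity[points$concentration == 0]
  blank_intensity <- if (length(blank)) mean(blank) else 0
  df <- tibble(
    mass = mass_per_window(points$concentration, cal),
    net = points$intensity - blank_intensity
  )
  if (max(df$mass) - min(df$mass) <= 0) abort("zero variance in detected mass")
  fit <- lm(net ~ 0 + mass, data = df)
  slope <- unname(coef(fit)[["mass"]])
  if (slope <= 0) abort("fitted sensitivity is not positive")
  # summary() warns on an exactly collinear ("perfect") fit; the slope and its
  # (zero) standard error are still what we want to report
  sm <- suppressWarnings(summary(fit))
  out <- cal
  out$sensitivity <- slope
  attr(out, "fit") <- list(
    estimate = slope,
    std.error = unname(sm$coefficients["mass", "Std. Error"]),
    r.squared = sm$r.squared,
    blank_intensity = blank_intensity,
    n_points = nrow(df),
    residuals = tibble(
      concentration = points$concentration,
      mass = df$mass, net = df$net,
      fitted = unname(fitted(fit)),
      residual = unname(residuals(fit))
    )
  )
  out
}

#' @export
tidy.sp_calibration <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(
    term = "sensitivity",
    estimate = x$sensitivity,
    std.error = if (is.null(fit)) NA_real_ else fit$std.error
  )
}

#' @export
glance.sp_calibration <- function(x, ...) {
  fit <- attr(x, "fit")
  tibble(
    transport_efficiency = x$transport_efficiency,
    flow_rate = x$flow_rate,
    dwell_time = x$dwell_time,
    sensitivity = x$sensitivity,
    molar_ratio = x$molar_ratio,
    particle_density = x$particle_density,
    lod_size = if (is.na(x$sensitivity)) NA_real_ else lod_size(x),
    r.squared = if (is.null(fit)) NA_real_ else fit$r.squared,
    n_points = if (is.null(fit)) NA_integer_ else fit$n_points
  )
}

#' Convert a net pulse intensity to an equivalent spherical diameter
#'
#' Net counts are divided by the sensitivity to give the element mass, scaled
#' by the oxide/element mass ratio to the particle mass, and converted to the
#' diameter of a sphere of the particle's bulk density. The size scales as
#' intensity^(1/3).
#'
#' @param net_intensity Net (background-subtracted) intensity in counts,
#'   vectorised, >= 0.
#' @param cal A complete [calibration_model()].
#' @return Diameter in nm.
#' @export
intensity_to_size <- function(net_intensity, cal) {
  assert_complete_calibration(cal)
  if (any(net_intensity < 0)) abort("net_intensity must be >= 0")
  mass_elem <- net_intensity / cal$sensitivity
  particle_size(mass_elem * cal$molar_ratio, cal$particle_density)
}

#' Size limit of detection
#'
#' The diameter whose whole-particle signal equals one count under the
#' calibration. After background correction the distinguishable particle size
#' is set by the instrument sensitivity alone, not by the background level:
#' a pulse of less than one net count cannot exist.
#'
#' @param cal A complete [calibration_model()].
#' @return Diameter in nm.
#' @export
lod_size <- function(cal) {
  intensity_to_size(1, cal)
}

#' Serialize a calibration model
#'
#' Flat key-value YAML; [read_calibration()] restores it.
#'
#' @param cal An [calibration_model()].
#' @param path File path.
#' @return `path` invisibly, or the restored calibration.
#' @export
write_calibration <- function(cal, path) {
  stopifnot(inherits(cal, "sp_calibration"))
  yaml::write_yaml(unclass(cal), path, precision = 17)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing file: %s", path))
  v <- yaml::read_yaml(path)
  calibration_model(
    transport_efficiency = v$transport_efficiency,
    flow_rate = v$flow_rate,
    dwell_time = v$dwell_time,
    sensitivity = v$sensitivity %||% NA_real_,
    molar_ratio = v$molar_ratio %||% tio2_ti_mass_ratio(),
    particle_density = v$particle_density %||% 4.23
  )
}
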