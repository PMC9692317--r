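test_that("spherical particle mass matches independent hand calculation", {
  expect_equal(particle_mass(0, 4.23), 0)
  # 60 nm silver sphere: (60e-7 cm)^3 * pi/6 * 10.49 g/cm^3
  expect_equal(particle_mass(60, 10.49), 1.186391e-15, tolerance = 1e-6)
  # 71 nm TiO2 sphere
  expect_equal(particle_mass(71, 4.23), 7.927095e-16, tolerance = 1e-6)
  expect_error(particle_mass(-1, 4.23), "negative diameter")
  expect_error(particle_mass(10, 0), "density")
})

test_that("mass and size are exact inverses across the whole size range", {
  expect_equal(particle_size(0, 4.23), 0)
  d <- c(1, 30, 71, 150, 200, 1000, 1e4)
  expect_equal(particle_size(particle_mass(d, 4.23), 4.23), d, tolerance = 1e-9)
  expect_equal(particle_size(particle_mass(d, 10.49), 10.49), d, tolerance = 1e-9)
  expect_equal(particle_size(7.927095e-16, 4.23), 71, tolerance = 1e-5)
  expect_error(particle_size(-1e-18, 4.23), "negative mass")
})

test_that("transport efficiency is the detected/introduced particle ratio", {
  # construct a standard so that exactly 1000 particles are introduced:
  # mass concentration = 1000 * m_NP / volume
  flow <- 0.28
  t_acq <- 60
  volume_l <- flow * 1e-3 / 60 * t_acq
  m_np <- particle_mass(60, 10.49)
  conc_ugl <- 1000 * m_np / volume_l / 1e-6
  std <- particle_standard(60, 10.49, mass_concentration = conc_ugl)
  expect_equal(transport_efficiency(57, std, flow, t_acq), 0.057, tolerance = 1e-12)
  expect_equal(transport_efficiency(1000, std, flow, t_acq), 1.0, tolerance = 1e-12)
  # doubling the mass concentration halves the efficiency
  std2 <- particle_standard(60, 10.49, mass_concentration = 2 * conc_ugl)
  expect_equal(
    transport_efficiency(57, std2, flow, t_acq),
    0.057 / 2,
    tolerance = 1e-12
  )
  expect_error(transport_efficiency(0, std, flow, t_acq), "> 0")
})

test_that("detected mass per window reconciles all the units", {
  cal <- calibration_model(0.057, 0.28, 10)
  expect_equal(mass_per_window(0, cal), 0)
  # 5.7% of 0.28 mL/min for 10 ms of a 1 ug/L standard
  expect_equal(mass_per_window(1, cal), 2.66e-15, tolerance = 1e-9)
  # linear in dwell time and concentration
  cal2 <- calibration_model(0.057, 0.28, 20)
  expect_equal(mass_per_window(1, cal2), 2 * mass_per_window(1, cal))
  expect_equal(mass_per_window(3, cal), 3 * mass_per_window(1, cal))
  # linear in transport efficiency and flow rate
  expect_equal(
    mass_per_window(1, calibration_model(0.114, 0.28, 10)),
    2 * mass_per_window(1, cal)
  )
  expect_equal(
    mass_per_window(1, calibration_model(0.057, 0.56, 10)),
    2 * mass_per_window(1, cal)
  )
})

test_that("sensitivity fit recovers exact and noisy slopes through the origin", {
  cal <- calibration_model(0.057, 0.28, 10)
  conc <- c(0, 1, 2, 5, 10)
  s_true <- 1e15
  exact <- tibble::tibble(
    concentration = conc,
    intensity = s_true * mass_per_window(conc, cal) + 40 # blank offset 40
  )
  fit <- fit_sensitivity(exact, cal)
  expect_equal(fit$sensitivity, s_true, tolerance = 1e-9)
  expect_equal(attr(fit, "fit")$blank_intensity, 40)

  set.seed(7)
  noisy <- tibble::tibble(
    concentration = conc,
    intensity = s_true * mass_per_window(conc, cal) + 40 + rnorm(5, 0, 1)
  )
  nf <- fit_sensitivity(noisy, cal)
  se <- attr(nf, "fit")$std.error
  expect_lt(abs(nf$sensitivity - s_true), 3 * se)

  expect_error(
    fit_sensitivity(tibble::tibble(concentration = 1, intensity = 10), cal),
    "2 distinct"
  )
})

test_that("intensity maps to size through mass, ratio and density", {
  # sensitivity anchored so that 1 count is the Ti mass of a 71 nm TiO2 sphere
  ti_mass_71 <- particle_mass(71, 4.23) / tio2_ti_mass_ratio()
  cal <- calibration_model(0.057, 0.28, 10, sensitivity = 1 / ti_mass_71)
  expect_equal(intensity_to_size(0, cal), 0)
  expect_equal(intensity_to_size(1, cal), 71, tolerance = 1 / 71)
  expect_equal(lod_size(cal), 71, tolerance = 1 / 71)
  # cube-root scaling in intensity
  i <- c(1, 2, 5, 8, 27)
  expect_equal(intensity_to_size(i, cal), intensity_to_size(1, cal) * i^(1 / 3))
  # doubling sensitivity lowers the LOD by 2^(1/3)
  cal2 <- calibration_model(0.057, 0.28, 10, sensitivity = 2 / ti_mass_71)
  expect_equal(lod_size(cal) / lod_size(cal2), 2^(1 / 3), tolerance = 1e-9)
  expect_error(intensity_to_size(1, calibration_model(0.057, 0.28, 10)), "incomplete")
})

test_that("a noiseless monodisperse population maps back to its diameter", {
  cal <- default_calibration(10)
  for (d0 in c(100, 150, 250)) {
    counts <- round(cal$sensitivity * particle_mass(d0, cal$particle_density) / cal$molar_ratio)
    expect_lt(abs(stats::median(intensity_to_size(counts, cal)) - d0) / d0, 0.01)
  }
})

test_that("calibration models serialise to YAML and back", {
  cal <- default_calibration(16)
  f <- withr::local_tempfile(fileext = ".yaml")
  write_calibration(cal, f)
  back <- read_calibration(f)
  expect_equal(back$sensitivity, cal$sensitivity, tolerance = 1e-12)
  expect_equal(back$dwell_time, 16)
  expect_equal(back$molar_ratio, 1.67)
  expect_equal(back$particle_density, 4.23)
  expect_equal(lod_size(back), lod_size(cal), tolerance = 1e-9)
})

test_that("tidy and glance surface the calibration fit", {
  cal <- calibration_model(0.057, 0.28, 10)
  pts <- tibble::tibble(concentration = c(0, 1, 2, 5), intensity = c(40, 42, 44, 50))
  fit <- fit_sensitivity(pts, cal)
  td <- tidy(fit)
  expect_equal(td$term, "sensitivity")
  expect_true(td$estimate > 0 && td$std.error >= 0)
  gl <- glance(fit)
  expect_equal(gl$transport_efficiency, 0.057)
  expect_equal(gl$n_points, 4)
  expect_true(gl$lod_size > 0)
})
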