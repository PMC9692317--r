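# The three-bin hand-traceable pair used throughout: sample {0:5, 1:3, 2:2}
# against blank {0:6, 1:4}, both built from 10 windows.
hand_sample <- function() make_dist(c(`0` = 5, `1` = 3, `2` = 2))
hand_blank <- function() make_dist(c(`0` = 6, `1` = 4))

test_that("histogram subtraction matches the hand-traced difference", {
  d <- subtract_distributions(hand_sample(), hand_blank())
  expect_true(is_signed(d))
  expect_equal(d$intensity, c(0L, 1L, 2L))
  expect_equal(d$frequency, c(-1, -1, 2))
  expect_equal(sum(d$frequency), 0)

  same <- subtract_distributions(hand_sample(), hand_sample())
  expect_true(all(same$frequency == 0))

  expect_error(
    subtract_distributions(hand_sample(), make_dist(c(`0` = 8, `1` = 4))),
    "mismatched window counts"
  )
  expect_error(
    subtract_distributions(hand_sample(), make_dist(c(`0` = 6, `1` = 4), dwell = 4)),
    "mismatched dwell"
  )
})

test_that("subtraction is antisymmetric", {
  for (seed in 1:10) {
    p <- random_pair(seed)
    a <- build_distribution(sp_trace(p$sample, 10))
    b <- build_distribution(sp_trace(p$blank, 10))
    ab <- subtract_distributions(a, b)
    ba <- subtract_distributions(b, a)
    expect_equal(ab$frequency, -ba$frequency)
  }
})

test_that("particle count is the negative mass and equals the positive mass", {
  d <- subtract_distributions(hand_sample(), hand_blank())
  expect_equal(particle_count(d), 2)
  zero <- subtract_distributions(hand_sample(), hand_sample())
  expect_equal(particle_count(zero), 0)
  for (seed in 1:20) {
    p <- random_pair(seed + 100)
    diff <- subtract_distributions(
      build_distribution(sp_trace(p$sample, 10)),
      build_distribution(sp_trace(p$blank, 10))
    )
    neg <- sum(abs(diff$frequency[diff$frequency < 0]))
    pos <- sum(diff$frequency[diff$frequency > 0])
    expect_identical(neg, pos)
    expect_identical(particle_count(diff), neg)
  }
})

test_that("background rescaling keeps fractions and conserves its total", {
  sc <- scale_background(hand_blank(), 8, 10)
  expect_equal(sc$frequency, c(4.8, 3.2))
  expect_equal(sum(sc$frequency), 8, tolerance = 1e-12)
  expect_equal(scale_background(hand_blank(), 10, 10)$frequency, c(6, 4))
  expect_equal(sum(scale_background(hand_blank(), 0, 10)$frequency), 0)
  expect_error(scale_background(hand_blank(), 11, 10), "exceed")
})

test_that("corrected difference matches the hand trace and shrinks the negative mass", {
  corr <- corrected_sample(hand_sample(), scale_background(hand_blank(), 8, 10))
  expect_equal(corr$intensity, c(0L, 1L, 2L))
  expect_equal(corr$frequency, c(0.2, -0.2, 2), tolerance = 1e-12)

  # rescaling can only reduce the negative mass relative to the raw difference
  for (seed in 1:10) {
    p <- random_pair(seed + 200)
    s <- build_distribution(sp_trace(p$sample, 10))
    b <- build_distribution(sp_trace(p$blank, 10))
    raw <- subtract_distributions(s, b)
    n_np <- particle_count(raw)
    corr <- corrected_sample(s, scale_background(b, p$n - n_np, p$n))
    expect_lte(
      sum(abs(corr$frequency[corr$frequency < 0])),
      sum(abs(raw$frequency[raw$frequency < 0])) + 1e-9
    )
  }
})

test_that("transition intensity is the last negative-to-positive crossing", {
  corr <- corrected_sample(hand_sample(), scale_background(hand_blank(), 8, 10))
  expect_equal(transition_intensity(corr), 1)
  all_pos <- intensity_distribution(c(2, 3), c(1, 4), signed = TRUE)
  expect_equal(transition_intensity(all_pos), -1)
  multi <- intensity_distribution(
    c(1, 3, 5, 7, 9, 12),
    c(2, -1, 4, -2, 3, 1),
    signed = TRUE
  )
  expect_equal(transition_intensity(multi), 7)
})

test_that("modal background takes the argmax with the smallest-intensity tie-break", {
  expect_equal(modal_background(make_dist(c(`38` = 10, `40` = 55, `42` = 12))), 40)
  expect_equal(modal_background(make_dist(c(`1` = 5, `2` = 5))), 1)
  # Poisson mode oracle: lambda - 1 <= mode <= lambda
  set.seed(5)
  d <- build_distribution(sp_trace(rpois(2e5, 40), dwell_time = 10))
  expect_true(abs(modal_background(d) - 40) <= 2)
})

test_that("the full correction reproduces the hand-traced worked example", {
  res <- run_correction(hand_sample(), hand_blank())
  expect_s3_class(res, "sp_correction")
  expect_equal(res$n_particles, 2)
  expect_equal(res$n_background, 8)
  expect_equal(res$n_particles + res$n_background, res$n_total)
  expect_equal(res$transition_intensity, 1)
  expect_equal(res$modal_background, 0)
  expect_equal(res$net$intensity, 2L)
  expect_equal(res$net$net, 2L)
  expect_equal(res$net$frequency, 2L)
  expect_equal(res$net_intensities, c(2L, 2L))
  expect_equal(res$diagnostics$residual_negative_mass, -0.2, tolerance = 1e-12)

  gl <- glance(res)
  expect_equal(gl$n_particles, 2)
  expect_equal(gl$n_net_pulses, 2)
  expect_equal(tidy(res), res$net)
})

test_that("a blank against itself yields no particles", {
  b <- hand_blank()
  res <- run_correction(b, b)
  expect_equal(res$n_particles, 0)
  expect_equal(res$n_background, res$n_total)
  expect_equal(res$transition_intensity, -1)
  expect_length(res$net_intensities, 0)
})

test_that("run_correction agrees with the brute-force oracle on random pairs", {
  for (seed in 1:25) {
    p <- random_pair(seed + 300)
    oracle <- brute_force_correction(p$sample, p$blank)
    res <- run_correction(
      build_distribution(sp_trace(p$sample, 10)),
      build_distribution(sp_trace(p$blank, 10))
    )
    expect_identical(res$n_particles, oracle$n_np)
    expect_identical(res$n_background, oracle$n_bgd)
    expect_identical(res$transition_intensity, oracle$i_t)
    expect_identical(res$modal_background, oracle$i_mode)
    # corrected frequencies agree bin by bin over the oracle's support
    m <- match(oracle$intensity, res$corrected$intensity)
    got <- ifelse(is.na(m), 0, res$corrected$frequency[m])
    expect_equal(got, oracle$corrected, tolerance = 1e-9)
  }
})

test_that("correction recovers injected pulses well above the background", {
  set.seed(12)
  n <- 6000
  blank_counts <- rpois(n, 40)
  sample_counts <- rpois(n, 40)
  n_true <- 500
  idx <- sample(n, n_true)
  sample_counts[idx] <- sample_counts[idx] + rpois(n_true, 200)
  res <- run_correction(
    build_distribution(sp_trace(sample_counts, 10)),
    build_distribution(sp_trace(blank_counts, 10))
  )
  expect_lt(abs(res$n_particles - n_true), 3 * sqrt(n_true))
  # net pulse intensities centre near the injected mean
  expect_lt(abs(stats::median(res$net_intensities) - 200) / 200, 0.1)
})

test_that("tail filtering trims only the rare high tail", {
  d <- make_dist(c(`100` = 50, `150` = 12, `200` = 3))
  f <- tail_filter(d, 10)
  expect_equal(f$intensity, c(100L, 150L))
  expect_equal(tail_filter(d, 0)$intensity, d$intensity)
  # an interior low-frequency bin is protected
  d2 <- make_dist(c(`100` = 3, `150` = 50))
  expect_equal(tail_filter(d2, 10)$intensity, c(100L, 150L))
  # everything below threshold vanishes
  d3 <- make_dist(c(`5` = 2, `9` = 1))
  expect_equal(nrow(tail_filter(d3, 10)), 0)
  expect_error(tail_filter(d, -1), "min_frequency")
})
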