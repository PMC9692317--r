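# Shared fixtures and independent oracles.

# histogram from a named vector: names are intensities, values frequencies
make_dist <- function(x, dwell = 10, signed = FALSE) {
  intensity_distribution(
    as.integer(names(x)), as.numeric(x),
    dwell_time = dwell, signed = signed
  )
}

# Independent brute-force evaluation of the correction chain, working
# directly on raw per-window count vectors with plain loops. Used as the
# oracle the package implementation is checked against.
brute_force_correction <- function(sample_counts, blank_counts) {
  stopifnot(length(sample_counts) == length(blank_counts))
  n <- length(sample_counts)
  ints <- 0:max(sample_counts, blank_counts)
  ns <- vapply(ints, function(i) sum(sample_counts == i), numeric(1))
  nb <- vapply(ints, function(i) sum(blank_counts == i), numeric(1))
  d <- ns - nb
  n_np <- sum(abs(d[d < 0]))
  n_bgd <- n - n_np
  nb_scaled <- nb * n_bgd / n
  d_corr <- ns - nb_scaled
  neg <- ints[d_corr < -1e-9]
  i_t <- if (length(neg)) max(neg) else -1
  i_mode <- ints[nb == max(nb)][1]
  list(
    intensity = ints, diff = d, n_np = n_np, n_bgd = n_bgd,
    scaled = nb_scaled, corrected = d_corr, i_t = i_t, i_mode = i_mode
  )
}

# seeded random matched sample/blank count pair with injected pulses
random_pair <- function(seed) {
  set.seed(seed)
  n <- sample(30:300, 1)
  lam <- runif(1, 1, 30)
  blank <- rpois(n, lam)
  smp <- rpois(n, lam)
  k <- sample(0:floor(n / 5), 1)
  if (k > 0) {
    idx <- sample(n, k)
    smp[idx] <- smp[idx] + rpois(k, 50) + 10
  }
  list(sample = smp, blank = blank, n = n)
}

# frequency-weighted mode of a plain diameter/frequency tibble
size_mode <- function(df) df$diameter[which.max(df$frequency)]
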