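# Histogram-subtraction background correction.
#
# The sample frequency-intensity distribution is the background distribution
# with N_NP of its windows displaced upward by particle pulses. Subtracting a
# matched blank histogram therefore leaves a signed difference whose negative
# mass equals its positive mass and, in expectation, equals the number of
# particles. Rescaling the blank by N_bgd/N before the final subtraction
# removes the remaining background expectation everywhere, after which the
# transition from negative to positive frequencies marks the background /
# particle boundary and the modal background intensity is netted out of each
# pulse.

align_bins <- function(a, b) {
  full_join(
    tibble(intensity = a$intensity, fa = a$frequency),
    tibble(intensity = b$intensity, fb = b$frequency),
    by = "intensity"
  ) |>
    mutate(
      fa = dplyr::coalesce(.data$fa, 0),
      fb = dplyr::coalesce(.data$fb, 0)
    ) |>
    arrange(.data$intensity)
}

check_matched <- function(sample, bgd) {
  assert_unsigned(sample, "sample distribution")
  assert_unsigned(bgd, "background distribution")
  n_s <- attr(sample, "n")
  n_b <- attr(bgd, "n")
  if (abs(n_s - n_b) > 1e-9) {
    abort(sprintf(
      "mismatched window counts: sample N = %g, background N = %g (equal acquisitions required)",
      n_s, n_b
    ))
  }
  d_s <- attr(sample, "dwell_time")
  d_b <- attr(bgd, "dwell_time")
  if (!is.na(d_s) && !is.na(d_b) && abs(d_s - d_b) > 1e-9) {
    abort(sprintf("mismatched dwell times: %g ms vs %g ms", d_s, d_b))
  }
  invisible(TRUE)
}

#' Subtract a matched blank histogram from a sample histogram
#'
#' Per-intensity difference of two frequency-intensity distributions built
#' from the same number of dwell windows at the same dwell time. The result
#' is a signed distribution whose frequencies sum to zero; its negative mass
#' equals its positive mass.
#'
#' @param sample,bgd Unsigned [intensity_distribution]s with equal N and
#'   equal dwell time.
#' @return A signed [intensity_distribution] over the union of intensities.
#' @export
subtract_distributions <- function(sample, bgd) {
  check_matched(sample, bgd)
  j <- align_bins(sample, bgd)
  intensity_distribution(
    j$intensity, j$fa - j$fb,
    dwell_time = attr(sample, "dwell_time"),
    signed = TRUE,
    label = "sample - bgd"
  )
}

#' Number of particles from a signed difference distribution
#'
#' The summed absolute frequency over the negative range of the difference
#' histogram. Because both histograms hold the same total number of windows,
#' this equals the summed frequency over the positive range: every window a
#' particle pulse removes from the background body of the sample histogram
#' reappears above it.
#'
#' @param diff A signed difference from [subtract_distributions()].
#' @return Particle count N_NP (non-negative).
#' @export
particle_count <- function(diff) {
  stopifnot(inherits(diff, "sp_distribution"))
  if (!is_signed(diff)) abort("particle_count expects a signed difference distribution")
  neg <- diff$frequency[diff$frequency < 0]
  sum(abs(neg))
}

#' Rescale the blank histogram by the background fraction
#'
#' Each particle pulse occupies a window that would otherwise have held a
#' background signal, so the sample contains only `n_bgd = N - N_NP`
#' background draws. Every blank frequency is multiplied by `n_bgd / n_total`
#' and kept fractional; the rescaled frequencies sum to `n_bgd`.
#'
#' @param bgd Unsigned blank [intensity_distribution] with N = `n_total`.
#' @param n_bgd Number of background signals (0 <= n_bgd <= n_total).
#' @param n_total Total number of dwell windows.
#' @return An unsigned distribution with fractional frequencies summing to
#'   `n_bgd`.
#' @export
scale_background <- function(bgd, n_bgd, n_total) {
  assert_unsigned(bgd, "background distribution")
  if (n_bgd < 0) abort("n_bgd must be >= 0")
  if (n_bgd > n_total) abort("n_bgd cannot exceed n_total")
  if (abs(attr(bgd, "n") - n_total) > 1e-9) {
    abort("background distribution N does not equal n_total")
  }
  intensity_distribution(
    bgd$intensity, bgd$frequency * (n_bgd / n_total),
    dwell_time = attr(bgd, "dwell_time"),
    label = "bgd_corr"
  )
}

#' Subtract the rescaled blank from the sample histogram
#'
#' The final difference: in expectation only particle pulses remain. Small
#' negative residuals can survive where small particles overlap the
#' background body; they are reported, not hidden.
#'
#' @param sample Unsigned sample [intensity_distribution].
#' @param bgd_corr Rescaled blank from [scale_background()].
#' @return A signed [intensity_distribution] ("sample - bgd_corr").
#' @export
corrected_sample <- function(sample, bgd_corr) {
  assert_unsigned(sample, "sample distribution")
  assert_unsigned(bgd_corr, "rescaled background")
  j <- align_bins(sample, bgd_corr)
  intensity_distribution(
    j$intensity, j$fa - j$fb,
    dwell_time = attr(sample, "dwell_time"),
    signed = TRUE,
    label = "sample - bgd_corr"
  )
}

#' Transition intensity of a corrected difference distribution
#'
#' The largest intensity whose frequency is still negative: below it the
#' histogram is background-dominated, above it particle-dominated. When no
#' negative frequencies remain the whole histogram is particle signal and -1
#' is returned. With multiple sign changes the last (largest) negative
#' intensity governs - the conservative reading.
#'
#' @param diff_corr Signed distribution from [corrected_sample()].
#' @return Transition intensity I_t (integer, or -1).
#' @export
transition_intensity <- function(diff_corr) {
  stopifnot(inherits(diff_corr, "sp_distribution"))
  if (!is_signed(diff_corr)) abort("transition_intensity expects a signed distribution")
  neg <- diff_corr$intensity[diff_corr$frequency < -1e-9]
  if (length(neg) == 0) -1L else max(neg)
}

#' Modal background intensity
#'
#' The intensity at the maximum of the blank frequency-intensity
#' distribution (smallest such intensity on ties). This is the per-window
#' background level netted out of each particle pulse.
#'
#' @param bgd Unsigned blank [intensity_distribution].
#' @return Modal intensity (integer).
#' @export
modal_background <- function(bgd) {
  assert_unsigned(bgd, "background distribution")
  dist_mode(bgd)
}

#' Run the full histogram-subtraction background correction
#'
#' Executes the whole chain on a matched sample/blank pair of
#' frequency-intensity distributions: raw difference, particle count from its
#' negative mass, background count, blank rescaling, corrected difference,
#' transition intensity and modal background. Per-particle net intensities
#' are then read off the corrected distribution: each intensity strictly
#' above the transition point contributes its (fractional) corrected
#' frequency rounded to the nearest non-negative integer, at a net value of
#' the gross intensity minus the modal background. Net values below one count
#' are indistinguishable from background and discarded.
#'
#' @param sample,bgd Unsigned [intensity_distribution]s with equal N and
#'   dwell time (sample and matched blank).
#' @return An object of class `sp_correction`: a list with elements
#'   `n_total`, `n_particles`, `n_background`, `transition_intensity`,
#'   `modal_background`, `raw_difference`, `scaled_background`, `corrected`
#'   (signed distribution), `net` (tibble of gross intensity, net intensity,
#'   integer frequency), `net_intensities` (expanded integer vector) and
#'   `diagnostics`.
#' @seealso [size_distribution()] to convert the net intensities to particle
#'   diameters, [tidy()] and [glance()] accessors, [autoplot()].
#' @export
run_correction <- function(sample, bgd) {
  check_matched(sample, bgd)
  n_total <- attr(sample, "n")

  raw_diff <- subtract_distributions(sample, bgd)
  n_np <- particle_count(raw_diff)
  n_bgd <- n_total - n_np

  bgd_corr <- scale_background(bgd, n_bgd, n_total)
  corrected <- corrected_sample(sample, bgd_corr)
  i_t <- transition_intensity(corrected)
  i_mode <- modal_background(bgd)

  warnings <- character()
  if (abs(i_mode - i_t) > 2 && i_t >= 0) {
    warnings <- c(warnings, sprintf(
      "modal background (%d) and transition intensity (%d) differ by more than 2 counts",
      i_mode, i_t
    ))
  }

  cand <- corrected[corrected$intensity > i_t, , drop = FALSE]
  freq_int <- floor(pmax(cand$frequency, 0) + 0.5) # round half up, clip at 0
  net_val <- cand$intensity - i_mode
  keep <- freq_int >= 1 & net_val >= 1
  net <- tibble(
    intensity = cand$intensity[keep],
    net = as.integer(net_val[keep]),
    frequency = as.integer(freq_int[keep])
  )
  residual_negative <- sum(pmin(corrected$frequency, 0))

  structure(
    list(
      n_total = n_total,
      n_particles = n_np,
      n_background = n_bgd,
      transition_intensity = i_t,
      modal_background = i_mode,
      raw_difference = raw_diff,
      scaled_background = bgd_corr,
      corrected = corrected,
      net = net,
      net_intensities = rep(net$net, net$frequency),
      diagnostics = list(
        residual_negative_mass = residual_negative,
        raw_negative_mass = -n_np,
        dwell_time = attr(sample, "dwell_time"),
        warnings = warnings
      )
    ),
    class = "sp_correction"
  )
}

#' Run the correction directly on a pair of traces
#'
#' Convenience wrapper: builds the frequency-intensity distributions of a
#' sample trace and its matched blank and calls [run_correction()].
#'
#' @param sample_trace,blank_trace [sp_trace]s of equal length and dwell time.
#' @return An `sp_correction`.
#' @export
correct_trace <- function(sample_trace, blank_trace) {
  run_correction(
    build_distribution(sample_trace),
    build_distribution(blank_trace)
  )
}

#' @export
print.sp_correction <- function(x, ...) {
  cat("<sp_correction>\n")
  cat(sprintf("  windows (N):           %g\n", x$n_total))
  cat(sprintf("  particles (N_NP):      %g\n", x$n_particles))
  cat(sprintf("  background (N_bgd):    %g\n", x$n_background))
  cat(sprintf("  transition intensity:  %d counts\n", x$transition_intensity))
  cat(sprintf("  modal background:      %d counts\n", x$modal_background))
  cat(sprintf("  residual negative:     %.3g\n", x$diagnostics$residual_negative_mass))
  for (w in x$diagnostics$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' @export
tidy.sp_correction <- function(x, ...) {
  x$net
}

#' @export
glance.sp_correction <- function(x, ...) {
  tibble(
    n_total = x$n_total,
    n_particles = x$n_particles,
    n_background = x$n_background,
    transition_intensity = x$transition_intensity,
    modal_background = x$modal_background,
    residual_negative_mass = x$diagnostics$residual_negative_mass,
    n_net_pulses = length(x$net_intensities)
  )
}

#' @export
autoplot.sp_correction <- function(object, ...) {
  autoplot(object$corrected) +
    ggplot2::geom_vline(
      xintercept = object$transition_intensity,
      linetype = "dashed", colour = "steelblue"
    ) +
    ggplot2::labs(
      title = "Corrected sample - bgd_corr distribution",
      subtitle = sprintf(
        "N_NP = %g, transition at %d counts, modal background %d counts",
        object$n_particles, object$transition_intensity, object$modal_background
      )
    )
}

#' Trim rare high-intensity tail bins
#'
#' Removes bins from the high end of a distribution inward while their
#' frequency stays below `min_frequency`; interior low-frequency bins are
#' never touched. Rare isolated high signals (large agglomerates, particle
#' coincidences, cross-contamination) are thereby excluded from the reported
#' distribution.
#'
#' @param dist An unsigned [intensity_distribution] or [size_distribution()]
#'   result (any tibble whose first column is the bin position and which has
#'   a `frequency` column, sorted ascending).
#' @param min_frequency Minimum frequency a tail bin must reach to be kept
#'   (default 10); 0 keeps everything.
#' @return The distribution with the rare tail removed.
#' @export
tail_filter <- function(dist, min_frequency = 10) {
  stopifnot(is.data.frame(dist), "frequency" %in% names(dist))
  if (min_frequency < 0) abort("min_frequency must be >= 0")
  if (nrow(dist) == 0 || min_frequency == 0) return(dist)
  if (inherits(dist, "sp_distribution") && is_signed(dist)) {
    abort("tail_filter expects an unsigned distribution")
  }
  keep_upto <- max(c(0L, which(dist$frequency >= min_frequency)))
  out <- dist[seq_len(keep_upto), , drop = FALSE]
  if (!is.null(attr(dist, "n"))) attr(out, "n") <- sum(out$frequency)
  out
}
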