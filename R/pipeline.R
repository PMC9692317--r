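#' Convert corrected net intensities to a particle size distribution
#'
#' Maps every net pulse intensity through the calibration to an equivalent
#' spherical diameter, drops anything below the size limit of detection,
#' rounds to the nearest nm (net intensities are integer counts, so sizes are
#' naturally discrete) and trims the rare high-size tail with [tail_filter()].
#'
#' @param result An `sp_correction` from [run_correction()].
#' @param cal A complete [calibration_model()].
#' @param min_frequency Tail-filter threshold (default 10; 0 disables).
#' @return A tibble of class `sp_sizedist` with columns `diameter` (nm) and
#'   `frequency`, plus attributes `n_particles`, `max_position` (modal
#'   diameter, smallest on ties), `right_wing` (largest surviving diameter),
#'   `lod_size`, `dwell_time`.
#' @export
size_distribution <- function(result, cal, min_frequency = 10) {
  stopifnot(inherits(result, "sp_correction"))
  assert_complete_calibration(cal)
  lod <- lod_size(cal)

  bins <- result$net
  if (nrow(bins) > 0) {
    sizes <- intensity_to_size(bins$net, cal)
    keep <- sizes >= lod - 1e-9
    df <- tibble(
      diameter = as.integer(round(sizes[keep])),
      frequency = bins$frequency[keep]
    ) |>
      group_by(.data$diameter) |>
      summarise(frequency = sum(.data$frequency), .groups = "drop") |>
      arrange(.data$diameter)
  } else {
    df <- tibble(diameter = integer(), frequency = integer())
  }
  df <- tail_filter(df, min_frequency)
  if (nrow(df) == 0) {
    warn("empty size distribution: no particle pulses survive the LOD and tail filters")
  }

  out <- df
  attr(out, "n_particles") <- sum(df$frequency)
  attr(out, "max_position") <- if (nrow(df)) df$diameter[which.max(df$frequency)] else NA_real_
  attr(out, "right_wing") <- if (nrow(df)) max(df$diameter) else NA_real_
  attr(out, "lod_size") <- lod
  attr(out, "dwell_time") <- result$diagnostics$dwell_time
  class(out) <- c("sp_sizedist", "tbl_df", "tbl", "data.frame")
  out
}

#' @export
print.sp_sizedist <- function(x, ...) {
  cat(sprintf(
    "<sp_sizedist> %d size bins, %g particles, max at %s nm, right wing %s nm, LOD %.1f nm\n",
    nrow(x), attr(x, "n_particles"),
    format(attr(x, "max_position")), format(attr(x, "right_wing")),
    attr(x, "lod_size")
  ))
  NextMethod()
}

#' @export
tidy.sp_sizedist <- function(x, ...) {
  tibble(diameter = x$diameter, frequency = x$frequency)
}

#' @export
glance.sp_sizedist <- function(x, ...) {
  tibble(
    n_particles = attr(x, "n_particles"),
    max_position = attr(x, "max_position"),
    right_wing = attr(x, "right_wing"),
    lod_size = attr(x, "lod_size"),
    dwell_time = attr(x, "dwell_time")
  )
}

#' @export
autoplot.sp_sizedist <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$diameter, y = .data$frequency)) +
    ggplot2::geom_col(width = 1, fill = "grey30") +
    ggplot2::geom_vline(
      xintercept = attr(object, "lod_size"),
      linetype = "dotted", colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "Equivalent spherical diameter (nm)", y = "Frequency (particles)",
      subtitle = sprintf(
        "%g particles, maximum at %s nm, LOD %.0f nm",
        attr(object, "n_particles"), format(attr(object, "max_position")),
        attr(object, "lod_size")
      )
    ) +
    ggplot2::theme_minimal()
}

# size distribution of candidate particle windows WITHOUT the modal-background
# subtraction: gross intensities above the transition point mapped straight
# through the calibration. This is the "before correction" view whose maximum
# drifts with dwell time because the background rides on every pulse.
uncorrected_size_distribution <- function(result, cal, min_frequency = 10) {
  stopifnot(inherits(result, "sp_correction"))
  assert_complete_calibration(cal)
  cand <- result$corrected[result$corrected$intensity > result$transition_intensity, ,
    drop = FALSE
  ]
  freq <- floor(pmax(cand$frequency, 0) + 0.5)
  keep <- freq >= 1
  df <- tibble(
    diameter = as.integer(round(intensity_to_size(cand$intensity[keep], cal))),
    frequency = as.integer(freq[keep])
  ) |>
    group_by(.data$diameter) |>
    summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    arrange(.data$diameter)
  tail_filter(df, min_frequency)
}

#' Dwell-time sweep report
#'
#' Processes matched sample/blank pairs acquired at several dwell times
#' through the full correction and sizing pipeline and reports, per dwell
#' time, the modal diameter before and after the background correction, the
#' right wing of the corrected distribution and the particle count. The
#' uncorrected maximum drifts upward with dwell time (the background rides on
#' every pulse); the corrected maximum should not.
#'
#' @param samples List of sample [sp_trace]s, one per dwell time.
#' @param blanks List of blank [sp_trace]s; each sample must have a blank at
#'   the same dwell time.
#' @param cal A complete [calibration_model()].
#' @param min_frequency Tail-filter threshold passed to [size_distribution()].
#' @return A tibble with one row per dwell time: `dwell_time`,
#'   `uncorrected_max`, `corrected_max`, `right_wing`, `n_particles`.
#' @export
dwell_sweep_report <- function(samples, blanks, cal, min_frequency = 10) {
  stopifnot(is.list(samples), is.list(blanks))
  blank_dwells <- vapply(blanks, dwell_time, numeric(1))
  rows <- purrr::map(samples, function(s) {
    dt <- dwell_time(s)
    match <- which(abs(blank_dwells - dt) < 1e-9)
    if (length(match) == 0) {
      abort(sprintf("unmatched dwell time: no blank at %g ms", dt))
    }
    res <- correct_trace(s, blanks[[match[1]]])
    sizes <- suppressWarnings(size_distribution(res, cal, min_frequency))
    unc <- uncorrected_size_distribution(res, cal, min_frequency)
    tibble(
      dwell_time = dt,
      uncorrected_max = if (nrow(unc)) unc$diameter[which.max(unc$frequency)] else NA_real_,
      corrected_max = attr(sizes, "max_position"),
      right_wing = attr(sizes, "right_wing"),
      n_particles = res$n_particles
    )
  })
  bind_rows(rows) |> arrange(.data$dwell_time)
}

#' Write / read a full analysis report
#'
#' TSV with a `#` header block carrying the correction summary (N, N_NP,
#' N_bgd, transition intensity, modal background, LOD, dwell time) followed
#' by one row per size bin. [read_report()] restores both parts with full
#' precision.
#'
#' @param sizes An `sp_sizedist` from [size_distribution()].
#' @param result The `sp_correction` the sizes came from.
#' @param path Output path.
#' @return `path` invisibly; `read_report()` returns a list
#'   `list(header, sizes)`.
#' @export
write_report <- function(sizes, result, path) {
  stopifnot(inherits(sizes, "sp_sizedist"), inherits(result, "sp_correction"))
  if (nrow(sizes) == 0) warn("writing report with empty size distribution")
  header <- c(
    sprintf("# n_total: %.17g", result$n_total),
    sprintf("# n_particles: %.17g", result$n_particles),
    sprintf("# n_background: %.17g", result$n_background),
    sprintf("# transition_intensity: %d", result$transition_intensity),
    sprintf("# modal_background: %d", result$modal_background),
    sprintf("# residual_negative_mass: %.17g", result$diagnostics$residual_negative_mass),
    sprintf("# lod_size_nm: %.17g", attr(sizes, "lod_size")),
    sprintf("# dwell_time_ms: %.17g", attr(sizes, "dwell_time"))
  )
  body <- sprintf("%d\t%.17g", sizes$diameter, sizes$frequency)
  readr::write_lines(c(header, "diameter_nm\tfrequency", body), path)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing file: %s", path))
  lines <- readr::read_lines(path)
  meta <- parse_hash_meta(lines[startsWith(lines, "#")])
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  sizes <- readr::read_tsv(I(body), show_col_types = FALSE)
  list(
    header = lapply(meta, function(v) as.numeric(v)),
    sizes = tibble(
      diameter = as.integer(sizes$diameter_nm),
      frequency = as.numeric(sizes$frequency)
    )
  )
}
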