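#' Frequency-intensity distributions
#'
#' The central data structure of the correction: a histogram of how many
#' dwell windows registered each integer count value ("frequency" against
#' "intensity"). Bin width is fixed at one count because detector counts are
#' integral. Difference distributions produced by the correction carry
#' `signed = TRUE` and may hold negative (and, after rescaling, fractional)
#' frequencies.
#'
#' @param intensity Integer vector of count values (>= 0).
#' @param frequency Numeric vector of frequencies, same length. Must be
#'   non-negative unless `signed = TRUE`.
#' @param dwell_time Dwell time in ms of the underlying trace (optional).
#' @param signed Is this a difference distribution?
#' @param label Optional free-text label.
#'
#' @return A tibble of class `sp_distribution` with columns `intensity`,
#'   `frequency`, sorted by intensity, and attributes `n` (total number of
#'   signals for unsigned distributions), `dwell_time`, `signed`, `label`.
#' @examples
#' intensity_distribution(c(0, 3, 5), c(1, 2, 1))
#' @export
intensity_distribution <- function(intensity, frequency, dwell_time = NA_real_,
                                   signed = FALSE, label = NULL) {
  if (length(intensity) != length(frequency)) {
    abort("intensity and frequency must have the same length")
  }
  if (length(intensity) > 0) {
    if (any(intensity < 0)) abort("intensity keys must be >= 0")
    if (any(abs(intensity - round(intensity)) > 1e-9)) {
      abort("intensity keys must be integers (bin width is 1 count)")
    }
    if (anyDuplicated(round(intensity))) abort("duplicate intensity keys")
    if (!signed && any(frequency < 0)) {
      abort("unsigned distribution with negative frequency")
    }
  }
  ord <- order(intensity)
  out <- tibble(
    intensity = as.integer(round(intensity))[ord],
    frequency = as.numeric(frequency)[ord]
  )
  attr(out, "n") <- if (signed) NA_real_ else sum(out$frequency)
  attr(out, "dwell_time") <- as.numeric(dwell_time)
  attr(out, "signed") <- isTRUE(signed)
  attr(out, "label") <- label
  class(out) <- c("sp_distribution", class(out))
  out
}

#' @rdname intensity_distribution
#' @param dist An `sp_distribution`.
#' @export
n_signals <- function(dist) attr(dist, "n")

#' @rdname intensity_distribution
#' @export
is_signed <- function(dist) isTRUE(attr(dist, "signed"))

#' @export
print.sp_distribution <- function(x, ...) {
  cat(sprintf(
    "<sp_distribution>%s %d bins%s%s\n",
    if (is_signed(x)) " (signed difference)" else "",
    nrow(x),
    if (!is_signed(x)) sprintf(", N = %g signals", attr(x, "n")) else "",
    if (!is.na(attr(x, "dwell_time"))) sprintf(", dwell %g ms", attr(x, "dwell_time")) else ""
  ))
  NextMethod()
}

assert_unsigned <- function(dist, what = "distribution") {
  stopifnot(inherits(dist, "sp_distribution"))
  if (is_signed(dist)) abort(sprintf("%s must be unsigned", what))
  if (nrow(dist) == 0 || sum(dist$frequency) == 0) {
    abort(sprintf("empty %s", what))
  }
  invisible(dist)
}

#' Build the frequency-intensity distribution of a trace
#'
#' Tabulates how many dwell windows registered each integer count value.
#' The total frequency always equals the number of windows.
#'
#' @param trace An [sp_trace].
#' @return An unsigned [intensity_distribution].
#' @examples
#' build_distribution(sp_trace(c(3, 5, 3, 0), dwell_time = 10))
#' @export
build_distribution <- function(trace) {
  stopifnot(inherits(trace, "sp_trace"))
  tab <- table(trace$count)
  intensity_distribution(
    intensity = as.integer(names(tab)),
    frequency = as.numeric(tab),
    dwell_time = attr(trace, "dwell_time"),
    label = attr(trace, "label")
  )
}

#' Summary statistics of a frequency-intensity distribution
#'
#' Frequency-weighted mean and population standard deviation, modal
#' intensity (smallest intensity on ties), range and width. These are the
#' quantities the classical n-sigma particle threshold is built from.
#'
#' @param dist An unsigned [intensity_distribution].
#' @return A one-row tibble with columns `n`, `mean`, `sd`, `mode`, `min`,
#'   `max`, `width`.
#' @export
summary_stats <- function(dist) {
  assert_unsigned(dist)
  n <- sum(dist$frequency)
  m <- sum(dist$intensity * dist$frequency) / n
  v <- sum(dist$frequency * (dist$intensity - m)^2) / n
  tibble(
    n = n,
    mean = m,
    sd = sqrt(v),
    mode = dist_mode(dist),
    min = min(dist$intensity[dist$frequency > 0]),
    max = max(dist$intensity[dist$frequency > 0]),
    width = diff(range(dist$intensity[dist$frequency > 0]))
  )
}

dist_mode <- function(dist) {
  keep <- dist$frequency > 0
  ints <- dist$intensity[keep]
  freq <- dist$frequency[keep]
  ints[which.max(freq)] # which.max takes the first, i.e. smallest intensity
}

#' Classical n-sigma particle threshold
#'
#' `mean + n * sd` of the background distribution; windows strictly above the
#' threshold are classified as candidate particles. Returned real-valued.
#'
#' @param dist Unsigned background [intensity_distribution].
#' @param n Sigma multiplier (> 0), conventionally 3, 5 or 10.
#' @return Threshold intensity (numeric scalar).
#' @export
nsigma_threshold <- function(dist, n = 3) {
  if (!is.numeric(n) || n <= 0) abort("sigma multiplier n must be > 0")
  s <- summary_stats(dist)
  s$mean + n * s$sd
}

#' Poisson decision threshold
#'
#' The smallest integer L such that a Poisson variate with the distribution's
#' mean exceeds L with probability at most `alpha`. This is the simple
#' counting-statistics decision threshold used by single-particle processing
#' software, provided here for comparison with the histogram-subtraction
#' correction.
#'
#' @param dist Unsigned background [intensity_distribution].
#' @param alpha Acceptable false-positive rate per window.
#' @return Integer threshold L; signals strictly above L are flagged.
#' @export
poisson_threshold <- function(dist, alpha = 0.001) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) {
    abort("alpha must be in (0, 1]")
  }
  s <- summary_stats(dist)
  # smallest L with P(X > L) <= alpha, i.e. ppois(L) >= 1 - alpha
  qpois(1 - alpha, lambda = s$mean)
}

#' Number of signals strictly above a threshold
#'
#' @param dist Unsigned [intensity_distribution].
#' @param threshold Intensity threshold (real-valued allowed).
#' @return Total frequency over intensities strictly greater than `threshold`.
#' @export
count_above <- function(dist, threshold) {
  assert_unsigned(dist)
  sum(dist$frequency[dist$intensity > threshold])
}

#' Write / read a distribution as two-column TSV
#'
#' @param dist An [intensity_distribution].
#' @param path File path.
#' @return `path` invisibly, or the re-read distribution.
#' @export
write_distribution <- function(dist, path) {
  stopifnot(inherits(dist, "sp_distribution"))
  header <- c(
    sprintf("# signed: %s", tolower(as.character(is_signed(dist)))),
    sprintf("# dwell_time_ms: %.10g", attr(dist, "dwell_time"))
  )
  body <- sprintf("%d\t%.17g", dist$intensity, dist$frequency)
  readr::write_lines(c(header, "intensity\tfrequency", body), path)
  invisible(path)
}

#' @rdname write_distribution
#' @export
read_distribution <- function(path) {
  if (!file.exists(path)) abort(sprintf("missing file: %s", path))
  lines <- readr::read_lines(path)
  meta <- parse_hash_meta(lines[startsWith(lines, "#")])
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  df <- readr::read_tsv(I(body), show_col_types = FALSE)
  intensity_distribution(
    df$intensity, df$frequency,
    dwell_time = as.numeric(meta$dwell_time_ms %||% NA_real_),
    signed = identical(meta$signed, "true")
  )
}

#' Plot a frequency-intensity distribution
#'
#' @param object An [intensity_distribution].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sp_distribution <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$intensity, y = .data$frequency)) +
    ggplot2::geom_col(
      ggplot2::aes(fill = .data$frequency < 0),
      width = 1, show.legend = FALSE
    ) +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey30", `TRUE` = "firebrick")) +
    ggplot2::geom_hline(yintercept = 0, linewidth = 0.3) +
    ggplot2::labs(
      x = "Intensity (counts)", y = "Frequency (signals)",
      title = attr(object, "label")
    ) +
    ggplot2::theme_minimal()
}
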