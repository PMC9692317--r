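#' Construct a time-resolved SP-ICP-MS trace
#'
#' A trace is the raw output of a time-resolved acquisition: one integer
#' detector count per dwell-time window. It is stored as a tibble with a
#' single `count` column plus acquisition metadata carried in attributes, so
#' it pipes into the usual dplyr verbs while staying a first-class object for
#' the rest of the pipeline.
#'
#' @param counts Non-negative integer vector, one value per dwell window.
#'   Values within 1e-9 of an integer are rounded; anything else is an error.
#' @param dwell_time Dwell time (window length) in milliseconds, > 0.
#' @param mz Optional integer mass-to-charge label (e.g. 48 for Ti, 107 for Ag).
#' @param label Optional free-text label.
#' @param total_time Optional total acquisition time in seconds. Defaults to
#'   `length(counts) * dwell_time / 1000`; if supplied it must agree with that
#'   value to within one window.
#'
#' @return A tibble of class `sp_trace` with column `count` and attributes
#'   `dwell_time` (ms), `mz`, `label`, `total_time` (s).
#' @examples
#' tr <- sp_trace(c(3, 5, 4), dwell_time = 10)
#' n_windows(tr)
#' @export
sp_trace <- function(counts, dwell_time, mz = NA_integer_, label = NULL,
                     total_time = NULL) {
  if (length(counts) < 1) {
    abort("no windows: a trace needs at least one dwell-time window")
  }
  if (!is.numeric(counts) || anyNA(counts)) {
    abort("counts must be numeric and non-missing")
  }
  rounded <- round(counts)
  if (any(abs(counts - rounded) > 1e-9)) {
    bad <- which(abs(counts - rounded) > 1e-9)[1]
    abort(sprintf("non-integer count %.6g at window %d", counts[bad], bad))
  }
  if (any(rounded < 0)) {
    abort("negative count: detector counts must be >= 0")
  }
  if (!is.numeric(dwell_time) || length(dwell_time) != 1 || dwell_time <= 0) {
    abort("dwell_time must be a single positive number of milliseconds")
  }
  implied <- length(rounded) * dwell_time / 1000
  if (is.null(total_time)) {
    total_time <- implied
  } else if (abs(total_time - implied) > dwell_time / 1000 + 1e-9) {
    abort(sprintf(
      "total_time (%.4g s) inconsistent with %d windows of %.4g ms",
      total_time, length(rounded), dwell_time
    ))
  }
  out <- tibble(count = as.integer(rounded))
  attr(out, "dwell_time") <- as.numeric(dwell_time)
  attr(out, "mz") <- if (is.na(mz)) NA_integer_ else as.integer(mz)
  attr(out, "label") <- label
  attr(out, "total_time") <- as.numeric(total_time)
  class(out) <- c("sp_trace", class(out))
  out
}

#' @rdname sp_trace
#' @param trace An `sp_trace`.
#' @export
n_windows <- function(trace) nrow(trace)

#' @rdname sp_trace
#' @export
dwell_time <- function(trace) attr(trace, "dwell_time")

#' @export
print.sp_trace <- function(x, ...) {
  cat(sprintf(
    "<sp_trace> %d windows, dwell %g ms, total %g s%s\n",
    nrow(x), attr(x, "dwell_time"), attr(x, "total_time"),
    if (!is.na(attr(x, "mz"))) sprintf(", m/z %d", attr(x, "mz")) else ""
  ))
  NextMethod()
}

#' Read a time-resolved trace from a delimited text file
#'
#' Accepts the simplest common denominator of vendor exports: one numeric
#' count per line. Lines starting with `#` are metadata of the form
#' `# key: value` (recognised keys: `dwell_time_ms`, `mz`, `label`,
#' `total_time_s`); a single non-numeric first data line is treated as a
#' column header and skipped. Values within 1e-9 of an integer are rounded,
#' anything else is an error.
#'
#' @param path Path to the file.
#' @param dwell_time Dwell time in ms. Optional when the file carries a
#'   `# dwell_time_ms:` header; an explicit argument wins over the header.
#' @param mz Optional m/z label, same precedence as `dwell_time`.
#' @return An [sp_trace].
#' @export
read_trace <- function(path, dwell_time = NULL, mz = NULL) {
  if (!file.exists(path)) abort(sprintf("missing file: %s", path))
  lines <- readr::read_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  meta_lines <- lines[startsWith(lines, "#")]
  data_lines <- lines[!startsWith(lines, "#")]
  meta <- parse_hash_meta(meta_lines)

  if (length(data_lines) >= 1) {
    first <- suppressWarnings(as.numeric(data_lines[1]))
    if (is.na(first)) data_lines <- data_lines[-1] # column header
  }
  if (length(data_lines) == 0) abort(sprintf("no windows in %s", path))
  values <- suppressWarnings(as.numeric(data_lines))
  if (anyNA(values)) {
    bad <- which(is.na(values))[1]
    abort(sprintf("non-numeric record '%s' in %s", data_lines[bad], path))
  }
  explicit_dwell <- !is.null(dwell_time)
  dwell_time <- dwell_time %||% meta$dwell_time_ms %||%
    abort(sprintf("dwell_time not given and no '# dwell_time_ms:' header in %s", path))
  # a header total_time describes the file's own dwell time; drop it when an
  # explicit dwell_time argument overrides the header
  total_time <- if (!explicit_dwell && !is.null(meta$total_time_s)) {
    as.numeric(meta$total_time_s)
  }
  sp_trace(
    values,
    dwell_time = as.numeric(dwell_time),
    mz = as.integer(mz %||% meta$mz %||% NA_integer_),
    label = meta$label,
    total_time = total_time
  )
}

parse_hash_meta <- function(lines) {
  out <- list()
  for (ln in lines) {
    body <- sub("^#\\s*", "", ln)
    if (!grepl(":", body, fixed = TRUE)) next
    key <- trimws(sub(":.*$", "", body))
    val <- trimws(sub("^[^:]*:", "", body))
    if (nzchar(key)) out[[key]] <- val
  }
  out
}

#' Write a trace to disk
#'
#' Writes `# key: value` metadata lines followed by one count per line.
#' [read_trace()] on the result reproduces the original trace exactly.
#'
#' @param trace An [sp_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "sp_trace"))
  header <- c(
    sprintf("# dwell_time_ms: %.10g", attr(trace, "dwell_time")),
    sprintf("# total_time_s: %.10g", attr(trace, "total_time")),
    if (!is.na(attr(trace, "mz"))) sprintf("# mz: %d", attr(trace, "mz")),
    if (!is.null(attr(trace, "label"))) sprintf("# label: %s", attr(trace, "label"))
  )
  readr::write_lines(c(header, format(trace$count, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}

#' Convert between absolute counts and counts per second
#'
#' Detector output is accumulated over one dwell window; dividing by the
#' window length expresses it as a rate. The two functions are exact inverses.
#'
#' @param counts Intensity in counts (vectorised).
#' @param cps Intensity in counts per second (vectorised).
#' @param dwell_time Dwell time in milliseconds, > 0.
#' @return Numeric vector.
#' @examples
#' counts_to_cps(40, 10) # 4000 cps
#' @export
counts_to_cps <- function(counts, dwell_time) {
  check_dwell(dwell_time)
  counts / (dwell_time / 1000)
}

#' @rdname counts_to_cps
#' @export
cps_to_counts <- function(cps, dwell_time) {
  check_dwell(dwell_time)
  cps * (dwell_time / 1000)
}

check_dwell <- function(dwell_time) {
  if (!is.numeric(dwell_time) || any(dwell_time <= 0)) {
    abort("dwell_time must be > 0 ms")
  }
  invisible(dwell_time)
}

#' Read a run configuration
#'
#' Flat key-value YAML with defaults filled in for anything not present.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return A list with elements `dwell_time` (ms), `min_tail_frequency`,
#'   `sigma_multiplier`, `seed`, `dilution_factor`, `paths`.
#' @export
read_run_config <- function(path = NULL) {
  defaults <- list(
    dwell_time = 10,
    min_tail_frequency = 10,
    sigma_multiplier = 3,
    seed = 1L,
    dilution_factor = 1,
    paths = list()
  )
  cfg <- if (is.null(path)) list() else yaml::read_yaml(path)
  out <- utils::modifyList(defaults, cfg)
  if (out$dwell_time <= 0) abort("dwell_time must be > 0")
  if (out$min_tail_frequency < 0) abort("min_tail_frequency must be >= 0")
  out
}
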