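#' Construct an interbeat-interval (IBI) series
#'
#' An IBI series is the package's core currency: one row per heartbeat, with
#' the interval in milliseconds, the beat onset in seconds from the start of
#' the recording (cumulative sum of intervals), and a logical artifact flag.
#' Intervals outside the hard physiological range (250--3000 ms by default,
#' i.e. 20--240 bpm) are always flagged: a chest-strap sensor dropout or a
#' doubled beat cannot be a real heartbeat.
#'
#' @param ibi_ms Numeric vector of interbeat intervals, milliseconds. All
#'   values must be positive and finite.
#' @param participant_id Participant identifier (recycled into a column).
#' @param source Free-text provenance label (e.g. file name, "synthetic").
#' @param range_ms Length-2 numeric: hard physiological range in ms; intervals
#'   outside it are artifact-flagged at construction.
#'
#' @return A tibble of class `ibi_df` with columns `t_s` (onset, seconds),
#'   `ibi_ms`, `artifact` (logical), `participant_id`, `source`.
#' @examples
#' ibi_series(c(857, 823, 910))
#' @export
ibi_series <- function(ibi_ms, participant_id = "anon", source = "memory",
                       range_ms = c(250, 3000)) {
  ibi_ms <- as.numeric(ibi_ms)
  if (length(ibi_ms) == 0) abort("no intervals")
  bad <- which(!is.finite(ibi_ms) | ibi_ms <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or non-positive interval at row %d", bad[1]))
  }
  out <- tibble(
    t_s = cumsum(ibi_ms) / 1000,
    ibi_ms = ibi_ms,
    artifact = ibi_ms < range_ms[1] | ibi_ms > range_ms[2],
    participant_id = as.character(participant_id),
    source = as.character(source)
  )
  class(out) <- c("ibi_df", class(out))
  out
}

#' Parse a delimited interbeat-interval stream
#'
#' Reads the plain-text format a beat logger emits: one interval (ms) per row.
#' Accepts a headerless single column, or a delimited file with an `ibi_ms`
#' column and an optional `t_s` device-timestamp column (ignored for onsets,
#' which are always recomputed cumulatively so the invariants hold).
#'
#' @param text Either a character scalar holding the raw stream (newline
#'   separated) or a path to a CSV/TSV file.
#' @param participant_id Participant identifier.
#' @inheritParams ibi_series
#' @return An [ibi_series()] tibble.
#' @examples
#' parse_ibi("857\n823\n910")
#' @export
parse_ibi <- function(text, participant_id = "anon", range_ms = c(250, 3000)) {
  is_path <- length(text) == 1 && !grepl("[\n,\t]", text) && file.exists(text)
  src <- if (is_path) text else "text"
  raw <- if (is_path) readLines(text, warn = FALSE) else {
    unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  }
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  if (length(raw) == 0) abort("no intervals")
  # header detection: first field of first row non-numeric
  fields <- strsplit(raw, "[,\t;]")
  first <- suppressWarnings(as.numeric(fields[[1]][1]))
  col <- 1L
  if (is.na(first)) {
    header <- trimws(fields[[1]])
    col <- match("ibi_ms", header)
    if (is.na(col)) col <- 1L
    raw <- raw[-1]
    fields <- fields[-1]
    if (length(raw) == 0) abort("no intervals")
  }
  vals <- suppressWarnings(as.numeric(vapply(fields, function(f) {
    trimws(f[min(col, length(f))])
  }, character(1))))
  bad <- which(is.na(vals) | vals <= 0)
  if (length(bad) > 0) {
    abort(sprintf("non-numeric or non-positive interval at row %d", bad[1]))
  }
  ibi_series(vals, participant_id = participant_id, source = src,
             range_ms = range_ms)
}

#' Write an IBI series to CSV
#'
#' Columns `ibi_ms`, `t_s`, `artifact` (0/1). [parse_ibi()] on the result
#' recovers the intervals exactly (round-trip identity).
#'
#' @param series An [ibi_series()] tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ibi_csv <- function(series, path) {
  df <- data.frame(ibi_ms = series$ibi_ms, t_s = series$t_s,
                   artifact = as.integer(series$artifact))
  readr::write_csv(df, path)
  invisible(path)
}

#' Flag and edit interbeat-interval artifacts
#'
#' Standard relative-deviation editing: a beat deviating more than
#' `rel_threshold` from the running median of `window` beats (centred, edges
#' padded) is flagged, together with anything outside the hard physiological
#' range. Flagged beats are then either replaced by linear interpolation
#' against beat index over the surviving neighbours (`policy = "interpolate"`,
#' the default) or dropped. Cleaning is idempotent: a cleaned series passes
#' through unchanged.
#'
#' @param series An [ibi_series()] tibble with at least `window` beats.
#' @param policy `"interpolate"` or `"drop"`.
#' @param rel_threshold Relative deviation from the running median that flags
#'   a beat (default 0.25 = 25%).
#' @param window Running-median width in beats (odd; default 5).
#' @param range_ms Hard physiological range, ms.
#' @return An `ibi_df` tibble satisfying all series invariants, with
#'   attribute `artifact_fraction` = flagged beats / input beats.
#' @examples
#' s <- ibi_series(c(800, 800, 800, 1600, 800, 800))
#' cleaned <- clean_ibi(s)
#' attr(cleaned, "artifact_fraction")
#' @export
clean_ibi <- function(series, policy = c("interpolate", "drop"),
                      rel_threshold = 0.25, window = 5,
                      range_ms = c(250, 3000)) {
  policy <- match.arg(policy)
  x <- series$ibi_ms
  n <- length(x)
  if (n < window) abort(sprintf("series shorter than running-median window (%d beats)", window))
  med <- stats::runmed(x, k = window, endrule = "median")
  flag <- abs(x - med) > rel_threshold * med
  flag <- flag | x < range_ms[1] | x > range_ms[2]
  frac <- mean(flag)
  if (!any(flag)) {
    out <- ibi_series(x, participant_id = series$participant_id[1],
                      source = series$source[1], range_ms = range_ms)
  } else if (policy == "drop") {
    if (all(flag)) abort("all beats flagged; nothing left to keep")
    out <- ibi_series(x[!flag], participant_id = series$participant_id[1],
                      source = series$source[1], range_ms = range_ms)
  } else {
    idx <- seq_len(n)
    good <- !flag
    if (sum(good) < 2) abort("too few clean beats to interpolate")
    x[flag] <- approx(idx[good], x[good], xout = idx[flag], rule = 2)$y
    out <- ibi_series(x, participant_id = series$participant_id[1],
                      source = series$source[1], range_ms = range_ms)
  }
  attr(out, "artifact_fraction") <- frac
  out
}

#' Signal-quality check for an IBI series
#'
#' Mirrors the pre-training signal review: the session may proceed only if the
#' recording is long enough and clean enough. Mean heart rate is computed over
#' unflagged beats only.
#'
#' @param series An [ibi_series()] tibble (ideally after [clean_ibi()], so the
#'   artifact mask is populated).
#' @param min_duration_s Minimum recording duration, seconds (default 60).
#' @param max_artifact_fraction Maximum tolerated artifact fraction
#'   (default 0.10).
#' @return An object of class `hrv_quality`: a list with `n_beats`,
#'   `duration_s`, `mean_hr_bpm`, `artifact_fraction`, `verdict`
#'   (`"pass"`/`"fail"`). `tidy()` returns it as a one-row tibble.
#' @examples
#' quality_check(ibi_series(rep(1000, 180)))
#' @export
quality_check <- function(series, min_duration_s = 60,
                          max_artifact_fraction = 0.10) {
  frac <- attr(series, "artifact_fraction") %||% mean(series$artifact)
  dur <- tail(series$t_s, 1)
  ok <- series$ibi_ms[!series$artifact]
  hr <- if (length(ok) > 0) 60000 / mean(ok) else NA_real_
  verdict <- if (!is.na(hr) && frac <= max_artifact_fraction &&
                 dur >= min_duration_s) "pass" else "fail"
  structure(
    list(n_beats = nrow(series), duration_s = dur, mean_hr_bpm = hr,
         artifact_fraction = frac, verdict = verdict,
         min_duration_s = min_duration_s,
         max_artifact_fraction = max_artifact_fraction),
    class = "hrv_quality"
  )
}

#' @export
print.hrv_quality <- function(x, ...) {
  cat(sprintf(
    "<hrv_quality> %s: %d beats, %.1f s, mean HR %.1f bpm, artifacts %.1f%%\n",
    toupper(x$verdict), x$n_beats, x$duration_s, x$mean_hr_bpm,
    100 * x$artifact_fraction))
  invisible(x)
}

#' @rdname quality_check
#' @param x An `hrv_quality` object.
#' @param ... Unused.
#' @export
tidy.hrv_quality <- function(x, ...) {
  tibble(n_beats = x$n_beats, duration_s = x$duration_s,
         mean_hr_bpm = x$mean_hr_bpm, artifact_fraction = x$artifact_fraction,
         verdict = x$verdict)
}

#' Serialize a quality report to JSON
#' @param report An `hrv_quality` object.
#' @param path Optional path; if `NULL`, the JSON string is returned.
#' @return JSON string (invisibly if written to `path`).
#' @export
quality_json <- function(report, path = NULL) {
  js <- jsonlite::toJSON(unclass(report)[c("n_beats", "duration_s",
                                           "mean_hr_bpm", "artifact_fraction",
                                           "verdict")],
                         auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
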