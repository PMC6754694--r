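#' Build a training-session plan
#'
#' Two session kinds are supported. The basic resilience-training session is
#' a 3-minute rest (baseline) segment followed by 5 minutes of paced-breathing
#' training. The training-game session inserts the cognitive stressor between
#' them: 3-minute rest, 4-minute flanker stressor, 3-minute post-stress
#' recovery, then the 5-minute training segment. The arm fixes the pacing
#' rate (5 or 6 breaths/min) and whether the biofeedback display is shown;
#' with biofeedback off the display flag is disabled but HRV is still
#' computed continuously in the background.
#'
#' @param kind `"basic"` or `"training_game"`.
#' @param rate_bpm Paced-breathing rate of the arm: 5 or 6.
#' @param biofeedback `TRUE` (display on) or `FALSE` (display off).
#' @return A list of class `session_plan` with elements `kind`, `rate_bpm`,
#'   `biofeedback`, `pacing_hz`, `total_s`, and `segments`, a tibble with
#'   columns `segment`, `start_s`, `end_s`, `duration_s` (half-open
#'   `[start_s, end_s)` intervals).
#' @examples
#' build_session_plan("basic", 6)            # 480 s total
#' build_session_plan("training_game", 5)    # 900 s total
#' @export
build_session_plan <- function(kind = c("basic", "training_game"),
                               rate_bpm = 6, biofeedback = TRUE) {
  kind <- match.arg(kind)
  if (!rate_bpm %in% c(5, 6)) abort("rate_bpm must be 5 or 6")
  durs <- if (kind == "basic") {
    c(rest = 180, training = 300)
  } else {
    c(rest = 180, stressor = 240, recovery = 180, training = 300)
  }
  ends <- cumsum(durs)
  segments <- tibble(
    segment = names(durs),
    start_s = ends - durs,
    end_s = as.numeric(ends),
    duration_s = as.numeric(durs)
  )
  structure(list(
    kind = kind, rate_bpm = rate_bpm, biofeedback = isTRUE(biofeedback),
    pacing_hz = rate_bpm / 60, total_s = sum(durs), segments = segments
  ), class = "session_plan")
}

#' @export
print.session_plan <- function(x, ...) {
  cat(sprintf("<session_plan> %s, %g bpm, biofeedback %s, %g s total\n",
              x$kind, x$rate_bpm, if (x$biofeedback) "on" else "off",
              x$total_s))
  print(x$segments)
  invisible(x)
}

#' Session event log
#'
#' Timing metadata of the non-HRV session events: segment boundaries, the
#' 30-s landscape fades and the per-minute narrator announcements in the
#' rest segment. No media are rendered; this is a timeline.
#'
#' @param plan A [build_session_plan()].
#' @return A tibble with columns `t_s`, `event`.
#' @export
session_events <- function(plan) {
  seg <- plan$segments
  ev <- tibble(t_s = c(seg$start_s, plan$total_s),
               event = c(paste0("segment_start:", seg$segment),
                         "session_end"))
  rest <- seg[seg$segment == "rest", ]
  fades <- seq(30, rest$end_s[1] - 30, by = 30)
  mins <- seq(60, rest$end_s[1] - 60, by = 60)
  ev <- bind_rows(
    ev,
    tibble(t_s = rest$start_s[1] + fades, event = "landscape_fade"),
    tibble(t_s = rest$start_s[1] + mins, event = "minute_announcement")
  )
  arrange(ev, .data$t_s)
}

#' Run a session's HRV analysis over an IBI recording
#'
#' Applies the streaming three-band HRV pipeline to the interbeat intervals
#' of a full session and tags every record with the segment containing its
#' window-end time (half-open segment intervals; a record before the first
#' full streaming window would carry no label). For a training-game plan, a
#' flanker stimulus schedule is generated for the stressor segment (onsets
#' offset to the segment start).
#'
#' @param plan A [build_session_plan()].
#' @param series An [ibi_series()] at least as long as the plan.
#' @param config An [hrv_config()].
#' @param seed Seed for the flanker schedule (training-game plans).
#' @return A list of class `session_result`: `records` (segment-tagged HRV
#'   tibble), `trials` (flanker tibble or `NULL`), `plan`, `quality`.
#' @export
run_session <- function(plan, series, config = hrv_config(), seed = NULL) {
  if (tail(series$t_s, 1) < plan$total_s) {
    abort("series shorter than the session plan")
  }
  records <- compute_hrv_stream(series, config, segments = plan$segments)
  trials <- NULL
  if (plan$kind == "training_game") {
    stressor <- plan$segments[plan$segments$segment == "stressor", ]
    trials <- schedule_trials(duration_s = stressor$duration_s, seed = seed)
    trials$onset_s <- trials$onset_s + stressor$start_s
  }
  structure(list(records = records, trials = trials, plan = plan,
                 quality = quality_check(series)),
            class = "session_result")
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %s: %d HRV records", x$plan$kind,
              nrow(x$records)))
  if (!is.null(x$trials)) cat(sprintf(", %d flanker trials", nrow(x$trials)))
  cat(sprintf(", quality %s\n", x$quality$verdict))
  invisible(x)
}

#' Calibrate the biofeedback meter from rest-segment records
#'
#' The 3-minute resting segment establishes the baseline: the meter is
#' centred on the mean and scaled by the standard deviation of the chosen
#' band's values at rest, after excluding values outside the plausible range.
#'
#' @param rest_records Tibble of HRV records from the rest segment.
#' @param band Which band feeds the meter (default `"wb"`, the wideband
#'   biofeedback measure).
#' @param valid_range Plausible ln-variance range applied before calibration.
#' @return An object of class `meter_calibration`: list with `baseline_mu`,
#'   `baseline_sd`, `band`, `n`.
#' @examples
#' calibrate_meter(tibble::tibble(wb = c(7.0, 7.2, 7.4)))
#' @export
calibrate_meter <- function(rest_records, band = "wb",
                            valid_range = c(0, 10)) {
  vals <- rest_records[[band]]
  vals <- vals[!is.na(vals) & vals >= valid_range[1] & vals <= valid_range[2]]
  if (length(vals) < 3) abort("need at least 3 in-range rest records")
  structure(list(baseline_mu = mean(vals), baseline_sd = sd(vals),
                 band = band, n = length(vals)),
            class = "meter_calibration")
}

#' @export
print.meter_calibration <- function(x, ...) {
  cat(sprintf("<meter_calibration> %s baseline %.3f (sd %.3f, n=%d)\n",
              x$band, x$baseline_mu, x$baseline_sd, x$n))
  invisible(x)
}

#' @rdname calibrate_meter
#' @param x A `meter_calibration` object.
#' @param ... Unused.
#' @export
tidy.meter_calibration <- function(x, ...) {
  tibble(band = x$band, baseline_mu = x$baseline_mu,
         baseline_sd = x$baseline_sd, n = x$n)
}

#' Biofeedback meter state for an HRV value
#'
#' Maps a current ln-variance value onto the calm/stress meter. The meter
#' position is `clamp((value - (mu - 2 sd)) / (4 sd), 0, 1)` — i.e. the
#' baseline mean sits at 0.5 and the scale spans baseline +/- 2 sd. Zones:
#' red (stressed) below 1/3, yellow in \[1/3, 2/3), green (calm) at or above
#' 2/3. With a degenerate zero-sd baseline the meter steps at the mean:
#' below it red (0), at it yellow (0.5), above it green (1).
#'
#' @param value HRV value(s), ln ms^2.
#' @param cal A [calibrate_meter()] object.
#' @return A tibble with columns `value`, `meter` in \[0, 1\], `zone`.
#' @export
meter_state <- function(value, cal) {
  if (cal$baseline_sd == 0) {
    meter <- ifelse(value < cal$baseline_mu, 0,
             ifelse(value > cal$baseline_mu, 1, 0.5))
  } else {
    meter <- pmin(pmax((value - (cal$baseline_mu - 2 * cal$baseline_sd)) /
                         (4 * cal$baseline_sd), 0), 1)
  }
  zone <- ifelse(meter < 1 / 3, "red",
          ifelse(meter < 2 / 3, "yellow", "green"))
  tibble(value = value, meter = meter, zone = zone)
}

#' Meter trace for a whole session
#'
#' Calibrates on the session's own rest segment, then evaluates the meter for
#' every streaming record (one update per streaming step, 2 s by default).
#'
#' @param result A [run_session()] result.
#' @param band Band driving the meter.
#' @return A tibble `t_s`, `value`, `meter`, `zone`, `displayed` (`FALSE`
#'   throughout for biofeedback-off arms, where HRV is computed but hidden).
#' @export
session_meter <- function(result, band = "wb") {
  rest <- result$records[result$records$segment %in% "rest", ]
  cal <- calibrate_meter(rest, band = band)
  st <- meter_state(result$records[[band]], cal)
  tibble(t_s = result$records$t_s, value = st$value, meter = st$meter,
         zone = st$zone, displayed = result$plan$biofeedback)
}

#' Write a session bundle to a directory
#'
#' Emits the session outputs as plain files: `hrv.csv` (tagged records),
#' `trials.csv` (training-game plans), `events.json` (segment boundaries and
#' rest-segment fades), and `meter.csv`.
#'
#' @param result A [run_session()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_session_bundle <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_hrv_csv(result$records, file.path(dir, "hrv.csv"))
  if (!is.null(result$trials)) {
    readr::write_csv(result$trials, file.path(dir, "trials.csv"))
  }
  ev <- session_events(result$plan)
  jsonlite::write_json(ev, file.path(dir, "events.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  mt <- session_meter(result)
  readr::write_csv(mt[, c("t_s", "meter", "zone")], file.path(dir, "meter.csv"))
  invisible(dir)
}

#' Plot a streaming HRV trace by segment
#' @param records Segment-tagged HRV tibble.
#' @param band Band to plot.
#' @return A ggplot object.
#' @export
plot_hrv_stream <- function(records, band = "wb") {
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$t_s, y = .data[[band]],
                               colour = .data$segment)) +
    ggplot2::geom_line(ggplot2::aes(group = 1)) +
    ggplot2::labs(x = "time (s)", y = sprintf("%s ln-variance (ln ms²)", band),
                  colour = "segment") +
    ggplot2::theme_minimal()
}
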