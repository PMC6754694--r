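#' Synthetic IBI generator settings
#'
#' Parameters of the additive-sinusoid interbeat-interval model used to
#' emulate a chest-strap recording: a mean interval plus a respiratory
#' modulation (rest breathing near 0.25 Hz; paced breathing at the pacing
#' frequency), a slower low-frequency modulation, white beat-to-beat noise,
#' and optional beat artifacts (randomly halved or doubled beats). The
#' default respiratory amplitude of 56.34 ms makes the band-limited
#' ln-variance of the respiratory component `log(56.34^2 / 2) = 7.37`
#' ln(ms^2), a typical resting wideband value.
#'
#' @param mean_ibi_ms Mean interbeat interval, ms (250--3000).
#' @param resp_hz Respiratory modulation frequency, Hz.
#' @param resp_amp_ms Respiratory modulation amplitude, ms.
#' @param lf_hz Low-frequency modulation frequency, Hz.
#' @param lf_amp_ms Low-frequency modulation amplitude, ms.
#' @param noise_sd_ms White noise SD per beat, ms.
#' @param artifact_rate Per-beat probability of an injected artifact.
#' @param seed Integer seed.
#' @return A list of class `synth_params`.
#' @export
synth_params <- function(mean_ibi_ms = 1000, resp_hz = 0.25,
                         resp_amp_ms = 56.34, lf_hz = 0.08,
                         lf_amp_ms = 15, noise_sd_ms = 3,
                         artifact_rate = 0, seed = NULL) {
  if (mean_ibi_ms < 250 || mean_ibi_ms > 3000) {
    abort("mean_ibi_ms outside the physiological range")
  }
  if (resp_amp_ms < 0 || lf_amp_ms < 0 || noise_sd_ms < 0) {
    abort("amplitudes must be non-negative")
  }
  nyq <- 0.5 * 1000 / mean_ibi_ms
  if (resp_hz >= nyq || lf_hz >= nyq) {
    abort("modulation frequency at or above the beat Nyquist rate")
  }
  if (resp_amp_ms + lf_amp_ms + 5 * noise_sd_ms >= mean_ibi_ms) {
    abort("parameters imply non-positive intervals")
  }
  structure(list(mean_ibi_ms = mean_ibi_ms, resp_hz = resp_hz,
                 resp_amp_ms = resp_amp_ms, lf_hz = lf_hz,
                 lf_amp_ms = lf_amp_ms, noise_sd_ms = noise_sd_ms,
                 artifact_rate = artifact_rate, seed = seed),
            class = "synth_params")
}

#' Amplitude giving a target sinusoid ln-variance
#'
#' Inverse of the closed-form sinusoid variance: a tone of amplitude A has
#' variance A^2/2, so `amp_for_ln_variance(v)` returns `sqrt(2 * exp(v))`.
#' Used to set the generator so the pipeline should recover a chosen
#' ln-variance set-point.
#'
#' @param ln_var Target ln-variance, ln(ms^2).
#' @return Amplitude in ms.
#' @examples
#' amp_for_ln_variance(7.37)   # ~56.34 ms
#' @export
amp_for_ln_variance <- function(ln_var) sqrt(2 * exp(ln_var))

#' Generate a synthetic IBI series
#'
#' Beats are generated sequentially: the k-th interval is
#' `mean + resp_amp * sin(2 pi resp_hz s_k) + lf_amp * sin(2 pi lf_hz s_k + phi)
#' + N(0, noise_sd)`, where `s_k` is the cumulative time at the beat's start
#' and `phi` a random phase. Beats continue until the series spans
#' `duration_s`. Artifacts are injected at `artifact_rate` by halving or
#' doubling a beat.
#'
#' @param params A [synth_params()].
#' @param duration_s Recording duration, seconds.
#' @param participant_id Participant label for the series.
#' @return An [ibi_series()] tibble.
#' @examples
#' s <- synth_ibi(synth_params(seed = 1), duration_s = 180)
#' @export
synth_ibi <- function(params, duration_s = 180, participant_id = "synth") {
  if (!is.null(params$seed)) set.seed(params$seed)
  phi <- runif(1, 0, 2 * pi)
  n_max <- ceiling(duration_s / (params$mean_ibi_ms / 1000)) + 60
  ibis <- numeric(n_max)
  t <- 0
  k <- 0
  while (t < duration_s) {
    k <- k + 1
    ib <- params$mean_ibi_ms +
      params$resp_amp_ms * sin(2 * pi * params$resp_hz * t) +
      params$lf_amp_ms * sin(2 * pi * params$lf_hz * t + phi) +
      rnorm(1, 0, params$noise_sd_ms)
    if (ib <= 0) abort("parameters produced a non-positive interval")
    ibis[k] <- ib
    t <- t + ib / 1000
  }
  ibis <- ibis[seq_len(k)]
  if (params$artifact_rate > 0) {
    hit <- runif(k) < params$artifact_rate
    mult <- ifelse(runif(k) < 0.5, 0.5, 2)
    ibis[hit] <- ibis[hit] * mult[hit]
  }
  ibi_series(ibis, participant_id = participant_id, source = "synthetic")
}

#' Per-segment generator effects
#'
#' Multipliers applied to the generator per session segment, encoding the
#' expected psychophysiology: the stressor lowers vagal (respiratory)
#' amplitude and shortens the mean interval (heart rate up); recovery
#' partially restores them; paced-breathing training moves respiration to
#' the pacing frequency and raises its amplitude. Defaults reproduce the
#' direction and approximate spacing of typical segment means (rest 7.37,
#' stressor ~6.92, recovery ~7.15, training ~8.2 ln ms^2 with the default
#' resting amplitude).
#'
#' @param stress_amp,stress_ibi Multipliers during the stressor segment.
#' @param recovery_amp,recovery_ibi Multipliers during recovery.
#' @param training_amp,training_ibi Multipliers during training.
#' @return A list of class `segment_effects`.
#' @export
segment_effects <- function(stress_amp = 0.80, stress_ibi = 0.92,
                            recovery_amp = 0.90, recovery_ibi = 0.97,
                            training_amp = 1.52, training_ibi = 1.0) {
  vals <- c(stress_amp, stress_ibi, recovery_amp, recovery_ibi,
            training_amp, training_ibi)
  if (any(vals <= 0)) abort("multipliers must be positive")
  structure(list(
    rest = list(amp = 1, ibi = 1),
    stressor = list(amp = stress_amp, ibi = stress_ibi),
    recovery = list(amp = recovery_amp, ibi = recovery_ibi),
    training = list(amp = training_amp, ibi = training_ibi)
  ), class = "segment_effects")
}

#' Generate a synthetic full-session IBI series
#'
#' Generates beats segment by segment with continuous time across segment
#' boundaries. The training segment's respiratory frequency is the arm's
#' pacing frequency (0.1 Hz at 6 bpm, 0.0833 Hz at 5 bpm); other segments
#' breathe at the resting rate.
#'
#' @param plan A [build_session_plan()].
#' @param params Base [synth_params()] (rest-segment values).
#' @param effects A [segment_effects()].
#' @param seed Integer seed.
#' @return An [ibi_series()] spanning the plan, with a short tail beyond the
#'   final segment so the last streaming window is complete.
#' @examples
#' plan <- build_session_plan("training_game", 6)
#' s <- synth_session(plan, seed = 7)
#' @export
synth_session <- function(plan, params = synth_params(),
                          effects = segment_effects(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  phi <- runif(1, 0, 2 * pi)
  seg <- plan$segments
  ibis <- c()
  t <- 0
  for (i in seq_len(nrow(seg))) {
    lab <- seg$segment[i]
    eff <- effects[[lab]]
    resp_hz <- if (lab == "training") plan$pacing_hz else params$resp_hz
    while (t < seg$end_s[i]) {
      ib <- params$mean_ibi_ms * eff$ibi +
        params$resp_amp_ms * eff$amp * sin(2 * pi * resp_hz * t) +
        params$lf_amp_ms * sin(2 * pi * params$lf_hz * t + phi) +
        rnorm(1, 0, params$noise_sd_ms)
      if (ib <= 0) abort("parameters produced a non-positive interval")
      ibis <- c(ibis, ib)
      t <- t + ib / 1000
    }
  }
  if (params$artifact_rate > 0) {
    k <- length(ibis)
    hit <- runif(k) < params$artifact_rate
    mult <- ifelse(runif(k) < 0.5, 0.5, 2)
    ibis[hit] <- ibis[hit] * mult[hit]
  }
  ibi_series(ibis, participant_id = "synth_session", source = "synthetic")
}

#' Simulate a cohort's adherence histories
#'
#' Generates per-participant activity histories consumable by the protocol
#' module. Each activity scheduled in week `k` (or in a later window,
#' indexed by the week of its start day) is completed with probability
#' `p_week1 * decay^(k - 1)`, so expected weekly session counts decay
#' geometrically, emulating the observed drop in training compliance.
#' Optionally, a fraction of participants are full completers who perform
#' every training and weekly survey in weeks 1--6.
#'
#' @param n_participants Cohort size.
#' @param p_week1 Week-1 completion probability per activity.
#' @param decay Weekly geometric decay of the completion probability.
#' @param completer_fraction If non-`NULL`, each participant is a full
#'   6-week completer with this probability; non-completers follow the
#'   decaying model.
#' @param baseline_p Completion probability of the day-0 baseline surveys.
#' @param start Date of the first study entry.
#' @param start_spread_days Entries are spread uniformly over this many days.
#' @param as_of_date Analysis date; defaults to `start + start_spread_days +
#'   180` so early entrants have a full schedule elapsed.
#' @param seed Integer seed.
#' @return A list with `histories` (tibble), `calendars` (list of
#'   [build_calendar()]), `as_of_date`.
#' @export
synth_cohort <- function(n_participants = 50, p_week1 = 0.9, decay = 0.85,
                         completer_fraction = NULL, baseline_p = 0.89,
                         start = as.Date("2024-01-01"),
                         start_spread_days = 180,
                         as_of_date = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (p_week1 < 0 || p_week1 > 1 || decay < 0 || decay > 1) {
    abort("probabilities must lie in [0, 1]")
  }
  start <- as.Date(start)
  if (is.null(as_of_date)) as_of_date <- start + start_spread_days + 180
  as_of_date <- as.Date(as_of_date)
  calendars <- list()
  hist_rows <- list()
  for (i in seq_len(n_participants)) {
    pid <- sprintf("p%03d", i)
    sd_i <- start + sample.int(start_spread_days + 1, 1) - 1
    cal <- build_calendar(pid, sd_i)
    calendars[[pid]] <- cal
    completer <- !is.null(completer_fraction) &&
      runif(1) < completer_fraction
    sched <- cal$scheduled
    for (j in seq_len(nrow(sched))) {
      row <- sched[j, ]
      week_idx <- max(1, ceiling(as.numeric(row$window_start - sd_i) / 7))
      p <- if (grepl("^baseline|^survey_baseline",
                     row$instance)) baseline_p
           else p_week1 * decay^(week_idx - 1)
      in_week6 <- grepl("week_[1-6]$", row$instance)
      for (r in seq_len(row$required_n)) {
        done <- if (completer && in_week6) TRUE else runif(1) < p
        if (done) {
          d <- row$window_start +
            sample.int(as.numeric(row$window_end - row$window_start) + 1,
                       1) - 1
          hist_rows[[length(hist_rows) + 1]] <- tibble(
            participant_id = pid, activity = row$activity, date = d,
            status = "completed")
        }
      }
    }
  }
  histories <- if (length(hist_rows) > 0) bind_rows(hist_rows) else
    tibble(participant_id = character(), activity = character(),
           date = as.Date(character()), status = character())
  list(histories = histories, calendars = calendars, as_of_date = as_of_date)
}
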