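#' Schedule a 4-minute Eriksen flanker stressor
#'
#' Generates the stimulus schedule of the arrow-identification stressor task.
#' Each stimulus is one of 4 combinations (central arrow left/right crossed
#' with flanking arrows left/right; the four bounding arrows share one
#' direction), drawn uniformly at random, shown for 400 ms, with a 2.7-s
#' response window. The next stimulus follows after a uniform random interval
#' of 1--3 s; by default the interval runs from the end of the response
#' window (`isi_origin = "window_end"`, giving 3.7--5.7 s between onsets), or
#' from stimulus offset with `isi_origin = "offset"`. Generation stops when
#' the next trial could not complete its response window within `duration_s`.
#'
#' @param duration_s Task duration, seconds (default 240).
#' @param isi_low,isi_high Inter-stimulus interval bounds, seconds.
#' @param response_window_s Response window, seconds (default 2.7).
#' @param presented_ms Stimulus display duration, milliseconds.
#' @param isi_origin Where the 1--3 s interval starts: `"window_end"` or
#'   `"offset"`.
#' @param seed Integer seed; the schedule is fully reproducible from it.
#' @return A tibble with one row per trial: `trial`, `onset_s`, `center`,
#'   `flankers`, `congruent`, `presented_ms`, `response`, `rt_s`, `outcome`
#'   (`response`/`rt_s`/`outcome` initialized to none/NA/missed until
#'   adjudicated).
#' @examples
#' trials <- schedule_trials(seed = 42)
#' nrow(trials)   # between 42 and 64 for the default parameters
#' @export
schedule_trials <- function(duration_s = 240, isi_low = 1, isi_high = 3,
                            response_window_s = 2.7, presented_ms = 400,
                            isi_origin = c("window_end", "offset"),
                            seed = NULL) {
  isi_origin <- match.arg(isi_origin)
  if (isi_low <= 0 || isi_high < isi_low) abort("invalid interval bounds")
  if (duration_s <= response_window_s + isi_high) {
    abort("duration too short for a single trial")
  }
  if (!is.null(seed)) set.seed(seed)
  gap_base <- if (isi_origin == "window_end") response_window_s else
    presented_ms / 1000
  onsets <- c()
  t <- runif(1, isi_low, isi_high)
  while (t + response_window_s <= duration_s) {
    onsets <- c(onsets, t)
    t <- t + gap_base + runif(1, isi_low, isi_high)
  }
  n <- length(onsets)
  dirs <- c("left", "right")
  center <- dirs[sample.int(2, n, replace = TRUE)]
  flankers <- dirs[sample.int(2, n, replace = TRUE)]
  tibble(
    trial = seq_len(n),
    onset_s = onsets,
    center = center,
    flankers = flankers,
    congruent = center == flankers,
    presented_ms = presented_ms,
    response_window_s = response_window_s,
    response = "none",
    rt_s = NA_real_,
    outcome = "missed"
  )
}

#' Score one flanker response
#'
#' A tap is correct when it matches the central arrow's direction and falls
#' within the response window measured from stimulus onset; the stimulus is
#' only visible for 400 ms but responses count through the full window. A
#' late tap, or no tap, is a miss.
#'
#' @param trial One-row tibble (a row of [schedule_trials()] output).
#' @param tapped `"left"`, `"right"`, or `"none"`.
#' @param t_tap_s Absolute tap time, seconds (ignored when `tapped` is
#'   `"none"`).
#' @return The trial row with `response`, `rt_s`, `outcome` filled in.
#' @examples
#' tr <- schedule_trials(seed = 1)[1, ]
#' adjudicate_response(tr, tr$center, tr$onset_s + 1.0)$outcome   # "correct"
#' @export
adjudicate_response <- function(trial, tapped, t_tap_s = NA_real_) {
  stopifnot(nrow(trial) == 1)
  if (!tapped %in% c("left", "right", "none")) abort("tapped must be left/right/none")
  if (tapped == "none") {
    trial$response <- "none"
    trial$rt_s <- NA_real_
    trial$outcome <- "missed"
    return(trial)
  }
  if (is.na(t_tap_s) || t_tap_s < trial$onset_s) abort("tap before stimulus onset")
  rt <- t_tap_s - trial$onset_s
  trial$response <- tapped
  trial$rt_s <- rt
  trial$outcome <- if (rt > trial$response_window_s) "missed"
    else if (tapped == trial$center) "correct" else "incorrect"
  trial
}

#' Summarize a block of flanker trials
#'
#' Accuracy overall and split by congruency, mean/median reaction time of
#' correct responses by congruency, and the miss count.
#'
#' @param trials Tibble of adjudicated trials.
#' @return A tibble with one row per group (`overall`, `congruent`,
#'   `incongruent`): `n`, `n_correct`, `n_incorrect`, `n_missed`, `accuracy`,
#'   `mean_rt_s`, `median_rt_s`. Groups with no trials have `n = 0` and `NA`
#'   statistics.
#' @export
summarize_flanker <- function(trials) {
  if (nrow(trials) == 0) abort("no trials to summarize")
  one <- function(df, label) {
    rts <- df$rt_s[df$outcome == "correct"]
    tibble(
      group = label,
      n = nrow(df),
      n_correct = sum(df$outcome == "correct"),
      n_incorrect = sum(df$outcome == "incorrect"),
      n_missed = sum(df$outcome == "missed"),
      accuracy = if (nrow(df) > 0) sum(df$outcome == "correct") / nrow(df)
                 else NA_real_,
      mean_rt_s = if (length(rts) > 0) mean(rts) else NA_real_,
      median_rt_s = if (length(rts) > 0) median(rts) else NA_real_
    )
  }
  bind_rows(
    one(trials, "overall"),
    one(trials[trials$congruent, , drop = FALSE], "congruent"),
    one(trials[!trials$congruent, , drop = FALSE], "incongruent")
  )
}

#' Simulate participant responses to a flanker schedule
#'
#' Convenience responder used by the synthetic session pipeline: each trial
#' is answered correctly with probability `p_correct`, missed with
#' probability `p_miss`, otherwise answered wrongly; reaction times are drawn
#' uniformly on `rt_range_s`.
#'
#' @param trials Tibble from [schedule_trials()].
#' @param p_correct,p_miss Outcome probabilities.
#' @param rt_range_s Reaction-time range, seconds.
#' @param seed Optional integer seed.
#' @return The trials tibble, adjudicated.
#' @export
simulate_responses <- function(trials, p_correct = 0.9, p_miss = 0.03,
                               rt_range_s = c(0.35, 1.2), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  for (i in seq_len(nrow(trials))) {
    u <- runif(1)
    if (u < p_miss) {
      trials[i, ] <- adjudicate_response(trials[i, ], "none")
    } else {
      rt <- runif(1, rt_range_s[1], rt_range_s[2])
      correct <- u < p_miss + p_correct
      tap <- if (correct) trials$center[i] else
        setdiff(c("left", "right"), trials$center[i])
      trials[i, ] <- adjudicate_response(trials[i, ], tap,
                                         trials$onset_s[i] + rt)
    }
  }
  trials
}
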