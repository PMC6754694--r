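#' Incentive rule table
#'
#' The incremental incentive schedule of the yearlong protocol: US $15 for
#' baseline part 1 (day 0), $5 each for baseline parts 2 and 3 (days 0--3),
#' $10 per week for the weekly training + survey bundle in weeks 1--6, $20
#' per quarterly survey (months 3, 6, 9) and $20 for the final survey
#' (month 12).
#'
#' @return A tibble with columns `rule_id`, `description`, `amount_usd`.
#' @export
incentive_rules <- function() {
  tibble(
    rule_id = c("baseline_1", "baseline_2", "baseline_3",
                paste0("weekly_", 1:6),
                paste0("quarterly_", 1:3), "final"),
    description = c(
      "Baseline part 1 completed on day 0",
      "Baseline part 2 completed in days 0-3",
      "Baseline part 3 completed in days 0-3",
      paste0("Week ", 1:6, ": trainings plus weekly survey"),
      paste0("Quarterly survey ", 1:3, " (months 3, 6, 9)"),
      "Final survey (month 12)"
    ),
    amount_usd = c(15, 5, 5, rep(10, 6), rep(20, 3), 20)
  )
}

#' Build a participant's study calendar
#'
#' Expands the protocol activity schedule from a participant's personal study
#' entry date (day 0). Week `k` covers study days `7(k-1)+1` to `7k`; months
#' are 30-day blocks, so the quarterly windows (months 3, 6, 9) cover days
#' 61--90, 151--180 and 241--270, and the final window (month 12) days
#' 331--360. Weeks 1--6 require 3 training sessions per week (2 basic + 1
#' training game) plus the weekly survey.
#'
#' @param participant_id Participant identifier.
#' @param start_date Study entry date (`Date` or parseable string), day 0.
#' @return A list of class `study_calendar` with `participant_id`,
#'   `start_date`, and `scheduled`, a tibble with columns `instance`
#'   (unique label), `activity`, `window_start`, `window_end` (inclusive
#'   `Date`s), `required_n`, `rule_id`.
#' @examples
#' cal <- build_calendar("p01", "2024-01-01")
#' sum(cal$scheduled$required_n[grepl("training", cal$scheduled$activity) &
#'                              grepl("week", cal$scheduled$instance)])  # 18
#' @export
build_calendar <- function(participant_id, start_date) {
  start_date <- as.Date(start_date)
  if (is.na(start_date)) abort("invalid start_date")
  day <- function(d) start_date + d
  rows <- list(
    tibble(instance = "baseline_1", activity = "survey_baseline_1",
           window_start = day(0), window_end = day(0), required_n = 1L,
           rule_id = "baseline_1"),
    tibble(instance = "practice_game_day0", activity = "training_game",
           window_start = day(0), window_end = day(1), required_n = 1L,
           rule_id = NA_character_),
    tibble(instance = "baseline_2", activity = "survey_baseline_2",
           window_start = day(0), window_end = day(3), required_n = 1L,
           rule_id = "baseline_2"),
    tibble(instance = "baseline_3", activity = "survey_baseline_3",
           window_start = day(0), window_end = day(3), required_n = 1L,
           rule_id = "baseline_3")
  )
  for (k in 1:6) {
    ws <- day(7 * (k - 1) + 1); we <- day(7 * k)
    rows <- c(rows, list(
      tibble(instance = paste0("training_basic_week_", k),
             activity = "training_basic", window_start = ws, window_end = we,
             required_n = 2L, rule_id = paste0("weekly_", k)),
      tibble(instance = paste0("training_game_week_", k),
             activity = "training_game", window_start = ws, window_end = we,
             required_n = 1L, rule_id = paste0("weekly_", k)),
      tibble(instance = paste0("survey_week_", k),
             activity = "survey_weekly", window_start = ws, window_end = we,
             required_n = 1L, rule_id = paste0("weekly_", k))
    ))
  }
  months <- c(3, 6, 9)
  for (q in 1:3) {
    m <- months[q]
    ws <- day(30 * (m - 1) + 1); we <- day(30 * m)
    rows <- c(rows, list(
      tibble(instance = paste0("survey_quarter_", q),
             activity = "survey_quarterly", window_start = ws,
             window_end = we, required_n = 1L,
             rule_id = paste0("quarterly_", q)),
      tibble(instance = paste0("training_basic_quarter_", q),
             activity = "training_basic", window_start = ws, window_end = we,
             required_n = 8L, rule_id = NA_character_),
      tibble(instance = paste0("training_game_quarter_", q),
             activity = "training_game", window_start = ws, window_end = we,
             required_n = 1L, rule_id = NA_character_)
    ))
  }
  ws <- day(331); we <- day(360)
  rows <- c(rows, list(
    tibble(instance = "survey_final", activity = "survey_final",
           window_start = ws, window_end = we, required_n = 1L,
           rule_id = "final"),
    tibble(instance = "training_basic_month12", activity = "training_basic",
           window_start = ws, window_end = we, required_n = 2L,
           rule_id = NA_character_),
    tibble(instance = "training_game_month12", activity = "training_game",
           window_start = ws, window_end = we, required_n = 1L,
           rule_id = NA_character_)
  ))
  structure(list(participant_id = as.character(participant_id),
                 start_date = start_date,
                 scheduled = bind_rows(rows)),
            class = "study_calendar")
}

#' @export
print.study_calendar <- function(x, ...) {
  cat(sprintf("<study_calendar> %s starting %s: %d scheduled items\n",
              x$participant_id, format(x$start_date), nrow(x$scheduled)))
  invisible(x)
}

# completions of one participant within a calendar row's window
completions_in_window <- function(history, row, as_of_date = NULL,
                                  status = "completed") {
  h <- history[history$activity == row$activity &
                 history$status %in% status &
                 history$date >= row$window_start &
                 history$date <= row$window_end, , drop = FALSE]
  if (!is.null(as_of_date)) h <- h[h$date <= as_of_date, , drop = FALSE]
  h
}

#' Daily activity menu
#'
#' Lists a participant's pending activities on a given date, the way the
#' in-app schedule manager maintains the home-screen menu: completed items
#' are removed, pending training items are annotated with the number of
#' sessions remaining this week, and an incomplete weekly survey expires
#' from the menu `survey_expire_days` (default 4) days after it was
#' scheduled.
#'
#' @param calendar A [build_calendar()].
#' @param date Menu date.
#' @param history Tibble of this participant's activity history with columns
#'   `participant_id`, `activity`, `date` (`Date`), `status`.
#' @param survey_expire_days Days a weekly survey stays on the menu.
#' @return A tibble with columns `instance`, `activity`, `remaining`,
#'   `annotation`.
#' @export
daily_menu <- function(calendar, date, history,
                       survey_expire_days = 4) {
  date <- as.Date(date)
  if (date < calendar$start_date) abort("date precedes study entry")
  sched <- calendar$scheduled
  active <- sched[sched$window_start <= date & sched$window_end >= date, ,
                  drop = FALSE]
  out <- list()
  for (i in seq_len(nrow(active))) {
    row <- active[i, ]
    done <- nrow(completions_in_window(history, row, as_of_date = date))
    remaining <- row$required_n - done
    if (remaining <= 0) next
    if (row$activity == "survey_weekly" &&
        date >= row$window_start + survey_expire_days) next
    annotation <- if (grepl("^training", row$activity)) {
      week_rows <- sched[sched$rule_id %in% row$rule_id &
                           grepl("^training", sched$activity), , drop = FALSE]
      week_done <- sum(vapply(seq_len(nrow(week_rows)), function(j) {
        min(nrow(completions_in_window(history, week_rows[j, ],
                                       as_of_date = date)),
            week_rows$required_n[j])
      }, numeric(1)))
      week_req <- sum(week_rows$required_n)
      sprintf("%d remaining", max(week_req - week_done, 0))
    } else {
      NA_character_
    }
    out[[length(out) + 1]] <- tibble(
      instance = row$instance, activity = row$activity,
      remaining = remaining, annotation = annotation
    )
  }
  if (length(out) == 0) {
    return(tibble(instance = character(), activity = character(),
                  remaining = integer(), annotation = character()))
  }
  bind_rows(out)
}

#' Evaluate incentive criteria
#'
#' Checks a participant's history against the incentive rules and returns
#' the newly earned ledger entries. Weekly ($10) criteria come in two modes,
#' both used in the study at different times: `"strict"` requires the week's
#' 2 basic trainings, 1 training game, and a completed weekly survey;
#' `"relaxed"` requires 3 training sessions of any kind and a weekly survey
#' at least initiated. Re-evaluating never duplicates an entry already in
#' the ledger.
#'
#' @param calendar A [build_calendar()].
#' @param history The participant's activity history tibble.
#' @param as_of_date Evaluation date; only completions up to it count, and a
#'   rule is evaluated once its criteria are met.
#' @param mode `"strict"` or `"relaxed"`.
#' @param ledger Existing ledger tibble (or `NULL`) used for deduplication.
#' @return Tibble of new entries: `participant_id`, `rule_id`, `amount_usd`,
#'   `earned_date`, `fulfilled`, `fulfilled_date`.
#' @export
evaluate_incentives <- function(calendar, history, as_of_date,
                                mode = c("strict", "relaxed"),
                                ledger = NULL) {
  mode <- match.arg(mode)
  as_of_date <- as.Date(as_of_date)
  rules <- incentive_rules()
  sched <- calendar$scheduled
  pid <- calendar$participant_id
  entries <- list()
  have <- if (!is.null(ledger) && nrow(ledger) > 0) {
    paste(ledger$participant_id, ledger$rule_id)
  } else character()
  add_entry <- function(rule_id, earned_date) {
    if (paste(pid, rule_id) %in% have) return()
    entries[[length(entries) + 1]] <<- tibble(
      participant_id = pid, rule_id = rule_id,
      amount_usd = rules$amount_usd[rules$rule_id == rule_id],
      earned_date = earned_date, fulfilled = FALSE,
      fulfilled_date = as.Date(NA)
    )
  }
  # survey-completion rules
  for (rid in c("baseline_1", "baseline_2", "baseline_3",
                paste0("quarterly_", 1:3), "final")) {
    row <- sched[sched$rule_id %in% rid & grepl("^survey", sched$activity), ]
    if (nrow(row) == 0) next
    done <- completions_in_window(history, row[1, ], as_of_date = as_of_date)
    if (nrow(done) > 0) add_entry(rid, min(done$date))
  }
  # weekly bundles
  for (k in 1:6) {
    rid <- paste0("weekly_", k)
    rows <- sched[sched$rule_id %in% rid, , drop = FALSE]
    basic <- rows[rows$activity == "training_basic", ][1, ]
    game <- rows[rows$activity == "training_game", ][1, ]
    surv <- rows[rows$activity == "survey_weekly", ][1, ]
    n_basic <- nrow(completions_in_window(history, basic, as_of_date))
    n_game <- nrow(completions_in_window(history, game, as_of_date))
    surv_done <- completions_in_window(history, surv, as_of_date)
    met <- if (mode == "strict") {
      n_basic >= 2 && n_game >= 1 && nrow(surv_done) > 0
    } else {
      surv_any <- completions_in_window(history, surv, as_of_date,
                                        status = c("completed", "started"))
      (n_basic + n_game) >= 3 && nrow(surv_any) > 0
    }
    if (met) {
      dates <- c(completions_in_window(history, basic, as_of_date)$date,
                 completions_in_window(history, game, as_of_date)$date,
                 completions_in_window(history, surv, as_of_date,
                                       status = c("completed",
                                                  "started"))$date)
      add_entry(rid, max(dates))
    }
  }
  if (length(entries) == 0) {
    return(tibble(participant_id = character(), rule_id = character(),
                  amount_usd = numeric(), earned_date = as.Date(character()),
                  fulfilled = logical(), fulfilled_date = as.Date(character())))
  }
  bind_rows(entries)
}

#' Nightly incentive fulfillment scan
#'
#' Mirrors the backend's nightly procedure: every earned, unfulfilled ledger
#' entry is marked fulfilled with the scan date and emitted as a payout. A
#' second immediate run issues nothing (idempotent).
#'
#' @param ledger Ledger tibble (as produced by [evaluate_incentives()]).
#' @param as_of_date Scan date, recorded as the fulfillment date.
#' @return A list with `ledger` (updated) and `payouts` (tibble
#'   `participant_id`, `rule_id`, `amount_usd`, `fulfilled_date`).
#' @export
fulfillment_scan <- function(ledger, as_of_date) {
  as_of_date <- as.Date(as_of_date)
  if (is.null(ledger) || nrow(ledger) == 0) {
    return(list(ledger = ledger,
                payouts = tibble(participant_id = character(),
                                 rule_id = character(),
                                 amount_usd = numeric(),
                                 fulfilled_date = as.Date(character()))))
  }
  pending <- !ledger$fulfilled
  payouts <- tibble(participant_id = ledger$participant_id[pending],
                    rule_id = ledger$rule_id[pending],
                    amount_usd = ledger$amount_usd[pending],
                    fulfilled_date = as_of_date)
  ledger$fulfilled[pending] <- TRUE
  ledger$fulfilled_date[pending] <- as_of_date
  list(ledger = ledger, payouts = payouts)
}

#' Compliance percentage
#'
#' The study's compliance arithmetic: completed over scheduled, as a
#' percentage rounded to one decimal (e.g. 207 of 328 is 63.1).
#'
#' @param completed,scheduled Counts.
#' @return Percentage rounded to one decimal place.
#' @examples
#' compliance_pct(207, 328)   # 63.1
#' @export
compliance_pct <- function(completed, scheduled) {
  ifelse(scheduled > 0, round(100 * completed / scheduled, 1), NA_real_)
}

#' Cohort compliance report
#'
#' Computes, for every protocol activity instance, the number of participants
#' scheduled to perform it by the analysis date (adjusted for each
#' individual's start date), the number who completed it within its window,
#' and the completed/scheduled ratio as a percentage. Also reports the
#' training-sessions-per-study-day histogram and the fraction of enrolled
#' participants completing the 6-week regimen (at least 3 training sessions
#' in each of weeks 1--6).
#'
#' @param histories Cohort history tibble (`participant_id`, `activity`,
#'   `date`, `status`).
#' @param calendars List of [build_calendar()] objects (one per participant).
#' @param as_of_date Analysis date.
#' @return A list of class `compliance_report`: `by_activity` (tibble
#'   `instance`, `activity`, `scheduled`, `completed`, `pct`),
#'   `sessions_by_day` (tibble `study_day`, `n_sessions`), `n_enrolled`,
#'   `n_completers`, `completer_pct`.
#' @export
compliance_report <- function(histories, calendars, as_of_date) {
  as_of_date <- as.Date(as_of_date)
  if (length(calendars) == 0) abort("need at least one participant")
  by_act <- list()
  n_completers <- 0L
  sessions <- list()
  for (cal in calendars) {
    pid <- cal$participant_id
    h <- histories[histories$participant_id == pid, , drop = FALSE]
    sched <- cal$scheduled
    started <- sched$window_start <= as_of_date
    done <- vapply(seq_len(nrow(sched)), function(i) {
      if (!started[i]) return(NA)
      nrow(completions_in_window(h, sched[i, ], as_of_date = as_of_date)) >=
        sched$required_n[i]
    }, logical(1))
    by_act[[pid]] <- tibble(instance = sched$instance,
                            activity = sched$activity,
                            scheduled = as.integer(started),
                            completed = as.integer(started & done %in% TRUE))
    # training sessions by study day
    tr <- h[grepl("^training", h$activity) & h$status == "completed" &
              h$date <= as_of_date, , drop = FALSE]
    if (nrow(tr) > 0) {
      sessions[[pid]] <- tibble(study_day = as.integer(tr$date -
                                                         cal$start_date))
    }
    # completer: >= 3 training sessions in each of weeks 1..6
    weeks_ok <- vapply(1:6, function(k) {
      ws <- cal$start_date + 7 * (k - 1) + 1
      we <- cal$start_date + 7 * k
      sum(tr$date >= ws & tr$date <= we) >= 3
    }, logical(1))
    if (all(weeks_ok)) n_completers <- n_completers + 1L
  }
  by_activity <- bind_rows(by_act) |>
    group_by(.data$instance, .data$activity) |>
    summarise(scheduled = sum(.data$scheduled),
              completed = sum(.data$completed), .groups = "drop") |>
    mutate(pct = compliance_pct(.data$completed, .data$scheduled))
  # keep protocol order
  order_ref <- calendars[[1]]$scheduled$instance
  by_activity <- by_activity[order(match(by_activity$instance, order_ref)), ]
  sessions_by_day <- if (length(sessions) > 0) {
    bind_rows(sessions) |>
      group_by(.data$study_day) |>
      summarise(n_sessions = n(), .groups = "drop") |>
      arrange(.data$study_day)
  } else {
    tibble(study_day = integer(), n_sessions = integer())
  }
  n_enrolled <- length(calendars)
  structure(list(
    by_activity = by_activity,
    sessions_by_day = sessions_by_day,
    n_enrolled = n_enrolled,
    n_completers = n_completers,
    completer_pct = compliance_pct(n_completers, n_enrolled),
    as_of_date = as_of_date
  ), class = "compliance_report")
}

#' @export
print.compliance_report <- function(x, ...) {
  cat(sprintf("<compliance_report> %d enrolled, %d (%.1f%%) completed the 6-week regimen\n",
              x$n_enrolled, x$n_completers, x$completer_pct))
  print(x$by_activity, n = 10)
  invisible(x)
}

#' @rdname compliance_report
#' @param x A `compliance_report`.
#' @param ... Unused.
#' @export
glance.compliance_report <- function(x, ...) {
  tibble(n_enrolled = x$n_enrolled, n_completers = x$n_completers,
         completer_pct = x$completer_pct,
         n_activities = nrow(x$by_activity),
         total_sessions = sum(x$sessions_by_day$n_sessions))
}

#' Plot per-activity compliance
#' @param report A [compliance_report()].
#' @return A ggplot object.
#' @export
plot_compliance <- function(report) {
  df <- report$by_activity
  df$instance <- factor(df$instance, levels = df$instance)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$instance, y = .data$pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "compliance (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Write a compliance report to files
#' @param report A [compliance_report()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_compliance_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$by_activity, file.path(dir, "compliance.csv"))
  readr::write_csv(report$sessions_by_day,
                   file.path(dir, "sessions_by_day.csv"))
  jsonlite::write_json(unclass(glance(report)),
                       file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
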