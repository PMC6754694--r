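start <- as.Date("2024-01-01")

test_that("the calendar expands the yearlong protocol from the entry date", {
  cal <- build_calendar("p01", start)
  sched <- cal$scheduled

  # weeks 1-6 require 18 training sessions (2 basic + 1 game per week)
  wk <- sched[grepl("week_[1-6]$", sched$instance) &
                grepl("^training", sched$activity), ]
  expect_equal(sum(wk$required_n), 18L)

  # day 0 baseline part 1 is worth $15
  b1 <- sched[sched$instance == "baseline_1", ]
  expect_equal(b1$window_start, start)
  expect_equal(b1$window_end, start)
  rules <- incentive_rules()
  expect_equal(rules$amount_usd[rules$rule_id == "baseline_1"], 15)
  expect_equal(rules$amount_usd[rules$rule_id == "weekly_3"], 10)
  expect_equal(rules$amount_usd[rules$rule_id == "quarterly_2"], 20)
  expect_equal(rules$amount_usd[rules$rule_id == "final"], 20)
  expect_equal(rules$amount_usd[rules$rule_id == "baseline_2"], 5)

  # quarterly windows anchored at months 3, 6, 9 (30-day blocks)
  q <- sched[grepl("^survey_quarter", sched$instance), ]
  expect_equal(q$window_start, start + c(61, 151, 241))

  # week k window = days 7(k-1)+1 .. 7k
  w2 <- sched[sched$instance == "survey_week_2", ]
  expect_equal(w2$window_start, start + 8)
  expect_equal(w2$window_end, start + 14)

  # determinism: two builds are identical
  expect_identical(cal$scheduled, build_calendar("p01", start)$scheduled)
  expect_error(build_calendar("p01", "not-a-date"))
})

test_that("the daily menu lists pending work and annotates trainings", {
  cal <- build_calendar("p01", start)
  # week-2 day with 1 of 3 trainings done
  d <- start + 10
  hist <- hrow("p01", "training_basic", start + 9)
  menu <- daily_menu(cal, d, hist)
  tr <- menu[grepl("^training", menu$activity), ]
  expect_true(all(tr$annotation == "2 remaining"))

  # completed survey is removed from the menu
  hist2 <- rbind(hist, hrow("p01", "survey_weekly", start + 9))
  menu2 <- daily_menu(cal, d, hist2)
  expect_false("survey_weekly" %in% menu2$activity)
  expect_true("survey_weekly" %in% menu$activity)

  # weekly survey expires 4 days after scheduling
  d5 <- start + 8 + 5   # week-2 window opened on day 8
  menu3 <- daily_menu(cal, d5, hist)
  expect_false("survey_weekly" %in% menu3$activity)
  menu4 <- daily_menu(cal, start + 8 + 3, hist)
  expect_true("survey_weekly" %in% menu4$activity)

  expect_error(daily_menu(cal, start - 1, hist), "precedes")
})

test_that("incentives are earned once per satisfied rule", {
  cal <- build_calendar("p01", start)
  # week 1 (days 1-7): 2 basic + 1 game + survey, strict mode
  hist <- rbind(
    hrow("p01", "training_basic", start + 2),
    hrow("p01", "training_basic", start + 4),
    hrow("p01", "training_game", start + 5),
    hrow("p01", "survey_weekly", start + 3),
    hrow("p01", "survey_baseline_1", start)
  )
  entries <- evaluate_incentives(cal, hist, start + 10, mode = "strict")
  expect_setequal(entries$rule_id, c("baseline_1", "weekly_1"))
  expect_equal(entries$amount_usd[entries$rule_id == "weekly_1"], 10)
  expect_equal(entries$amount_usd[entries$rule_id == "baseline_1"], 15)

  # re-evaluation with the ledger present adds nothing
  again <- evaluate_incentives(cal, hist, start + 10, mode = "strict",
                               ledger = entries)
  expect_equal(nrow(again), 0)

  # strict mode rejects a week with only a started survey
  hist_started <- rbind(
    hrow("p01", "training_basic", start + 2),
    hrow("p01", "training_basic", start + 4),
    hrow("p01", "training_game", start + 5),
    hrow("p01", "survey_weekly", start + 3, status = "started")
  )
  strict <- evaluate_incentives(cal, hist_started, start + 10, "strict")
  expect_false("weekly_1" %in% strict$rule_id)
  # relaxed mode accepts it (3 trainings + survey initiated)
  relaxed <- evaluate_incentives(cal, hist_started, start + 10, "relaxed")
  expect_true("weekly_1" %in% relaxed$rule_id)
})

test_that("the nightly fulfillment scan pays each entry exactly once", {
  cal <- build_calendar("p01", start)
  hist <- rbind(hrow("p01", "survey_baseline_1", start),
                hrow("p01", "survey_baseline_2", start + 1))
  ledger <- evaluate_incentives(cal, hist, start + 2)
  expect_equal(nrow(ledger), 2)

  scan <- fulfillment_scan(ledger, start + 2)
  expect_equal(nrow(scan$payouts), 2)
  expect_true(all(scan$ledger$fulfilled))
  expect_equal(sum(scan$payouts$amount_usd), 20)

  # immediate re-run issues nothing
  scan2 <- fulfillment_scan(scan$ledger, start + 3)
  expect_equal(nrow(scan2$payouts), 0)
  # empty ledger
  empty <- fulfillment_scan(ledger[0, ], start)
  expect_equal(nrow(empty$payouts), 0)

  # conservation: total paid equals the sum of fulfilled amounts
  expect_equal(sum(scan$payouts$amount_usd),
               sum(scan$ledger$amount_usd[scan$ledger$fulfilled]))
  expect_lte(sum(scan$payouts$amount_usd), sum(ledger$amount_usd))
})

test_that("compliance percentages use the printed-count arithmetic", {
  expect_equal(compliance_pct(207, 328), 63.1)
  expect_equal(compliance_pct(164, 328), 50.0)
  expect_equal(compliance_pct(0, 328), 0)
  expect_true(is.na(compliance_pct(0, 0)))
  # ratios weakly decrease as scheduled grows with completions fixed
  expect_true(all(diff(compliance_pct(50, 100:200)) <= 0))
})

test_that("the cohort compliance report adjusts for individual start dates", {
  co <- synth_cohort(n_participants = 30, p_week1 = 1, decay = 1,
                     baseline_p = 1, start = start,
                     start_spread_days = 60, seed = 7)
  rep <- compliance_report(co$histories, co$calendars, co$as_of_date)
  # full adherence: every started activity complete
  wk <- rep$by_activity[grepl("week", rep$by_activity$instance), ]
  expect_true(all(wk$pct == 100))
  expect_equal(rep$completer_pct, 100)
  expect_true(all(rep$by_activity$pct >= 0 & rep$by_activity$pct <= 100,
                  na.rm = TRUE))

  g <- glance(rep)
  expect_equal(g$n_enrolled, 30)

  # decay 0 after week 1: weeks >= 2 have zero compliance
  co0 <- synth_cohort(n_participants = 20, p_week1 = 1, decay = 0,
                      baseline_p = 1, start = start,
                      start_spread_days = 30, seed = 8)
  rep0 <- compliance_report(co0$histories, co0$calendars, co0$as_of_date)
  w26 <- rep0$by_activity[grepl("week_[2-6]$", rep0$by_activity$instance), ]
  expect_true(all(w26$pct == 0))
  expect_equal(rep0$n_completers, 0)
})

test_that("the completer fraction tracks its generator parameter", {
  p <- 0.6
  co <- synth_cohort(n_participants = 328, completer_fraction = p,
                     p_week1 = 0.5, decay = 0.7, start = start, seed = 11)
  rep <- compliance_report(co$histories, co$calendars, co$as_of_date)
  ci <- p + c(-3, 3) * sqrt(p * (1 - p) / 328)
  expect_gte(rep$n_completers / rep$n_enrolled, ci[1])
  expect_lte(rep$n_completers / rep$n_enrolled, ci[2])
})
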