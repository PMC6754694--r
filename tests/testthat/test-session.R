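test_that("session plans follow the two-segment and four-segment protocols", {
  basic <- build_session_plan("basic", 6)
  expect_equal(basic$segments$segment, c("rest", "training"))
  expect_equal(basic$segments$duration_s, c(180, 300))
  expect_equal(basic$total_s, 480)

  game <- build_session_plan("training_game", 5, biofeedback = FALSE)
  expect_equal(game$segments$segment,
               c("rest", "stressor", "recovery", "training"))
  expect_equal(game$segments$duration_s, c(180, 240, 180, 300))
  expect_equal(game$total_s, 900)
  expect_equal(game$pacing_hz, 5 / 60)
  # biofeedback-off arm: display disabled, HRV still computed
  expect_false(game$biofeedback)

  expect_equal(sum(basic$segments$duration_s), basic$total_s)
  expect_error(build_session_plan("unknown"))
  expect_error(build_session_plan("basic", 7), "rate")
})

test_that("session events log segment boundaries, fades and announcements", {
  ev <- session_events(build_session_plan("training_game", 6))
  expect_equal(sum(ev$event == "landscape_fade"), 5)   # 30-s fades in 180-s rest
  expect_equal(sum(ev$event == "minute_announcement"), 2)
  expect_true("segment_start:stressor" %in% ev$event)
})

test_that("run_session tags records by segment and schedules the stressor", {
  plan <- build_session_plan("training_game", 6)
  s <- synth_session(plan, seed = 4)
  res <- run_session(plan, s, seed = 4)
  rec <- res$records
  expect_setequal(unique(rec$segment),
                  c("rest", "stressor", "recovery", "training"))
  # half-open rule at the rest/stressor boundary
  expect_equal(rec$segment[rec$t_s == 180], "stressor")
  # per-segment counts match the streaming count restricted to the interval
  seg <- plan$segments
  for (i in seq_len(nrow(seg))) {
    ends <- rec$t_s[rec$t_s >= seg$start_s[i] & rec$t_s < seg$end_s[i]]
    expected <- sum(seq(30, max(rec$t_s), by = 2) >= seg$start_s[i] &
                      seq(30, max(rec$t_s), by = 2) < seg$end_s[i])
    expect_equal(length(ends), expected)
  }
  # stressor trials land inside the stressor segment
  expect_true(all(res$trials$onset_s >= 180 & res$trials$onset_s < 420))
  expect_error(run_session(plan, synth_ibi(synth_params(seed = 1), 60)),
               "shorter")

  basic <- build_session_plan("basic", 6)
  sb <- synth_session(basic, seed = 5)
  resb <- run_session(basic, sb)
  expect_setequal(unique(resb$records$segment), c("rest", "training"))
  expect_null(resb$trials)
})

test_that("segment tagging partitions the session timeline", {
  plan <- build_session_plan("training_game", 6)
  s <- synth_session(plan, seed = 6)
  rec <- run_session(plan, s)$records
  inside <- rec$t_s <= plan$total_s
  expect_true(all(!is.na(rec$segment[inside])))
  # each time maps to exactly one label
  seg <- plan$segments
  for (t in c(0, 90, 180, 419.9, 420, 600, 899)) {
    hits <- sum(t >= seg$start_s & t < seg$end_s)
    expect_equal(hits, 1)
  }
})

test_that("meter calibration and state follow the baseline mu +/- 2 sd map", {
  cal <- calibrate_meter(tibble::tibble(wb = c(7.0, 7.2, 7.4)))
  expect_equal(cal$baseline_mu, 7.2)

  st <- meter_state(cal$baseline_mu, cal)
  expect_equal(st$meter, 0.5)
  expect_equal(st$zone, "yellow")
  st_hi <- meter_state(cal$baseline_mu + 2 * cal$baseline_sd, cal)
  expect_equal(st_hi$meter, 1)
  expect_equal(st_hi$zone, "green")
  st_lo <- meter_state(cal$baseline_mu - 3 * cal$baseline_sd, cal)
  expect_equal(st_lo$meter, 0)
  expect_equal(st_lo$zone, "red")

  # out-of-range rest values are excluded before calibration
  cal2 <- calibrate_meter(tibble::tibble(wb = c(7.0, 7.2, 7.4, -3, 12)))
  expect_equal(cal2$n, 3)
  expect_equal(cal2$baseline_mu, 7.2)

  expect_error(calibrate_meter(tibble::tibble(wb = c(7, 11))), "at least 3")
})

test_that("a zero-sd baseline degenerates to a three-zone step", {
  cal <- calibrate_meter(tibble::tibble(wb = rep(7, 5)))
  expect_equal(cal$baseline_sd, 0)
  expect_equal(meter_state(6.9, cal)$zone, "red")
  expect_equal(meter_state(7.0, cal)$zone, "yellow")
  expect_equal(meter_state(7.1, cal)$zone, "green")
})

test_that("the meter is monotone in the HRV value", {
  cal <- calibrate_meter(tibble::tibble(wb = c(6.8, 7.1, 7.3, 7.6)))
  vals <- seq(5, 9, by = 0.1)
  m <- meter_state(vals, cal)$meter
  expect_true(all(diff(m) >= 0))
  expect_true(all(m >= 0 & m <= 1))
})

test_that("session bundles serialize to plain files", {
  plan <- build_session_plan("training_game", 6)
  s <- synth_session(plan, seed = 8)
  res <- run_session(plan, s, seed = 8)
  dir <- tempfile("bundle")
  write_session_bundle(res, dir)
  expect_true(all(file.exists(file.path(dir, c("hrv.csv", "trials.csv",
                                               "events.json", "meter.csv")))))
  mt <- readr::read_csv(file.path(dir, "meter.csv"), show_col_types = FALSE)
  expect_true(all(mt$meter >= 0 & mt$meter <= 1))
})
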