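test_that("synthetic series are reproducible and span the duration", {
  p <- synth_params(seed = 42)
  a <- synth_ibi(p, 180)
  b <- synth_ibi(p, 180)
  expect_identical(a$ibi_ms, b$ibi_ms)

  # mean IBI 1000 ms, 180 s: beat count 180 +/- 2
  expect_lte(abs(nrow(a) - 180), 2)
  expect_gte(tail(a$t_s, 1), 180)

  expect_error(synth_params(mean_ibi_ms = 100), "range")
  expect_error(synth_params(resp_amp_ms = 600, noise_sd_ms = 200),
               "non-positive")
  expect_error(synth_params(resp_hz = 0.6), "Nyquist")
})

test_that("amp_for_ln_variance inverts the sinusoid closed form", {
  expect_equal(amp_for_ln_variance(7.37), 56.34, tolerance = 1e-3)
  for (v in c(5, 6.92, 8.205)) {
    expect_equal(log(amp_for_ln_variance(v)^2 / 2), v)
  }
})

test_that("the pipeline recovers the generator's band-limited set-point", {
  # parameter recovery across seeded replicates at the resting set-point
  target <- 7.37
  amp <- amp_for_ln_variance(target)
  est <- vapply(1:20, function(sd) {
    s <- synth_ibi(synth_params(resp_amp_ms = amp, lf_amp_ms = 0,
                                noise_sd_ms = 3, seed = sd), 180)
    mean(filter_hrv_range(band_ln_variance(clean_ibi(s), "wb"))$value,
         na.rm = TRUE)
  }, numeric(1))
  expect_lt(abs(mean(est) - target), 0.2)
})

test_that("injected artifacts are recovered by cleaning", {
  rate <- 0.05
  fracs <- vapply(1:10, function(sd) {
    s <- synth_ibi(synth_params(artifact_rate = rate, seed = sd), 300)
    attr(clean_ibi(s), "artifact_fraction")
  }, numeric(1))
  expect_lt(abs(mean(fracs) - rate) / rate, 0.2)
})

test_that("segment effects shift the wideband value as the amplitude ratio", {
  plan <- build_session_plan("training_game", 6)
  eff <- segment_effects(stress_amp = 0.8, stress_ibi = 1,
                         recovery_amp = 1, recovery_ibi = 1)
  d <- vapply(1:8, function(sd) {
    s <- synth_session(plan, synth_params(lf_amp_ms = 0, noise_sd_ms = 2),
                       eff, seed = sd)
    rec <- compute_hrv_stream(clean_ibi(s), segments = plan$segments)
    rec <- filter_hrv_range(rec)
    st <- segment_stats(rec, "wb")
    st$mean[st$segment == "stressor"] - st$mean[st$segment == "rest"]
  }, numeric(1))
  # amplitude ratio r maps to a 2*log(r) shift in ln-variance
  expect_lt(abs(mean(d) - 2 * log(0.8)), 0.15)

  # recovery multiplier 1 returns to the rest level
  d2 <- vapply(1:8, function(sd) {
    s <- synth_session(plan, synth_params(lf_amp_ms = 0, noise_sd_ms = 2),
                       eff, seed = sd)
    rec <- filter_hrv_range(compute_hrv_stream(clean_ibi(s),
                                               segments = plan$segments))
    st <- segment_stats(rec, "wb")
    st$mean[st$segment == "recovery"] - st$mean[st$segment == "rest"]
  }, numeric(1))
  expect_lt(abs(mean(d2)), 0.15)
})

test_that("paced training raises wideband while RSA falls relative to rest", {
  plan <- build_session_plan("training_game", 6)   # pacing at 0.1 Hz
  s <- synth_session(plan, synth_params(lf_amp_ms = 0, noise_sd_ms = 2),
                     seed = 3)
  rec <- filter_hrv_range(compute_hrv_stream(clean_ibi(s),
                                             segments = plan$segments))
  wb <- segment_stats(rec, "wb")
  rsa <- segment_stats(rec, "rsa")
  expect_gt(wb$mean[wb$segment == "training"], wb$mean[wb$segment == "rest"])
  expect_lt(rsa$mean[rsa$segment == "training"],
            rsa$mean[rsa$segment == "rest"])
})

test_that("cohort generation is reproducible and well-formed", {
  a <- synth_cohort(n_participants = 10, seed = 5)
  b <- synth_cohort(n_participants = 10, seed = 5)
  expect_identical(a$histories, b$histories)
  expect_equal(length(a$calendars), 10)
  expect_true(all(a$histories$participant_id %in% names(a$calendars)))
  expect_error(synth_cohort(5, p_week1 = 1.5), "0, 1")
})
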