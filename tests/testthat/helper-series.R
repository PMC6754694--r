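# Deterministic sinusoidally modulated IBI series: a pure tone of amplitude
# amp_ms at freq_hz around mean_ms, no noise, no artifacts. The closed-form
# band-limited ln-variance of the modulation is log(amp_ms^2 / 2).
tone_series <- function(freq_hz, amp_ms, duration_s, mean_ms = 1000) {
  synth_ibi(synth_params(mean_ibi_ms = mean_ms, resp_hz = freq_hz,
                         resp_amp_ms = amp_ms, lf_amp_ms = 0,
                         noise_sd_ms = 0, seed = 1),
            duration_s = duration_s)
}

tone_oracle <- function(amp_ms) log(amp_ms^2 / 2)

# history row helper
hrow <- function(pid, activity, date, status = "completed") {
  tibble::tibble(participant_id = pid, activity = activity,
                 date = as.Date(date), status = status)
}
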