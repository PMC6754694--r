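#' HRV analysis configuration
#'
#' Bundles every tunable of the band-limited ln-variance pipeline. The three
#' default bands follow the moving-polynomial-filter HRV tradition:
#' respiratory sinus arrhythmia (RSA) 0.12--0.40 Hz for spontaneous breathing,
#' low-frequency (LF) 0.06--0.10 Hz, and a wideband 0.03--0.40 Hz measure that
#' also covers the 5--6 breaths/min (0.083--0.1 Hz) paced-breathing rates, so
#' slow paced breathing is not scored as "no variability".
#'
#' @param resample_hz Uniform resampling rate for the IBI tachogram (Hz).
#' @param interp Interpolation used to resample the tachogram: `"spline"`
#'   (cubic, default) or `"step"` (sample-and-hold).
#' @param detrend_window_s Moving polynomial detrend window (seconds). When an
#'   analysis window is shorter than this, a single polynomial of
#'   `detrend_order` is fitted over the whole window instead.
#' @param detrend_order Polynomial order of the detrend filter.
#' @param band_rsa,band_lf,band_wb Frequency intervals in Hz, each
#'   `c(low, high)` with `0 < low < high < resample_hz / 2`.
#' @param transition_hz Raised-cosine transition width of the zero-phase
#'   band-pass (Hz).
#' @param epoch_s Epoch length for offline per-epoch measures (seconds).
#' @param stream_window_s Trailing analysis window of the streaming feed (s).
#' @param stream_step_s Streaming update interval (seconds; the biofeedback
#'   display updates every 2 s).
#' @param valid_range Plausible range for ln-variance values; values outside
#'   it are treated as artifact-driven and excluded from analysis.
#' @param var_floor_ms2 Variance floor (ms^2); variances below it report
#'   `log(var_floor_ms2)` instead of `-Inf`.
#' @return A list of class `hrv_config`.
#' @examples
#' hrv_config()
#' @export
hrv_config <- function(resample_hz = 5,
                       interp = c("spline", "step"),
                       detrend_window_s = 60,
                       detrend_order = 3,
                       band_rsa = c(0.12, 0.40),
                       band_lf = c(0.06, 0.10),
                       band_wb = c(0.03, 0.40),
                       transition_hz = 0.01,
                       epoch_s = 30,
                       stream_window_s = 30,
                       stream_step_s = 2,
                       valid_range = c(0, 10),
                       var_floor_ms2 = 1e-6) {
  interp <- match.arg(interp)
  nyq <- resample_hz / 2
  for (b in list(band_rsa, band_lf, band_wb)) {
    if (!(length(b) == 2 && b[1] > 0 && b[1] < b[2] && b[2] < nyq)) {
      abort("each band must satisfy 0 < low < high < resample_hz/2")
    }
  }
  structure(list(
    resample_hz = resample_hz, interp = interp,
    detrend_window_s = detrend_window_s, detrend_order = detrend_order,
    band_rsa = band_rsa, band_lf = band_lf, band_wb = band_wb,
    transition_hz = transition_hz, epoch_s = epoch_s,
    stream_window_s = stream_window_s, stream_step_s = stream_step_s,
    valid_range = valid_range, var_floor_ms2 = var_floor_ms2
  ), class = "hrv_config")
}

#' @export
print.hrv_config <- function(x, ...) {
  cat("<hrv_config>\n")
  cat(sprintf("  resample %g Hz (%s), detrend order %d over %g s\n",
              x$resample_hz, x$interp, x$detrend_order, x$detrend_window_s))
  cat(sprintf("  bands (Hz): RSA %.2f-%.2f  LF %.2f-%.2f  WB %.2f-%.2f\n",
              x$band_rsa[1], x$band_rsa[2], x$band_lf[1], x$band_lf[2],
              x$band_wb[1], x$band_wb[2]))
  cat(sprintf("  epoch %g s; stream window %g s step %g s; valid [%g, %g]\n",
              x$epoch_s, x$stream_window_s, x$stream_step_s,
              x$valid_range[1], x$valid_range[2]))
  invisible(x)
}

# ---- internal pipeline stages -------------------------------------------

# Resample the tachogram (ibi_ms vs onset t_s) to a uniform grid.
# Grid starts at the first onset and steps by 1/resample_hz.
resample_tachogram <- function(series, config) {
  keep <- !series$artifact
  tt <- series$t_s[keep]
  ib <- series$ibi_ms[keep]
  if (length(ib) < 4) abort("too few clean beats to resample")
  # anchor at t = 0 so the grid spans [0, duration]
  if (tt[1] > 0) { tt <- c(0, tt); ib <- c(ib[1], ib) }
  t1 <- tt[length(tt)]
  tg <- seq(0, t1, by = 1 / config$resample_hz)
  x <- if (config$interp == "spline") {
    spline(tt, ib, xout = tg, method = "fmm")$y
  } else {
    approx(tt, ib, xout = tg, method = "constant", f = 0, rule = 2)$y
  }
  list(t = tg, x = x)
}

# Remove the slow trend: moving polynomial (Savitzky-Golay) when the record
# is longer than the detrend window, otherwise one whole-window polynomial.
detrend_series <- function(x, config) {
  n <- length(x)
  nw <- round(config$detrend_window_s * config$resample_hz)
  if (nw %% 2 == 0) nw <- nw + 1
  if (n > nw) {
    x - signal::sgolayfilt(x, p = config$detrend_order, n = nw)
  } else {
    idx <- seq_len(n)
    residuals(lm(x ~ stats::poly(idx, degree = min(config$detrend_order,
                                                   n - 1))))
  }
}

# Zero-phase FFT band-pass with raised-cosine transitions.
bandpass_fft <- function(x, band, config) {
  n <- length(x)
  fs <- config$resample_hz
  f <- (0:(n - 1)) / n * fs
  f <- pmin(f, fs - f)
  lo <- band[1]; hi <- band[2]; tr <- config$transition_hz
  g <- ifelse(f >= lo & f <= hi, 1,
       ifelse(f > lo - tr & f < lo, 0.5 * (1 - cos(pi * (f - (lo - tr)) / tr)),
       ifelse(f > hi & f < hi + tr, 0.5 * (1 + cos(pi * (f - hi) / tr)), 0)))
  Re(fft(fft(x) * g, inverse = TRUE)) / n
}

ln_var <- function(y, config) {
  v <- var(y)
  log(max(v, config$var_floor_ms2))
}

check_band <- function(band, config) {
  if (band[2] >= config$resample_hz / 2 || band[1] <= 0) {
    abort("band outside (0, Nyquist)")
  }
}

resolve_band <- function(band, config) {
  if (is.character(band)) {
    band <- switch(match.arg(band, c("rsa", "lf", "wb")),
                   rsa = config$band_rsa, lf = config$band_lf,
                   wb = config$band_wb)
  }
  check_band(band, config)
  band
}

# ---- user-facing operations ---------------------------------------------

#' Per-epoch band-limited ln-variance of an IBI series
#'
#' The offline HRV measure. Pipeline: resample the interbeat intervals to a
#' uniform tachogram, remove the slow trend with a moving polynomial filter,
#' band-pass to the requested band with a zero-phase filter, partition into
#' epochs, and report the natural log of the within-epoch variance (ln ms^2).
#' For a pure sinusoidal modulation of amplitude A inside the band, the value
#' is `log(A^2 / 2)` up to filter gain.
#'
#' @param series A cleaned [ibi_series()] tibble at least one epoch long.
#' @param band `"rsa"`, `"lf"`, `"wb"`, or a numeric `c(low, high)` in Hz.
#' @param config An [hrv_config()].
#' @return A tibble with columns `t_s` (epoch end, seconds from first onset)
#'   and `value` (ln ms^2), one row per complete epoch.
#' @examples
#' s <- synth_ibi(synth_params(noise_sd_ms = 0, seed = 1), duration_s = 120)
#' band_ln_variance(s, "rsa")
#' @export
band_ln_variance <- function(series, band = "wb", config = hrv_config()) {
  band <- resolve_band(band, config)
  rs <- resample_tachogram(series, config)
  npe <- round(config$epoch_s * config$resample_hz)
  if (length(rs$x) < npe + 1) abort("series shorter than one epoch")
  y <- bandpass_fft(detrend_series(rs$x, config), band, config)
  n_epochs <- (length(y) - 1) %/% npe
  vals <- vapply(seq_len(n_epochs), function(k) {
    ln_var(y[((k - 1) * npe + 2):(k * npe + 1)], config)
  }, numeric(1))
  tibble(t_s = seq_len(n_epochs) * config$epoch_s, value = vals)
}

#' Streaming three-band HRV feed
#'
#' Emulates the real-time biofeedback computation: every `stream_step_s`
#' seconds (2 s by default), the trailing `stream_window_s` of the tachogram
#' is detrended and band-passed, and the single-window ln-variance is reported
#' for each of the three bands. Record times are window-end times in seconds
#' from the start of the series; the first record appears once a full window
#' is available.
#'
#' @inheritParams band_ln_variance
#' @param segments Optional tibble with columns `segment`, `start_s`, `end_s`
#'   (half-open intervals) used to label each record by its window-end time;
#'   see [build_session_plan()].
#' @return A tibble with columns `t_s`, `rsa`, `lf`, `wb` (ln ms^2) and
#'   `segment` (`NA` when no segment table given or the time is uncovered).
#' @examples
#' s <- synth_ibi(synth_params(noise_sd_ms = 0, seed = 1), duration_s = 60)
#' compute_hrv_stream(s)
#' @export
compute_hrv_stream <- function(series, config = hrv_config(), segments = NULL) {
  rs <- resample_tachogram(series, config)
  fs <- config$resample_hz
  npw <- round(config$stream_window_s * fs)
  nps <- round(config$stream_step_s * fs)
  if (length(rs$x) < npw + 1) abort("series shorter than stream_window_s")
  # window ending at grid index e covers [t_e - window, t_e]
  ends <- seq(npw + 1, length(rs$x), by = nps)
  bands <- list(rsa = config$band_rsa, lf = config$band_lf, wb = config$band_wb)
  vals <- vapply(ends, function(e) {
    w <- rs$x[(e - npw):e]
    wd <- detrend_series(w, config)
    vapply(bands, function(b) ln_var(bandpass_fft(wd, b, config), config),
           numeric(1))
  }, numeric(3))
  out <- tibble(
    t_s = rs$t[ends],
    rsa = vals[1, ], lf = vals[2, ], wb = vals[3, ],
    segment = NA_character_
  )
  if (!is.null(segments)) out$segment <- label_times(out$t_s, segments)
  out
}

# Label times by half-open segment intervals [start_s, end_s); a time equal
# to the final end is clamped into the final segment so the last streaming
# window (ending exactly at session end) is not orphaned.
label_times <- function(t, segments) {
  lab <- rep(NA_character_, length(t))
  for (i in seq_len(nrow(segments))) {
    inside <- t >= segments$start_s[i] & t < segments$end_s[i]
    lab[inside] <- segments$segment[i]
  }
  lab[t == max(segments$end_s)] <- segments$segment[nrow(segments)]
  lab
}

#' Filter HRV values to the plausible range
#'
#' Values outside `valid_range` (default \[0, 10\] ln ms^2) are almost always
#' driven by interbeat-interval artifacts and are masked (set `NA`) on a
#' per-value basis before analysis. A record is dropped only if every band
#' value is masked.
#'
#' @param records A tibble of streaming records ([compute_hrv_stream()]) or
#'   any tibble with some of the columns `rsa`, `lf`, `wb`, `value`.
#' @param valid_range Length-2 numeric range of acceptable values.
#' @return The filtered tibble, with attribute `n_excluded` = number of
#'   individual values masked.
#' @examples
#' r <- tibble::tibble(t_s = 1:4, wb = c(7.2, -0.5, 11.3, 9.9))
#' filter_hrv_range(r)
#' @export
filter_hrv_range <- function(records, valid_range = c(0, 10)) {
  cols <- intersect(c("rsa", "lf", "wb", "value"), names(records))
  n_excluded <- 0L
  if (nrow(records) == 0 || length(cols) == 0) {
    attr(records, "n_excluded") <- 0L
    return(records)
  }
  for (cl in cols) {
    bad <- !is.na(records[[cl]]) &
      (records[[cl]] < valid_range[1] | records[[cl]] > valid_range[2])
    n_excluded <- n_excluded + sum(bad)
    records[[cl]][bad] <- NA_real_
  }
  keep <- rowSums(!is.na(records[, cols, drop = FALSE])) > 0
  out <- records[keep, , drop = FALSE]
  attr(out, "n_excluded") <- as.integer(n_excluded)
  out
}

#' Write a streaming HRV feed to CSV
#' @param records Tibble from [compute_hrv_stream()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hrv_csv <- function(records, path) {
  readr::write_csv(records[, intersect(c("t_s", "rsa", "lf", "wb", "segment"),
                                       names(records))], path)
  invisible(path)
}
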