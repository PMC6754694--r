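#' Paced-breathing cycle timing
#'
#' Computes the timing of one guided breath at a prescribed rate. The cycle is
#' inhale, end-inspiration pause, exhale, end-expiration pause; the study
#' defaults are an inspiration-to-expiration ratio of 0.435 and 1.5-s pauses,
#' at 5 or 6 breaths/min. With `cycle_s = 60 / rate_bpm`:
#' `inhale_s = ie_ratio / (1 + ie_ratio) * (cycle_s - 2 * pause_s)` and
#' `exhale_s = (cycle_s - 2 * pause_s) / (1 + ie_ratio)`.
#'
#' @param rate_bpm Breathing rate, breaths per minute (> 0).
#' @param ie_ratio Inspiration-to-expiration duration ratio (> 0).
#' @param pause_s End-inspiration and end-expiration pause, seconds.
#' @return An object of class `breath_cycle` (list with `rate_bpm`,
#'   `ie_ratio`, `pause_s`, `cycle_s`, `inhale_s`, `exhale_s`, `pacing_hz`).
#'   `tidy()` returns it as a one-row tibble.
#' @examples
#' breath_cycle(6)   # 10-s cycle: inhale 2.12 s, exhale 4.88 s
#' breath_cycle(5)   # 12-s cycle
#' @export
breath_cycle <- function(rate_bpm, ie_ratio = 0.435, pause_s = 1.5) {
  if (rate_bpm <= 0 || ie_ratio <= 0 || pause_s < 0) {
    abort("rate_bpm and ie_ratio must be positive; pause_s non-negative")
  }
  cycle_s <- 60 / rate_bpm
  if (2 * pause_s >= cycle_s) abort("pauses exceed the breath cycle")
  active <- cycle_s - 2 * pause_s
  structure(list(
    rate_bpm = rate_bpm, ie_ratio = ie_ratio, pause_s = pause_s,
    cycle_s = cycle_s,
    inhale_s = ie_ratio / (1 + ie_ratio) * active,
    exhale_s = active / (1 + ie_ratio),
    pacing_hz = rate_bpm / 60
  ), class = "breath_cycle")
}

#' @export
print.breath_cycle <- function(x, ...) {
  cat(sprintf(
    "<breath_cycle> %g bpm: cycle %.1f s = inhale %.2f + pause %.1f + exhale %.2f + pause %.1f\n",
    x$rate_bpm, x$cycle_s, x$inhale_s, x$pause_s, x$exhale_s, x$pause_s))
  invisible(x)
}

#' @rdname breath_cycle
#' @param x A `breath_cycle` object.
#' @param ... Unused.
#' @export
tidy.breath_cycle <- function(x, ...) {
  tibble(rate_bpm = x$rate_bpm, ie_ratio = x$ie_ratio, pause_s = x$pause_s,
         cycle_s = x$cycle_s, inhale_s = x$inhale_s, exhale_s = x$exhale_s,
         pacing_hz = x$pacing_hz)
}

#' Pacer animation waveform
#'
#' Height of the animated breathing ball in \[0, 1\] over time: it rises
#' during the inhale, holds at 1 through the end-inspiration pause, falls
#' during the exhale and holds at 0 through the end-expiration pause. The
#' waveform is periodic with period `cycle_s`; a synchronized audio tone is
#' the same waveform mapped onto a pitch range.
#'
#' @param cycle A [breath_cycle()].
#' @param duration_s Total duration, seconds (at least one cycle).
#' @param dt_s Sampling interval, seconds.
#' @param shape `"linear"` ramps (default) or `"cosine"` (raised-cosine
#'   eased) ramps; timing is identical.
#' @return A tibble with columns `t_s`, `height`, `phase`
#'   (inhale/pause_top/exhale/pause_bottom).
#' @examples
#' w <- pacer_waveform(breath_cycle(6), duration_s = 30, dt_s = 0.1)
#' @export
pacer_waveform <- function(cycle, duration_s, dt_s = 0.1,
                           shape = c("linear", "cosine")) {
  shape <- match.arg(shape)
  if (dt_s <= 0) abort("dt_s must be positive")
  if (duration_s < cycle$cycle_s) abort("duration shorter than one cycle")
  t <- seq(0, duration_s, by = dt_s)
  ph <- t %% cycle$cycle_s
  b1 <- cycle$inhale_s
  b2 <- b1 + cycle$pause_s
  b3 <- b2 + cycle$exhale_s
  frac_up <- pmin(ph / b1, 1)
  frac_down <- pmin(pmax((ph - b2) / cycle$exhale_s, 0), 1)
  ease <- function(u) if (shape == "cosine") (1 - cos(pi * u)) / 2 else u
  height <- ifelse(ph < b1, ease(frac_up),
            ifelse(ph < b2, 1,
            ifelse(ph < b3, 1 - ease(frac_down), 0)))
  phase <- ifelse(ph < b1, "inhale",
           ifelse(ph < b2, "pause_top",
           ifelse(ph < b3, "exhale", "pause_bottom")))
  tibble(t_s = t, height = height, phase = phase)
}

#' Plot a pacer waveform
#' @param waveform Tibble from [pacer_waveform()].
#' @return A ggplot object.
#' @export
plot_pacer <- function(waveform) {
  ggplot2::ggplot(waveform, ggplot2::aes(x = .data$t_s, y = .data$height)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::labs(x = "time (s)", y = "ball height",
                  title = "Paced-breathing pacer") +
    ggplot2::theme_minimal()
}
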