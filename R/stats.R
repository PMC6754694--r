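#' Per-segment descriptive statistics
#'
#' Mean and standard error of a band's values per session segment, counting
#' measures (a participant may contribute several), the way grouped HRV
#' results are reported as mean (SE) with mean +/- 2 SE error bars. Apply
#' [filter_hrv_range()] first so artifact-driven values are excluded.
#'
#' @param records Segment-tagged HRV tibble (column `segment` plus the band
#'   column).
#' @param band Column to summarize (default `"wb"`).
#' @return A tibble with columns `segment`, `n`, `mean`, `se`, `ci_lo`,
#'   `ci_hi` (mean -/+ 2 SE).
#' @examples
#' r <- tibble::tibble(segment = c("rest", "rest", "rest"), wb = c(7, 8, 9))
#' segment_stats(r)   # mean 8, se 0.577
#' @export
segment_stats <- function(records, band = "wb") {
  vals <- records[[band]]
  keep <- !is.na(vals) & !is.na(records$segment)
  if (!any(keep)) abort("no segment-tagged values to summarize")
  df <- tibble(segment = records$segment[keep], value = vals[keep])
  out <- df |>
    group_by(.data$segment) |>
    summarise(n = n(),
              mean = mean(.data$value),
              se = if (n() > 1) sd(.data$value) / sqrt(n()) else 0,
              .groups = "drop") |>
    mutate(ci_lo = .data$mean - 2 * .data$se,
           ci_hi = .data$mean + 2 * .data$se)
  seg_order <- c("rest", "stressor", "recovery", "training")
  out[order(match(out$segment, seg_order)), ]
}

#' Unpaired t test between sequential training segments
#'
#' Two-sample t test comparing HRV measures of two session segments, as used
#' to evaluate changes across sequential segments. Welch's unequal-variance
#' form is the default; `pooled = TRUE` gives the classical equal-variance
#' test. The degenerate case (no variance in either group and equal means)
#' reports t = 0, p = 1.
#'
#' @param a,b Numeric vectors of band values for the two segments (at least
#'   2 each), in sequence order (a before b).
#' @param pooled Use the pooled-variance test instead of Welch.
#' @return A one-row tibble: `t`, `df`, `p`, `direction` (sign of
#'   `mean(b) - mean(a)`), `mean_a`, `mean_b`, `n_a`, `n_b`, `method`.
#' @examples
#' sequential_t_test(c(1, 2, 3), c(4, 5, 6))
#' @export
sequential_t_test <- function(a, b, pooled = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) abort("need at least 2 values per group")
  method <- if (pooled) "pooled" else "welch"
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = length(a) + length(b) - 2, p = 1,
                    direction = 0, mean_a = mean(a), mean_b = mean(b),
                    n_a = length(a), n_b = length(b), method = method))
    }
    abort("zero variance in both groups with unequal means")
  }
  tt <- t.test(b, a, var.equal = pooled)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, direction = sign(mean(b) - mean(a)),
         mean_a = mean(a), mean_b = mean(b),
         n_a = length(a), n_b = length(b), method = method)
}

#' One-way ANOVA across segments
#'
#' Fixed-effects one-way analysis of variance of a band's values on segment
#' label, the segment-level analogue of a univariate general linear model.
#'
#' @inheritParams segment_stats
#' @return A one-row tibble: `F`, `df1`, `df2`, `p`.
#' @export
segment_anova <- function(records, band = "wb") {
  vals <- records[[band]]
  keep <- !is.na(vals) & !is.na(records$segment)
  df <- data.frame(value = vals[keep], segment = factor(records$segment[keep]))
  if (nlevels(df$segment) < 2) abort("need at least 2 segments")
  fit <- aov(value ~ segment, data = df)
  s <- summary(fit)[[1]]
  tibble(F = s[["F value"]][1], df1 = s[["Df"]][1], df2 = s[["Df"]][2],
         p = s[["Pr(>F)"]][1])
}

#' Sequential t tests across a whole session
#'
#' Runs [sequential_t_test()] for every adjacent pair of segments present in
#' protocol order (rest, stressor, recovery, training).
#'
#' @inheritParams segment_stats
#' @return A tibble with one row per adjacent pair, with a `comparison`
#'   column like `"rest->stressor"`.
#' @export
session_t_tests <- function(records, band = "wb") {
  seg_order <- c("rest", "stressor", "recovery", "training")
  present <- seg_order[seg_order %in% unique(records$segment)]
  if (length(present) < 2) abort("need at least 2 segments")
  out <- list()
  for (i in seq_len(length(present) - 1)) {
    a <- records[[band]][records$segment %in% present[i]]
    b <- records[[band]][records$segment %in% present[i + 1]]
    res <- sequential_t_test(a[!is.na(a)], b[!is.na(b)])
    res$comparison <- paste0(present[i], "->", present[i + 1])
    out[[i]] <- res
  }
  bind_rows(out)[, c("comparison", "t", "df", "p", "direction",
                     "mean_a", "mean_b", "n_a", "n_b", "method")]
}

#' Plot segment means with 2-SE error bars
#' @param stats Tibble from [segment_stats()].
#' @return A ggplot object.
#' @export
plot_segment_means <- function(stats) {
  stats$segment <- factor(stats$segment, levels = stats$segment)
  ggplot2::ggplot(stats, ggplot2::aes(x = .data$segment, y = .data$mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_lo,
                                        ymax = .data$ci_hi), width = 0.15) +
    ggplot2::labs(x = NULL, y = "HRV ln-variance (ln ms²), mean ± 2 SE") +
    ggplot2::theme_minimal()
}
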