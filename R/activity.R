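#' Per-electrode mean firing rate map
#'
#' MFR is the spike count divided by the recording duration, reported for
#' every electrode of the layout including silent ones, so that
#' `sum(mfr_hz) * duration_s` equals the total spike count exactly.
#'
#' @param raster A [spike_raster()].
#' @return Tibble with `electrode_id`, `x_mm`, `y_mm`, `n_spikes`, `mfr_hz`.
#' @export
mean_firing_rate <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  counts <- table(factor(raster$spikes$electrode_id, levels = raster$layout$electrode_id))
  tibble::tibble(
    electrode_id = raster$layout$electrode_id,
    x_mm = raster$layout$x_mm,
    y_mm = raster$layout$y_mm,
    n_spikes = as.integer(counts),
    mfr_hz = as.numeric(counts) / raster$duration_s
  )
}

#' Interspike intervals
#'
#' Successive-spike differences within each electrode, in milliseconds.
#' Electrodes with fewer than two spikes contribute nothing.  All intervals
#' are retained (no burst/inter-burst distinction).
#'
#' @param raster A [spike_raster()].
#' @param pooling `"pooled"` returns one table of all intervals;
#'   `"per_electrode"` additionally nests nothing but signals, in
#'   [average_isi_ratio()], that averaging happens per electrode first.
#' @return Tibble with `electrode_id`, `isi_ms`.
#' @export
interspike_intervals <- function(raster, pooling = c("pooled", "per_electrode")) {
  stopifnot(inherits(raster, "spike_raster"))
  match.arg(pooling)
  raster$spikes |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::reframe(isi_ms = diff(.data$time_s) * 1000)
}

#' Ratio of average ISI between two recordings
#'
#' `100 * mean(ISI_b) / mean(ISI_a)` in percent, the "average ISI dropped to
#' X%" statistic used to compare consecutive DIVs.  The default pools all
#' intervals across electrodes before averaging; `per_electrode` averages
#' within electrodes first and then across electrodes.
#'
#' @param raster_a Reference recording (denominator).
#' @param raster_b Comparison recording (numerator).
#' @param pooling See [interspike_intervals()].
#' @return A single percentage.
#' @export
average_isi_ratio <- function(raster_a, raster_b, pooling = c("pooled", "per_electrode")) {
  pooling <- match.arg(pooling)
  mean_isi <- function(r) {
    isi <- interspike_intervals(r)
    if (nrow(isi) == 0) stop_no_data("recording yields no interspike intervals")
    if (pooling == "pooled") {
      mean(isi$isi_ms)
    } else {
      isi |>
        dplyr::group_by(.data$electrode_id) |>
        dplyr::summarise(m = mean(.data$isi_ms), .groups = "drop") |>
        dplyr::pull("m") |>
        mean()
    }
  }
  100 * mean_isi(raster_b) / mean_isi(raster_a)
}

#' Distribution summary
#'
#' The summary behind the package's box/violin statistics: median and
#' quartiles by linear interpolation between order statistics
#' (`stats::quantile()` type 7), whiskers at 1.5x the interquartile range
#' clipped to the data range, mean, and SEM (`sd/sqrt(n)` with the n-1
#' denominator; `NA` for a single value).
#'
#' @param values Numeric vector (NAs dropped; at least one value required).
#' @return One-row tibble: `n`, `mean`, `sd`, `sem`, `median`, `q25`, `q75`,
#'   `whisker_low`, `whisker_high`, `min`, `max`.
#' @export
summarize_distribution <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop_no_data("no values to summarise")
  q <- unname(quantile(values, c(0.25, 0.5, 0.75), type = 7))
  iqr <- q[3] - q[1]
  s <- if (length(values) > 1) sd(values) else NA_real_
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = s,
    sem = s / sqrt(length(values)),
    median = q[2],
    q25 = q[1],
    q75 = q[3],
    whisker_low = max(min(values), q[1] - 1.5 * iqr),
    whisker_high = min(max(values), q[3] + 1.5 * iqr),
    min = min(values),
    max = max(values)
  )
}

#' Welch's unpaired two-tailed t-test
#'
#' The group comparison used throughout the condition contrasts: unequal
#' variances are allowed (Welch-Satterthwaite degrees of freedom) and the
#' p-value is two-sided.  Delegates the computation to [stats::t.test()].
#'
#' @param group_a,group_b Numeric vectors, each with at least two values.
#' @param name_a,name_b Labels carried into the result.
#' @return Object of class `welch_test` with a [tidy()] method; printing
#'   shows t, df, p and the significance tier (`***` p < 0.005, `**`
#'   p < 0.01, `*` p < 0.05).
#' @export
welch_t_test <- function(group_a, group_b, name_a = "a", name_b = "b") {
  group_a <- group_a[!is.na(group_a)]
  group_b <- group_b[!is.na(group_b)]
  if (length(group_a) < 2 || length(group_b) < 2) {
    stop_invalid("each group needs at least two values")
  }
  if (sd(group_a) == 0 && sd(group_b) == 0) {
    rlang::abort("both groups have zero variance; the Welch statistic is undefined",
                 class = c("hdmeanet_degenerate_input", "hdmeanet_error"))
  }
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE, alternative = "two.sided")
  structure(
    list(
      statistic = unname(ht$statistic),
      df = unname(ht$parameter),
      p_value = ht$p.value,
      mean_a = mean(group_a), mean_b = mean(group_b),
      n_a = length(group_a), n_b = length(group_b),
      name_a = name_a, name_b = name_b
    ),
    class = "welch_test"
  )
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("Welch t-test (%s vs %s): t = %.4g, df = %.2f, p = %.4g %s\n",
              x$name_a, x$name_b, x$statistic, x$df, x$p_value,
              significance_tier(x$p_value)))
  invisible(x)
}

#' @rdname welch_t_test
#' @param x A `welch_test` object.
#' @param ... Unused.
#' @export
tidy.welch_test <- function(x, ...) {
  tibble::tibble(
    group_a = x$name_a, group_b = x$name_b,
    mean_a = x$mean_a, mean_b = x$mean_b,
    n_a = x$n_a, n_b = x$n_b,
    estimate = x$mean_a - x$mean_b,
    statistic = x$statistic, df = x$df, p_value = x$p_value,
    significance = significance_tier(x$p_value)
  )
}
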