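#' Detect single-channel spike bursts (max-ISI run method)
#'
#' A burst is a maximal run of consecutive spikes on one electrode in which
#' every interspike interval is at most `max_isi_ms`, with at least
#' `min_spikes` spikes.  Burst start/end are the first/last spike times of
#' the run, so bursts on one electrode never overlap.
#'
#' @param raster A [spike_raster()], or a numeric vector of spike times for
#'   a single train.
#' @param max_isi_ms Maximum in-burst interspike interval (ms, default 100).
#' @param min_spikes Minimum spikes per burst (default 5).
#' @return Tibble: `electrode_id`, `start_s`, `end_s`, `duration_ms`,
#'   `n_spikes`.
#' @export
detect_bursts <- function(raster, max_isi_ms = 100, min_spikes = 5) {
  max_isi_ms <- check_positive(max_isi_ms, "max_isi_ms")
  min_spikes <- check_count(min_spikes, "min_spikes", min = 2L)
  trains <- if (inherits(raster, "spike_raster")) {
    ev <- raster$spikes
    split(ev$time_s, ev$electrode_id)
  } else {
    list(`1` = sort(as.numeric(raster)))
  }
  out <- purrr::imap(trains, function(times, id) {
    b <- burst_runs(times, max_isi_ms / 1000, min_spikes)
    if (nrow(b) == 0) return(NULL)
    b$electrode_id <- as.integer(id)
    b
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble::tibble(electrode_id = integer(), start_s = numeric(),
                          end_s = numeric(), duration_ms = numeric(),
                          n_spikes = integer()))
  }
  res |>
    dplyr::mutate(duration_ms = (.data$end_s - .data$start_s) * 1000) |>
    dplyr::select("electrode_id", "start_s", "end_s", "duration_ms", "n_spikes") |>
    dplyr::arrange(.data$electrode_id, .data$start_s)
}

burst_runs <- function(times, max_isi_s, min_spikes) {
  n <- length(times)
  if (n < min_spikes) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(), n_spikes = integer()))
  }
  ok <- diff(times) <= max_isi_s
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths + 1L >= min_spikes)
  tibble::tibble(
    start_s = times[starts[keep]],
    end_s = times[ends[keep] + 1L],
    n_spikes = r$lengths[keep] + 1L
  )
}

#' Detect population network bursts
#'
#' Population spike counts are binned at `bin_ms`; bins whose count exceeds
#' the mean plus `k` standard deviations of the binned series are burst
#' candidates; candidates separated by at most `merge_gap_ms` are merged
#' into one event; an event is kept when it contains at least `min_bins`
#' candidate bins and recruits at least `min_participation` of the active
#' electrodes (see [active_electrodes()]).  Raising `k` never adds events
#' on a fixed raster.
#'
#' @param raster A [spike_raster()].
#' @param bin_ms Population-rate bin width (ms, default 25).
#' @param k Threshold stringency in SD units (default 3).
#' @param merge_gap_ms Maximum gap between merged candidate bins (ms,
#'   default 100).
#' @param min_participation Minimum fraction of active electrodes with at
#'   least one spike inside the event (default 0.1).
#' @param min_bins Minimum number of candidate bins per event (default 4);
#'   suppresses single-bin excursions of a Poisson baseline.
#' @param active_rate_hz Activity floor defining the active-electrode pool.
#' @return Tibble: `burst_id`, `start_s`, `end_s`, `duration_ms`,
#'   `n_participants`, `peak_rate_hz` (peak binned population rate),
#'   `n_candidate_bins`.
#' @export
detect_network_bursts <- function(raster, bin_ms = 25, k = 3, merge_gap_ms = 100,
                                  min_participation = 0.1, min_bins = 4,
                                  active_rate_hz = 0.02) {
  stopifnot(inherits(raster, "spike_raster"))
  bin_ms <- check_positive(bin_ms, "bin_ms")
  min_participation <- check_fraction(min_participation, "min_participation")
  empty <- tibble::tibble(burst_id = integer(), start_s = numeric(), end_s = numeric(),
                          duration_ms = numeric(), n_participants = integer(),
                          peak_rate_hz = numeric(), n_candidate_bins = integer())
  if (nrow(raster$spikes) == 0) return(empty)

  bin_s <- bin_ms / 1000
  n_bins <- max(1L, ceiling(raster$duration_s / bin_s))
  bin_idx <- pmin(floor(raster$spikes$time_s / bin_s) + 1L, n_bins)
  counts <- tabulate(bin_idx, nbins = n_bins)
  thr <- mean(counts) + k * sd(counts)
  cand <- which(counts > thr)
  if (length(cand) == 0) return(empty)

  gap_bins <- max(1L, floor(merge_gap_ms / bin_ms))
  grp <- cumsum(c(1L, diff(cand) > gap_bins))
  active <- active_electrodes(raster, active_rate_hz)
  min_part_n <- ceiling(min_participation * length(active))

  events <- purrr::map(split(cand, grp), function(bins) {
    start_s <- (min(bins) - 1L) * bin_s
    end_s <- min(max(bins) * bin_s, raster$duration_s)
    if (length(bins) < min_bins) return(NULL)
    sel <- raster$spikes$time_s >= start_s & raster$spikes$time_s <= end_s
    participants <- unique(raster$spikes$electrode_id[sel])
    if (length(intersect(participants, active)) < min_part_n) return(NULL)
    tibble::tibble(
      start_s = start_s, end_s = end_s,
      duration_ms = (end_s - start_s) * 1000,
      n_participants = length(participants),
      peak_rate_hz = max(counts[bins]) / bin_s,
      n_candidate_bins = length(bins)
    )
  })
  res <- dplyr::bind_rows(events)
  if (nrow(res) == 0) return(empty)
  res |>
    dplyr::arrange(.data$start_s) |>
    dplyr::mutate(burst_id = dplyr::row_number()) |>
    dplyr::relocate("burst_id")
}

#' Count, frequency and duration statistics of a burst table
#'
#' Applies equally to single-channel bursts and network bursts: the
#' frequency is `count / (duration_s / 60)` exactly, and durations are
#' summarised in milliseconds.  With no bursts the duration summary is
#' absent (flagged by `has_durations = FALSE`) and the frequency is 0.
#'
#' @param bursts A tibble with a `duration_ms` column (as returned by
#'   [detect_bursts()] or [detect_network_bursts()]).
#' @param duration_s Recording duration in seconds (> 0).
#' @return One-row tibble: `count`, `frequency_per_min`, `mean_duration_ms`,
#'   `has_durations`, plus the [summarize_distribution()] columns of the
#'   durations prefixed `dur_`.
#' @export
burst_stats <- function(bursts, duration_s) {
  duration_s <- check_positive(duration_s, "duration_s")
  count <- nrow(bursts)
  base <- tibble::tibble(
    count = count,
    frequency_per_min = count / (duration_s / 60),
    mean_duration_ms = if (count > 0) mean(bursts$duration_ms) else NA_real_,
    has_durations = count > 0
  )
  if (count > 0) {
    dur <- summarize_distribution(bursts$duration_ms)
    names(dur) <- paste0("dur_", names(dur))
    base <- dplyr::bind_cols(base, dur)
  }
  base
}
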