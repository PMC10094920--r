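#' Centre of activity per time bin
#'
#' The centre of activity (CA) of a bin is the spike-count-weighted centroid
#' of electrode positions, `CA(t) = sum_i n_i(t) p_i / sum_i n_i(t)`, with
#' positions in mm relative to the arena centre (the centroid of the
#' electrode grid).  Bins with no spikes are flagged undefined rather than
#' interpolated.  Homogeneous activity on a symmetric layout places the CA
#' exactly at the origin; localized activity displaces it towards the
#' active region.
#'
#' @param raster A [spike_raster()].
#' @param window Numeric `c(start_s, end_s)` within the recording.
#' @param bin_ms Bin width in ms (default 10).  Full bins only; a trailing
#'   partial bin shorter than `bin_ms` is dropped.
#' @return Tibble: `bin`, `t_s` (bin centre), `n_spikes`, `x_mm`, `y_mm`
#'   (`NA` when `n_spikes` is 0), `defined`.
#' @export
center_of_activity <- function(raster, window, bin_ms = 10) {
  stopifnot(inherits(raster, "spike_raster"))
  bin_ms <- check_positive(bin_ms, "bin_ms")
  if (length(window) != 2 || window[1] < 0 || window[2] > raster$duration_s ||
      window[2] <= window[1]) {
    stop_invalid("`window` must be c(start, end) inside the recording")
  }
  bin_s <- bin_ms / 1000
  n_bins <- floor((window[2] - window[1]) / bin_s + 1e-9)
  if (n_bins < 1) stop_invalid("`window` is shorter than one bin")

  sel <- raster$spikes$time_s >= window[1] &
    raster$spikes$time_s < window[1] + n_bins * bin_s
  ev <- raster$spikes[sel, ]
  bin <- floor((ev$time_s - window[1]) / bin_s) + 1L
  pos <- raster$layout[match(ev$electrode_id, raster$layout$electrode_id), ]
  n <- tabulate(bin, nbins = n_bins)
  sx <- rep(0, n_bins); sy <- rep(0, n_bins)
  if (nrow(ev) > 0) {
    sx_t <- rowsum(pos$x_mm, bin)
    sy_t <- rowsum(pos$y_mm, bin)
    idx <- as.integer(rownames(sx_t))
    sx[idx] <- sx_t[, 1]
    sy[idx] <- sy_t[, 1]
  }
  tibble::tibble(
    bin = seq_len(n_bins),
    t_s = window[1] + (seq_len(n_bins) - 0.5) * bin_s,
    n_spikes = n,
    x_mm = ifelse(n > 0, sx / n, NA_real_),
    y_mm = ifelse(n > 0, sy / n, NA_real_),
    defined = n > 0
  )
}

#' Centre-of-activity trajectory of one network burst
#'
#' The time-ordered sequence of defined CA points across the burst window,
#' summarised by duration (first to last defined point, ms), path length
#' (sum of consecutive CA displacements, mm), mean velocity (path length /
#' duration, mm/s), terminal distance (distance of the last CA point from
#' the arena centre, mm) and dispersion (RMS distance of the CA points from
#' their centroid, mm).  Empty bins are skipped, so velocities use the
#' actual time gaps between defined points.  A trajectory with fewer than
#' two defined points is flagged degenerate and its velocity is undefined.
#'
#' @param raster A [spike_raster()].
#' @param burst One row of [detect_network_bursts()] output (or any list
#'   with `start_s`, `end_s`, optionally `burst_id`).
#' @param bin_ms CA bin width (ms, default 10).
#' @return Object of class `cat_trajectory`: list with `points` (the
#'   [center_of_activity()] tibble) and `summary` (one-row tibble:
#'   `burst_id`, `n_points`, `duration_ms`, `path_length_mm`,
#'   `mean_velocity_mm_s`, `terminal_distance_mm`, `dispersion_mm`,
#'   `degenerate`).
#' @export
compute_cat <- function(raster, burst, bin_ms = 10) {
  ca <- center_of_activity(raster, c(burst$start_s, burst$end_s), bin_ms)
  pts <- ca[ca$defined, ]
  k <- nrow(pts)
  degenerate <- k < 2
  if (k >= 1) {
    terminal <- sqrt(pts$x_mm[k]^2 + pts$y_mm[k]^2)
    cx <- mean(pts$x_mm); cy <- mean(pts$y_mm)
    dispersion <- sqrt(mean((pts$x_mm - cx)^2 + (pts$y_mm - cy)^2))
  } else {
    terminal <- NA_real_
    dispersion <- NA_real_
  }
  if (!degenerate) {
    duration_ms <- (pts$t_s[k] - pts$t_s[1]) * 1000
    path <- sum(sqrt(diff(pts$x_mm)^2 + diff(pts$y_mm)^2))
    velocity <- if (duration_ms > 0) path / (duration_ms / 1000) else 0
  } else {
    duration_ms <- NA_real_
    path <- NA_real_
    velocity <- NA_real_
  }
  structure(
    list(
      points = ca,
      summary = tibble::tibble(
        burst_id = burst$burst_id %||% NA_integer_,
        n_points = k,
        duration_ms = duration_ms,
        path_length_mm = path,
        mean_velocity_mm_s = velocity,
        terminal_distance_mm = terminal,
        dispersion_mm = dispersion,
        degenerate = degenerate
      )
    ),
    class = "cat_trajectory"
  )
}

#' @export
print.cat_trajectory <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<cat_trajectory> %d points, %.0f ms, %.2f mm/s, terminal %.3f mm%s\n",
              s$n_points, s$duration_ms, s$mean_velocity_mm_s,
              s$terminal_distance_mm, if (s$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Trajectories of every network burst in a recording
#'
#' @param raster A [spike_raster()].
#' @param network_bursts Output of [detect_network_bursts()].
#' @param bin_ms CA bin width (ms).
#' @return Tibble of per-burst trajectory summaries (one row per burst).
#' @export
compute_cat_all <- function(raster, network_bursts, bin_ms = 10) {
  if (nrow(network_bursts) == 0) {
    return(compute_cat(raster,
                       list(start_s = 0, end_s = raster$duration_s))$summary[0, ])
  }
  purrr::map(seq_len(nrow(network_bursts)), function(b) {
    compute_cat(raster, network_bursts[b, ], bin_ms)$summary
  }) |> dplyr::bind_rows()
}

#' Condition-level CAT summary
#'
#' Distribution summaries of velocity, duration, terminal distance and
#' dispersion over the non-degenerate trajectories; degenerate trajectories
#' are excluded and `n` reflects the exclusion.
#'
#' @param trajectories Tibble of trajectory summaries ([compute_cat_all()]).
#' @return Tibble with one row per metric: `metric`, `units`, plus the
#'   [summarize_distribution()] columns.
#' @export
cat_summary <- function(trajectories) {
  ok <- trajectories[!trajectories$degenerate, ]
  if (nrow(ok) == 0) stop_no_data("no non-degenerate trajectories to summarise")
  metrics <- c(mean_velocity_mm_s = "mm/s", duration_ms = "ms",
               terminal_distance_mm = "mm", dispersion_mm = "mm")
  purrr::imap(metrics, function(units, col) {
    dplyr::bind_cols(tibble::tibble(metric = col, units = units),
                     summarize_distribution(ok[[col]]))
  }) |> dplyr::bind_rows()
}
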