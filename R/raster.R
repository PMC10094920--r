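#' Construct a spike raster
#'
#' A spike raster bundles the spike-event table of one recording with its
#' electrode layout and duration.  Spike times are stored in seconds, sorted
#' within each electrode, and must lie strictly inside `(0, duration_s)`.
#'
#' @param spikes Data frame with columns `electrode_id`, `time_s`.  May be
#'   empty.  Unsorted input is sorted on construction.
#' @param layout An [make_chip_layout()] layout (or any data frame with
#'   `electrode_id`, `x_mm`, `y_mm`).
#' @param duration_s Recording duration in seconds (> 0).
#' @param meta Named list of free-form metadata (condition, div, seed, ...).
#' @return An object of class `spike_raster`: a list with elements `spikes`
#'   (tibble), `layout`, `duration_s`, `meta`.
#' @export
spike_raster <- function(spikes, layout, duration_s, meta = list()) {
  layout <- as_layout(layout)
  duration_s <- check_positive(duration_s, "duration_s")
  if (is.null(spikes) || nrow(spikes) == 0L) {
    spikes <- tibble::tibble(electrode_id = integer(), time_s = numeric())
  }
  if (!all(c("electrode_id", "time_s") %in% names(spikes))) {
    stop_invalid("`spikes` must have columns electrode_id and time_s")
  }
  spikes <- tibble::as_tibble(spikes[c("electrode_id", "time_s")])
  unknown <- setdiff(unique(spikes$electrode_id), layout$electrode_id)
  if (length(unknown) > 0L) {
    stop_format(sprintf("spike table refers to electrode id(s) not in layout: %s",
                        paste(utils::head(unknown, 5L), collapse = ", ")))
  }
  if (nrow(spikes) > 0L && (min(spikes$time_s) <= 0 || max(spikes$time_s) >= duration_s)) {
    stop_invalid("spike times must lie strictly within (0, duration_s)")
  }
  spikes <- dplyr::arrange(spikes, .data$electrode_id, .data$time_s)
  structure(
    list(spikes = spikes, layout = layout, duration_s = duration_s, meta = meta),
    class = "spike_raster"
  )
}

#' @export
print.spike_raster <- function(x, ...) {
  cat(sprintf("<spike_raster> %d spikes on %d electrodes, %.1f s",
              nrow(x$spikes), nrow(x$layout), x$duration_s))
  if (!is.null(x$meta$condition)) {
    cat(sprintf(" [%s, DIV %s]", x$meta$condition, x$meta$div %||% "?"))
  }
  cat("\n")
  invisible(x)
}

#' Spike events of a raster as a tibble
#' @param raster A `spike_raster`.
#' @return Tibble with `electrode_id`, `time_s`.
#' @export
spike_events <- function(raster) {
  stopifnot(inherits(raster, "spike_raster"))
  raster$spikes
}

#' Per-electrode spike trains
#'
#' @param raster A `spike_raster`.
#' @param electrode_ids Electrodes to extract (default: all in the layout,
#'   silent ones included as empty vectors).
#' @return Named list of sorted numeric vectors of spike times (s).
#' @export
spike_trains <- function(raster, electrode_ids = NULL) {
  stopifnot(inherits(raster, "spike_raster"))
  ids <- electrode_ids %||% raster$layout$electrode_id
  found <- split(raster$spikes$time_s, factor(raster$spikes$electrode_id, levels = ids))
  lapply(found, as.numeric)
}

#' Active electrodes of a recording
#'
#' An electrode is considered active when its mean firing rate over the whole
#' recording reaches `min_rate_hz` (default 0.02 spikes/s, i.e. at least 6
#' spikes in 5 minutes).  Participation fractions of network-burst detection
#' and the node set of connectivity inference are defined over active
#' electrodes so that sparse early recordings are not dominated by silent
#' channels.
#'
#' @inheritParams spike_trains
#' @param min_rate_hz Minimum mean firing rate (spikes/s).
#' @return Integer vector of electrode ids.
#' @export
active_electrodes <- function(raster, min_rate_hz = 0.02) {
  stopifnot(inherits(raster, "spike_raster"))
  counts <- table(raster$spikes$electrode_id)
  ids <- as.integer(names(counts)[as.numeric(counts) / raster$duration_s >= min_rate_hz])
  sort(ids)
}
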