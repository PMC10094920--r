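#' Read and write spike rasters, layouts, graphs and metrics tables
#'
#' All formats are line-oriented tab-separated text with a header row, so
#' files diff cleanly and round-trip exactly at the 0.1 ms acquisition
#' resolution (times are written in seconds with six decimals).  Raster
#' files carry the recording duration on a leading `#` metadata line.
#'
#' @param raster A [spike_raster()].
#' @param path File path.
#' @name raster_io
NULL

#' @rdname raster_io
#' @export
write_raster <- function(raster, path) {
  stopifnot(inherits(raster, "spike_raster"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# duration_s=%.6f", raster$duration_s), con)
  writeLines("electrode_id\ttime_s", con)
  if (nrow(raster$spikes) > 0) {
    writeLines(sprintf("%d\t%.6f", raster$spikes$electrode_id, raster$spikes$time_s), con)
  }
  invisible(path)
}

#' @rdname raster_io
#' @param layout Electrode layout the events must belong to.
#' @param duration_s Recording duration; taken from the file's metadata line
#'   when `NULL`.
#' @return `read_raster()` returns a [spike_raster()]; unsorted rows are
#'   sorted on load, and an event naming an electrode outside the layout is
#'   a format error reporting the offending line.
#' @export
read_raster <- function(path, layout, duration_s = NULL) {
  layout <- as_layout(layout)
  first <- readLines(path, n = 1L)
  if (is.null(duration_s)) {
    m <- regmatches(first, regexec("^#\\s*duration_s=([0-9.eE+-]+)", first))[[1]]
    if (length(m) < 2) {
      stop_format(sprintf("%s: missing '# duration_s=' metadata line and no duration_s given", path))
    }
    duration_s <- as.numeric(m[2])
  }
  tbl <- suppressWarnings(
    readr::read_tsv(path, comment = "#", show_col_types = FALSE, progress = FALSE,
                    col_types = readr::cols(electrode_id = readr::col_integer(),
                                            time_s = readr::col_double())))
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop_format(sprintf("%s: malformed row at line %d", path, prob$row[1] + 2L))
  }
  bad <- which(!tbl$electrode_id %in% layout$electrode_id)
  if (length(bad) > 0) {
    stop_format(sprintf("%s: line %d names electrode id %d which is not in the layout",
                        path, bad[1] + 2L, tbl$electrode_id[bad[1]]))
  }
  spike_raster(tbl, layout, duration_s, meta = list(source = path))
}

#' @rdname raster_io
#' @export
write_layout <- function(layout, path) {
  layout <- as_layout(layout)
  readr::write_tsv(tibble::as_tibble(as.data.frame(layout)), path, progress = FALSE)
  invisible(path)
}

#' @rdname raster_io
#' @export
read_layout <- function(path) {
  tbl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  out <- as_layout(tbl)
  class(out) <- c("mea_layout", class(tbl))
  out
}

#' Write / read a graph edge list
#'
#' Delimited `(source, target, weight)` rows; extra columns (lag, mutual
#' flag) are preserved.  The directed edge set round-trips exactly.
#'
#' @param edges Data frame with columns `from`, `to` and optionally `weight`
#'   and further edge attributes.
#' @param path File path.
#' @export
write_graph_edgelist <- function(edges, path) {
  if (!all(c("from", "to") %in% names(edges))) {
    stop_invalid("`edges` must have columns from and to")
  }
  out <- tibble::as_tibble(edges)
  if (!"weight" %in% names(out)) out$weight <- rep(1, nrow(out))
  out <- dplyr::relocate(out, "from", "to", "weight")
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_graph_edgelist
#' @export
read_graph_edgelist <- function(path) {
  tbl <- suppressWarnings(readr::read_tsv(path, show_col_types = FALSE, progress = FALSE))
  prob <- readr::problems(tbl)
  if (nrow(prob) > 0) {
    stop_format(sprintf("%s: malformed row at line %d", path, prob$row[1] + 1L))
  }
  if (!all(c("from", "to", "weight") %in% names(tbl))) {
    stop_format(sprintf("%s: expected columns from, to, weight", path))
  }
  if (nrow(tbl) > 0 && (anyNA(tbl$from) || anyNA(tbl$to) || anyNA(tbl$weight))) {
    stop_format(sprintf("%s: malformed row at line %d", path,
                        which(is.na(tbl$from) | is.na(tbl$to) | is.na(tbl$weight))[1] + 1L))
  }
  tbl
}

#' Write a long metrics table
#'
#' One row per `(condition, div, metric)` with value, units and sample size;
#' the stable column order and full-precision numeric formatting make runs
#' diff-able.
#'
#' @param records Tibble with columns `condition`, `div`, `metric`, `value`,
#'   `units`, `n` (additional columns are appended after these).
#' @param path File path.
#' @export
write_metrics_table <- function(records, path) {
  required <- c("condition", "div", "metric", "value", "units", "n")
  if (nrow(records) > 0 && !all(required %in% names(records))) {
    stop_invalid(sprintf("metrics records must share the schema: %s",
                         paste(required, collapse = ", ")))
  }
  if (nrow(records) == 0) {
    records <- tibble::as_tibble(setNames(
      lapply(required, function(x) logical(0)), required))
  }
  out <- dplyr::relocate(tibble::as_tibble(records), dplyr::all_of(required))
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
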