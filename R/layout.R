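#' Build a rectangular electrode-grid layout
#'
#' Electrode coordinates are expressed in millimetres relative to the centre
#' of the arena, defined as the centroid of the grid, so a symmetric layout
#' has mean position exactly (0, 0).  The full CMOS chip modelled here is a
#' 64 x 64 grid (4096 electrodes) at 42 um pitch; a 10 x 10 grid is used as
#' the desk-scale default throughout the examples and the packaged demo.
#'
#' @param n_rows,n_cols Number of grid rows / columns (>= 1).
#' @param pitch_mm Centre-to-centre electrode spacing in mm (default 0.042).
#' @return A tibble of class `mea_layout` with columns `electrode_id`, `row`,
#'   `col`, `x_mm`, `y_mm`, and attributes `n_rows`, `n_cols`, `pitch_mm`.
#'   Electrodes are numbered row-major starting at 1.
#' @examples
#' chip <- make_chip_layout(64, 64, 0.042)
#' nrow(chip) # 4096
#' @export
make_chip_layout <- function(n_rows, n_cols, pitch_mm = 0.042) {
  n_rows <- check_count(n_rows, "n_rows")
  n_cols <- check_count(n_cols, "n_cols")
  pitch_mm <- check_positive(pitch_mm, "pitch_mm")

  row <- rep(seq_len(n_rows), each = n_cols)
  col <- rep(seq_len(n_cols), times = n_rows)
  out <- tibble::tibble(
    electrode_id = seq_len(n_rows * n_cols),
    row = row,
    col = col,
    x_mm = (col - (n_cols + 1) / 2) * pitch_mm,
    y_mm = (row - (n_rows + 1) / 2) * pitch_mm
  )
  attr(out, "n_rows") <- n_rows
  attr(out, "n_cols") <- n_cols
  attr(out, "pitch_mm") <- pitch_mm
  class(out) <- c("mea_layout", class(out))
  out
}

as_layout <- function(layout) {
  required <- c("electrode_id", "x_mm", "y_mm")
  if (!is.data.frame(layout) || !all(required %in% names(layout))) {
    stop_invalid("`layout` must be a data frame with columns electrode_id, x_mm, y_mm")
  }
  if (anyDuplicated(layout$electrode_id)) {
    stop_invalid("layout electrode ids must be unique")
  }
  layout
}

# half-extent of the layout (max |coordinate|), used to express spatial
# profile widths on a scale-free basis
layout_half_extent <- function(layout) {
  max(abs(c(layout$x_mm, layout$y_mm)), 1e-12)
}
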