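#' Path to the packaged phenotype configuration
#'
#' The default generator parameters for both culture phenotypes across DIVs
#' 1-16 live in a documented YAML file shipped with the package; see the
#' methods vignette for the rationale behind each value.
#'
#' @return Path to `phenotypes.yaml`.
#' @export
default_phenotype_config <- function() {
  system.file("extdata", "phenotypes.yaml", package = "hdmeanet", mustWork = TRUE)
}

phenotype_columns <- c(
  "condition", "div", "base_rate_hz", "rate_dispersion", "n_network_bursts",
  "burst_participation", "within_burst_rate_hz", "burst_duration_mean_ms",
  "burst_duration_rel_sd", "spatial_profile", "spatial_center_x_rel",
  "spatial_center_y_rel", "spatial_width_rel", "graph_type", "mean_degree",
  "rewiring_prob", "inter_module_edges", "module_alternation_ms",
  "propagation_delay_ms"
)

#' Phenotype schedule for one culture condition
#'
#' Returns the generator parameters for every recorded day in vitro (DIVs 1,
#' 4, 7, 10, 13 and 16) of one condition.  With the packaged defaults the
#' control baseline rate rises strictly with age and its firing becomes
#' spatially homogeneous from DIV7, while the abeta42 baseline rises until
#' DIV10 and then declines and its firing stays localized in an off-centre
#' hotspot at every age; control network-burst counts grow from 0 to 55 per
#' 5-minute recording, abeta42 counts stay at 25.
#'
#' @param condition `"control"` or `"abeta42"`.
#' @param config Path to a YAML configuration (defaults to the packaged one).
#' @return A tibble with one row per DIV; see the packaged YAML for units.
#' @export
phenotype_schedule <- function(condition = c("control", "abeta42"),
                               config = default_phenotype_config()) {
  if (length(condition) != 1L && !identical(condition, c("control", "abeta42"))) {
    condition <- condition[1]
  }
  condition <- tryCatch(match.arg(condition, c("control", "abeta42")),
                        error = function(e) stop_invalid(
                          sprintf("unknown condition %s", deparse(condition))))
  cfg <- yaml::read_yaml(config)
  if (is.null(cfg[[condition]])) {
    stop_invalid(sprintf("condition '%s' not present in config %s", condition, config))
  }
  section <- cfg[[condition]]
  shared <- section[setdiff(names(section), "divs")]
  rows <- purrr::map(section$divs, function(d) {
    row <- c(list(condition = condition), shared, d)
    tibble::as_tibble(row[!vapply(row, is.null, logical(1))])
  })
  out <- dplyr::bind_rows(rows)
  for (col in phenotype_columns) {
    if (!col %in% names(out)) out[[col]] <- NA
  }
  out <- out[phenotype_columns]
  validate_phenotype_rows(out)
  dplyr::arrange(out, .data$div)
}

validate_phenotype_rows <- function(tbl) {
  bad_rate <- !is.na(tbl$base_rate_hz) & tbl$base_rate_hz < 0
  if (any(bad_rate) || any(tbl$within_burst_rate_hz < 0, na.rm = TRUE)) {
    stop_invalid("phenotype rates must be >= 0")
  }
  if (any(tbl$n_network_bursts < 0, na.rm = TRUE)) {
    stop_invalid("n_network_bursts must be >= 0")
  }
  part <- tbl$burst_participation
  if (any(!is.na(part) & (part < 0 | part > 1))) {
    stop_invalid("burst_participation must lie in [0, 1]")
  }
  invisible(tbl)
}

# normalise a one-row tibble / list phenotype config into a plain list
as_phenotype_cfg <- function(cfg) {
  if (is.data.frame(cfg)) {
    if (nrow(cfg) != 1L) stop_invalid("`cfg` must be a single phenotype row")
    cfg <- as.list(cfg)
  }
  if (!is.list(cfg)) stop_invalid("`cfg` must be a list or one-row data frame")
  cfg
}
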