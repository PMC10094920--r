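# internal argument checks; all user-facing errors carry class "hdmeanet_error"
# so callers can distinguish contract violations from R-level failures.

stop_invalid <- function(msg, class = "hdmeanet_invalid_argument") {
  rlang::abort(msg, class = c(class, "hdmeanet_error"))
}

stop_no_data <- function(msg) {
  rlang::abort(msg, class = c("hdmeanet_no_data", "hdmeanet_error"))
}

stop_format <- function(msg) {
  rlang::abort(msg, class = c("hdmeanet_format_error", "hdmeanet_error"))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    stop_invalid(sprintf("`%s` must be a single integer >= %d, got %s",
                         name, min, deparse(substitute(x, environment()))[1]))
  }
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x <= 0) {
    stop_invalid(sprintf("`%s` must be a single positive number", name))
  }
  as.numeric(x)
}

check_fraction <- function(x, name, allow_zero = FALSE) {
  lo_ok <- if (allow_zero) x >= 0 else x > 0
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || !lo_ok || x > 1) {
    stop_invalid(sprintf("`%s` must be in (0, 1]", name))
  }
  as.numeric(x)
}

# round-half-away-from-zero, matching C++ std::lround; used for lag-bin
# indices and counts so R and compiled code agree on bin layout
lround <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

lag_bin_index <- function(d, bin) {
  lround(d / bin)
}

#' Significance tier used in reports
#'
#' Maps a p-value to the significance tiers used throughout the package's
#' comparison tables: `***` for p < 0.005, `**` for p < 0.01, `*` for p < 0.05,
#' `ns` otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of tiers.
#' @export
significance_tier <- function(p) {
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.005 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "ns"
  )
}
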