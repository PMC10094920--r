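#' Default configuration of the two-condition DIV-series experiment
#'
#' The packaged demo: both conditions at DIVs 1-16 on a desk-scale 10 x 10
#' grid (42 um pitch), 5-minute recordings, all analysis stages at their
#' default parameters.  Every entry can be overridden by passing a modified
#' copy to [run_experiment()].
#'
#' @return Named list of configuration entries.
#' @export
demo_config <- function() {
  list(
    conditions = c("control", "abeta42"),
    divs = c(1, 4, 7, 10, 13, 16),
    n_rows = 10, n_cols = 10, pitch_mm = 0.042,
    duration_s = 300,
    seed = 20230402,
    infer_connectivity = TRUE,
    phenotype_config = default_phenotype_config(),
    active_rate_hz = 0.02,
    burst = list(max_isi_ms = 100, min_spikes = 5),
    network_burst = list(bin_ms = 25, k = 3, merge_gap_ms = 100,
                         min_participation = 0.1, min_bins = 4),
    connectivity = list(bin_ms = 2, max_lag_ms = 25, n_surrogates = 20,
                        jitter_ms = 25, c = 4),
    cat = list(bin_ms = 10)
  )
}

validate_run_config <- function(config) {
  known <- names(demo_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0) {
    stop_invalid(sprintf("unknown configuration key(s): %s",
                         paste(unknown, collapse = ", ")))
  }
  merged <- utils::modifyList(demo_config(), config)
  check_positive(merged$duration_s, "duration_s")
  check_count(merged$n_rows, "n_rows")
  check_count(merged$n_cols, "n_cols")
  bad <- setdiff(merged$conditions, c("control", "abeta42"))
  if (length(bad) > 0) stop_invalid(sprintf("unknown condition(s): %s",
                                            paste(bad, collapse = ", ")))
  merged
}

cell_seed <- function(config, condition, div) {
  as.integer(config$seed + 131L * as.integer(div) +
               7919L * match(condition, c("control", "abeta42")))
}

#' Run the full DIV-series, two-condition experiment
#'
#' Simulates (with ground truth) a recording for every condition x DIV cell,
#' runs every analysis stage -- firing-rate map, ISI statistics, spike-burst
#' and network-burst detection, centre-of-activity trajectories, optional
#' connectivity inference, and graph metrics of both the inferred and the
#' ground-truth graph -- and collects a long metrics table plus
#' cross-condition Welch tests per metric per DIV.  Deterministic given
#' `config$seed`; a failing cell is recorded with its reason and the run
#' continues.  Progress is logged to stderr; results go only to the return
#' value and to `out_dir` files.
#'
#' @param config Configuration list; entries override [demo_config()].
#' @param out_dir Optional output directory: writes `metrics.tsv`,
#'   `comparisons.tsv`, `network_bursts.tsv`, `trajectories.tsv`, inferred
#'   graph edge lists under `graphs/`, and a `manifest.yaml` with the full
#'   configuration, package version and per-cell seeds.
#' @param quiet Suppress progress messages.
#' @return Object of class `div_series_result`: list with `metrics` (long
#'   tibble), `comparisons` (Welch-test tibble), `cells` (per-cell results
#'   and samples) and `config`.
#' @export
run_experiment <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  config <- validate_run_config(config)
  layout <- make_chip_layout(config$n_rows, config$n_cols, config$pitch_mm)
  say <- function(...) if (!quiet) message(sprintf(...))

  cells <- list()
  for (condition in config$conditions) {
    sched <- phenotype_schedule(condition, config$phenotype_config)
    for (div in config$divs) {
      key <- sprintf("%s_div%02d", condition, div)
      seed <- cell_seed(config, condition, div)
      t0 <- Sys.time()
      cells[[key]] <- tryCatch({
        cfg <- sched[sched$div == div, ]
        if (nrow(cfg) != 1) stop_invalid(sprintf("no phenotype entry for DIV %s", div))
        sim <- simulate_recording(cfg, layout, config$duration_s, seed)
        cell <- analyze_cell(sim$raster, sim$ground_truth, config, seed)
        cell$condition <- condition
        cell$div <- div
        cell$seed <- seed
        say("[%s] done in %.1f s (%d spikes, %d network bursts)", key,
            as.numeric(difftime(Sys.time(), t0, units = "secs")),
            nrow(sim$raster$spikes), nrow(cell$network_bursts))
        cell
      }, error = function(e) {
        say("[%s] FAILED: %s", key, conditionMessage(e))
        list(failed = TRUE, reason = conditionMessage(e),
             condition = condition, div = div, seed = seed)
      })
    }
  }

  metrics <- purrr::map(cells, function(cell) {
    if (isTRUE(cell$failed)) return(NULL)
    dplyr::mutate(cell$metrics, condition = cell$condition, div = cell$div,
                  .before = 1)
  }) |> dplyr::bind_rows()

  result <- structure(
    list(metrics = metrics, comparisons = NULL, cells = cells, config = config),
    class = "div_series_result"
  )
  result$comparisons <- compare_conditions(result)

  if (!is.null(out_dir)) write_experiment(result, out_dir)
  result
}

# all analysis stages for one simulated (or loaded) recording
analyze_cell <- function(raster, ground_truth, config, seed) {
  dur <- raster$duration_s
  mfr <- mean_firing_rate(raster)
  isi <- interspike_intervals(raster)
  isi_by_el <- isi |>
    dplyr::group_by(.data$electrode_id) |>
    dplyr::summarise(mean_isi_ms = mean(.data$isi_ms), .groups = "drop")

  bursts <- detect_bursts(raster, config$burst$max_isi_ms, config$burst$min_spikes)
  bstats <- burst_stats(bursts, dur)
  nb <- do.call(detect_network_bursts,
                c(list(raster = raster), config$network_burst,
                  list(active_rate_hz = config$active_rate_hz)))
  nbstats <- burst_stats(nb, dur)
  trajectories <- compute_cat_all(raster, nb, config$cat$bin_ms)
  traj_ok <- trajectories[!trajectories$degenerate, ]

  row <- function(metric, value, units, n) {
    tibble::tibble(metric = metric, value = as.numeric(value), units = units,
                   n = as.integer(n))
  }
  metrics <- list(
    row("mfr_mean", mean(mfr$mfr_hz), "spikes/s", nrow(mfr)),
    row("mfr_median", median(mfr$mfr_hz), "spikes/s", nrow(mfr)),
    row("isi_mean", if (nrow(isi)) mean(isi$isi_ms) else NA, "ms", nrow(isi)),
    row("n_spike_bursts", bstats$count, "bursts", bstats$count),
    row("spike_burst_frequency", bstats$frequency_per_min, "bursts/min", bstats$count),
    row("spike_burst_duration", bstats$mean_duration_ms, "ms", bstats$count),
    row("n_network_bursts", nbstats$count, "network bursts", nbstats$count),
    row("network_burst_frequency", nbstats$frequency_per_min, "bursts/min", nbstats$count),
    row("network_burst_duration", nbstats$mean_duration_ms, "ms", nbstats$count),
    row("cat_velocity", mean(traj_ok$mean_velocity_mm_s), "mm/s", nrow(traj_ok)),
    row("cat_duration", mean(traj_ok$duration_ms), "ms", nrow(traj_ok)),
    row("cat_terminal_distance", mean(traj_ok$terminal_distance_mm), "mm", nrow(traj_ok)),
    row("cat_dispersion", mean(traj_ok$dispersion_mm), "mm", nrow(traj_ok))
  )

  graph_truth_metrics <- NULL
  if (!is.null(ground_truth)) {
    gm <- graph_metrics(ground_truth$graph)
    g <- glance(gm)
    metrics <- c(metrics, list(
      row("avg_cc_truth", g$avg_cc, "unitless", g$n_nodes),
      row("network_pl_truth", g$network_pl, "links", g$n_nodes),
      row("nd_mean_truth", g$nd_mean, "links", g$n_nodes)
    ))
    graph_truth_metrics <- gm
  }

  graph <- NULL
  graph_inferred_metrics <- NULL
  if (isTRUE(config$infer_connectivity)) {
    graph <- do.call(infer_graph,
                     c(list(raster = raster), config$connectivity,
                       list(active_rate_hz = config$active_rate_hz,
                            seed = seed + 1L)))
    metrics <- c(metrics, list(row("n_edges_inferred", nrow(graph$edges),
                                   "edges", nrow(graph$nodes))))
    if (nrow(graph$edges) > 0) {
      gm <- graph_metrics(graph)
      g <- glance(gm)
      metrics <- c(metrics, list(
        row("avg_cc_inferred", g$avg_cc, "unitless", g$n_nodes),
        row("network_pl_inferred", g$network_pl, "links", g$n_nodes),
        row("nd_mean_inferred", g$nd_mean, "links", g$n_nodes)
      ))
      graph_inferred_metrics <- gm
    }
  }

  samples <- list(
    mfr = mfr$mfr_hz,
    isi_mean_by_electrode = isi_by_el$mean_isi_ms,
    spike_burst_duration = bursts$duration_ms,
    network_burst_duration = nb$duration_ms,
    cat_velocity = traj_ok$mean_velocity_mm_s,
    cat_duration = traj_ok$duration_ms,
    cat_terminal_distance = traj_ok$terminal_distance_mm
  )
  list(
    failed = FALSE,
    metrics = dplyr::bind_rows(metrics),
    samples = samples,
    mfr = mfr,
    bursts = bursts,
    network_bursts = nb,
    trajectories = trajectories,
    graph = graph,
    graph_truth_metrics = graph_truth_metrics,
    graph_inferred_metrics = graph_inferred_metrics,
    ground_truth = ground_truth
  )
}

#' Cross-condition Welch tests per metric per DIV
#'
#' Compares the two conditions at each DIV with unpaired two-tailed Welch
#' t-tests on the per-unit samples collected by [run_experiment()]
#' (electrodes for firing-rate and ISI metrics, bursts for duration
#' metrics, trajectories for CAT metrics).  No multiple-testing correction
#' is applied by default; `p_adjust = "BH"` applies Benjamini-Hochberg
#' across the table.
#'
#' @param result A `div_series_result`.
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble: `div`, `metric`, group means and ns, `statistic`, `df`,
#'   `p_value`, `significance`.
#' @export
compare_conditions <- function(result, p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  cells <- result$cells
  conditions <- result$config$conditions
  if (length(conditions) < 2) return(tibble::tibble())
  divs <- result$config$divs
  rows <- list()
  for (div in divs) {
    a <- cells[[sprintf("%s_div%02d", conditions[1], div)]]
    b <- cells[[sprintf("%s_div%02d", conditions[2], div)]]
    if (is.null(a) || is.null(b) || isTRUE(a$failed) || isTRUE(b$failed)) {
      rlang::warn(sprintf("DIV %d skipped: missing or failed condition", div))
      next
    }
    for (metric in union(names(a$samples), names(b$samples))) {
      xa <- a$samples[[metric]]
      xb <- b$samples[[metric]]
      xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
      if (length(xa) < 2 || length(xb) < 2) next
      wt <- tryCatch(welch_t_test(xa, xb, conditions[1], conditions[2]),
                     hdmeanet_error = function(e) NULL)
      if (is.null(wt)) next
      rows[[length(rows) + 1L]] <- dplyr::mutate(tidy(wt), div = div,
                                                 metric = metric, .before = 1)
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0 && p_adjust == "BH") {
    out$p_adjusted <- stats::p.adjust(out$p_value, "BH")
    out$significance <- significance_tier(out$p_adjusted)
  }
  out
}

write_experiment <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "graphs"), showWarnings = FALSE)
  write_metrics_table(result$metrics, file.path(out_dir, "metrics.tsv"))
  readr::write_tsv(result$comparisons, file.path(out_dir, "comparisons.tsv"),
                   progress = FALSE)
  nb_all <- purrr::map(result$cells, function(cell) {
    if (isTRUE(cell$failed) || nrow(cell$network_bursts) == 0) return(NULL)
    dplyr::mutate(cell$network_bursts, condition = cell$condition,
                  div = cell$div, .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_tsv(nb_all, file.path(out_dir, "network_bursts.tsv"), progress = FALSE)
  traj_all <- purrr::map(result$cells, function(cell) {
    if (isTRUE(cell$failed) || nrow(cell$trajectories) == 0) return(NULL)
    dplyr::mutate(cell$trajectories, condition = cell$condition,
                  div = cell$div, .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_tsv(traj_all, file.path(out_dir, "trajectories.tsv"), progress = FALSE)
  for (key in names(result$cells)) {
    cell <- result$cells[[key]]
    if (isTRUE(cell$failed) || is.null(cell$graph)) next
    write_graph_edgelist(cell$graph$edges,
                         file.path(out_dir, "graphs", paste0(key, "_inferred.tsv")))
  }
  manifest <- list(
    package = "hdmeanet",
    version = as.character(utils::packageVersion("hdmeanet")),
    config = lapply(result$config, function(x) if (is.list(x)) x else as.vector(x)),
    cell_seeds = lapply(result$cells, function(cell) cell$seed),
    failed_cells = names(result$cells)[vapply(result$cells,
                                              function(cell) isTRUE(cell$failed),
                                              logical(1))]
  )
  yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(out_dir)
}

#' @export
print.div_series_result <- function(x, ...) {
  ok <- vapply(x$cells, function(cell) !isTRUE(cell$failed), logical(1))
  cat(sprintf("<div_series_result> %d/%d cells analysed, %d metric rows\n",
              sum(ok), length(ok), nrow(x$metrics)))
  invisible(x)
}

#' @rdname run_experiment
#' @param x A `div_series_result`.
#' @param ... Unused.
#' @export
tidy.div_series_result <- function(x, ...) x$metrics

#' @rdname run_experiment
#' @export
glance.div_series_result <- function(x, ...) {
  ok <- vapply(x$cells, function(cell) !isTRUE(cell$failed), logical(1))
  tibble::tibble(
    n_cells = length(x$cells),
    n_failed = sum(!ok),
    n_metrics = nrow(x$metrics),
    n_comparisons = if (is.null(x$comparisons)) 0L else nrow(x$comparisons),
    seed = x$config$seed
  )
}
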