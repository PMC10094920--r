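#' Spatial activation-weight map
#'
#' Per-electrode multiplicative weights with mean exactly 1.  `homogeneous`
#' gives every electrode weight 1; `localized` weights electrodes by an
#' isotropic Gaussian centred on the hotspot, so a narrow hotspot yields a
#' high-variance weight map (inhomogeneous firing).
#'
#' @param layout Electrode layout.
#' @param profile `"homogeneous"` or `"localized"`.
#' @param center_x_rel,center_y_rel Hotspot centre as a fraction of the
#'   layout half-extent.
#' @param width_rel Hotspot standard deviation as a fraction of the layout
#'   half-extent.
#' @return Tibble `electrode_id`, `weight` (mean 1).
#' @export
spatial_weights <- function(layout, profile = c("homogeneous", "localized"),
                            center_x_rel = 0, center_y_rel = 0, width_rel = 0.3) {
  layout <- as_layout(layout)
  profile <- match.arg(profile)
  if (profile == "homogeneous") {
    w <- rep(1, nrow(layout))
  } else {
    half <- layout_half_extent(layout)
    sigma <- check_positive(width_rel, "width_rel") * half
    d2 <- (layout$x_mm - center_x_rel * half)^2 + (layout$y_mm - center_y_rel * half)^2
    w <- exp(-d2 / (2 * sigma^2))
    w <- w / mean(w)
  }
  tibble::tibble(electrode_id = layout$electrode_id, weight = w)
}

#' Homogeneous Poisson raster
#'
#' Independent homogeneous Poisson spike trains at a common rate on every
#' electrode of the layout; the building block of the baseline model and of
#' the ISI calibration experiments.
#'
#' @param layout Electrode layout.
#' @param rate_hz Firing rate per electrode (spikes/s, >= 0).
#' @param duration_s Recording duration (s).
#' @param seed Integer seed.
#' @return A [spike_raster()].
#' @export
simulate_poisson_raster <- function(layout, rate_hz, duration_s = 300, seed = 1L) {
  layout <- as_layout(layout)
  duration_s <- check_positive(duration_s, "duration_s")
  if (rate_hz < 0) stop_invalid("`rate_hz` must be >= 0")
  spikes <- withr::with_seed(as.integer(seed), {
    counts <- rpois(nrow(layout), rate_hz * duration_s)
    tibble::tibble(
      electrode_id = rep(layout$electrode_id, counts),
      time_s = runif(sum(counts), 0, duration_s)
    )
  })
  spikes <- clip_times(spikes, duration_s)
  spike_raster(spikes, layout, duration_s,
               meta = list(kind = "poisson", rate_hz = rate_hz, seed = seed))
}

# keep spike times strictly inside the recording and representable at the
# 0.1 ms acquisition ceiling
clip_times <- function(spikes, duration_s) {
  dplyr::filter(spikes, .data$time_s > 1e-4, .data$time_s < duration_s - 1e-4)
}

#' Simulate one recording of a phenotype
#'
#' Forward model of a 5-minute recording: each electrode fires baseline
#' Poisson spikes at `base_rate_hz` scaled by the spatial weight map and a
#' per-electrode gamma dispersion multiplier; on top of the baseline,
#' `n_network_bursts` non-overlapping network-burst windows are placed in
#' which the recruited electrodes emit a 3-spike volley time-locked to their
#' onset (staggered along ground-truth graph hops by `propagation_delay_ms`)
#' followed by Poisson firing at `within_burst_rate_hz` until the window
#' ends.  Control recruitment is a breadth-first ball grown from one seeded
#' origin on the small-world graph.  abeta42 recruitment is fragmented: the
#' module nearest the spatial hotspot and the most distal module fire in
#' alternation (`module_alternation_ms` blocks), emulating the localized,
#' disoriented population events of the perturbed phenotype.  The latent
#' ground truth (graph, burst
#' windows, rates, weights, recruitment order) is returned alongside the
#' raster so every downstream analysis has a recoverable target.
#'
#' @param cfg One row of [phenotype_schedule()] (or an equivalent list).
#' @param layout Electrode layout.
#' @param duration_s Recording duration in seconds (default 300, the
#'   recording length modelled throughout).
#' @param seed Integer seed; identical `(cfg, layout, duration_s, seed)`
#'   yields a bit-identical raster.
#' @return List with elements `raster` (a [spike_raster()]) and
#'   `ground_truth` (list: `graph`, `windows`, `rates`, `weights`,
#'   `recruitment`).
#' @export
simulate_recording <- function(cfg, layout, duration_s = 300, seed = 1L) {
  cfg <- as_phenotype_cfg(cfg)
  layout <- as_layout(layout)
  duration_s <- check_positive(duration_s, "duration_s")
  seed <- as.integer(seed)
  n <- nrow(layout)

  graph <- generate_ground_truth_graph(cfg, layout, seed = seed + 1L)

  out <- withr::with_seed(seed, {
    weights <- spatial_weights(
      layout,
      profile = cfg$spatial_profile %||% "homogeneous",
      center_x_rel = cfg$spatial_center_x_rel %||% 0,
      center_y_rel = cfg$spatial_center_y_rel %||% 0,
      width_rel = cfg$spatial_width_rel %||% 0.3
    )
    disp <- cfg$rate_dispersion %||% 0
    g <- if (!is.na(disp) && disp > 0) {
      rgamma(n, shape = 1 / disp^2, rate = 1 / disp^2)
    } else {
      rep(1, n)
    }
    rates <- (cfg$base_rate_hz %||% 0) * weights$weight * g

    n_bursts <- as.integer(cfg$n_network_bursts %||% 0)
    windows <- place_burst_windows(
      n_bursts, duration_s,
      dur_mean_s = (cfg$burst_duration_mean_ms %||% 300) / 1000,
      dur_rel_sd = cfg$burst_duration_rel_sd %||% 0.08
    )
    recruitment <- burst_recruitment(cfg, graph, layout)

    # baseline spikes
    counts <- rpois(n, rates * duration_s)
    base_spikes <- tibble::tibble(
      electrode_id = rep(layout$electrode_id, counts),
      time_s = runif(sum(counts), 0, duration_s)
    )

    burst_spikes <- list()
    if (n_bursts > 0 && nrow(recruitment) > 0) {
      locked <- c(0, 3, 6) / 1000  # onset volley offsets (s)
      wb_rate <- cfg$within_burst_rate_hz %||% 50
      alt_s <- (cfg$module_alternation_ms %||% NA) / 1000
      n_groups <- max(recruitment$group)
      for (b in seq_len(n_bursts)) {
        w0 <- windows$start_s[b]
        w1 <- windows$end_s[b]
        for (e in seq_len(nrow(recruitment))) {
          iv <- active_intervals(w0, w1, recruitment$group[e], n_groups, alt_s)
          if (nrow(iv) == 0) next
          onset <- iv$start[1] + recruitment$onset_ms[e] / 1000
          if (onset >= iv$end[1]) next
          iv$start[1] <- onset
          lock <- onset + locked
          lock <- lock[lock < iv$end[1]]
          spans <- iv$end - iv$start
          n_extra <- rpois(nrow(iv), wb_rate * spans)
          times <- c(lock, runif(sum(n_extra),
                                 rep(iv$start, n_extra), rep(iv$end, n_extra)))
          burst_spikes[[length(burst_spikes) + 1L]] <- tibble::tibble(
            electrode_id = recruitment$electrode_id[e], time_s = times
          )
        }
      }
    }
    spikes <- dplyr::bind_rows(base_spikes, dplyr::bind_rows(burst_spikes))
    spikes <- clip_times(spikes, duration_s)
    list(spikes = spikes, weights = weights, rates = rates,
         windows = windows, recruitment = recruitment)
  })

  raster <- spike_raster(
    out$spikes, layout, duration_s,
    meta = list(condition = cfg$condition %||% NA_character_,
                div = cfg$div %||% NA_integer_, seed = seed)
  )
  ground_truth <- list(
    graph = graph,
    windows = out$windows,
    rates = tibble::tibble(electrode_id = layout$electrode_id, rate_hz = out$rates),
    weights = out$weights,
    recruitment = out$recruitment
  )
  list(raster = raster, ground_truth = ground_truth)
}

# non-overlapping window placement with guaranteed success when the windows
# fit: minimum 0.5 s separation, 1 s margins, remaining slack distributed as
# random extra gaps (stick breaking)
place_burst_windows <- function(n_bursts, duration_s, dur_mean_s, dur_rel_sd,
                                min_gap_s = 0.5, margin_s = 1) {
  if (n_bursts == 0L) {
    return(tibble::tibble(burst_id = integer(), start_s = numeric(), end_s = numeric()))
  }
  durs <- rnorm(n_bursts, dur_mean_s, dur_rel_sd * dur_mean_s)
  durs <- pmin(pmax(durs, dur_mean_s * (1 - 2 * dur_rel_sd)),
               dur_mean_s * (1 + 2 * dur_rel_sd))
  slack <- duration_s - 2 * margin_s - sum(durs) - (n_bursts - 1) * min_gap_s
  if (slack < 0) {
    rlang::abort(
      sprintf("cannot place %d non-overlapping bursts (total %.1f s) in %.1f s",
              n_bursts, sum(durs), duration_s),
      class = c("hdmeanet_placement_error", "hdmeanet_error")
    )
  }
  u <- runif(n_bursts + 1L)
  extra <- slack * u / sum(u)
  starts <- numeric(n_bursts)
  cursor <- margin_s + extra[1]
  for (b in seq_len(n_bursts)) {
    starts[b] <- cursor
    cursor <- cursor + durs[b] + min_gap_s + extra[b + 1L]
  }
  tibble::tibble(burst_id = seq_len(n_bursts), start_s = starts, end_s = starts + durs)
}

# the within-window activation intervals of one recruitment group: the whole
# window when there is a single group, otherwise alternating blocks of
# `alt_s` seconds (fragmented multi-compartment activation)
active_intervals <- function(w0, w1, group, n_groups, alt_s) {
  if (n_groups <= 1 || is.na(alt_s)) {
    return(tibble::tibble(start = w0, end = w1))
  }
  starts <- seq(w0, w1 - 1e-9, by = alt_s)
  g <- ((seq_along(starts) - 1L) %% n_groups) + 1L
  keep <- g == group
  tibble::tibble(start = starts[keep], end = pmin(starts[keep] + alt_s, w1))
}

# which electrodes take part in network bursts, with onset delay per
# ground-truth graph hop; one recruitment pattern per recording.  Modular
# (abeta42-style) graphs recruit the module nearest the hotspot plus the
# most distal module as a second alternation group; small-world (control)
# graphs recruit a breadth-first ball from one seeded origin.
burst_recruitment <- function(cfg, graph, layout) {
  nodes <- attr(graph, "nodes")
  n <- length(nodes)
  if (n == 0L) {
    return(tibble::tibble(electrode_id = integer(), depth = integer(),
                          onset_ms = numeric(), group = integer()))
  }
  delay <- cfg$propagation_delay_ms %||% 5
  type <- attr(graph, "graph_type") %||% "smallworld"
  if (type == "modules") {
    membership <- attr(graph, "membership")
    n_modules <- max(membership)
    pick <- unique(c(1L, n_modules))
    rows <- purrr::map(seq_along(pick), function(gi) {
      members <- as.integer(names(membership)[membership == pick[gi]])
      depth <- c(0L, rep(1L, length(members) - 1L))
      tibble::tibble(electrode_id = members, depth = depth,
                     onset_ms = depth * delay, group = gi)
    })
    return(dplyr::bind_rows(rows))
  }
  m <- max(1L, round((cfg$burst_participation %||% 0.5) * n))
  adj <- undirected_adjacency(graph, nodes)
  origin <- sample.int(n, 1L)
  bfs <- bfs_from(adj, origin)
  order_idx <- bfs$order
  if (length(order_idx) < m) {
    # graph fragmented below the recruitment size: append unreached nodes in
    # grid order at one hop beyond the deepest reached level
    rest <- setdiff(seq_len(n), order_idx)
    extra_depth <- max(bfs$depth, na.rm = TRUE) + 1L
    bfs$depth[rest] <- extra_depth
    order_idx <- c(order_idx, rest)
  }
  take <- order_idx[seq_len(m)]
  tibble::tibble(
    electrode_id = nodes[take],
    depth = bfs$depth[take],
    onset_ms = bfs$depth[take] * delay,
    group = 1L
  )
}
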