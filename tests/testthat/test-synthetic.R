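sched_ctl <- phenotype_schedule("control")
sched_ab <- phenotype_schedule("abeta42")
lay <- test_layout()

test_that("packaged phenotype schedules encode the two developmental profiles", {
  expect_equal(sched_ctl$div, c(1, 4, 7, 10, 13, 16))
  # control baseline rate strictly increases; homogeneous firing from DIV7
  expect_true(all(diff(sched_ctl$base_rate_hz) > 0))
  expect_true(all(sched_ctl$spatial_profile[sched_ctl$div >= 7] == "homogeneous"))
  # control network bursts: none at DIV1, non-decreasing, 55 by DIV16
  expect_equal(sched_ctl$n_network_bursts[sched_ctl$div == 1], 0)
  expect_true(all(diff(sched_ctl$n_network_bursts) >= 0))
  expect_gte(sched_ctl$n_network_bursts[sched_ctl$div == 16], 55)
  # abeta42: biphasic baseline peaking at DIV10, localized at every age,
  # flat 25 network bursts from DIV4 on
  ab <- sched_ab$base_rate_hz
  peak <- which.max(ab)
  expect_equal(sched_ab$div[peak], 10)
  expect_true(all(diff(ab[1:peak]) > 0) && all(diff(ab[peak:length(ab)]) < 0))
  expect_true(all(sched_ab$spatial_profile == "localized"))
  expect_true(all(sched_ab$n_network_bursts[sched_ab$div >= 4] == 25))
  expect_error(phenotype_schedule("vehicle"), class = "hdmeanet_invalid_argument")
})

test_that("small-world generator: lattice degrees, determinism, bad degree", {
  cfg <- list(graph_type = "smallworld", mean_degree = 6, rewiring_prob = 0)
  g <- generate_ground_truth_graph(cfg, lay, seed = 1)
  deg <- table(factor(c(g$from, g$to), levels = lay$electrode_id))
  expect_true(all(deg == 6))  # pure ring lattice: every total degree = k

  cfg$rewiring_prob <- 0.1
  g1 <- generate_ground_truth_graph(cfg, lay, seed = 7)
  g2 <- generate_ground_truth_graph(cfg, lay, seed = 7)
  expect_identical(g1, g2)
  g3 <- generate_ground_truth_graph(cfg, lay, seed = 8)
  expect_false(identical(g1$to, g3$to))

  expect_error(
    generate_ground_truth_graph(list(graph_type = "smallworld", mean_degree = 100),
                                lay, seed = 1),
    class = "hdmeanet_invalid_argument"
  )
})

test_that("modular generator yields cliques with unit clustering", {
  cfg <- list(graph_type = "modules", burst_participation = 0.2,
              inter_module_edges = 0, spatial_center_x_rel = 0.45,
              spatial_center_y_rel = 0.33)
  g <- generate_ground_truth_graph(cfg, lay, seed = 3)
  nodes <- attr(g, "nodes")
  adj <- matrix(0L, length(nodes), length(nodes),
                dimnames = list(nodes, nodes))
  for (e in seq_len(nrow(g))) {
    adj[as.character(g$from[e]), as.character(g$to[e])] <- 1L
    adj[as.character(g$to[e]), as.character(g$from[e])] <- 1L
  }
  expect_equal(mean(oracle_cc(adj)), 1)  # isolated full modules are cliques
})

test_that("ground-truth clustering separates the phenotypes at DIV >= 4", {
  for (d in c(4, 7, 10, 13, 16)) {
    gc <- generate_ground_truth_graph(sched_ctl[sched_ctl$div == d, ], lay,
                                      seed = 10 + d)
    ga <- generate_ground_truth_graph(sched_ab[sched_ab$div == d, ], lay,
                                      seed = 20 + d)
    cc_of <- function(g) {
      nodes <- attr(g, "nodes")
      adj <- matrix(0L, length(nodes), length(nodes), dimnames = list(nodes, nodes))
      for (e in seq_len(nrow(g))) {
        adj[as.character(g$from[e]), as.character(g$to[e])] <- 1L
        adj[as.character(g$to[e]), as.character(g$from[e])] <- 1L
      }
      cc <- oracle_cc(adj)
      mean(cc[rowSums(adj) >= 2])
    }
    expect_gt(cc_of(ga), cc_of(gc))
  }
})

test_that("simulated rasters honour rates, counts and burst placement", {
  # zero rate, zero bursts -> empty raster
  cfg0 <- list(condition = "control", graph_type = "smallworld", mean_degree = 2,
               rewiring_prob = 0, base_rate_hz = 0, n_network_bursts = 0,
               rate_dispersion = 0, spatial_profile = "homogeneous")
  empty <- simulate_recording(cfg0, lay, 60, seed = 1)
  expect_equal(nrow(empty$raster$spikes), 0)

  # Poisson total count within 5 SD of its expectation
  cfg1 <- utils::modifyList(cfg0, list(base_rate_hz = 1))
  r <- simulate_recording(cfg1, lay, 300, seed = 2)$raster
  expect_lt(abs(nrow(r$spikes) - 30000), 5 * sqrt(30000))

  # per-electrode rate recovery within 5% on burst-free simulation
  expect_lt(abs(mean(mean_firing_rate(r)$mfr_hz) - 1), 0.05)

  # exactly the requested number of disjoint in-range windows
  sim <- simulate_recording(sched_ab[sched_ab$div == 16, ], lay, 300, seed = 3)
  w <- sim$ground_truth$windows
  expect_equal(nrow(w), 25)
  expect_true(all(w$end_s > w$start_s))
  expect_true(all(w$start_s[-1] > w$end_s[-nrow(w)]))
  expect_true(min(w$start_s) >= 0 && max(w$end_s) <= 300)

  # impossible placement is an explicit error
  cfg_full <- utils::modifyList(
    as.list(sched_ab[sched_ab$div == 16, ]), list(n_network_bursts = 500L))
  expect_error(simulate_recording(cfg_full, lay, 300, seed = 1),
               class = "hdmeanet_placement_error")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- simulate_recording(sched_ctl[sched_ctl$div == 7, ], lay, 60, seed = 11)
  b <- simulate_recording(sched_ctl[sched_ctl$div == 7, ], lay, 60, seed = 11)
  expect_identical(a$raster$spikes, b$raster$spikes)
  expect_identical(a$ground_truth$windows, b$ground_truth$windows)
  c <- simulate_recording(sched_ctl[sched_ctl$div == 7, ], lay, 60, seed = 12)
  expect_false(identical(a$raster$spikes, c$raster$spikes))
})

test_that("abeta42 weight maps are more inhomogeneous than control at every DIV", {
  w_of <- function(cfg) {
    if (cfg$spatial_profile == "homogeneous") {
      return(spatial_weights(lay, "homogeneous")$weight)
    }
    spatial_weights(lay, "localized", cfg$spatial_center_x_rel,
                    cfg$spatial_center_y_rel, cfg$spatial_width_rel)$weight
  }
  for (d in c(1, 4, 7, 10, 13, 16)) {
    wc <- w_of(sched_ctl[sched_ctl$div == d, ])
    wa <- w_of(sched_ab[sched_ab$div == d, ])
    expect_gt(var(wa), var(wc))
    expect_equal(mean(wa), 1, tolerance = 1e-12)
    expect_equal(mean(wc), 1, tolerance = 1e-12)
  }
})
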