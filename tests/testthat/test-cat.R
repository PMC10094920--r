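lay <- test_layout()

uniform_raster <- function(layout, spikes_per_el = 5, duration = 10) {
  n <- nrow(layout)
  spike_raster(
    tibble::tibble(
      electrode_id = rep(layout$electrode_id, each = spikes_per_el),
      time_s = rep(seq(0.5, duration - 0.5, length.out = spikes_per_el), n)
    ),
    layout, duration
  )
}

test_that("centre of activity is the activity-weighted centroid", {
  # uniform activity on the symmetric grid: CA exactly at the origin
  r <- uniform_raster(lay)
  ca <- center_of_activity(r, c(0, 10), bin_ms = 1000)
  expect_true(all(abs(ca$x_mm[ca$defined]) < 1e-12))
  expect_true(all(abs(ca$y_mm[ca$defined]) < 1e-12))

  # all spikes on one electrode: CA at that electrode
  r1 <- spike_raster(tibble::tibble(electrode_id = rep(7L, 10),
                                    time_s = seq(0.1, 0.9, length.out = 10)), lay, 1)
  ca1 <- center_of_activity(r1, c(0, 1), bin_ms = 1000)
  expect_equal(ca1$x_mm[1], lay$x_mm[lay$electrode_id == 7])
  expect_equal(ca1$y_mm[1], lay$y_mm[lay$electrode_id == 7])

  # two electrodes at (+-x, y), counts 3:1 -> CA at the weighted mean
  two <- make_chip_layout(1, 2, 2)  # positions (-1, 0) and (1, 0)
  r2 <- spike_raster(tibble::tibble(electrode_id = c(rep(1L, 3), 2L),
                                    time_s = c(0.1, 0.2, 0.3, 0.4)), two, 1)
  ca2 <- center_of_activity(r2, c(0, 1), bin_ms = 1000)
  expect_equal(ca2$x_mm[1], -0.5)
  r2b <- spike_raster(tibble::tibble(electrode_id = c(1L, rep(2L, 3)),
                                     time_s = c(0.1, 0.2, 0.3, 0.4)), two, 1)
  expect_equal(center_of_activity(r2b, c(0, 1), bin_ms = 1000)$x_mm[1], 0.5)

  # empty bins are flagged, not interpolated
  gap <- spike_raster(tibble::tibble(electrode_id = c(1L, 1L), time_s = c(0.1, 2.5)),
                      lay, 3)
  cag <- center_of_activity(gap, c(0, 3), bin_ms = 1000)
  expect_equal(cag$defined, c(TRUE, FALSE, TRUE))
  expect_true(is.na(cag$x_mm[2]))

  expect_error(center_of_activity(r, c(5, 20), bin_ms = 10),
               class = "hdmeanet_invalid_argument")
})

test_that("CA is translation-equivariant and scale-invariant in counts", {
  r <- simulate_poisson_raster(lay, 5, 10, seed = 3)
  ca <- center_of_activity(r, c(0, 10), bin_ms = 500)
  shift <- lay
  shift$x_mm <- shift$x_mm + 0.7
  shift$y_mm <- shift$y_mm - 0.3
  r_sh <- spike_raster(r$spikes, shift, 10)
  ca_sh <- center_of_activity(r_sh, c(0, 10), bin_ms = 500)
  expect_equal(ca_sh$x_mm, ca$x_mm + 0.7, tolerance = 1e-12)
  expect_equal(ca_sh$y_mm, ca$y_mm - 0.3, tolerance = 1e-12)

  # duplicating every spike (uniform count scaling) leaves CA unchanged
  r_dup <- spike_raster(dplyr::bind_rows(r$spikes, r$spikes), lay, 10)
  ca_dup <- center_of_activity(r_dup, c(0, 10), bin_ms = 500)
  expect_equal(ca_dup$x_mm, ca$x_mm, tolerance = 1e-12)
  expect_equal(ca_dup$n_spikes, 2L * ca$n_spikes)
})

test_that("CA stays inside the convex hull of the electrode grid", {
  withr::with_seed(81, {
    for (i in 1:10) {
      r <- simulate_poisson_raster(lay, runif(1, 0.5, 5), 10, seed = 500 + i)
      ca <- center_of_activity(r, c(0, 10), bin_ms = 100)
      ca <- ca[ca$defined, ]
      expect_true(all(ca$x_mm >= min(lay$x_mm) & ca$x_mm <= max(lay$x_mm)))
      expect_true(all(ca$y_mm >= min(lay$y_mm) & ca$y_mm <= max(lay$y_mm)))
    }
  })
})

test_that("more homogeneous firing pulls the expected CA toward the origin", {
  # rates mix a corner hotspot with a uniform field; increasing the uniform
  # share must shrink the mean CA displacement
  half <- max(abs(lay$x_mm))
  hot <- exp(-((lay$x_mm - half)^2 + (lay$y_mm - half)^2) / (2 * (0.3 * half)^2))
  norms <- vapply(c(0, 0.5, 1), function(mix) {
    rates <- 40 * (mix + (1 - mix) * hot / mean(hot))
    r <- withr::with_seed(1000 + round(100 * mix), {
      counts <- rpois(nrow(lay), rates * 30)
      spike_raster(tibble::tibble(electrode_id = rep(lay$electrode_id, counts),
                                  time_s = runif(sum(counts), 0, 30)), lay, 30)
    })
    ca <- center_of_activity(r, c(0, 30), bin_ms = 100)
    mean(sqrt(ca$x_mm^2 + ca$y_mm^2), na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("trajectory kinematics: stationary, stepping and degenerate cases", {
  # identical CA every bin: zero path, zero velocity
  r <- spike_raster(tibble::tibble(electrode_id = rep(7L, 50),
                                   time_s = seq(0.005, 0.495, 0.01)), lay, 1)
  tr <- compute_cat(r, list(start_s = 0, end_s = 0.5, burst_id = 1L))
  expect_equal(tr$summary$path_length_mm, 0)
  expect_equal(tr$summary$mean_velocity_mm_s, 0)
  expect_false(tr$summary$degenerate)

  # CA stepping 0.1 mm per 10 ms bin -> 10 mm/s
  stepper <- make_chip_layout(1, 6, 0.1)  # x = -0.25 ... 0.25
  sp <- tibble::tibble(electrode_id = 1:6,
                       time_s = 0.105 + 0.01 * (0:5))
  rs <- spike_raster(sp, stepper, 1)
  trs <- compute_cat(rs, list(start_s = 0.1, end_s = 0.16, burst_id = 1L))
  expect_equal(trs$summary$path_length_mm, 0.5, tolerance = 1e-9)
  expect_equal(trs$summary$mean_velocity_mm_s, 10, tolerance = 1e-9)
  expect_equal(trs$summary$duration_ms, 50, tolerance = 1e-9)
  expect_equal(trs$summary$terminal_distance_mm, 0.25, tolerance = 1e-9)

  # single defined point: degenerate, velocity undefined
  r1 <- spike_raster(tibble::tibble(electrode_id = 1L, time_s = 0.105), lay, 1)
  tr1 <- compute_cat(r1, list(start_s = 0.1, end_s = 0.2, burst_id = 2L))
  expect_true(tr1$summary$degenerate)
  expect_true(is.na(tr1$summary$mean_velocity_mm_s))
})

test_that("condition-level CAT summaries exclude degenerate trajectories", {
  one <- tibble::tibble(burst_id = 1L, n_points = 10L, duration_ms = 90,
                        path_length_mm = 0.9, mean_velocity_mm_s = 10,
                        terminal_distance_mm = 0.1, dispersion_mm = 0.05,
                        degenerate = FALSE)
  s <- cat_summary(one)
  expect_equal(s$mean[s$metric == "mean_velocity_mm_s"], 10)
  expect_equal(s$n, rep(1L, 4))

  mixed <- dplyr::bind_rows(one, dplyr::mutate(one, burst_id = 2L, degenerate = TRUE,
                                               mean_velocity_mm_s = NA))
  s2 <- cat_summary(mixed)
  expect_equal(s2$n, rep(1L, 4))
  expect_error(cat_summary(mixed[mixed$degenerate, ]), class = "hdmeanet_no_data")
})
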