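lay <- test_layout(4)

test_that("MFR map: arithmetic, silent electrodes, conservation", {
  r <- spike_raster(
    tibble::tibble(electrode_id = rep(1L, 300), time_s = seq(0.5, 299.5, length.out = 300)),
    lay, 300)
  mfr <- mean_firing_rate(r)
  expect_equal(mfr$mfr_hz[mfr$electrode_id == 1], 1.0)
  expect_true(all(mfr$mfr_hz[mfr$electrode_id != 1] == 0))
  # 3000 spikes / 300 s = 10 spikes/s, the activity-map display ceiling
  r10 <- spike_raster(
    tibble::tibble(electrode_id = rep(2L, 3000), time_s = seq(0.01, 299.99, length.out = 3000)),
    lay, 300)
  expect_equal(mean_firing_rate(r10)$mfr_hz[2], 10.0)
  # conservation on a random raster
  rr <- simulate_poisson_raster(lay, 2, 50, seed = 8)
  expect_equal(sum(mean_firing_rate(rr)$mfr_hz) * 50, nrow(rr$spikes))
})

test_that("interspike intervals: arithmetic, exclusions, exponential mean", {
  r <- spike_raster(
    tibble::tibble(electrode_id = c(1L, 1L, 1L, 2L), time_s = c(0.1, 0.2, 0.4, 5)),
    lay, 10)
  isi <- interspike_intervals(r)
  expect_equal(isi$isi_ms[isi$electrode_id == 1], c(100, 200))
  expect_false(2 %in% isi$electrode_id)  # single-spike electrode contributes nothing

  # ISI count = spike count - 1 per electrode with >= 1 spike
  rr <- simulate_poisson_raster(lay, 3, 60, seed = 9)
  per_el <- table(rr$spikes$electrode_id)
  isi_n <- table(interspike_intervals(rr)$electrode_id)
  for (id in names(per_el)) {
    got <- if (id %in% names(isi_n)) isi_n[[id]] else 0L
    expect_equal(got, unname(per_el[[id]]) - 1L)
  }

  # Poisson train at 2 Hz: mean ISI within 5% of 500 ms
  rp <- simulate_poisson_raster(test_layout(10), 2, 300, seed = 10)
  expect_lt(abs(mean(interspike_intervals(rp)$isi_ms) - 500) / 500, 0.05)
})

test_that("average ISI ratio behaves as a ratio of mean intervals", {
  a <- spike_raster(tibble::tibble(electrode_id = rep(1L, 11), time_s = seq(1, 2, 0.1)),
                    lay, 10)
  expect_equal(average_isi_ratio(a, a), 100)
  b <- spike_raster(tibble::tibble(electrode_id = rep(1L, 11), time_s = seq(1, 1.5, 0.05)),
                    lay, 10)
  expect_equal(average_isi_ratio(a, b), 50)
  silent <- spike_raster(NULL, lay, 10)
  expect_error(average_isi_ratio(a, silent), class = "hdmeanet_no_data")
})

test_that("distribution summary follows the documented quantile convention", {
  s <- summarize_distribution(c(1, 2, 3, 4, 5))
  expect_equal(c(s$q25, s$median, s$q75), c(2, 3, 4))
  expect_equal(s$sem, sd(1:5) / sqrt(5))

  const <- summarize_distribution(rep(7, 10))
  expect_equal(const$sem, 0)
  expect_equal(const$whisker_low, 7)

  one <- summarize_distribution(3.14)
  expect_equal(c(one$q25, one$median, one$q75), rep(3.14, 3))
  expect_true(is.na(one$sem))

  expect_error(summarize_distribution(numeric(0)), class = "hdmeanet_no_data")
})

test_that("Welch t-test matches the textbook computation to 1e-10", {
  a <- c(1, 2, 3, 4); b <- c(2, 3, 4, 5)
  got <- welch_t_test(a, b)
  ref <- oracle_welch(a, b)
  expect_equal(got$statistic, ref$t, tolerance = 1e-10)
  expect_equal(got$df, ref$df, tolerance = 1e-10)
  expect_equal(got$p_value, ref$p, tolerance = 1e-10)

  withr::with_seed(3, {
    for (i in 1:20) {
      x <- rnorm(sample(3:30, 1), sd = runif(1, 0.5, 3))
      y <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
      got <- welch_t_test(x, y)
      ref <- oracle_welch(x, y)
      expect_equal(got$statistic, ref$t, tolerance = 1e-10)
      expect_equal(got$p_value, ref$p, tolerance = 1e-10)
    }
  })
})

test_that("Welch t-test symmetry, identity and degenerate input", {
  g <- c(1, 2, 3)
  same <- welch_t_test(g, g)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 7)
  ab <- welch_t_test(a, b); ba <- welch_t_test(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p_value, ba$p_value)

  expect_error(welch_t_test(1, c(1, 2)), class = "hdmeanet_invalid_argument")
  expect_error(welch_t_test(c(1, 1, 1), c(2, 2)), class = "hdmeanet_degenerate_input")

  expect_equal(significance_tier(c(0.2, 0.04, 0.009, 0.004)),
               c("ns", "*", "**", "***"))
  expect_equal(tidy(ab)$significance, significance_tier(ab$p_value))
})
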