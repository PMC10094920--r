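lay <- test_layout()

test_that("cross-correlogram matches definitions on constructed trains", {
  # a train against itself: zero-lag pairs of a spike with itself excluded
  t0 <- sort(runif(50, 0, 10))
  auto <- cross_correlogram(t0, t0)
  manual <- oracle_correlogram(t0, t0, exclude_self = TRUE)
  expect_equal(auto$count, manual$count)
  with_self <- cross_correlogram(t0, t0, exclude_self = FALSE)
  expect_equal(with_self$count[with_self$lag_ms == 0],
               auto$count[auto$lag_ms == 0] + 50L)

  # a +5 ms shifted copy: a single peak at +5 ms (1 ms bins)
  shifted <- cross_correlogram(t0, t0 + 0.005, bin_ms = 1, max_lag_ms = 25)
  expect_equal(shifted$lag_ms[which.max(shifted$count)], 5)
  expect_equal(max(shifted$count), 50L)

  # swapping the trains mirrors the lag axis
  a <- poisson_train(5, 20, 1); b <- poisson_train(5, 20, 2)
  ab <- cross_correlogram(a, b); ba <- cross_correlogram(b, a)
  expect_equal(ab$count, rev(ba$count))
})

test_that("cross-correlogram equals the O(n^2) pair-counting oracle", {
  withr::with_seed(51, {
    for (i in 1:30) {
      a <- sort(runif(sample(5:150, 1), 0, 5))
      b <- sort(runif(sample(5:150, 1), 0, 5))
      bin <- sample(c(1, 2, 5), 1)
      lag <- sample(c(10, 25), 1)
      expect_equal(cross_correlogram(a, b, bin, lag)$count,
                   oracle_correlogram(a, b, bin, lag)$count)
    }
    # bursty trains with many coincidences
    core <- sort(rep(runif(20, 0, 5), each = 4) + runif(80, 0, 0.01))
    expect_equal(cross_correlogram(core, core)$count,
                 oracle_correlogram(core, core, exclude_self = TRUE)$count)
  })
})

test_that("surrogate threshold separates locked pairs from independent ones", {
  # perfectly locked pair: peak far above threshold
  t0 <- poisson_train(8, 60, 5)
  locked <- t0 + 0.005
  pk <- max(cross_correlogram(t0, locked)$count)
  thr <- significance_threshold(t0, locked, seed = 2)
  expect_gt(pk, 3 * thr)

  # deterministic under seed
  expect_identical(significance_threshold(t0, locked, seed = 7),
                   significance_threshold(t0, locked, seed = 7))
  expect_error(significance_threshold(numeric(0), t0), class = "hdmeanet_no_data")

  # independent Poisson pairs cross the c = 4 threshold rarely (<= 5%)
  hits <- withr::with_seed(99, {
    vapply(1:100, function(i) {
      a <- sort(runif(150, 0, 60)); b <- sort(runif(150, 0, 60))
      pk <- max(cross_correlogram(a, b)$count)
      pk > significance_threshold(a, b, seed = i)
    }, logical(1))
  })
  expect_lte(mean(hits), 0.05)
})

test_that("a 3-electrode chain with 5 ms hops is recovered with correct direction", {
  small <- make_chip_layout(1, 3, 0.042)
  withr::with_seed(61, {
    starts <- seq(2, 58, length.out = 50)
    ev <- purrr::map(starts, function(s0) {
      base <- s0 + sort(runif(6, 0, 0.05))
      tibble::tibble(
        electrode_id = rep(1:3, each = 6),
        time_s = c(base, base + 0.005, base + 0.010)
      )
    })
    noise <- tibble::tibble(electrode_id = rep(1:3, each = 30),
                            time_s = runif(90, 0, 60))
    r <- spike_raster(dplyr::bind_rows(c(ev, list(noise))), small, 60)
  })
  g <- infer_graph(r, seed = 3)
  key <- paste(g$edges$from, g$edges$to)
  expect_true(all(c("1 2", "2 3") %in% key))
  directed <- g$edges[!g$edges$mutual, ]
  expect_false(any(paste(directed$from, directed$to) %in% c("2 1", "3 2", "3 1")))
})

test_that("inference on generator output: direction accuracy and determinism", {
  sched <- phenotype_schedule("control")
  sim <- simulate_recording(sched[sched$div == 16, ], lay, 300, seed = 42)
  g1 <- infer_graph(sim$raster, seed = 7)
  g2 <- infer_graph(sim$raster, seed = 7)
  expect_identical(g1$edges, g2$edges)

  depth <- setNames(sim$ground_truth$recruitment$depth,
                    sim$ground_truth$recruitment$electrode_id)
  directed <- g1$edges[!g1$edges$mutual, ]
  ok <- depth[as.character(directed$from)] < depth[as.character(directed$to)]
  expect_gt(sum(!is.na(ok)), 100)
  expect_gt(mean(ok, na.rm = TRUE), 0.9)

  # silent raster -> empty graph
  g0 <- infer_graph(spike_raster(NULL, lay, 60))
  expect_equal(nrow(g0$edges), 0)
  expect_equal(nrow(g0$nodes), 0)
})

test_that("recovered edge counts track ground-truth edge counts across DIVs", {
  sched <- phenotype_schedule("control")
  truth_n <- c(); inferred_n <- c()
  for (d in c(1, 4, 7, 10, 13, 16)) {
    sim <- simulate_recording(sched[sched$div == d, ], lay, 300, seed = 100 + d)
    g <- infer_graph(sim$raster, seed = 1)
    truth_n <- c(truth_n, nrow(sim$ground_truth$graph))
    inferred_n <- c(inferred_n, nrow(g$edges))
  }
  expect_gt(cor(truth_n, inferred_n, method = "spearman"), 0.8)
})

test_that("node roles partition by in/out degree balance", {
  star <- list(
    nodes = tibble::tibble(electrode_id = 1:5),
    edges = tibble::tibble(from = 1L, to = 2:5, weight = 1, lag_ms = 5, mutual = FALSE)
  )
  roles <- classify_node_roles(star)
  expect_equal(roles$role[roles$electrode_id == 1], "sender")
  expect_true(all(roles$role[roles$electrode_id != 1] == "receiver"))

  cyc <- list(
    nodes = tibble::tibble(electrode_id = 1:3),
    edges = tibble::tibble(from = c(1L, 2L), to = c(2L, 1L), weight = 1,
                           lag_ms = 0, mutual = TRUE)
  )
  roles <- classify_node_roles(cyc)
  expect_true(all(roles$role[1:2] == "broker"))
  expect_true(is.na(roles$role[3]))  # isolated node excluded from the partition
})
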