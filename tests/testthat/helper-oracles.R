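# Brute-force reference implementations, kept deliberately independent of the
# package's own algorithms: plain double loops and textbook formulas only.

# O(n^2) pair counter with the same bin convention (bins centred at k*bin,
# membership round-half-away-from-zero)
oracle_correlogram <- function(ti, tj, bin_ms = 2, max_lag_ms = 25,
                               exclude_self = FALSE) {
  L <- floor(abs(max_lag_ms / bin_ms) + 0.5)
  counts <- integer(2 * L + 1)
  for (a in seq_along(ti)) {
    for (b in seq_along(tj)) {
      if (exclude_self && a == b) next
      d <- (tj[b] - ti[a]) * 1000
      k <- sign(d) * floor(abs(d / bin_ms) + 0.5)
      if (abs(k) <= L) counts[k + L + 1] <- counts[k + L + 1] + 1L
    }
  }
  tibble::tibble(lag_ms = seq(-L, L) * bin_ms, count = counts)
}

# exhaustive run-scan spike-burst detector
oracle_bursts <- function(times, max_isi_ms = 100, min_spikes = 5) {
  times <- sort(times)
  n <- length(times)
  out <- list()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && (times[j + 1] - times[j]) * 1000 <= max_isi_ms) j <- j + 1L
    if (j - i + 1L >= min_spikes) {
      out[[length(out) + 1L]] <- c(start_s = times[i], end_s = times[j],
                                   n_spikes = j - i + 1L)
    }
    i <- j + 1L
  }
  if (length(out) == 0) {
    return(tibble::tibble(start_s = numeric(), end_s = numeric(), n_spikes = integer()))
  }
  m <- do.call(rbind, out)
  tibble::tibble(start_s = unname(m[, 1]), end_s = unname(m[, 2]),
                 n_spikes = as.integer(m[, 3]))
}

# per-node clustering coefficient by explicit neighbour-pair enumeration
oracle_cc <- function(adj) {
  n <- nrow(adj)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] > 0)
    k <- length(nb)
    if (k < 2) next
    links <- 0L
    for (a in seq_len(k - 1)) {
      for (b in seq((a + 1), k)) {
        if (adj[nb[a], nb[b]] > 0) links <- links + 1L
      }
    }
    cc[i] <- 2 * links / (k * (k - 1))
  }
  cc
}

# Floyd-Warshall all-pairs shortest paths (Inf where unreachable)
oracle_fw <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj > 0] <- 1
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

# Welch statistic from the textbook formulas
oracle_welch <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  p <- 2 * stats::pt(-abs(t), df)
  list(t = t, df = df, p = p)
}

# random undirected adjacency matrix (no self loops)
rand_adj <- function(n, p) {
  adj <- matrix(0L, n, n)
  up <- which(upper.tri(adj))
  adj[up] <- as.integer(runif(length(up)) < p)
  adj + t(adj)
}

adj_to_edges <- function(adj) {
  idx <- which(adj > 0 & upper.tri(adj), arr.ind = TRUE)
  edges <- tibble::tibble(from = idx[, 1], to = idx[, 2])
  attr(edges, "nodes") <- seq_len(nrow(adj))
  edges
}

# small shared fixtures
test_layout <- function(n = 10) make_chip_layout(n, n, 0.042)

poisson_train <- function(rate_hz, duration_s, seed) {
  withr::with_seed(seed, sort(runif(rpois(1, rate_hz * duration_s), 0, duration_s)))
}
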