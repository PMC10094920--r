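#' Binned cross-correlogram of two spike trains
#'
#' Counts spike pairs by lag `t_j - t_i` in bins centred at multiples of
#' `bin_ms` spanning `[-max_lag_ms, +max_lag_ms]` (bin membership is
#' round-half-away-from-zero, so each bin covers its centre +/- half a bin).
#' When the two trains are the same vector, pairs of a spike with itself are
#' excluded by default, so the zero-lag bin of an autocorrelogram counts
#' only distinct coincident spikes.
#'
#' @param train_i,train_j Sorted numeric vectors of spike times (s).
#' @param bin_ms Lag bin width (ms, default 2).
#' @param max_lag_ms Maximum lag (ms, default 25; must be >= `bin_ms`).
#' @param exclude_self Skip same-index pairs (default: only when the trains
#'   are identical).
#' @return Tibble with `lag_ms` (bin centres) and `count`.
#' @export
cross_correlogram <- function(train_i, train_j, bin_ms = 2, max_lag_ms = 25,
                              exclude_self = identical(train_i, train_j)) {
  bin_ms <- check_positive(bin_ms, "bin_ms")
  max_lag_ms <- check_positive(max_lag_ms, "max_lag_ms")
  if (max_lag_ms < bin_ms) stop_invalid("`max_lag_ms` must be >= `bin_ms`")
  L <- lround(max_lag_ms / bin_ms)
  counts <- cc_counts_cpp(as.numeric(train_i), as.numeric(train_j),
                          bin_ms / 1000, max_lag_ms / 1000, isTRUE(exclude_self))
  tibble::tibble(lag_ms = (seq(-L, L)) * bin_ms, count = as.integer(counts))
}

# peak of a correlogram with a deterministic tie-break: largest count,
# then smallest |lag|, then positive lag
correlogram_peak <- function(cc) {
  best <- which(cc$count == max(cc$count))
  if (length(best) > 1) {
    best <- best[order(abs(cc$lag_ms[best]), -sign(cc$lag_ms[best]))][1]
  }
  list(count = cc$count[best], lag_ms = cc$lag_ms[best])
}

# n jittered, re-sorted copies of a train (uniform +/- jitter)
jitter_surrogates <- function(train, n_surrogates, jitter_ms) {
  purrr::map(seq_len(n_surrogates), function(s) {
    sort(train + runif(length(train), -jitter_ms / 1000, jitter_ms / 1000))
  })
}

#' Surrogate-based significance threshold for a correlogram peak
#'
#' Each surrogate displaces every spike of `train_j` independently and
#' uniformly within +/- `jitter_ms` and records the resulting correlogram
#' peak; the threshold is `mean + c * sd` of the surrogate peaks.  Jitter on
#' the scale of the maximum lag destroys millisecond-precise locking while
#' preserving slow co-modulation (e.g. common burst participation), so only
#' sharply time-locked structure crosses the threshold.
#'
#' @inheritParams cross_correlogram
#' @param n_surrogates Number of jittered surrogates (>= 10, default 20).
#' @param jitter_ms Jitter half-width (ms, default 25).
#' @param c Threshold stringency in SD units (default 4).
#' @param seed Integer seed making the surrogate draw reproducible.
#' @return A single threshold (pair count).
#' @export
significance_threshold <- function(train_i, train_j, n_surrogates = 20, jitter_ms = 25,
                                   c = 4, bin_ms = 2, max_lag_ms = 25, seed = 1L) {
  if (length(train_i) == 0 || length(train_j) == 0) {
    stop_no_data("cannot compute a surrogate threshold for an empty train")
  }
  n_surrogates <- check_count(n_surrogates, "n_surrogates", min = 10L)
  jitter_ms <- check_positive(jitter_ms, "jitter_ms")
  peaks <- withr::with_seed(as.integer(seed), {
    surr <- jitter_surrogates(train_j, n_surrogates, jitter_ms)
    vapply(surr, function(tj) {
      correlogram_peak(cross_correlogram(train_i, tj, bin_ms, max_lag_ms,
                                         exclude_self = FALSE))$count
    }, numeric(1))
  })
  mean(peaks) + c * sd(peaks)
}

#' Infer a directed functional-connectivity graph
#'
#' For every pair of active electrodes the cross-correlogram peak is
#' compared against its jitter-surrogate threshold; a significant peak at a
#' positive lag adds the edge i -> j (i leads j), a negative lag the
#' reverse, and a zero-lag peak adds both directions flagged `mutual`.
#' Edge weight is the peak count normalised by the geometric mean of the
#' two spike counts.  Node roles follow [classify_node_roles()].
#'
#' @param raster A [spike_raster()].
#' @param bin_ms,max_lag_ms Correlogram parameters (defaults 2 and 25 ms).
#' @param n_surrogates,jitter_ms,c Surrogate-threshold parameters (defaults
#'   20, 25 ms, 4); one jittered copy set per electrode is shared across all
#'   pairs involving that electrode as target.
#' @param active_rate_hz Activity floor restricting the node set.
#' @param seed Integer seed; inference is deterministic given raster + params.
#' @return Object of class `functional_graph`: list with `nodes` (tibble:
#'   `electrode_id`, `x_mm`, `y_mm`, `n_spikes`, `in_degree`, `out_degree`,
#'   `role`), `edges` (tibble: `from`, `to`, `weight`, `lag_ms`, `mutual`)
#'   and `params`.
#' @export
infer_graph <- function(raster, bin_ms = 2, max_lag_ms = 25, n_surrogates = 20,
                        jitter_ms = 25, c = 4, active_rate_hz = 0.02, seed = 1L) {
  stopifnot(inherits(raster, "spike_raster"))
  active <- active_electrodes(raster, active_rate_hz)
  trains <- spike_trains(raster, active)
  n_sp <- vapply(trains, length, integer(1))

  edges <- tibble::tibble(from = integer(), to = integer(), weight = numeric(),
                          lag_ms = numeric(), mutual = logical())
  if (length(active) >= 2) {
    surr <- withr::with_seed(as.integer(seed), {
      lapply(trains, jitter_surrogates, n_surrogates = n_surrogates,
             jitter_ms = jitter_ms)
    })
    bin_s <- bin_ms / 1000
    lag_s <- max_lag_ms / 1000
    L <- lround(max_lag_ms / bin_ms)
    lags <- seq(-L, L) * bin_ms
    rows <- list()
    for (i in seq_along(active)[-length(active)]) {
      ti <- trains[[i]]
      if (length(ti) == 0) next
      for (j in seq((i + 1), length(active))) {
        tj <- trains[[j]]
        if (length(tj) == 0) next
        counts <- cc_counts_cpp(ti, tj, bin_s, lag_s, FALSE)
        pk <- correlogram_peak(tibble::tibble(lag_ms = lags, count = as.integer(counts)))
        s_peaks <- vapply(surr[[j]], function(sj) {
          max(cc_counts_cpp(ti, sj, bin_s, lag_s, FALSE))
        }, numeric(1))
        thr <- mean(s_peaks) + c * sd(s_peaks)
        if (pk$count <= thr) next
        w <- pk$count / sqrt(n_sp[i] * n_sp[j])
        if (pk$lag_ms > 0) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            from = active[i], to = active[j], weight = w, lag_ms = pk$lag_ms,
            mutual = FALSE)
        } else if (pk$lag_ms < 0) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            from = active[j], to = active[i], weight = w, lag_ms = -pk$lag_ms,
            mutual = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            from = c(active[i], active[j]), to = c(active[j], active[i]),
            weight = w, lag_ms = 0, mutual = TRUE)
        }
      }
    }
    if (length(rows) > 0) edges <- dplyr::bind_rows(rows)
  }

  pos <- raster$layout[match(active, raster$layout$electrode_id), ]
  nodes <- tibble::tibble(
    electrode_id = active,
    x_mm = pos$x_mm, y_mm = pos$y_mm,
    n_spikes = as.integer(n_sp)
  )
  graph <- structure(
    list(nodes = nodes, edges = edges,
         params = list(bin_ms = bin_ms, max_lag_ms = max_lag_ms,
                       n_surrogates = n_surrogates, jitter_ms = jitter_ms,
                       c = c, active_rate_hz = active_rate_hz, seed = seed)),
    class = "functional_graph"
  )
  graph$nodes <- classify_node_roles(graph)
  graph
}

#' @export
print.functional_graph <- function(x, ...) {
  cat(sprintf("<functional_graph> %d nodes, %d directed edges (%d mutual)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$mutual)))
  invisible(x)
}

#' Sender / receiver / broker node roles
#'
#' A node is a sender when its out-degree exceeds its in-degree, a receiver
#' when in-degree exceeds out-degree, and a broker when the two are equal
#' and non-zero.  Isolated nodes (degree 0) carry role `NA` and are excluded
#' from the role partition.
#'
#' @param graph A `functional_graph` (or a list with `nodes` and `edges`).
#' @return The `nodes` tibble with `in_degree`, `out_degree`, `role` columns.
#' @export
classify_node_roles <- function(graph) {
  nodes <- graph$nodes
  edges <- graph$edges
  out_deg <- table(factor(edges$from, levels = nodes$electrode_id))
  in_deg <- table(factor(edges$to, levels = nodes$electrode_id))
  nodes$out_degree <- as.integer(out_deg)
  nodes$in_degree <- as.integer(in_deg)
  nodes$role <- dplyr::case_when(
    nodes$out_degree + nodes$in_degree == 0 ~ NA_character_,
    nodes$out_degree > nodes$in_degree ~ "sender",
    nodes$in_degree > nodes$out_degree ~ "receiver",
    TRUE ~ "broker"
  )
  nodes
}
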