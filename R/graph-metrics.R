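# Graph-theory summaries are computed on the undirected projection of the
# (possibly directed) input graph: the development analysis treats a link as
# a link regardless of its inferred direction.

# normalise input: functional_graph, ground-truth edge tibble, or a plain
# edge data frame (+ optional nodes vector) -> list(nodes, adj)
graph_input <- function(graph, nodes = NULL) {
  if (inherits(graph, "functional_graph")) {
    nodes <- graph$nodes$electrode_id
    edges <- graph$edges
  } else if (is.data.frame(graph)) {
    edges <- graph
    nodes <- nodes %||% attr(graph, "nodes") %||%
      sort(unique(c(edges$from, edges$to)))
  } else {
    stop_invalid("`graph` must be a functional_graph or an edge data frame")
  }
  if (length(nodes) == 0) stop_invalid("graph has no nodes")
  list(nodes = nodes, adj = undirected_adjacency(edges, nodes))
}

#' Clustering coefficient
#'
#' Local clustering of each node on the undirected projection:
#' `cc_i = 2 T_i / (k_i (k_i - 1))` where `T_i` is the number of links
#' between node i's neighbours.  Nodes with fewer than two neighbours have
#' `cc = 0` and are excluded from the average.
#'
#' @param graph A `functional_graph` or an edge data frame (`from`, `to`).
#' @param nodes Optional node ids (defaults to the graph's nodes).
#' @return List with `per_node` (tibble `node`, `degree`, `triangles`, `cc`)
#'   and `average` (mean cc over nodes with degree >= 2; `NaN` if none).
#' @export
clustering_coefficient <- function(graph, nodes = NULL) {
  g <- graph_input(graph, nodes)
  adj <- g$adj
  n <- length(adj)
  deg <- lengths(adj)
  tri <- integer(n)
  is_nb <- vector("list", n)
  for (i in seq_len(n)) {
    if (deg[i] < 2) next
    nb <- adj[[i]]
    t_i <- 0L
    for (a in seq_len(deg[i] - 1L)) {
      t_i <- t_i + sum(adj[[nb[a]]] %in% nb[(a + 1L):deg[i]])
    }
    tri[i] <- t_i
  }
  cc <- ifelse(deg >= 2, 2 * tri / (deg * (deg - 1)), 0)
  per_node <- tibble::tibble(node = g$nodes, degree = deg, triangles = tri, cc = cc)
  list(per_node = per_node, average = mean(cc[deg >= 2]))
}

#' Characteristic path length with histogram
#'
#' Unweighted shortest paths (breadth-first search) on the undirected
#' projection.  Each node's average path length is taken over its reachable
#' targets only, so fragmented graphs contribute finite values; nodes that
#' reach no other node are excluded.  The network path length is the mean
#' of the per-node averages.  Per-node averages are binned at `bin_width`
#' links (default 0.25, so medians such as 2.75 links are representable)
#' and the bin containing the median node is reported.
#'
#' @inheritParams clustering_coefficient
#' @param bin_width Histogram bin width in links (default 0.25).
#' @param largest_component If `TRUE`, restrict the analysis to the largest
#'   connected component instead of averaging over reachable targets.
#' @return List: `network_pl`, `per_node` (tibble `node`, `avg_pl`,
#'   `n_reachable`), `histogram` (tibble `bin_left`, `count`), `median_bin`
#'   (left edge of the bin holding the median per-node average), `median_pl`.
#' @export
path_length_analysis <- function(graph, bin_width = 0.25, largest_component = FALSE,
                                 nodes = NULL) {
  g <- graph_input(graph, nodes)
  if (length(g$nodes) < 2) stop_invalid("path-length analysis needs at least 2 nodes")
  adj <- g$adj
  n <- length(adj)
  keep <- seq_len(n)
  if (largest_component) {
    comp <- components_of(adj)
    biggest <- which.max(tabulate(comp))
    keep <- which(comp == biggest)
  }
  avg_pl <- rep(NA_real_, n)
  n_reach <- integer(n)
  for (i in keep) {
    d <- bfs_distances(adj, i)
    reach <- which(!is.na(d) & seq_len(n) != i & seq_len(n) %in% keep)
    n_reach[i] <- length(reach)
    if (length(reach) > 0) avg_pl[i] <- mean(d[reach])
  }
  ok <- !is.na(avg_pl)
  if (!any(ok)) {
    rlang::abort("graph is fully disconnected: no node reaches any other",
                 class = c("hdmeanet_no_path", "hdmeanet_error"))
  }
  vals <- avg_pl[ok]
  bin_left <- floor(vals / bin_width) * bin_width
  hist <- tibble::as_tibble(table(bin_left)) |>
    dplyr::transmute(bin_left = as.numeric(.data$bin_left), count = .data$n)
  med <- median(vals)
  list(
    network_pl = mean(vals),
    per_node = tibble::tibble(node = g$nodes, avg_pl = avg_pl, n_reachable = n_reach),
    histogram = hist,
    median_pl = med,
    median_bin = floor(med / bin_width) * bin_width
  )
}

bfs_distances <- function(adj, origin) {
  n <- length(adj)
  d <- rep(NA_real_, n)
  d[origin] <- 0
  frontier <- origin
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

components_of <- function(adj) {
  n <- length(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    frontier <- i
    comp[i] <- cur
    while (length(frontier) > 0) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.na(comp[w])) {
            comp[w] <- cur
            nxt <- c(nxt, w)
          }
        }
      }
      frontier <- nxt
    }
  }
  comp
}

#' Node-degree distribution
#'
#' Undirected-projection degree of every node, the integer-binned histogram,
#' and the tail mass (fraction of nodes whose degree exceeds the
#' `tail_quantile` degree quantile) used to compare fat-tailed degree
#' distributions.
#'
#' @inheritParams clustering_coefficient
#' @param tail_quantile Quantile defining the tail (default 0.9).
#' @return List: `per_node` (tibble `node`, `degree`), `histogram` (tibble
#'   `degree`, `count`), `median`, `mean`, `tail_mass`.
#' @export
degree_analysis <- function(graph, tail_quantile = 0.9, nodes = NULL) {
  g <- graph_input(graph, nodes)
  deg <- lengths(g$adj)
  hist <- tibble::as_tibble(table(deg)) |>
    dplyr::transmute(degree = as.integer(.data$deg), count = .data$n)
  list(
    per_node = tibble::tibble(node = g$nodes, degree = deg),
    histogram = hist,
    median = median(deg),
    mean = mean(deg),
    tail_mass = mean(deg > quantile(deg, tail_quantile, type = 7))
  )
}

#' All graph metrics of one graph
#'
#' Convenience wrapper bundling [clustering_coefficient()],
#' [path_length_analysis()] and [degree_analysis()] into one result with
#' [tidy()] (per-node values) and [glance()] (one-row summary) methods.
#' A fully disconnected graph yields `NA` path-length fields rather than an
#' error.
#'
#' @inheritParams path_length_analysis
#' @param tail_quantile See [degree_analysis()].
#' @return Object of class `graph_metrics_result`.
#' @export
graph_metrics <- function(graph, bin_width = 0.25, largest_component = FALSE,
                          tail_quantile = 0.9, nodes = NULL) {
  cc <- clustering_coefficient(graph, nodes)
  nd <- degree_analysis(graph, tail_quantile, nodes)
  pl <- tryCatch(
    path_length_analysis(graph, bin_width, largest_component, nodes),
    hdmeanet_no_path = function(e) NULL,
    hdmeanet_invalid_argument = function(e) NULL
  )
  n_edges <- sum(nd$per_node$degree) / 2
  structure(
    list(cc = cc, pl = pl, nd = nd,
         n_nodes = nrow(nd$per_node), n_edges = n_edges),
    class = "graph_metrics_result"
  )
}

#' @export
print.graph_metrics_result <- function(x, ...) {
  cat(sprintf("<graph_metrics_result> %d nodes, %g undirected edges\n",
              x$n_nodes, x$n_edges))
  cat(sprintf("  avg CC %.3f | network PL %s | mean ND %.2f\n",
              x$cc$average,
              if (is.null(x$pl)) "NA" else sprintf("%.3f", x$pl$network_pl),
              x$nd$mean))
  invisible(x)
}

#' @rdname graph_metrics
#' @param x A `graph_metrics_result`.
#' @param ... Unused.
#' @export
tidy.graph_metrics_result <- function(x, ...) {
  out <- dplyr::left_join(x$cc$per_node, x$nd$per_node[c("node", "degree")],
                          by = c("node", "degree"))
  if (!is.null(x$pl)) {
    out <- dplyr::left_join(out, x$pl$per_node, by = "node")
  } else {
    out$avg_pl <- NA_real_
    out$n_reachable <- NA_integer_
  }
  out
}

#' @rdname graph_metrics
#' @export
glance.graph_metrics_result <- function(x, ...) {
  tibble::tibble(
    n_nodes = x$n_nodes,
    n_edges = x$n_edges,
    avg_cc = x$cc$average,
    network_pl = if (is.null(x$pl)) NA_real_ else x$pl$network_pl,
    pl_median_bin = if (is.null(x$pl)) NA_real_ else x$pl$median_bin,
    nd_mean = x$nd$mean,
    nd_median = x$nd$median,
    nd_tail_mass = x$nd$tail_mass
  )
}
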