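#' Generate a ground-truth connectivity graph for one phenotype
#'
#' Two generative families are provided, matching the contrast the analysis
#' is meant to recover.  The control graph is a directed ring lattice over
#' grid-ordered electrodes (each node sends edges to its `mean_degree / 2`
#' clockwise neighbours) with each edge rewired to a uniform random target
#' with probability `rewiring_prob` -- the classic small-world construction.
#' The abeta42 graph is a union of dense local modules: electrodes are sorted
#' by distance from the spatial hotspot, grouped into consecutive modules of
#' `round(burst_participation * n)` electrodes, each module fully connected,
#' with `inter_module_edges` random links between adjacent modules.  At
#' matched size the modular graph has a far higher clustering coefficient
#' than the rewired lattice.
#'
#' @param cfg One row of [phenotype_schedule()] (or an equivalent list).
#' @param layout Electrode layout; nodes are the layout's electrodes.
#' @param seed Integer seed; the same `(cfg, layout, seed)` always yields the
#'   same edge set.
#' @return A tibble with columns `from`, `to` (electrode ids, directed) and
#'   attributes `nodes` (electrode ids in the graph), `membership` (named
#'   module index, modular graphs only) and `graph_type`.
#' @export
generate_ground_truth_graph <- function(cfg, layout, seed = 1L) {
  cfg <- as_phenotype_cfg(cfg)
  layout <- as_layout(layout)
  n <- nrow(layout)
  withr::with_seed(as.integer(seed), {
    switch(cfg$graph_type %||% "smallworld",
      smallworld = generate_smallworld(cfg, layout, n),
      modules = generate_modules(cfg, layout, n),
      stop_invalid(sprintf("unknown graph_type '%s'", cfg$graph_type))
    )
  })
}

generate_smallworld <- function(cfg, layout, n) {
  k <- cfg$mean_degree
  if (is.null(k) || is.na(k)) stop_invalid("smallworld graphs need `mean_degree`")
  if (k %% 2 != 0 || k < 0) stop_invalid("`mean_degree` must be a non-negative even integer")
  if (k >= n) stop_invalid("`mean_degree` must be smaller than the number of nodes")
  p <- cfg$rewiring_prob %||% 0
  ids <- layout$electrode_id          # grid order defines the ring
  if (k == 0) {
    edges <- tibble::tibble(from = integer(), to = integer())
  } else {
    from_idx <- rep(seq_len(n), times = k / 2)
    offset <- rep(seq_len(k / 2), each = n)
    to_idx <- ((from_idx - 1L + offset) %% n) + 1L
    # rewire: draw targets avoiding self-loops and duplicate edges
    rewire <- runif(length(from_idx)) < p
    key <- function(a, b) paste(a, b)
    existing <- new.env(parent = emptyenv())
    for (e in which(!rewire)) assign(key(from_idx[e], to_idx[e]), TRUE, existing)
    for (e in which(rewire)) {
      for (try in 1:100) {
        cand <- sample.int(n, 1L)
        if (cand != from_idx[e] && !exists(key(from_idx[e], cand), existing)) {
          to_idx[e] <- cand
          break
        }
      }
      assign(key(from_idx[e], to_idx[e]), TRUE, existing)
    }
    edges <- tibble::tibble(from = ids[from_idx], to = ids[to_idx])
  }
  attr(edges, "nodes") <- ids
  attr(edges, "graph_type") <- "smallworld"
  edges
}

generate_modules <- function(cfg, layout, n) {
  part <- cfg$burst_participation %||% 0.15
  m <- max(2L, round(part * n))
  if (m > n) stop_invalid("module size exceeds node count")
  half <- layout_half_extent(layout)
  cx <- (cfg$spatial_center_x_rel %||% 0) * half
  cy <- (cfg$spatial_center_y_rel %||% 0) * half
  d2 <- (layout$x_mm - cx)^2 + (layout$y_mm - cy)^2
  ord <- order(d2, layout$electrode_id)
  n_modules <- n %/% m
  assigned <- ord[seq_len(n_modules * m)]
  membership <- rep(seq_len(n_modules), each = m)
  ids <- layout$electrode_id[assigned]

  within <- purrr::map(seq_len(n_modules), function(mod) {
    members <- ids[membership == mod]
    pairs <- t(utils::combn(sort(members), 2L))
    tibble::tibble(from = pairs[, 1], to = pairs[, 2])
  })
  edges <- dplyr::bind_rows(within)
  n_inter <- cfg$inter_module_edges %||% 0
  if (n_modules > 1 && n_inter > 0) {
    inter <- purrr::map(seq_len(n_modules - 1L), function(mod) {
      a <- ids[membership == mod]
      b <- ids[membership == mod + 1L]
      tibble::tibble(from = sample(a, n_inter, replace = TRUE),
                     to = sample(b, n_inter, replace = TRUE))
    })
    edges <- dplyr::bind_rows(edges, dplyr::bind_rows(inter))
    edges <- dplyr::distinct(edges)
  }
  attr(edges, "nodes") <- ids
  attr(edges, "membership") <- setNames(membership, ids)
  attr(edges, "graph_type") <- "modules"
  edges
}

# adjacency list of the undirected projection, over `nodes`
undirected_adjacency <- function(edges, nodes) {
  idx <- setNames(seq_along(nodes), nodes)
  adj <- vector("list", length(nodes))
  if (nrow(edges) > 0) {
    a <- idx[as.character(edges$from)]
    b <- idx[as.character(edges$to)]
    keep <- !is.na(a) & !is.na(b) & a != b
    a <- a[keep]; b <- b[keep]
    und <- unique(cbind(pmin(a, b), pmax(a, b)))
    for (i in seq_along(nodes)) adj[[i]] <- integer()
    if (nrow(und) > 0) {
      nb <- split(c(und[, 2], und[, 1]), c(und[, 1], und[, 2]))
      for (nm in names(nb)) adj[[as.integer(nm)]] <- sort(unique(nb[[nm]]))
    }
  } else {
    for (i in seq_along(nodes)) adj[[i]] <- integer()
  }
  adj
}

# breadth-first order and depths from one origin over the undirected
# projection; unreached nodes get depth NA
bfs_from <- function(adj, origin_idx) {
  n <- length(adj)
  depth <- rep(NA_integer_, n)
  depth[origin_idx] <- 0L
  order_out <- integer(0)
  frontier <- origin_idx
  while (length(frontier) > 0) {
    order_out <- c(order_out, sort(frontier))
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (is.na(depth[w])) {
          depth[w] <- depth[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(order = order_out, depth = depth)
}
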