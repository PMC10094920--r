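#' @rdname infer_graph
#' @param x A `functional_graph`.
#' @param ... Unused.
#' @export
tidy.functional_graph <- function(x, ...) x$edges

#' @rdname infer_graph
#' @export
glance.functional_graph <- function(x, ...) {
  roles <- table(factor(x$nodes$role, levels = c("sender", "receiver", "broker")))
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_edges = nrow(x$edges),
    n_mutual = sum(x$edges$mutual),
    n_senders = as.integer(roles[["sender"]]),
    n_receivers = as.integer(roles[["receiver"]]),
    n_brokers = as.integer(roles[["broker"]]),
    mean_weight = if (nrow(x$edges)) mean(x$edges$weight) else NA_real_,
    mean_abs_lag_ms = if (nrow(x$edges)) mean(abs(x$edges$lag_ms)) else NA_real_
  )
}

#' @rdname compute_cat
#' @param x A `cat_trajectory`.
#' @param ... Unused.
#' @export
tidy.cat_trajectory <- function(x, ...) x$points

#' @rdname compute_cat
#' @export
glance.cat_trajectory <- function(x, ...) x$summary
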