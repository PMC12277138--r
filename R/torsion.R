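#' Analytic-torsion propagation weights for a bipartite graph
#'
#' For every association edge `(u, v)` of the graph, extracts the edge-centered
#' subgraph of order `order_p`, builds its clique complex up to dimension
#' `max_dim_q` and computes the log analytic torsion; likewise for every node's
#' own neighborhood subgraph (the self-loop weight of the propagation rule).
#' Structurally identical neighborhoods receive identical weights, since the
#' torsion depends only on the subgraph's isomorphism class.
#'
#' With `enabled = FALSE` every weight is 1, which reduces the downstream
#' encoders to their standard (unweighted) forms; this is the ablation arm.
#'
#' @param graph A `cda_graph`.
#' @param order_p Subgraph order P (BFS radius, >= 1).
#' @param max_dim_q Complex dimension Q (1 or 2).
#' @param enabled If `FALSE`, skip all computation and return unit weights.
#' @param tol Zero-eigenvalue threshold for the pseudo-determinant.
#' @return An object of class `cda_torsion` with fields `edges` (E x 2 matrix
#'   of global indices, circRNA first), `edge_lt` (log-torsion per edge),
#'   `node_lt` (self log-torsion per node), and the settings used. Use
#'   [tidy()] for a per-edge tibble.
#' @export
torsion_weights <- function(graph, order_p = 1L, max_dim_q = 1L,
                            enabled = TRUE, tol = 1e-8) {
  stopifnot(inherits(graph, "cda_graph"))
  if (!max_dim_q %in% c(1L, 2L)) abort("`max_dim_q` must be 1 or 2.")
  hit <- which(graph$A == 1L, arr.ind = TRUE)
  edges <- cbind(hit[, 1], graph$n_circ + hit[, 2])
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  nn <- n_nodes(graph)

  if (!enabled) {
    return(structure(
      list(edges = edges, edge_lt = rep(1, nrow(edges)),
           node_lt = rep(1, nn), enabled = FALSE,
           order_p = as.integer(order_p), max_dim_q = as.integer(max_dim_q)),
      class = "cda_torsion"
    ))
  }

  edge_lt <- vapply(seq_len(nrow(edges)), function(e) {
    sub <- edge_subgraph(graph, edges[e, 1], edges[e, 2], order_p)
    subgraph_log_torsion(sub, max_dim_q, tol)
  }, numeric(1))
  node_lt <- vapply(seq_len(nn), function(a) {
    sub <- node_subgraph(graph, a, order_p)
    subgraph_log_torsion(sub, max_dim_q, tol)
  }, numeric(1))

  structure(
    list(edges = edges, edge_lt = edge_lt, node_lt = node_lt, enabled = TRUE,
         order_p = as.integer(order_p), max_dim_q = as.integer(max_dim_q)),
    class = "cda_torsion"
  )
}

# Log torsion of a subgraph's clique complex. For a 1-dimensional complex
# (and for any triangle-free subgraph) the non-zero spectrum of Z1 = t(B1) B1
# equals that of the graph Laplacian Z0 = B1 t(B1), so we take the eigenvalues
# of the (usually much smaller) node-indexed Laplacian instead of the
# edge-indexed one. With triangles present under Q = 2 the general route
# through the complex is used.
subgraph_log_torsion <- function(sub, max_dim_q, tol = 1e-8) {
  ne <- if (is.null(sub$edges)) 0L else nrow(sub$edges)
  if (ne == 0) return(0)
  if (max_dim_q >= 2L) {
    cx <- build_complex(sub, max_dim_q)
    if (n_simplices(cx, 2) > 0) return(log_torsion(cx, tol))
  }
  nodes <- sub$nodes
  loc <- match(sub$edges, nodes)
  dim(loc) <- dim(sub$edges)
  n <- length(nodes)
  L <- matrix(0, n, n)
  L[loc] <- -1
  L[loc[, c(2, 1)]] <- -1
  diag(L) <- -rowSums(L) + diag(L)
  0.5 * log(pseudo_determinant(L, tol))
}

#' @describeIn torsion_weights Per-edge log-torsion values as a tibble with
#'   columns `circ_index`, `drug_index`, `log_torsion`.
#' @param x A `cda_torsion` object.
#' @param ... Unused.
#' @method tidy cda_torsion
#' @export
tidy.cda_torsion <- function(x, ...) {
  tibble::tibble(
    circ_index = x$edges[, 1],
    drug_index = x$edges[, 2],
    log_torsion = x$edge_lt
  )
}

#' Per-edge torsion table with node names
#'
#' @param cache A `cda_torsion` from [torsion_weights()].
#' @param graph The `cda_graph` the cache was computed on.
#' @return A tibble with columns `circ_id`, `drug_id`, `log_torsion`, sorted
#'   by `(circ_id, drug_id)`.
#' @export
torsion_table <- function(cache, graph) {
  stopifnot(inherits(cache, "cda_torsion"), inherits(graph, "cda_graph"))
  out <- tibble::tibble(
    circ_id = graph$circ_ids[cache$edges[, 1]],
    drug_id = graph$drug_ids[cache$edges[, 2] - graph$n_circ],
    log_torsion = cache$edge_lt
  )
  dplyr::arrange(out, .data$circ_id, .data$drug_id)
}

#' @export
print.cda_torsion <- function(x, ...) {
  cat(sprintf("<cda_torsion> %d edge weights, %d self weights (P=%d, Q=%d, %s)\n",
              nrow(x$edges), length(x$node_lt), x$order_p, x$max_dim_q,
              ifelse(x$enabled, "torsion on", "torsion off (unit weights)")))
  invisible(x)
}
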