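#' Build the bipartite circRNA-drug graph
#'
#' Constructs the bipartite association graph from a labeled pair table.
#' Positive (label 1) records become edges; label-0 records contribute their
#' ids as isolated-eligible nodes but no edges. Node order is first-appearance
#' order in the table. Nodes carry a global 1-based index: circRNAs occupy
#' `1..N`, drugs `N+1..N+M`.
#'
#' @param table A data frame with columns `circ_id`, `drug_id`, `label`.
#' @param circ_ids,drug_ids Optional explicit node universes (character
#'   vectors); ids in `table` must be a subset. Used to keep a common indexing
#'   across cross-validation folds.
#' @return An object of class `cda_graph` with fields `circ_ids`, `drug_ids`,
#'   `A` (N x M binary matrix), `n_circ`, `n_drug`, and an adjacency list
#'   `adj` over global indices.
#' @export
#' @examples
#' tbl <- tibble::tibble(circ_id = c("c1", "c2"), drug_id = c("d1", "d1"),
#'                       label = c(1L, 0L))
#' g <- cda_graph(tbl)
#' g$A
cda_graph <- function(table, circ_ids = NULL, drug_ids = NULL) {
  stopifnot(all(c("circ_id", "drug_id", "label") %in% names(table)))
  validate_associations(table)
  if (!any(table$label == 1)) {
    abort("Cannot build a graph without any positive (label 1) association.")
  }
  if (is.null(circ_ids)) circ_ids <- unique(table$circ_id)
  if (is.null(drug_ids)) drug_ids <- unique(table$drug_id)
  if (anyDuplicated(circ_ids) || anyDuplicated(drug_ids)) {
    abort("Node id lists must be duplicate-free.")
  }
  if (!all(table$circ_id %in% circ_ids) || !all(table$drug_id %in% drug_ids)) {
    abort("Association table contains ids outside the supplied node universe.")
  }
  n <- length(circ_ids)
  m <- length(drug_ids)
  A <- matrix(0L, n, m, dimnames = list(circ_ids, drug_ids))
  pos <- table[table$label == 1L, ]
  A[cbind(match(pos$circ_id, circ_ids), match(pos$drug_id, drug_ids))] <- 1L

  adj <- vector("list", n + m)
  for (i in seq_len(n)) adj[[i]] <- n + which(A[i, ] == 1L)
  for (j in seq_len(m)) adj[[n + j]] <- which(A[, j] == 1L)

  structure(
    list(circ_ids = circ_ids, drug_ids = drug_ids, A = A,
         n_circ = n, n_drug = m, adj = adj),
    class = "cda_graph"
  )
}

#' @export
print.cda_graph <- function(x, ...) {
  cat(sprintf("<cda_graph> %d circRNAs x %d drugs, %d associations\n",
              x$n_circ, x$n_drug, sum(x$A)))
  invisible(x)
}

n_nodes <- function(graph) graph$n_circ + graph$n_drug

# TRUE for global indices on the circRNA side.
is_circ_index <- function(graph, i) i <= graph$n_circ

#' Node degrees with the self-loop convention
#'
#' Returns, for every node in global-index order, its bipartite degree plus 1.
#' The +1 accounts for the self term of the propagation rule, which sums over
#' a node's neighborhood including the node itself; it also keeps the
#' symmetric normalization well defined for isolated nodes.
#'
#' @param graph A `cda_graph`.
#' @return A numeric vector of length `N + M`.
#' @export
degrees <- function(graph) {
  stopifnot(inherits(graph, "cda_graph"))
  c(rowSums(graph$A), colSums(graph$A)) + 1
}

#' Extract the local subgraph around an association
#'
#' Collects all nodes within BFS distance `order_p` of either endpoint of the
#' edge `(u, v)` and every parent-graph edge with both endpoints inside that
#' set. This edge-centered subgraph is the support of the local simplicial
#' complex whose analytic torsion weights the `(u, v)` message.
#'
#' @param graph A `cda_graph`.
#' @param u,v Global node indices on opposite sides (circRNA, drug in either
#'   order).
#' @param order_p BFS radius P (>= 1).
#' @return A list of class `cda_subgraph` with `center` (the pair), `nodes`
#'   (sorted global indices), `edges` (2-column matrix of global index pairs,
#'   circRNA first), and `order`.
#' @export
edge_subgraph <- function(graph, u, v, order_p = 1L) {
  stopifnot(inherits(graph, "cda_graph"))
  nn <- n_nodes(graph)
  if (!is_count(order_p, 1L)) abort("`order_p` must be an integer >= 1.")
  if (u < 1 || u > nn || v < 1 || v > nn) abort("Node index out of range.")
  if (is_circ_index(graph, u) == is_circ_index(graph, v)) {
    abort("Edge endpoints must lie on opposite sides of the bipartite graph.")
  }
  nodes <- bfs_ball(graph, c(u, v), order_p)
  make_subgraph(graph, nodes, center = c(u, v), order = order_p)
}

#' Extract the local subgraph around a single node
#'
#' Like [edge_subgraph()] but centered on one node; used for the self-loop
#' weight of the propagation rule.
#'
#' @param graph A `cda_graph`.
#' @param a Global node index.
#' @param order_p BFS radius P (>= 1).
#' @return A `cda_subgraph` (see [edge_subgraph()]); `center` has length 1.
#' @export
node_subgraph <- function(graph, a, order_p = 1L) {
  stopifnot(inherits(graph, "cda_graph"))
  if (a < 1 || a > n_nodes(graph)) abort("Node index out of range.")
  if (!is_count(order_p, 1L)) abort("`order_p` must be an integer >= 1.")
  nodes <- bfs_ball(graph, a, order_p)
  make_subgraph(graph, nodes, center = a, order = order_p)
}

# All nodes within BFS distance <= p of any seed node (seeds included).
bfs_ball <- function(graph, seeds, p) {
  seen <- logical(n_nodes(graph))
  seen[seeds] <- TRUE
  frontier <- seeds
  for (step in seq_len(p)) {
    if (length(frontier) == 0) break
    nb <- unique(unlist(graph$adj[frontier], use.names = FALSE))
    frontier <- nb[!seen[nb]]
    seen[frontier] <- TRUE
  }
  sort(which(seen))
}

make_subgraph <- function(graph, nodes, center, order) {
  n <- graph$n_circ
  circ <- nodes[nodes <= n]
  drug <- nodes[nodes > n]
  if (length(circ) > 0 && length(drug) > 0) {
    sub_a <- graph$A[circ, drug - n, drop = FALSE]
    hit <- which(sub_a == 1L, arr.ind = TRUE)
    edges <- cbind(circ[hit[, 1]], drug[hit[, 2]])
  } else {
    edges <- matrix(integer(), 0, 2)
  }
  ord <- order(edges[, 1], edges[, 2])
  structure(
    list(center = center, nodes = nodes,
         edges = edges[ord, , drop = FALSE], order = order),
    class = "cda_subgraph"
  )
}
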