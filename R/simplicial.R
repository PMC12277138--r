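#' Build the oriented clique complex of a subgraph
#'
#' Constructs the simplicial complex whose g-simplices are the (g+1)-cliques
#' of the subgraph, up to dimension `max_dim_q`: 0-simplices are the nodes,
#' 1-simplices the edges and (for `max_dim_q = 2`) 2-simplices the triangles.
#' Simplices are stored as strictly ascending tuples of global node indices,
#' which fixes a consistent orientation; the complex is closed under faces by
#' construction. In a purely bipartite graph no triangles exist, so the
#' 2-dimensional complex coincides with the 1-dimensional one.
#'
#' @param sub A `cda_subgraph` from [edge_subgraph()]/[node_subgraph()], or any
#'   list with `nodes` (integer vector) and `edges` (2-column integer matrix).
#' @param max_dim_q Maximum simplex dimension Q (1 or 2).
#' @return An object of class `cda_complex`: a list with `simplices`, a list
#'   mapping dimension g (as index g+1) to a matrix with g+1 columns whose
#'   rows are the g-simplices, and `max_dim_q`.
#' @export
build_complex <- function(sub, max_dim_q = 1L) {
  if (!max_dim_q %in% c(1L, 2L)) abort("`max_dim_q` must be 1 or 2.")
  nodes <- sort(unique(as.integer(sub$nodes)))
  edges <- sub$edges
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- matrix(integer(), 0, 2)
  } else {
    edges <- cbind(pmin(edges[, 1], edges[, 2]), pmax(edges[, 1], edges[, 2]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
    if (!all(edges %in% nodes)) abort("Edge endpoint outside the node set.")
  }
  simplices <- list(matrix(nodes, ncol = 1), edges)
  if (max_dim_q >= 2L) {
    simplices[[3]] <- enumerate_triangles(nodes, edges)
  }
  structure(list(simplices = simplices, max_dim_q = as.integer(max_dim_q)),
            class = "cda_complex")
}

# All 3-cliques as ascending triples, ordered lexicographically.
enumerate_triangles <- function(nodes, edges) {
  if (nrow(edges) < 3) return(matrix(integer(), 0, 3))
  loc <- match(edges, nodes)
  dim(loc) <- dim(edges)
  n <- length(nodes)
  adj <- matrix(FALSE, n, n)
  adj[loc] <- TRUE
  adj[loc[, c(2, 1)]] <- TRUE
  tri <- list()
  for (e in seq_len(nrow(loc))) {
    a <- loc[e, 1]; b <- loc[e, 2]
    common <- which(adj[a, ] & adj[b, ])
    common <- common[common > b]
    if (length(common) > 0) {
      tri[[length(tri) + 1]] <- cbind(nodes[a], nodes[b], nodes[common])
    }
  }
  if (length(tri) == 0) return(matrix(integer(), 0, 3))
  out <- do.call(rbind, tri)
  out[order(out[, 1], out[, 2], out[, 3]), , drop = FALSE]
}

n_simplices <- function(cx, g) {
  if (g + 1 > length(cx$simplices)) return(0L)
  nrow(cx$simplices[[g + 1]])
}

#' Boundary matrix of a simplicial complex
#'
#' Returns the signed incidence matrix `B_g` between (g-1)-simplices (rows)
#' and g-simplices (columns). The column of a simplex `(v0 < ... < vg)` has
#' entry `(-1)^j` in the row of the face obtained by deleting `vj`, so
#' `B_g %*% B_{g+1}` is identically zero.
#'
#' @param cx A `cda_complex`.
#' @param g Simplex dimension, `1 <= g <= max_dim_q`.
#' @return A numeric matrix of shape (number of (g-1)-simplices) x (number of
#'   g-simplices).
#' @export
boundary_matrix <- function(cx, g) {
  stopifnot(inherits(cx, "cda_complex"))
  if (!is_count(g, 1L) || g > cx$max_dim_q) {
    abort(sprintf("`g` must be an integer in 1..%d.", cx$max_dim_q))
  }
  faces <- cx$simplices[[g]]
  simps <- cx$simplices[[g + 1]]
  B <- matrix(0, nrow(faces), max(nrow(simps), 0L))
  if (nrow(simps) == 0) return(B)
  face_key <- apply(faces, 1, paste, collapse = ",")
  for (j in 0:g) {
    sub <- simps[, -(j + 1), drop = FALSE]
    key <- apply(sub, 1, paste, collapse = ",")
    idx <- match(key, face_key)
    if (anyNA(idx)) abort("Complex is not closed under faces.")
    B[cbind(idx, seq_len(nrow(simps)))] <- (-1)^j
  }
  B
}

#' Hodge Laplacian of a simplicial complex
#'
#' Computes `Z_g = t(B_g) %*% B_g + B_{g+1} %*% t(B_{g+1})`, with the down
#' term absent for g = 0 (`Z_0 = B_1 %*% t(B_1)`, the ordinary graph
#' Laplacian) and the up term absent when no (g+1)-simplices exist (top
#' dimension: `Z_m = t(B_m) %*% B_m`).
#'
#' @param cx A `cda_complex`.
#' @param g Dimension, `0 <= g <= max_dim_q`.
#' @return A symmetric positive semi-definite matrix over the g-simplices.
#' @export
hodge_laplacian <- function(cx, g) {
  stopifnot(inherits(cx, "cda_complex"))
  if (!(is.numeric(g) && length(g) == 1 && g >= 0 && g <= cx$max_dim_q &&
        g == as.integer(g))) {
    abort(sprintf("`g` must be an integer in 0..%d.", cx$max_dim_q))
  }
  ng <- n_simplices(cx, g)
  Z <- matrix(0, ng, ng)
  if (g >= 1) {
    B <- boundary_matrix(cx, g)
    Z <- Z + crossprod(B)            # t(B) %*% B
  }
  if (g + 1 <= cx$max_dim_q && n_simplices(cx, g + 1) > 0) {
    Bup <- boundary_matrix(cx, g + 1)
    Z <- Z + tcrossprod(Bup)         # B %*% t(B)
  }
  Z
}

#' Pseudo-determinant of a positive semi-definite matrix
#'
#' Product of the eigenvalues exceeding a scale-aware cutoff
#' `tol * max(1, lambda_max)`; an all-zero spectrum yields 1 (the empty
#' product). Eigenvalues significantly below zero raise an error, since the
#' Hodge Laplacians this is applied to are PSD by construction.
#'
#' @param Z A symmetric numeric matrix.
#' @param tol Relative zero threshold.
#' @return A positive scalar.
#' @export
pseudo_determinant <- function(Z, tol = 1e-8) {
  if (length(Z) == 0) return(1)
  ev <- eigen(Z, symmetric = TRUE, only.values = TRUE)$values
  scale <- max(1, abs(ev[1]))
  if (any(ev < -1e-6 * scale)) {
    abort("Matrix has a significantly negative eigenvalue; not PSD.")
  }
  keep <- ev[ev > tol * scale]
  if (length(keep) == 0) return(1)
  prod(keep)
}

#' Log analytic torsion of a local complex
#'
#' The analytic torsion of a complex combines the pseudo-determinants of its
#' Hodge Laplacians. In log form, the 1-dimensional complex gives
#' `log T = 1/2 * log |Z_1|` and the 2-dimensional complex
#' `log T = 1/2 * log |Z_1| + log |Z_2|`, where `|.|` denotes the product of
#' non-zero eigenvalues. A complex with no edges has torsion 1, i.e. log
#' torsion 0 (neutral weight).
#'
#' For a connected 1-dimensional complex on n nodes the matrix-tree theorem
#' gives `|Z_1| = n * (number of spanning trees)`, a useful independent check.
#'
#' @param cx A `cda_complex`.
#' @param tol Zero-eigenvalue threshold passed to [pseudo_determinant()].
#' @return A finite scalar, >= 0 for integer graph Laplacians.
#' @export
log_torsion <- function(cx, tol = 1e-8) {
  stopifnot(inherits(cx, "cda_complex"))
  if (n_simplices(cx, 1) == 0) return(0)
  lt <- 0.5 * log(pseudo_determinant(hodge_laplacian(cx, 1), tol))
  if (cx$max_dim_q >= 2 && n_simplices(cx, 2) > 0) {
    lt <- lt + log(pseudo_determinant(hodge_laplacian(cx, 2), tol))
  }
  lt
}
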