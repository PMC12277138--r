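# Random general (not necessarily bipartite) graph for clique-complex tests.
random_graph_edges <- function(n, p, seed) {
  withr::with_seed(seed, {
    pairs <- t(utils::combn(n, 2))
    keep <- runif(nrow(pairs)) < p
    list(nodes = seq_len(n), edges = pairs[keep, , drop = FALSE])
  })
}

test_that("clique complexes are face-closed with correct simplex counts", {
  # single edge
  cx <- build_complex(list(nodes = 1:2, edges = rbind(c(1, 2))), 1)
  expect_equal(nrow(cx$simplices[[1]]), 2L)
  expect_equal(nrow(cx$simplices[[2]]), 1L)

  # triangle graph under Q = 2
  tri <- list(nodes = 1:3, edges = rbind(c(1, 2), c(1, 3), c(2, 3)))
  cx2 <- build_complex(tri, 2)
  expect_equal(nrow(cx2$simplices[[1]]), 3L)
  expect_equal(nrow(cx2$simplices[[2]]), 3L)
  expect_equal(nrow(cx2$simplices[[3]]), 1L)
  expect_equal(unname(cx2$simplices[[3]][1, ]), c(1L, 2L, 3L))

  # bipartite subgraphs have no triangles
  g <- random_bipartite_graph(4, 4, 0.6, seed = 5)
  hit <- which(g$A == 1L, arr.ind = TRUE)
  sub <- edge_subgraph(g, hit[1, 1], g$n_circ + hit[1, 2], 1)
  cxb <- build_complex(sub, 2)
  expect_equal(nrow(cxb$simplices[[3]]), 0L)
})

test_that("boundary matrices carry the alternating sign convention", {
  cx <- build_complex(list(nodes = 1:2, edges = rbind(c(1, 2))), 1)
  expect_equal(unname(boundary_matrix(cx, 1)), matrix(c(-1, 1), 2, 1))

  tri <- build_complex(list(nodes = 1:3,
                            edges = rbind(c(1, 2), c(1, 3), c(2, 3))), 2)
  B2 <- boundary_matrix(tri, 2)
  # edges ordered (1,2), (1,3), (2,3); faces of (1,2,3): +(2,3) -(1,3) +(1,2)
  expect_equal(unname(drop(B2)), c(1, -1, 1))
  expect_error(boundary_matrix(tri, 3), "1..2")
})

test_that("boundary-of-boundary vanishes exactly on random clique complexes", {
  for (seed in 1:25) {
    gr <- random_graph_edges(sample(4:8, 1), 0.5, seed)
    if (nrow(gr$edges) == 0) next
    cx <- build_complex(gr, 2)
    if (nrow(cx$simplices[[3]]) == 0) next
    prod <- boundary_matrix(cx, 1) %*% boundary_matrix(cx, 2)
    expect_true(all(prod == 0))  # exact integer arithmetic
  }
})

test_that("Hodge Laplacians are symmetric PSD and Z0 matches the piecewise form", {
  for (seed in 1:15) {
    gr <- random_graph_edges(sample(4:8, 1), 0.5, seed)
    if (nrow(gr$edges) == 0) next
    cx <- build_complex(gr, 2)
    for (g in 0:2) {
      Z <- hodge_laplacian(cx, g)
      if (length(Z) == 0) next
      expect_equal(Z, t(Z))
      ev <- eigen(Z, symmetric = TRUE, only.values = TRUE)$values
      expect_true(all(ev >= -1e-9))
    }
    # Z0: degree on the diagonal, -1 where two vertices share an edge
    Z0 <- hodge_laplacian(cx, 0)
    n <- length(gr$nodes)
    ref <- matrix(0, n, n)
    for (k in seq_len(nrow(gr$edges))) {
      a <- gr$edges[k, 1]; b <- gr$edges[k, 2]
      ref[a, b] <- ref[b, a] <- -1
    }
    diag(ref) <- -rowSums(ref)
    expect_equal(Z0, ref)
  }
})

test_that("single-edge Laplacians match the worked example", {
  cx <- build_complex(list(nodes = 1:2, edges = rbind(c(1, 2))), 1)
  expect_equal(unname(hodge_laplacian(cx, 0)),
               matrix(c(1, -1, -1, 1), 2, 2))
  expect_equal(unname(hodge_laplacian(cx, 1)), matrix(2))
  # path of 3 nodes: Z1 has diagonal 2 with +/-1 off-diagonal
  px <- build_complex(list(nodes = 1:3, edges = rbind(c(1, 2), c(2, 3))), 1)
  Z1 <- hodge_laplacian(px, 1)
  expect_equal(diag(Z1), c(2, 2))
  expect_equal(abs(Z1[1, 2]), 1)
})

test_that("pseudo-determinant takes the product of non-zero eigenvalues", {
  expect_equal(pseudo_determinant(diag(c(0, 2, 3))), 6)
  expect_equal(pseudo_determinant(matrix(0, 3, 3)), 1)
  # Z0 of a single edge has eigenvalues {0, 2}
  cx <- build_complex(list(nodes = 1:2, edges = rbind(c(1, 2))), 1)
  expect_equal(pseudo_determinant(hodge_laplacian(cx, 0)), 2)
  expect_error(pseudo_determinant(diag(c(-1, 2))), "negative")
})

test_that("log torsion matches closed forms and the matrix-tree theorem", {
  single <- build_complex(list(nodes = 1:2, edges = rbind(c(1, 2))), 1)
  expect_equal(log_torsion(single), 0.5 * log(2), tolerance = 1e-12)

  path3 <- build_complex(list(nodes = 1:3, edges = rbind(c(1, 2), c(2, 3))), 1)
  expect_equal(log_torsion(path3), 0.5 * log(3), tolerance = 1e-12)

  cyc4 <- build_complex(list(nodes = 1:4,
                             edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4))),
                        1)
  expect_equal(log_torsion(cyc4), 0.5 * log(16), tolerance = 1e-12)

  # edgeless complex is neutral
  empty <- build_complex(list(nodes = 1:3, edges = NULL), 1)
  expect_equal(log_torsion(empty), 0)
})

test_that("nonzero spectra of t(B1) B1 and B1 t(B1) agree", {
  for (seed in 1:10) {
    g <- random_bipartite_graph(sample(3:5, 1), sample(3:5, 1), 0.5, seed)
    hit <- which(g$A == 1L, arr.ind = TRUE)
    sub <- edge_subgraph(g, hit[1, 1], g$n_circ + hit[1, 2], 1)
    cx <- build_complex(sub, 1)
    e0 <- eigen(hodge_laplacian(cx, 0), symmetric = TRUE, only.values = TRUE)$values
    e1 <- eigen(hodge_laplacian(cx, 1), symmetric = TRUE, only.values = TRUE)$values
    nz0 <- sort(e0[e0 > 1e-8])
    nz1 <- sort(e1[e1 > 1e-8])
    expect_equal(nz0, nz1, tolerance = 1e-9)
  }
})

test_that("log torsion is invariant under node relabeling", {
  for (seed in 1:8) {
    gr <- random_graph_edges(6, 0.5, seed)
    if (nrow(gr$edges) == 0) next
    base <- log_torsion(build_complex(gr, 2))
    for (rep in 1:5) {
      perm <- withr::with_seed(seed * 100 + rep, sample(100, 6))
      relab <- list(nodes = perm[gr$nodes],
                    edges = matrix(perm[gr$edges], ncol = 2))
      expect_equal(log_torsion(build_complex(relab, 2)), base,
                   tolerance = 1e-9)
    }
  }
})

test_that("torsion weights compose subgraph extraction with the complex", {
  tbl <- tibble::tibble(circ_id = "c1", drug_id = "d1", label = 1L)
  g <- cda_graph(tbl)
  cache <- torsion_weights(g, 1, 1)
  expect_equal(cache$edge_lt, 0.5 * log(2), tolerance = 1e-12)
  # both endpoints' node subgraphs contain the single edge
  expect_equal(cache$node_lt, rep(0.5 * log(2), 2), tolerance = 1e-12)

  # structurally identical edges get identical weights
  two <- tibble::tibble(circ_id = c("a", "b"), drug_id = c("x", "y"),
                        label = 1L)
  c2 <- torsion_weights(cda_graph(two), 1, 1)
  expect_equal(c2$edge_lt[1], c2$edge_lt[2])

  # ablation contract: disabled cache is all ones
  off <- torsion_weights(g, 1, 1, enabled = FALSE)
  expect_equal(off$edge_lt, 1)
  expect_equal(off$node_lt, rep(1, 2))

  # the fast Laplacian route agrees with the complex route on random graphs
  for (seed in 1:6) {
    gr <- random_bipartite_graph(4, 4, 0.5, seed)
    cache <- torsion_weights(gr, 1, 1)
    hit <- which(gr$A == 1L, arr.ind = TRUE)
    for (k in seq_len(min(3, nrow(hit)))) {
      sub <- edge_subgraph(gr, hit[k, 1], gr$n_circ + hit[k, 2], 1)
      via_complex <- log_torsion(build_complex(sub, 1))
      idx <- which(cache$edges[, 1] == hit[k, 1] &
                   cache$edges[, 2] == gr$n_circ + hit[k, 2])
      expect_equal(cache$edge_lt[idx], via_complex, tolerance = 1e-9)
    }
  }
})

test_that("torsion table aligns ids with cached edges", {
  g <- cda_graph(star_table())
  cache <- torsion_weights(g, 1, 1)
  tt <- torsion_table(cache, g)
  expect_equal(nrow(tt), 4L)
  expect_true(all(c("circ_id", "drug_id", "log_torsion") %in% names(tt)))
  expect_true(all(is.finite(tt$log_torsion)))
})
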