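# Independent oracles used across the suite. These deliberately use brute
# force (enumeration, per-node loops) so they share no code path with the
# implementation they check.

# Random connected bipartite graph as a cda_graph, n_left x n_right, keeping
# edges until connected (rejection sampling under the given seed).
random_bipartite_graph <- function(n_left, n_right, p = 0.5, seed = 1) {
  withr::with_seed(seed, {
    repeat {
      A <- matrix(rbinom(n_left * n_right, 1L, p), n_left, n_right)
      if (all(rowSums(A) > 0) && all(colSums(A) > 0) &&
          bipartite_connected(A)) break
    }
    tbl <- as_assoc_table(A)
    cda_graph(tbl)
  })
}

bipartite_connected <- function(A) {
  n <- nrow(A); m <- ncol(A)
  adj <- lapply(seq_len(n + m), function(i) {
    if (i <= n) n + which(A[i, ] == 1L) else which(A[, i - n] == 1L)
  })
  seen <- logical(n + m)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue) > 0) {
    cur <- queue[1]; queue <- queue[-1]
    nb <- adj[[cur]][!seen[adj[[cur]]]]
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

as_assoc_table <- function(A) {
  hit <- which(A == 1L, arr.ind = TRUE)
  tibble::tibble(circ_id = paste0("c", hit[, 1]),
                 drug_id = paste0("d", hit[, 2]),
                 label = 1L)
}

# Brute-force spanning tree count: enumerate all (n-1)-subsets of edges.
count_spanning_trees <- function(nodes, edges) {
  n <- length(nodes)
  ne <- nrow(edges)
  if (n <= 1) return(1L)
  if (ne < n - 1) return(0L)
  combos <- utils::combn(ne, n - 1)
  count <- 0L
  for (k in seq_len(ncol(combos))) {
    sub <- edges[combos[, k], , drop = FALSE]
    if (edges_connect_all(nodes, sub)) count <- count + 1L
  }
  count
}

edges_connect_all <- function(nodes, edges) {
  # union-find over `nodes`
  parent <- seq_along(nodes)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(edges))) {
    a <- find(match(edges[k, 1], nodes))
    b <- find(match(edges[k, 2], nodes))
    if (a != b) parent[a] <- b
  }
  length(unique(vapply(seq_along(nodes), find, integer(1)))) == 1
}

# Breadth-first ball oracle: all nodes within distance p of any seed,
# scanning the full edge list each round.
bfs_ball_oracle <- function(graph, seeds, p) {
  hit <- which(graph$A == 1L, arr.ind = TRUE)
  edges <- cbind(hit[, 1], graph$n_circ + hit[, 2])
  reach <- seeds
  for (step in seq_len(p)) {
    nxt <- c(edges[edges[, 1] %in% reach, 2], edges[edges[, 2] %in% reach, 1])
    reach <- sort(unique(c(reach, nxt)))
  }
  reach
}

# Exhaustive pairwise AUC: mean over all positive-negative pairs with ties
# counted half.
auc_oracle <- function(scores, labels) {
  ps <- scores[labels == 1]
  ns <- scores[labels == 0]
  tot <- 0
  for (p in ps) for (q in ns) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(ps) * length(ns))
}

# Threshold-walking AUPR oracle: at each distinct score threshold, count TP
# and FP directly.
aupr_oracle <- function(scores, labels) {
  np <- sum(labels == 1)
  thr <- sort(unique(scores), decreasing = TRUE)
  prev_rec <- 0
  area <- 0
  for (t in thr) {
    sel <- scores >= t
    tp <- sum(labels[sel] == 1)
    prec <- tp / sum(sel)
    rec <- tp / np
    area <- area + (rec - prev_rec) * prec
    prev_rec <- rec
  }
  area
}

# Per-node loop oracle for one torsion-weighted GCN layer.
gcn_layer_oracle <- function(h_prev, graph, cache, w, sigmoid = TRUE) {
  nn <- nrow(h_prev)
  d <- torsioncda::degrees(graph)
  wt <- matrix(0, nn, nn)
  for (k in seq_len(nrow(cache$edges))) {
    e <- cache$edges[k, ]
    wt[e[1], e[2]] <- wt[e[2], e[1]] <- cache$edge_lt[k]
  }
  diag(wt) <- cache$node_lt
  out <- matrix(0, nn, ncol(w))
  for (a in seq_len(nn)) {
    acc <- numeric(ncol(w))
    for (b in seq_len(nn)) {
      if (wt[a, b] != 0 || b == a) {
        nbr <- b == a || wt[a, b] != 0
        if (nbr) {
          acc <- acc + (wt[a, b] / sqrt(d[a] * d[b])) *
            drop(h_prev[b, ] %*% w)
        }
      }
    }
    out[a, ] <- if (sigmoid) 1 / (1 + exp(-acc)) else acc
  }
  out
}

# Per-node loop oracle for one torsion-weighted GIN layer.
gin_layer_oracle <- function(h_prev, graph, cache, params) {
  nn <- nrow(h_prev)
  wt <- matrix(0, nn, nn)
  for (k in seq_len(nrow(cache$edges))) {
    e <- cache$edges[k, ]
    wt[e[1], e[2]] <- wt[e[2], e[1]] <- cache$edge_lt[k]
  }
  out <- matrix(0, nn, ncol(params$w1))
  for (a in seq_len(nn)) {
    agg <- (1 + params$eps) * h_prev[a, ]
    for (b in seq_len(nn)) {
      if (wt[a, b] != 0) agg <- agg + wt[a, b] * h_prev[b, ]
    }
    z1 <- drop(agg %*% params$w1)
    out[a, ] <- drop(pmax(z1, 0) %*% params$w2)
  }
  out
}

# Per-node loop oracle for one torsion-biased GAT layer.
gat_layer_oracle <- function(h_prev, graph, cache, params, sigmoid = TRUE) {
  nn <- nrow(h_prev)
  wt <- matrix(NA_real_, nn, nn)
  for (k in seq_len(nrow(cache$edges))) {
    e <- cache$edges[k, ]
    wt[e[1], e[2]] <- wt[e[2], e[1]] <- cache$edge_lt[k]
  }
  diag(wt) <- cache$node_lt
  Z <- h_prev %*% params$w
  lrelu <- function(x) ifelse(x > 0, x, 0.2 * x)
  out <- matrix(0, nn, ncol(Z))
  for (a in seq_len(nn)) {
    nbrs <- which(!is.na(wt[a, ]))
    logit <- vapply(nbrs, function(b) {
      lrelu(sum(params$a_l * Z[a, ]) + sum(params$a_r * Z[b, ])) + wt[a, b]
    }, numeric(1))
    alpha <- exp(logit - max(logit))
    alpha <- alpha / sum(alpha)
    acc <- numeric(ncol(Z))
    for (j in seq_along(nbrs)) acc <- acc + alpha[j] * Z[nbrs[j], ]
    out[a, ] <- if (sigmoid) 1 / (1 + exp(-acc)) else acc
  }
  out
}

# A tiny deterministic fixture: star circRNA c1 linked to d1..d3, plus c2-d1.
star_table <- function() {
  tibble::tibble(
    circ_id = c("c1", "c1", "c1", "c2"),
    drug_id = c("d1", "d2", "d3", "d1"),
    label = 1L
  )
}
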