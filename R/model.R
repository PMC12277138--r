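#' Torsion-weighted propagation matrix
#'
#' Builds the dense `(N+M) x (N+M)` propagation operator
#' `P[a, b] = w(a, b) / sqrt(d_a * d_b)` for `b` in `N(a) U {a}` and 0
#' elsewhere, where `w` is the cached log-torsion of the `(a, b)` edge
#' subgraph (self log-torsion on the diagonal) and `d` the degree-plus-one
#' convention of [degrees()]. With a disabled cache (`w == 1`) this is exactly
#' the symmetric-normalized adjacency with self-loops,
#' `D^{-1/2} (A + I) D^{-1/2}`.
#'
#' @param graph A `cda_graph`.
#' @param cache A `cda_torsion` from [torsion_weights()] on the same graph.
#' @return A symmetric numeric matrix.
#' @export
propagation_matrix <- function(graph, cache) {
  stopifnot(inherits(graph, "cda_graph"), inherits(cache, "cda_torsion"))
  nn <- n_nodes(graph)
  d <- unname(degrees(graph))
  W <- matrix(0, nn, nn)
  if (nrow(cache$edges) > 0) {
    W[cache$edges] <- cache$edge_lt
    W[cache$edges[, c(2, 1), drop = FALSE]] <- cache$edge_lt
  }
  diag(W) <- cache$node_lt
  W / sqrt(outer(d, d))
}

# Weighted adjacency without self-loops or normalization (GIN aggregation).
weighted_adjacency <- function(graph, cache) {
  nn <- n_nodes(graph)
  W <- matrix(0, nn, nn)
  if (nrow(cache$edges) > 0) {
    W[cache$edges] <- cache$edge_lt
    W[cache$edges[, c(2, 1), drop = FALSE]] <- cache$edge_lt
  }
  W
}

# Directed edge arrays (both directions plus self-loops) with torsion biases;
# used by the attention encoder.
attention_edges <- function(graph, cache) {
  e <- cache$edges
  src <- c(e[, 2], e[, 1], seq_len(n_nodes(graph)))
  dst <- c(e[, 1], e[, 2], seq_len(n_nodes(graph)))
  bias <- c(cache$edge_lt, cache$edge_lt, cache$node_lt)
  list(center = dst, nbr = src, bias = bias)
}

act_fun <- function(activation) {
  switch(activation,
         sigmoid = function(z) 1 / (1 + exp(-z)),
         identity = function(z) z,
         abort("Unknown activation."))
}

#' One torsion-weighted GCN layer
#'
#' Computes `act(P %*% H_prev %*% W)` where `P` is the torsion-weighted
#' symmetric-normalized propagation matrix of [propagation_matrix()]. The
#' update uses a sigmoid activation inside every layer; `activation
#' = "identity"` is a test hook that exposes the bare linear propagation.
#'
#' @param h_prev Input representation matrix, `(N+M) x d_in`.
#' @param graph A `cda_graph`.
#' @param cache A `cda_torsion` for the same graph (disabled cache = plain
#'   GCN propagation).
#' @param w Weight matrix `d_in x d_out`.
#' @param activation `"sigmoid"` (default) or `"identity"`.
#' @return The next representation matrix, `(N+M) x d_out`.
#' @export
torsion_gcn_layer <- function(h_prev, graph, cache, w,
                              activation = c("sigmoid", "identity")) {
  activation <- match.arg(activation)
  if (ncol(h_prev) != nrow(w)) abort("Feature/weight dimension mismatch.")
  P <- propagation_matrix(graph, cache)
  act_fun(activation)(P %*% h_prev %*% w)
}

#' One torsion-biased GAT layer
#'
#' Single-head attention over `N(a) U {a}` where the log-torsion of each edge
#' subgraph enters as an additive bias on the attention logit before the
#' softmax. With a disabled cache every bias is the constant 1, which cancels
#' in the softmax, recovering plain attention. Logits are
#' `leakyrelu(a_l . Wh_a + a_r . Wh_b) + bias(a, b)` with negative slope 0.2.
#'
#' @param h_prev Input representation matrix.
#' @param graph A `cda_graph`.
#' @param cache A `cda_torsion`.
#' @param params List with `w` (`d_in x d_out`), `a_l`, `a_r` (length
#'   `d_out`).
#' @param activation `"sigmoid"` (default) or `"identity"`.
#' @param return_attention If `TRUE`, attach the per-edge attention weights as
#'   attribute `"attention"` (a list with `center`, `nbr`, `alpha`).
#' @return The next representation matrix.
#' @export
torsion_gat_layer <- function(h_prev, graph, cache, params,
                              activation = c("sigmoid", "identity"),
                              return_attention = FALSE) {
  activation <- match.arg(activation)
  if (ncol(h_prev) != nrow(params$w)) abort("Feature/weight dimension mismatch.")
  ed <- attention_edges(graph, cache)
  Zm <- h_prev %*% params$w
  sL <- drop(Zm %*% params$a_l)
  sR <- drop(Zm %*% params$a_r)
  raw <- sL[ed$center] + sR[ed$nbr]
  logits <- ifelse(raw > 0, raw, 0.2 * raw) + ed$bias
  alpha <- edge_softmax(logits, ed$center, n_nodes(graph))
  agg <- index_rowsum(alpha * Zm[ed$nbr, , drop = FALSE], ed$center,
                      n_nodes(graph))
  out <- act_fun(activation)(agg)
  if (return_attention) {
    attr(out, "attention") <- list(center = ed$center, nbr = ed$nbr,
                                   alpha = alpha)
  }
  out
}

#' One torsion-weighted GIN layer
#'
#' Sum aggregation with torsion-scaled neighbor contributions:
#' `MLP((1 + eps) * h_a + sum_b w(a, b) * h_b)`, where the MLP is
#' linear-ReLU-linear. With a disabled cache (`w == 1`) and `eps = 0` this is
#' the standard GIN update.
#'
#' @param h_prev Input representation matrix.
#' @param graph A `cda_graph`.
#' @param cache A `cda_torsion`.
#' @param params List with `w1` (`d_in x d_out`), `w2` (`d_out x d_out`) and
#'   scalar `eps`.
#' @return The next representation matrix.
#' @export
torsion_gin_layer <- function(h_prev, graph, cache, params) {
  if (ncol(h_prev) != nrow(params$w1)) abort("Feature/weight dimension mismatch.")
  Pw <- weighted_adjacency(graph, cache)
  agg <- (1 + params$eps) * h_prev + Pw %*% h_prev
  z1 <- agg %*% params$w1
  pmax(z1, 0) %*% params$w2
}

# Group-wise softmax over edges sharing a center node.
edge_softmax <- function(logits, center, n) {
  mx <- rep(-Inf, n)
  mx_by <- tapply(logits, center, max)
  mx[as.integer(names(mx_by))] <- mx_by
  w <- exp(logits - mx[center])
  s <- numeric(n)
  s_by <- tapply(w, center, sum)
  s[as.integer(names(s_by))] <- s_by
  w / s[center]
}

# rowsum() into a fixed number of rows, tolerating absent groups.
index_rowsum <- function(mat, idx, n) {
  out <- matrix(0, n, ncol(mat))
  rs <- rowsum(mat, idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

#' Encode node representations with stacked torsion-weighted layers
#'
#' Applies `config$layers` layers of the configured encoder (GCN, GAT or GIN)
#' to the initial features. Widths chain `d_in -> hidden_dim -> ... ->
#' out_dim`.
#'
#' @param h0 Initial feature matrix `(N+M) x d_in`.
#' @param graph A `cda_graph`.
#' @param cache A `cda_torsion`.
#' @param config A `cda_config`.
#' @param params Encoder parameters from [init_params()] (the `$encoder`
#'   component).
#' @return The final representation matrix `(N+M) x out_dim`.
#' @export
encode <- function(h0, graph, cache, config, params) {
  H <- h0
  for (i in seq_len(config$layers)) {
    H <- switch(config$encoder,
      gcn = torsion_gcn_layer(H, graph, cache, params[[i]]$w),
      gat = torsion_gat_layer(H, graph, cache, params[[i]]),
      gin = torsion_gin_layer(H, graph, cache, params[[i]]))
  }
  H
}

#' Score circRNA-drug pairs with the MLP decoder
#'
#' For each pair the decoder input is the concatenation of the elementwise
#' sum, the Hadamard product, and both embeddings, total length `4 d`; the
#' MLP maps `4d -> d -> d/2 -> 1` with ReLU hidden activations and a sigmoid
#' output, so scores lie in (0, 1). Prediction always uses (circRNA, drug)
#' order: the final concatenation block is order-sensitive.
#'
#' @param h_u,h_v Embedding matrices with one row per pair (or single
#'   vectors).
#' @param dec Decoder parameters from [init_params()] (the `$decoder`
#'   component).
#' @return A numeric vector of probabilities.
#' @export
decode_pair <- function(h_u, h_v, dec) {
  if (is.null(dim(h_u))) h_u <- matrix(h_u, 1)
  if (is.null(dim(h_v))) h_v <- matrix(h_v, 1)
  if (!all(dim(h_u) == dim(h_v))) abort("Embedding dimension mismatch.")
  X <- cbind(h_u + h_v, h_u * h_v, h_u, h_v)
  decoder_forward(X, dec)$p
}

decoder_forward <- function(X, dec) {
  Z1 <- sweep(X %*% dec$w1, 2, dec$b1, "+")
  R1 <- pmax(Z1, 0)
  Z2 <- sweep(R1 %*% dec$w2, 2, dec$b2, "+")
  R2 <- pmax(Z2, 0)
  z3 <- drop(R2 %*% dec$w3) + dec$b3
  list(X = X, Z1 = Z1, R1 = R1, Z2 = Z2, R2 = R2, z3 = z3,
       p = 1 / (1 + exp(-z3)))
}

#' Binary cross-entropy loss
#'
#' Mean of `-(y * log(p) + (1 - y) * log(1 - p))`.
#'
#' @param preds Predicted probabilities in (0, 1).
#' @param labels 0/1 labels of the same length.
#' @return A non-negative scalar.
#' @export
bce_loss <- function(preds, labels) {
  if (length(preds) == 0) abort("Empty prediction vector.")
  if (length(preds) != length(labels)) abort("preds/labels length mismatch.")
  if (any(preds <= 0 | preds >= 1)) abort("Predictions must lie in (0, 1).")
  if (!all(labels %in% c(0, 1))) abort("Labels must be 0/1.")
  -mean(labels * log(preds) + (1 - labels) * log(1 - preds))
}
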