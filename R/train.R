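# Hand-authored training engine: full-batch forward/backward passes for the
# three torsion-weighted encoders plus the MLP pair decoder, optimized with
# Adam. Gradients are verified against finite differences in the test suite.

glorot <- function(nr, nc) {
  limit <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -limit, limit), nr, nc)
}

#' Initialize model parameters
#'
#' Glorot-uniform initialization of every weight matrix under the given seed;
#' biases start at zero, GIN epsilons at zero.
#'
#' @param config A `cda_config`.
#' @param d_in Input feature dimension.
#' @param seed Integer seed.
#' @return A list with components `encoder` (per-layer parameter lists) and
#'   `decoder` (MLP weights `4d -> d -> d/2 -> 1`).
#' @export
init_params <- function(config, d_in, seed = config$seed) {
  dims <- c(d_in,
            rep(config$hidden_dim, max(config$layers - 1L, 0L)),
            config$out_dim)
  with_seed(seed, {
    enc <- lapply(seq_len(config$layers), function(i) {
      di <- dims[i]; do <- dims[i + 1]
      switch(config$encoder,
        gcn = list(w = glorot(di, do)),
        gat = list(w = glorot(di, do),
                   a_l = drop(glorot(do, 1)), a_r = drop(glorot(do, 1))),
        gin = list(w1 = glorot(di, do), w2 = glorot(do, do), eps = 0))
    })
    d <- config$out_dim
    d2 <- max(1L, d %/% 2L)
    # hidden biases start slightly positive so no ReLU unit is dead at
    # initialization (an all-dead layer freezes full-batch training)
    dec <- list(w1 = glorot(4L * d, d), b1 = rep(0.01, d),
                w2 = glorot(d, d2), b2 = rep(0.01, d2),
                w3 = glorot(d2, 1), b3 = 0)
    list(encoder = enc, decoder = dec)
  })
}

# Precomputed propagation context reused across epochs.
build_train_context <- function(graph, cache, config, h0) {
  ctx <- list(graph = graph, config = config, h0 = h0, nn = n_nodes(graph))
  if (config$encoder == "gcn") {
    ctx$P <- propagation_matrix(graph, cache)
    ctx$Ph0 <- ctx$P %*% h0
  } else if (config$encoder == "gin") {
    ctx$Pw <- weighted_adjacency(graph, cache)
    ctx$Pwh0 <- ctx$Pw %*% h0
  } else {
    ctx$ed <- attention_edges(graph, cache)
  }
  ctx
}

sigmoid <- function(z) 1 / (1 + exp(-z))

encoder_forward <- function(params, ctx) {
  cfg <- ctx$config
  H <- ctx$h0
  caches <- vector("list", cfg$layers)
  for (i in seq_len(cfg$layers)) {
    p <- params$encoder[[i]]
    if (cfg$encoder == "gcn") {
      PH <- if (i == 1) ctx$Ph0 else ctx$P %*% H
      Hn <- sigmoid(PH %*% p$w)
      caches[[i]] <- list(PH = PH, H = Hn)
    } else if (cfg$encoder == "gin") {
      PwH <- if (i == 1) ctx$Pwh0 else ctx$Pw %*% H
      A <- (1 + p$eps) * H + PwH
      Z1 <- A %*% p$w1
      R <- pmax(Z1, 0)
      Hn <- R %*% p$w2
      caches[[i]] <- list(Hin = H, A = A, Z1 = Z1, R = R, H = Hn)
    } else {
      Zm <- H %*% p$w
      sL <- drop(Zm %*% p$a_l)
      sR <- drop(Zm %*% p$a_r)
      raw <- sL[ctx$ed$center] + sR[ctx$ed$nbr]
      logits <- ifelse(raw > 0, raw, 0.2 * raw) + ctx$ed$bias
      alpha <- edge_softmax(logits, ctx$ed$center, ctx$nn)
      agg <- index_rowsum(alpha * Zm[ctx$ed$nbr, , drop = FALSE],
                          ctx$ed$center, ctx$nn)
      Hn <- sigmoid(agg)
      caches[[i]] <- list(Hin = H, Zm = Zm, raw = raw, alpha = alpha, H = Hn)
    }
    H <- caches[[i]]$H
  }
  list(H = H, caches = caches)
}

index_sum <- function(vals, idx, n) {
  out <- numeric(n)
  s <- tapply(vals, idx, sum)
  out[as.integer(names(s))] <- s
  out
}

encoder_backward <- function(params, ctx, caches, dH) {
  cfg <- ctx$config
  grads <- vector("list", cfg$layers)
  for (i in rev(seq_len(cfg$layers))) {
    p <- params$encoder[[i]]
    ch <- caches[[i]]
    if (cfg$encoder == "gcn") {
      dZ <- dH * ch$H * (1 - ch$H)
      grads[[i]] <- list(w = crossprod(ch$PH, dZ))
      if (i > 1) dH <- ctx$P %*% (dZ %*% t(p$w))
    } else if (cfg$encoder == "gin") {
      dW2 <- crossprod(ch$R, dH)
      dR <- dH %*% t(p$w2)
      dZ1 <- dR * (ch$Z1 > 0)
      dW1 <- crossprod(ch$A, dZ1)
      dA <- dZ1 %*% t(p$w1)
      grads[[i]] <- list(w1 = dW1, w2 = dW2, eps = sum(dA * ch$Hin))
      if (i > 1) dH <- (1 + p$eps) * dA + ctx$Pw %*% dA
    } else {
      ed <- ctx$ed
      dAgg <- dH * ch$H * (1 - ch$H)
      dAgg_c <- dAgg[ed$center, , drop = FALSE]
      Zm_n <- ch$Zm[ed$nbr, , drop = FALSE]
      dalpha <- rowSums(dAgg_c * Zm_n)
      dZm <- index_rowsum(ch$alpha * dAgg_c, ed$nbr, ctx$nn)
      Sdot <- index_sum(ch$alpha * dalpha, ed$center, ctx$nn)
      de <- ch$alpha * (dalpha - Sdot[ed$center])
      draw <- de * ifelse(ch$raw > 0, 1, 0.2)
      dsL <- index_sum(draw, ed$center, ctx$nn)
      dsR <- index_sum(draw, ed$nbr, ctx$nn)
      dZm <- dZm + outer(dsL, p$a_l) + outer(dsR, p$a_r)
      grads[[i]] <- list(w = crossprod(ch$Hin, dZm),
                         a_l = drop(crossprod(ch$Zm, dsL)),
                         a_r = drop(crossprod(ch$Zm, dsR)))
      if (i > 1) dH <- dZm %*% t(p$w)
    }
  }
  grads
}

# Full model pass over a set of (u, v) index pairs; returns probabilities,
# loss and (optionally) gradients for all parameters.
model_pass <- function(params, ctx, u, v, y, want_grads = TRUE) {
  enc <- encoder_forward(params, ctx)
  H <- enc$H
  Hu <- H[u, , drop = FALSE]
  Hv <- H[v, , drop = FALSE]
  X <- cbind(Hu + Hv, Hu * Hv, Hu, Hv)
  fw <- decoder_forward(X, params$decoder)
  eps <- 1e-12
  p <- pmin(pmax(fw$p, eps), 1 - eps)
  loss <- -mean(y * log(p) + (1 - y) * log(1 - p))
  if (!want_grads) return(list(p = fw$p, loss = loss))

  n_pairs <- length(u)
  dlogit <- (p - y) / n_pairs
  dec <- params$decoder
  db3 <- sum(dlogit)
  dw3 <- crossprod(fw$R2, dlogit)
  dR2 <- dlogit %*% t(dec$w3)
  dZ2 <- dR2 * (fw$Z2 > 0)
  dw2 <- crossprod(fw$R1, dZ2)
  db2 <- colSums(dZ2)
  dR1 <- dZ2 %*% t(dec$w2)
  dZ1 <- dR1 * (fw$Z1 > 0)
  dw1 <- crossprod(fw$X, dZ1)
  db1 <- colSums(dZ1)
  dX <- dZ1 %*% t(dec$w1)

  d <- ncol(H)
  dSum <- dX[, seq_len(d), drop = FALSE]
  dProd <- dX[, d + seq_len(d), drop = FALSE]
  dU <- dX[, 2 * d + seq_len(d), drop = FALSE]
  dV <- dX[, 3 * d + seq_len(d), drop = FALSE]
  dHu <- dSum + Hv * dProd + dU
  dHv <- dSum + Hu * dProd + dV
  dH <- index_rowsum(rbind(dHu, dHv), c(u, v), ctx$nn)

  grads <- list(
    encoder = encoder_backward(params, ctx, enc$caches, dH),
    decoder = list(w1 = dw1, b1 = db1, w2 = dw2, b2 = db2,
                   w3 = dw3, b3 = db3)
  )
  list(p = fw$p, loss = loss, grads = grads)
}

adam_init <- function(theta) {
  list(m = numeric(length(theta)), v = numeric(length(theta)), t = 0L)
}

adam_step <- function(theta, grad, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

# Core optimization loop: full-batch Adam, optionally with early stopping on
# explicit validation pairs (whose positive edges are absent from the graph
# behind `ctx`). Returns the best parameters and the per-epoch loss trace.
fit_model <- function(params, ctx, u, v, y, config, val = NULL) {
  tr <- seq_along(u)
  has_val <- !is.null(val) && length(val$u) >= 2 &&
    length(unique(val$y)) == 2

  theta <- unlist(params)
  skeleton <- params
  state <- adam_init(theta)
  best_theta <- theta
  best_val <- -Inf
  since_best <- 0
  trace <- numeric(0)

  for (epoch in seq_len(config$epochs)) {
    params_now <- relist(theta, skeleton)
    pass <- model_pass(params_now, ctx, u[tr], v[tr], y[tr], want_grads = TRUE)
    trace[epoch] <- pass$loss
    grad <- unlist(pass$grads)
    upd <- adam_step(theta, grad, state, config$lr)
    theta <- upd$theta
    state <- upd$state

    if (has_val) {
      # model selection on validation AUC: more robust than validation loss,
      # whose minimum can precede the best ranking by many epochs
      params_now <- relist(theta, skeleton)
      vp <- model_pass(params_now, ctx, val$u, val$v, val$y,
                       want_grads = FALSE)$p
      vauc <- evaluate(vp, val$y)$auc
      if (vauc > best_val + 1e-9) {
        best_val <- vauc
        best_theta <- theta
        since_best <- 0
      } else {
        since_best <- since_best + 1
        if (since_best >= config$patience && epoch >= config$min_epochs) break
      }
    } else {
      best_theta <- theta
    }
  }
  list(params = relist(best_theta, skeleton), trace = trace)
}
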