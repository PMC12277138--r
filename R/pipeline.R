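#' Sample negative circRNA-drug pairs
#'
#' Draws `n` distinct unobserved (zero-entry) pairs uniformly without
#' replacement from the biadjacency matrix, reproducibly under `seed`.
#' Negatives are sampled once per run, not per epoch, mirroring the balanced
#' sampling protocol of the method.
#'
#' @param graph A `cda_graph`.
#' @param n Number of negatives; at most the number of zero entries.
#' @param seed Integer seed.
#' @return A tibble with columns `circ_id`, `drug_id`, `label` (all 0).
#' @export
sample_negatives <- function(graph, n, seed = 1L) {
  stopifnot(inherits(graph, "cda_graph"))
  zeros <- which(graph$A == 0L)
  if (n > length(zeros)) {
    abort(sprintf("Requested %d negatives but only %d unobserved pairs exist.",
                  n, length(zeros)))
  }
  pick <- with_seed(seed, sample(zeros, n))
  ri <- ((pick - 1) %% graph$n_circ) + 1
  ci <- ((pick - 1) %/% graph$n_circ) + 1
  tibble::tibble(circ_id = graph$circ_ids[ri], drug_id = graph$drug_ids[ci],
                 label = 0L)
}

#' Stratified k-fold split of positive and negative pairs
#'
#' Shuffles positives and negatives independently under `seed` and partitions
#' each into `k` near-equal test sets; the training side of each fold is the
#' complement. Test sets are disjoint and jointly cover every pair exactly
#' once.
#'
#' @param pos,neg Tibbles of pairs (columns `circ_id`, `drug_id`).
#' @param k Number of folds (>= 2, <= number of positives and negatives).
#' @param seed Integer seed.
#' @return A list of `k` fold objects, each a list with `fold_id`,
#'   `train_pos`, `train_neg`, `test_pos`, `test_neg`.
#' @export
kfold_split <- function(pos, neg, k = 5L, seed = 1L) {
  if (!is_count(k, 2L)) abort("`k` must be an integer >= 2.")
  if (nrow(pos) < k) abort("More folds than positive pairs.")
  if (nrow(neg) < k) abort("More folds than negative pairs.")
  assign_folds <- function(n, off) {
    with_seed(seed + off, sample(rep_len(seq_len(k), n)))
  }
  fp <- assign_folds(nrow(pos), 0L)
  fn <- assign_folds(nrow(neg), 1L)
  lapply(seq_len(k), function(i) {
    list(fold_id = i,
         train_pos = pos[fp != i, , drop = FALSE],
         train_neg = neg[fn != i, , drop = FALSE],
         test_pos = pos[fp == i, , drop = FALSE],
         test_neg = neg[fn == i, , drop = FALSE])
  })
}

# Map (circ_id, drug_id) pairs to global indices of `graph`.
pair_indices <- function(graph, pairs) {
  u <- match(pairs$circ_id, graph$circ_ids)
  v <- match(pairs$drug_id, graph$drug_ids)
  if (anyNA(u) || anyNA(v)) abort("Pair references an unknown node id.")
  list(u = u, v = graph$n_circ + v)
}

#' Train on one cross-validation fold and evaluate held-out pairs
#'
#' Builds the training graph from the fold's positive training edges only
#' (test edges never touch the graph, the torsion cache or the
#' adjacency-derived features), computes torsion weights, trains the encoder
#' plus decoder by full-batch Adam on binary cross-entropy, and scores the
#' held-out pairs.
#'
#' @param split One fold from [kfold_split()].
#' @param table The full association table (defines the node universe shared
#'   across folds).
#' @param config A `cda_config`.
#' @param extras Optional list with `sequences` and/or `smiles` for
#'   similarity features.
#' @return A list of class `cda_fit` with the trained `params`, held-out
#'   `metrics` (one-row tibble), the training `graph`, torsion `cache`,
#'   feature matrix `h0`, embeddings `H`, loss `trace` and `config`.
#' @export
train_fold <- function(split, table, config, extras = list()) {
  if (nrow(split$train_pos) == 0) abort("No positive training edges.")
  fold_seed <- config$seed + (split$fold_id %||% 0L)
  circ_ids <- unique(table$circ_id)
  drug_ids <- unique(table$drug_id)

  # Early-stopping split: validation pairs are carved from the training pairs
  # and their positive edges are withheld from the message-passing graph, so
  # validation loss is measured under the same conditions as the test side.
  n_vp <- floor(config$val_fraction * nrow(split$train_pos))
  n_vn <- floor(config$val_fraction * nrow(split$train_neg))
  vp <- with_seed(fold_seed + 10007L,
                  sample.int(nrow(split$train_pos), n_vp))
  vn <- with_seed(fold_seed + 10009L,
                  sample.int(nrow(split$train_neg), n_vn))
  use_val <- n_vp >= 1 && n_vn >= 1 && nrow(split$train_pos) - n_vp >= 1
  fit_pos <- if (use_val) split$train_pos[-vp, , drop = FALSE] else split$train_pos
  fit_neg <- if (use_val) split$train_neg[-vn, , drop = FALSE] else split$train_neg

  graph <- cda_graph(dplyr::mutate(fit_pos, label = 1L),
                     circ_ids = circ_ids, drug_ids = drug_ids)
  cache <- torsion_weights(graph, config$order_p, config$max_dim_q,
                           enabled = config$torsion_enabled)
  h0 <- build_features(graph, config, extras)
  ctx <- build_train_context(graph, cache, config, h0)

  train_pairs <- dplyr::bind_rows(
    dplyr::mutate(fit_pos, label = 1L),
    dplyr::mutate(fit_neg, label = 0L))
  ti <- pair_indices(graph, train_pairs)
  val <- NULL
  if (use_val) {
    val_pairs <- dplyr::bind_rows(
      dplyr::mutate(split$train_pos[vp, , drop = FALSE], label = 1L),
      dplyr::mutate(split$train_neg[vn, , drop = FALSE], label = 0L))
    vi <- pair_indices(graph, val_pairs)
    val <- list(u = vi$u, v = vi$v, y = val_pairs$label)
  }
  params0 <- init_params(config, ncol(h0), seed = fold_seed)
  fit <- fit_model(params0, ctx, ti$u, ti$v, train_pairs$label, config,
                   val = val)

  H <- encoder_forward(fit$params, ctx)$H
  test_pairs <- dplyr::bind_rows(
    dplyr::mutate(split$test_pos, label = 1L),
    dplyr::mutate(split$test_neg, label = 0L))
  metrics <- NULL
  scores <- NULL
  if (nrow(test_pairs) > 0) {
    si <- pair_indices(graph, test_pairs)
    scores <- decode_pair(H[si$u, , drop = FALSE], H[si$v, , drop = FALSE],
                          fit$params$decoder)
    metrics <- evaluate(scores, test_pairs$label)
  }
  structure(
    list(params = fit$params, metrics = metrics, graph = graph, cache = cache,
         h0 = h0, H = H, trace = fit$trace, config = config,
         test_scores = scores, test_pairs = test_pairs,
         fold_id = split$fold_id %||% NA_integer_),
    class = "cda_fit"
  )
}

#' Cross-validated association prediction
#'
#' The main entry point: takes a labeled association table, balances it with
#' uniformly sampled negatives if none are supplied, splits positives and
#' negatives into `config$folds` stratified folds, trains a torsion-weighted
#' model on each fold's training side and evaluates on its held-out side.
#'
#' @param table Association tibble (columns `circ_id`, `drug_id`, `label`).
#'   If it contains no label-0 rows, one negative per positive is sampled.
#' @param config A `cda_config`.
#' @param extras Optional list with `sequences` / `smiles` for similarity
#'   features.
#' @return An object of class `cda_cv` with per-fold fits and metrics. Use
#'   [tidy()] for per-fold metrics, [glance()] for mean and SD, and
#'   [autoplot()] for a metric overview plot.
#' @export
#' @examples
#' \donttest{
#' tbl <- generate_block_model(block_model_spec(30, 24, n_blocks = 2,
#'                                              p_in = 0.5, p_out = 0.05))
#' cv <- cda_cv(tbl, cda_config(folds = 2, epochs = 30, hidden_dim = 16,
#'                              out_dim = 8))
#' glance(cv)
#' }
cda_cv <- function(table, config = cda_config(), extras = list()) {
  validate_associations(table)
  pos <- table[table$label == 1L, c("circ_id", "drug_id")]
  neg <- table[table$label == 0L, c("circ_id", "drug_id")]
  if (nrow(neg) == 0) {
    full_graph <- cda_graph(table)
    neg <- sample_negatives(full_graph, nrow(pos),
                            seed = config$seed)[, c("circ_id", "drug_id")]
  }
  splits <- kfold_split(pos, neg, config$folds, config$seed)
  fits <- lapply(splits, train_fold, table = table, config = config,
                 extras = extras)
  metrics <- dplyr::bind_rows(lapply(fits, function(f) f$metrics))
  metrics <- dplyr::mutate(metrics, fold = dplyr::row_number(),
                           .before = 1)
  structure(list(fits = fits, metrics = metrics, config = config),
            class = "cda_cv")
}

#' Train a final model on the full table
#'
#' Trains one model on every labeled pair (sampling balanced negatives if the
#' table has none); no held-out evaluation. Used for candidate ranking and
#' the command-line `train`/`predict` workflow.
#'
#' @inheritParams cda_cv
#' @return A `cda_fit` (with `metrics = NULL`).
#' @export
cda_train <- function(table, config = cda_config(), extras = list()) {
  validate_associations(table)
  pos <- table[table$label == 1L, c("circ_id", "drug_id")]
  neg <- table[table$label == 0L, c("circ_id", "drug_id")]
  if (nrow(neg) == 0) {
    full_graph <- cda_graph(table)
    neg <- sample_negatives(full_graph, nrow(pos),
                            seed = config$seed)[, c("circ_id", "drug_id")]
  }
  split <- list(fold_id = 0L, train_pos = pos, train_neg = neg,
                test_pos = pos[0, ], test_neg = neg[0, ])
  train_fold(split, table, config, extras)
}

#' Rank candidate drugs for a circRNA
#'
#' Scores every drug not already linked to the query circRNA in the training
#' graph and returns the `top_k` highest-scoring candidates, ties broken
#' lexicographically by drug id.
#'
#' @param fit A `cda_fit` from [cda_train()] (or [train_fold()]).
#' @param query_circ_id A circRNA id present in the model's graph.
#' @param top_k Maximum number of candidates to return.
#' @return A tibble with columns `drug_id`, `score`, sorted by descending
#'   score.
#' @export
rank_candidates <- function(fit, query_circ_id, top_k = 20L) {
  stopifnot(inherits(fit, "cda_fit"))
  graph <- fit$graph
  ui <- match(query_circ_id, graph$circ_ids)
  if (is.na(ui)) abort(sprintf("Unknown circRNA id: %s", query_circ_id))
  known <- graph$A[ui, ] == 1L
  cand <- which(!known)
  if (length(cand) == 0) {
    return(tibble::tibble(drug_id = character(), score = numeric()))
  }
  vi <- graph$n_circ + cand
  scores <- decode_pair(
    fit$H[rep(ui, length(vi)), , drop = FALSE],
    fit$H[vi, , drop = FALSE],
    fit$params$decoder)
  out <- tibble::tibble(drug_id = graph$drug_ids[cand], score = scores)
  out <- dplyr::arrange(out, dplyr::desc(.data$score), .data$drug_id)
  head(out, top_k)
}

#' Score arbitrary circRNA-drug pairs with a trained model
#'
#' @param object A `cda_fit`.
#' @param pairs A data frame with columns `circ_id`, `drug_id`.
#' @param ... Unused.
#' @return The input tibble with an added `score` column.
#' @export
predict.cda_fit <- function(object, pairs, ...) {
  idx <- pair_indices(object$graph, pairs)
  scores <- decode_pair(object$H[idx$u, , drop = FALSE],
                        object$H[idx$v, , drop = FALSE],
                        object$params$decoder)
  dplyr::mutate(tibble::as_tibble(pairs), score = scores)
}
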