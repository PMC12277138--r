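#' Run configuration for a torsion-weighted CDA model
#'
#' Collects every tunable of the pipeline in one validated list: the encoder
#' family, network depth and widths, the node-feature initialization scheme,
#' the locality parameters of the torsion computation (subgraph order `order_p`
#' and complex dimension `max_dim_q`), the cross-validation layout and the
#' optimizer settings.
#'
#' Defaults follow the tuned operating point of the method: a 2-layer GCN
#' encoder with 128-dimensional hidden and output representations, position
#' (adjacency-row) features, torsion weights computed on 1-hop edge subgraphs
#' with a 1-dimensional complex, and 5-fold cross-validation.
#'
#' @param encoder One of `"gcn"`, `"gat"`, `"gin"`.
#' @param layers Number of message-passing layers (>= 1).
#' @param hidden_dim,out_dim Hidden and output embedding widths.
#' @param feature_init One of `"uniform"`, `"normal"`, `"onehot"`,
#'   `"position"`, `"sim"`.
#' @param order_p Subgraph order P: BFS radius around an edge when building its
#'   local complex. One of 1, 2, 3.
#' @param max_dim_q Maximum simplex dimension Q of the local complex (1 or 2).
#'   On a purely bipartite graph no triangles exist, so Q = 2 equals Q = 1.
#' @param torsion_enabled If `FALSE` all propagation weights are 1 (ablation).
#' @param folds Number of cross-validation folds (>= 2).
#' @param seed Integer seed; per-fold seeds are derived as `seed + fold_id`.
#' @param lr Learning rate of the Adam optimizer.
#' @param epochs Maximum number of full-batch epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement); `Inf` disables early stopping.
#' @param min_epochs Epochs to run before early stopping may trigger; guards
#'   against stopping inside the initial sigmoid warm-up plateau.
#' @param val_fraction Fraction of training pairs held out for early stopping.
#' @param kmer_k k-mer length for circular sequence features.
#' @param feature_dim Width of random (`uniform`/`normal`) feature matrices.
#'
#' @return A list of class `cda_config`.
#' @export
#' @examples
#' cda_config(encoder = "gcn", layers = 2)
cda_config <- function(encoder = "gcn",
                       layers = 2L,
                       hidden_dim = 128L,
                       out_dim = 128L,
                       feature_init = "position",
                       order_p = 1L,
                       max_dim_q = 1L,
                       torsion_enabled = TRUE,
                       folds = 5L,
                       seed = 1L,
                       lr = 1e-3,
                       epochs = 500L,
                       patience = 50L,
                       min_epochs = 150L,
                       val_fraction = 0.1,
                       kmer_k = 4L,
                       feature_dim = 64L) {
  cfg <- list(
    encoder = match.arg(encoder, c("gcn", "gat", "gin")),
    layers = as.integer(layers),
    hidden_dim = as.integer(hidden_dim),
    out_dim = as.integer(out_dim),
    feature_init = match.arg(feature_init,
                             c("position", "onehot", "uniform", "normal", "sim")),
    order_p = as.integer(order_p),
    max_dim_q = as.integer(max_dim_q),
    torsion_enabled = isTRUE(torsion_enabled),
    folds = as.integer(folds),
    seed = as.integer(seed),
    lr = as.numeric(lr),
    epochs = as.integer(epochs),
    patience = as.numeric(patience),
    min_epochs = as.integer(min_epochs),
    val_fraction = as.numeric(val_fraction),
    kmer_k = as.integer(kmer_k),
    feature_dim = as.integer(feature_dim)
  )
  validate_config(cfg)
  structure(cfg, class = "cda_config")
}

validate_config <- function(cfg) {
  if (!is_count(cfg$layers, 1L)) abort("`layers` must be an integer >= 1.")
  if (!cfg$max_dim_q %in% c(1L, 2L)) abort("`max_dim_q` must be 1 or 2.")
  if (!cfg$order_p %in% c(1L, 2L, 3L)) abort("`order_p` must be 1, 2 or 3.")
  if (!is_count(cfg$folds, 2L)) abort("`folds` must be an integer >= 2.")
  if (!is_count(cfg$hidden_dim, 1L) || !is_count(cfg$out_dim, 1L)) {
    abort("`hidden_dim` and `out_dim` must be positive integers.")
  }
  if (!is_count(cfg$kmer_k, 1L)) abort("`kmer_k` must be a positive integer.")
  if (!is.finite(cfg$lr) || cfg$lr <= 0) abort("`lr` must be positive.")
  if (!is_count(cfg$epochs, 1L)) abort("`epochs` must be a positive integer.")
  if (cfg$val_fraction < 0 || cfg$val_fraction >= 1) {
    abort("`val_fraction` must be in [0, 1).")
  }
  invisible(cfg)
}

#' Read a run configuration from a flat YAML file
#'
#' Reads a flat YAML document whose keys are arguments of [cda_config()].
#' Unknown keys raise an error so that typos do not silently fall back to
#' defaults; keys that are absent keep their defaults.
#'
#' @param path Path to a YAML file.
#' @return A `cda_config` object.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("Config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) abort("Config must be a flat YAML mapping.")
  known <- names(formals(cda_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config key(s): %s", paste(unknown, collapse = ", ")))
  }
  do.call(cda_config, raw)
}

#' @export
print.cda_config <- function(x, ...) {
  cat("<cda_config>\n")
  cat(sprintf("  encoder: %s (%d layer(s), hidden %d, out %d)\n",
              x$encoder, x$layers, x$hidden_dim, x$out_dim))
  cat(sprintf("  features: %s | torsion: %s (P=%d, Q=%d)\n",
              x$feature_init, ifelse(x$torsion_enabled, "on", "off"),
              x$order_p, x$max_dim_q))
  cat(sprintf("  CV: %d folds | seed %d | lr %g | epochs %d\n",
              x$folds, x$seed, x$lr, x$epochs))
  invisible(x)
}
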