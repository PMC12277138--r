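# broom-style methods and plots for fitted objects.

#' @describeIn cda_cv Per-fold metrics as a tibble (`fold`, `auc`, `aupr`,
#'   `f1`, `accuracy`, `recall`, `precision`).
#' @param x A `cda_cv` object.
#' @param ... Unused.
#' @method tidy cda_cv
#' @export
tidy.cda_cv <- function(x, ...) {
  x$metrics
}

#' @describeIn cda_cv One-row summary: mean and SD of every metric across
#'   folds, plus fold count.
#' @method glance cda_cv
#' @export
glance.cda_cv <- function(x, ...) {
  m <- x$metrics[, setdiff(names(x$metrics), "fold")]
  out <- tibble::as_tibble(as.list(colMeans(m)))
  sds <- tibble::as_tibble(as.list(vapply(m, stats::sd, numeric(1))))
  names(sds) <- paste0(names(sds), "_sd")
  dplyr::bind_cols(out, sds, tibble::tibble(n_folds = nrow(m)))
}

#' @describeIn cda_cv Dot plot of per-fold metrics with mean bars.
#' @param object A `cda_cv` object.
#' @method autoplot cda_cv
#' @export
autoplot.cda_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"fold",
                              names_to = "metric", values_to = "value")
  means <- dplyr::summarise(dplyr::group_by(long, .data$metric),
                            value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$fold)),
                        position = ggplot2::position_jitter(width = 0.08,
                                                            height = 0),
                        alpha = 0.8) +
    ggplot2::geom_crossbar(data = means,
                           ggplot2::aes(ymin = .data$value,
                                        ymax = .data$value),
                           width = 0.45, linewidth = 0.4) +
    ggplot2::labs(x = NULL, y = "held-out value", colour = "fold",
                  title = "Cross-validated association prediction metrics") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' @export
print.cda_cv <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<cda_cv> %d folds | encoder %s | torsion %s\n",
              g$n_folds, x$config$encoder,
              ifelse(x$config$torsion_enabled, "on", "off")))
  cat(sprintf("  AUC %.4f +/- %.4f | AUPR %.4f +/- %.4f | F1 %.4f\n",
              g$auc, g$auc_sd, g$aupr, g$aupr_sd, g$f1))
  invisible(x)
}

#' @describeIn train_fold Held-out metrics of the fold as a tibble (empty for
#'   a final [cda_train()] fit).
#' @param x A `cda_fit` object.
#' @param ... Unused.
#' @method tidy cda_fit
#' @export
tidy.cda_fit <- function(x, ...) {
  if (is.null(x$metrics)) {
    return(tibble::tibble(auc = numeric(), aupr = numeric(), f1 = numeric(),
                          accuracy = numeric(), recall = numeric(),
                          precision = numeric()))
  }
  x$metrics
}

#' @describeIn train_fold One-row training summary: epochs run, final
#'   training loss, embedding width and edge count of the training graph.
#' @method glance cda_fit
#' @export
glance.cda_fit <- function(x, ...) {
  tibble::tibble(epochs_run = length(x$trace),
                 final_loss = x$trace[length(x$trace)],
                 out_dim = ncol(x$H),
                 n_train_edges = sum(x$graph$A))
}

#' @export
print.cda_fit <- function(x, ...) {
  cat(sprintf("<cda_fit> %s encoder, %d layer(s), %d training edges\n",
              x$config$encoder, x$config$layers, sum(x$graph$A)))
  if (!is.null(x$metrics)) {
    cat(sprintf("  held-out AUC %.4f | AUPR %.4f\n",
                x$metrics$auc, x$metrics$aupr))
  }
  invisible(x)
}

#' Plot the training loss trace of a fitted model
#'
#' @param object A `cda_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cda_fit
#' @export
autoplot.cda_fit <- function(object, ...) {
  df <- tibble::tibble(epoch = seq_along(object$trace), loss = object$trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "training BCE loss",
                  title = "Full-batch training trace") +
    ggplot2::theme_minimal()
}
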