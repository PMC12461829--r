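#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_col
#'   facet_wrap labs theme_minimal position_dodge
#' @export
ggplot2::autoplot

#' Tidy a trained classifier
#'
#' One row per layer with trainable parameters: branch, position, type,
#' parameter count and the largest output-unit weight norm (the quantity
#' the max-norm constraint bounds).
#'
#' @param x an `allodyn_fit`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.allodyn_fit <- function(x, ...) {
  rows <- list()
  for (br in names(branch_list(x$model))) {
    layers <- branch_list(x$model)[[br]]
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      pn <- layer_param_names(ly)
      if (!length(pn)) next
      rows[[length(rows) + 1L]] <- tibble::tibble(
        branch = br, position = i, type = ly$type,
        n_params = sum(vapply(pn, function(nm) length(ly[[nm]]), numeric(1))),
        max_row_norm = if (ly$type %in% c("conv", "dense"))
          sqrt(max(rowSums(ly$W^2))) else NA_real_)
    }
  }
  dplyr::bind_rows(rows)
}

#' Glance at a trained classifier
#'
#' @param x an `allodyn_fit`.
#' @param ... unused.
#' @return a one-row tibble: parameter count, epochs, final losses, the
#'   final focusing parameter, the entropy weight and the seed.
#' @export
glance.allodyn_fit <- function(x, ...) {
  lg <- x$log
  tibble::tibble(
    n_parameters = n_parameters(x$model),
    epochs = nrow(lg),
    final_gamma = lg$gamma[nrow(lg)],
    lambda = x$loss_cfg$lambda,
    final_train_loss = lg$train_loss[nrow(lg)],
    final_val_loss = lg$val_loss[nrow(lg)],
    seed = x$seed)
}

#' @export
tidy.allodyn_imputer_fit <- function(x, ...) x$log

#' @export
glance.allodyn_imputer_fit <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$log), initial_mse = x$initial_mse,
                 final_mse = x$final_mse,
                 mse_reduction = x$initial_mse / x$final_mse)
}

#' Tidy a selective-metrics report
#'
#' @param x an `allodyn_metrics`.
#' @param ... unused.
#' @return a long tibble of metric/value pairs.
#' @export
tidy.allodyn_metrics <- function(x, ...) {
  tibble::tibble(
    metric = c("accuracy", "f1", "kappa", "coverage"),
    value = c(x$accuracy, x$f1, x$kappa, x$coverage))
}

#' @export
glance.allodyn_metrics <- function(x, ...) {
  tibble::tibble(accuracy = x$accuracy, f1 = x$f1, kappa = x$kappa,
                 coverage = x$coverage, n = x$n, f1_average = x$f1_average)
}

#' Training-curve plot for a classifier fit
#'
#' @param object an `allodyn_fit`.
#' @param ... unused.
#' @return a ggplot of train/validation loss (and gamma) per epoch.
#' @export
autoplot.allodyn_fit <- function(object, ...) {
  lg <- tidyr::pivot_longer(
    dplyr::select(object$log, "epoch", "train_loss", "val_loss", "gamma"),
    -"epoch", names_to = "series", values_to = "value")
  ggplot(lg, aes(x = .data$epoch, y = .data$value,
                 colour = .data$series)) +
    geom_line() +
    facet_wrap(~ifelse(series == "gamma", "focusing parameter", "loss"),
               scales = "free_y") +
    labs(x = "epoch", y = NULL, colour = NULL) +
    theme_minimal()
}

#' Modality-attribution bar plot
#'
#' @param object an `allodyn_attribution` tibble.
#' @param ... unused.
#' @return a ggplot comparing total and mean attribution percentages per
#'   modality and class.
#' @export
autoplot.allodyn_attribution <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object), -"class",
                              names_to = "measure", values_to = "pct")
  long$view <- ifelse(grepl("^total", long$measure), "total", "mean")
  long$modality <- ifelse(grepl("dynamics", long$measure),
                          "dynamics", "fingerprints")
  ggplot(long, aes(x = .data$class, y = .data$pct, fill = .data$modality)) +
    geom_col(position = position_dodge()) +
    facet_wrap(~view) +
    labs(y = "attribution (%)", x = NULL, fill = NULL) +
    theme_minimal()
}

#' Scatter plot of a UMAP projection
#'
#' @param projection tibble from [project_dataset()].
#' @return a ggplot colored by class.
#' @export
plot_projection <- function(projection) {
  projection$class <- int_to_label(projection$label)
  ggplot(projection, aes(x = .data$umap_1, y = .data$umap_2,
                         colour = .data$class)) +
    geom_point(alpha = 0.7) +
    labs(x = "UMAP 1", y = "UMAP 2", colour = NULL) +
    theme_minimal()
}

#' Threshold-sweep plot
#'
#' @param sweep tibble from [threshold_sweep()].
#' @return a ggplot of accuracy/F1/kappa/coverage against the threshold.
#' @export
plot_threshold_sweep <- function(sweep) {
  long <- tidyr::pivot_longer(
    dplyr::select(sweep, "threshold", "accuracy", "f1", "kappa", "coverage"),
    -"threshold", names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$threshold, y = .data$value)) +
    geom_line() + geom_point() +
    facet_wrap(~metric, scales = "free_y") +
    labs(x = "confidence threshold", y = NULL) +
    theme_minimal()
}
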