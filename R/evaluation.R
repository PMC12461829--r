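#' Numerically stable softmax
#'
#' @param logits length-2 vector or 2 x n matrix (one column per sample).
#' @return probabilities of the same shape; columns sum to 1.
#' @export
softmax_probs <- function(logits) {
  if (is.matrix(logits)) {
    z <- logits - rep(apply(logits, 2, max), each = nrow(logits))
    e <- exp(z)
    return(e / rep(colSums(e), each = nrow(e)))
  }
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

#' Threshold decision with abstention
#'
#' Assigns the argmax class when the maximum class probability strictly
#' exceeds the confidence threshold tau; otherwise the sample is assigned
#' to the `"uncertain"` class ("did not exceed" is read as a strict
#' inequality, so a (0.5, 0.5) output is uncertain at any valid tau).
#'
#' @param probs length-2 probability vector (orthosteric, allosteric).
#' @param threshold tau in `[0.5, 1]`.
#' @return `"orthosteric"`, `"allosteric"` or `"uncertain"`.
#' @export
decide <- function(probs, threshold = 0.5) {
  drop(decide_matrix(matrix(probs, ncol = 1), threshold))
}

decide_matrix <- function(probs, threshold) {
  if (length(threshold) != 1L || !is.finite(threshold) ||
      threshold < 0.5 || threshold > 1) {
    abort("`threshold` must lie in [0.5, 1]")
  }
  pmax_ <- apply(probs, 2, max)
  cls <- ALLODYN_CLASSES[apply(probs, 2, which.max)]
  ifelse(pmax_ > threshold, cls, "uncertain")
}

#' Cohen's kappa from a 2 x 2 confident confusion table
#'
#' `(p_o - p_e) / (1 - p_e)` with the marginal-product expected agreement.
#' The degenerate case `p_e = 1` returns 0 with a warning.
#'
#' @param confusion 2 x 2 matrix of counts (rows = true, cols = predicted).
#' @return kappa in `[-1, 1]`.
#' @export
cohens_kappa <- function(confusion) {
  stopifnot(is.matrix(confusion), all(dim(confusion) == c(2L, 2L)))
  n <- sum(confusion)
  if (n < 1) abort("confusion table must contain at least one count")
  po <- sum(diag(confusion)) / n
  pe <- sum(rowSums(confusion) * colSums(confusion)) / n^2
  if (abs(1 - pe) < 1e-12) {
    warn("degenerate confusion table (expected agreement 1); kappa set to 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

macro_f1 <- function(confusion2x2) {
  f1s <- vapply(1:2, function(k) {
    tp <- confusion2x2[k, k]
    fp <- sum(confusion2x2[-k, k])
    fn <- sum(confusion2x2[k, -k])
    if (2 * tp + fp + fn == 0) return(NA_real_)
    2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1s, na.rm = TRUE)
}

#' Selective classification metrics
#'
#' Accuracy, F1 and Cohen's kappa over the confidently classified samples
#' only, plus the coverage (fraction not abstained) and the full 2 x 3
#' confusion matrix (true class x \{orthosteric, allosteric, uncertain\}).
#' When no sample is confident, the metrics are reported as `NA` with
#' coverage 0.
#'
#' @param decisions character vector of decisions
#'   (`"orthosteric"`/`"allosteric"`/`"uncertain"`), e.g. the `decision`
#'   column of [predict_samples()].
#' @param labels true labels (0/1 or class names).
#' @param f1_average `"macro"` (default, one F1 per class averaged) or
#'   `"binary"` (positive = allosteric).
#' @return an object of class `allodyn_metrics`: list with `accuracy` and
#'   `f1` (percent), `kappa`, `coverage`, `confusion`, `n` and
#'   `f1_average`.
#' @export
selective_metrics <- function(decisions, labels, f1_average = c("macro", "binary")) {
  f1_average <- match.arg(f1_average)
  y <- label_to_int(labels)
  if (length(decisions) != length(y) || length(y) < 1L) {
    abort("`decisions` and `labels` must be equal-length, non-empty")
  }
  if (!all(decisions %in% c(ALLODYN_CLASSES, "uncertain"))) {
    abort("invalid decision values")
  }
  confusion <- matrix(0L, 2L, 3L,
                      dimnames = list(true = ALLODYN_CLASSES,
                                      predicted = c(ALLODYN_CLASSES, "uncertain")))
  for (k in seq_along(y)) {
    j <- match(decisions[k], c(ALLODYN_CLASSES, "uncertain"))
    confusion[y[k] + 1L, j] <- confusion[y[k] + 1L, j] + 1L
  }
  conf2 <- confusion[, 1:2, drop = FALSE]
  n_conf <- sum(conf2)
  coverage <- n_conf / length(y)
  if (n_conf == 0L) {
    metrics <- list(accuracy = NA_real_, f1 = NA_real_, kappa = NA_real_)
  } else {
    acc <- 100 * sum(diag(conf2)) / n_conf
    f1 <- if (f1_average == "macro") {
      100 * macro_f1(conf2)
    } else {
      tp <- conf2[2, 2]; fp <- conf2[1, 2]; fn <- conf2[2, 1]
      if (2 * tp + fp + fn == 0) NA_real_ else 100 * 2 * tp / (2 * tp + fp + fn)
    }
    kap <- if (n_conf >= 1) cohens_kappa(conf2) else NA_real_
    metrics <- list(accuracy = acc, f1 = f1, kappa = kap)
  }
  structure(c(metrics,
              list(coverage = coverage, confusion = confusion,
                   n = length(y), f1_average = f1_average)),
            class = "allodyn_metrics")
}

#' @export
print.allodyn_metrics <- function(x, ...) {
  cat(sprintf(
    "Selective metrics (n = %d, coverage %.3f)\n  accuracy %s  F1(%s) %s  kappa %s\n",
    x$n, x$coverage,
    if (is.na(x$accuracy)) "NA" else sprintf("%.2f%%", x$accuracy),
    x$f1_average,
    if (is.na(x$f1)) "NA" else sprintf("%.2f%%", x$f1),
    if (is.na(x$kappa)) "NA" else sprintf("%.3f", x$kappa)))
  print(x$confusion)
  invisible(x)
}

#' Metrics across confidence thresholds
#'
#' Computes the decision and the selective metrics once per threshold from
#' a single set of predicted probabilities. The number of abstentions is
#' non-decreasing in the threshold by construction.
#'
#' @param probs 2 x n probability matrix, or a tibble from
#'   [predict_samples()] (columns `p_orthosteric`, `p_allosteric`,
#'   `label`).
#' @param labels true labels (ignored when `probs` is a prediction
#'   tibble).
#' @param thresholds confidence thresholds to sweep.
#' @param f1_average passed to [selective_metrics()].
#' @return a tibble with one row per threshold: `threshold`, `accuracy`,
#'   `f1`, `kappa`, `coverage`, `n_uncertain` and a `metrics` list-column
#'   holding the full `allodyn_metrics` objects.
#' @export
threshold_sweep <- function(probs, labels = NULL,
                            thresholds = c(0.5, 0.8, 0.95),
                            f1_average = "macro") {
  if (is.data.frame(probs)) {
    labels <- probs$label
    probs <- rbind(probs$p_orthosteric, probs$p_allosteric)
  }
  stopifnot(is.matrix(probs), nrow(probs) == 2L, !is.null(labels))
  rows <- purrr::map(thresholds, function(tau) {
    dec <- decide_matrix(probs, tau)
    m <- selective_metrics(dec, labels, f1_average = f1_average)
    tibble::tibble(threshold = tau, accuracy = m$accuracy, f1 = m$f1,
                   kappa = m$kappa, coverage = m$coverage,
                   n_uncertain = sum(dec == "uncertain"),
                   metrics = list(m))
  })
  dplyr::bind_rows(rows)
}

#' Two-dimensional UMAP projection of the dataset
#'
#' Projects the samples' fingerprints into two dimensions with UMAP, using
#' the Jaccard distance between binary fingerprints, 20 neighbors and
#' 1000 optimization epochs. Deterministic per seed (single-threaded
#' optimization).
#'
#' @param samples flat sample list or dataset.
#' @param n_neighbors UMAP neighborhood size.
#' @param n_epochs UMAP optimization epochs.
#' @param seed RNG seed.
#' @return a tibble: sample metadata plus `umap_1`, `umap_2`.
#' @export
project_dataset <- function(samples, n_neighbors = 20L, n_epochs = 1000L,
                            seed = 42L) {
  samples <- dataset_samples(samples)
  info <- samples_info(samples)
  n <- length(samples)
  if (n < n_neighbors + 1L) {
    abort(sprintf("need at least n_neighbors + 1 = %d samples, got %d",
                  n_neighbors + 1L, n))
  }
  fps <- do.call(rbind, lapply(samples, function(s) as.numeric(s$fingerprint)))
  d <- vegan::vegdist(fps, method = "jaccard", binary = TRUE)
  d[is.na(d)] <- 0  # pairs of all-zero fingerprints: treat as identical
  set.seed(seed)
  coords <- uwot::umap(stats::as.dist(d), n_neighbors = n_neighbors,
                       n_epochs = n_epochs, n_threads = 1,
                       n_sgd_threads = 0, verbose = FALSE)
  info$umap_1 <- coords[, 1]
  info$umap_2 <- coords[, 2]
  info
}
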