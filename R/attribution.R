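#' Integrated gradients over both input modalities
#'
#' Joint-wrapper integrated gradients: both inputs are interpolated
#' simultaneously from the baseline to the sample along a straight path,
#' and the gradient of the target-class logit is averaged over `n_steps`
#' midpoint-rule path points (the model runs in eval mode, so the mapping
#' is piecewise smooth and the Riemann sum converges to the path
#' integral). Attribution of element i is
#' `(x_i - baseline_i) * mean_k grad_i(baseline + alpha_k (x - baseline))`.
#' By the completeness axiom the attributions of both modalities sum to
#' `F(x) - F(baseline)` up to discretization error.
#'
#' @param model an `allodyn_model` (eval mode is used).
#' @param matrix 16 x T descriptor matrix.
#' @param fingerprint 0/1 vector.
#' @param target_class class whose logit is attributed (`"orthosteric"`,
#'   `"allosteric"`, 0/1, or `NULL` for the predicted class).
#' @param baseline list with elements `matrix` and `fingerprint`; the
#'   default is the all-zero baseline for both inputs.
#' @param n_steps path resolution of the Riemann sum.
#' @param chunk_size path points evaluated per forward pass (memory
#'   control).
#' @return a list with `matrix` (16 x T attributions), `fingerprint`
#'   (length-2048 attributions), `target_class`, `n_steps`,
#'   `baseline_spec`, `output` (logit at the input), and
#'   `output_baseline`.
#' @export
integrated_gradients_joint <- function(model, matrix, fingerprint,
                                       target_class = NULL, baseline = NULL,
                                       n_steps = 64L, chunk_size = 64L) {
  stopifnot(is.matrix(matrix))
  fp <- as.numeric(fingerprint)
  if (is.null(baseline)) {
    baseline <- list(matrix = matrix * 0, fingerprint = fp * 0,
                     spec = "zero matrix + zero fingerprint")
  }
  b_mat <- baseline$matrix
  b_fp <- as.numeric(baseline$fingerprint)
  stopifnot(identical(dim(b_mat), dim(matrix)), length(b_fp) == length(fp))
  if (is.null(target_class)) {
    pred <- classify(model, fp, matrix)
    target_class <- which.max(pred$probs) - 1L
  }
  tc <- label_to_int(target_class) + 1L
  Tn <- ncol(matrix)
  d_mat <- matrix - b_mat
  d_fp <- fp - b_fp
  alphas <- (seq_len(n_steps) - 0.5) / n_steps
  grad_mat <- matrix * 0
  grad_fp <- fp * 0
  for (chunk in split(alphas, ceiling(seq_along(alphas) / chunk_size))) {
    B <- length(chunk)
    Xt <- do.call(cbind, lapply(chunk, function(a) b_mat + a * d_mat))
    Xb <- vapply(chunk, function(a) b_fp + a * d_fp, numeric(length(fp)))
    fwd <- classifier_forward(model, Xt, Xb, B = B, training = FALSE)
    dLogits <- base::matrix(0, 2L, B)
    dLogits[tc, ] <- 1
    bwd <- classifier_backward(model, fwd, dLogits)
    if (any(!is.finite(bwd$dXt)) || any(!is.finite(bwd$dXb))) {
      abort("non-finite gradients in the integrated-gradients path")
    }
    # sum gradients over the chunk's path points
    grad_mat <- grad_mat +
      base::matrix(rowSums(base::matrix(bwd$dXt, nrow(matrix) * Tn, B)),
                   nrow(matrix), Tn)
    grad_fp <- grad_fp + rowSums(bwd$dXb)
  }
  attr_mat <- d_mat * grad_mat / n_steps
  attr_fp <- d_fp * grad_fp / n_steps
  out_x <- classifier_forward(model, matrix, base::matrix(fp, ncol = 1),
                              B = 1L)$logits[tc, 1]
  out_b <- classifier_forward(model, b_mat, base::matrix(b_fp, ncol = 1),
                              B = 1L)$logits[tc, 1]
  list(matrix = attr_mat, fingerprint = attr_fp,
       target_class = ALLODYN_CLASSES[tc], n_steps = n_steps,
       baseline_spec = baseline$spec %||% "custom baseline",
       output = out_x, output_baseline = out_b)
}

#' Summarize attributions across samples and modalities
#'
#' Mirrors the two headline views of modality importance:
#' * Total attribution: the sum of absolute attributions within each
#'   modality as a percentage of the grand total of both modalities.
#' * Mean attribution: the mean absolute attribution per feature within
#'   each modality, normalized to a percentage across the two modalities.
#'
#' With equal per-element magnitudes the higher-dimensional dynamics
#' input dominates the Total view (32000 vs 2048 elements) while the Mean
#' view splits 50/50 — the dimensional-dominance mechanism.
#'
#' @param attributions list of results from
#'   [integrated_gradients_joint()], one per sample.
#' @param labels true class labels, one per sample.
#' @return an object of class `allodyn_attribution`: a tibble with
#'   columns `class` (`orthosteric`, `allosteric`, `average`),
#'   `total_dynamics_pct`, `total_fingerprints_pct`, `mean_dynamics_pct`,
#'   `mean_fingerprints_pct`; attributes record `n_steps` and
#'   `baseline_spec`.
#' @export
summarize_attributions <- function(attributions, labels) {
  stopifnot(length(attributions) >= 1L,
            length(labels) == length(attributions))
  y <- label_to_int(labels)
  tot_dyn <- vapply(attributions, function(a) sum(abs(a$matrix)), numeric(1))
  tot_fp <- vapply(attributions, function(a) sum(abs(a$fingerprint)), numeric(1))
  n_dyn <- length(attributions[[1]]$matrix)
  n_fp <- length(attributions[[1]]$fingerprint)
  if (all(tot_dyn + tot_fp == 0)) {
    warn("all attributions are zero; no report produced")
    return(NULL)
  }
  one_row <- function(idx, class_name) {
    td <- sum(tot_dyn[idx]); tf <- sum(tot_fp[idx])
    md <- td / (n_dyn * length(idx)); mf <- tf / (n_fp * length(idx))
    tibble::tibble(
      class = class_name,
      total_dynamics_pct = 100 * td / (td + tf),
      total_fingerprints_pct = 100 * tf / (td + tf),
      mean_dynamics_pct = 100 * md / (md + mf),
      mean_fingerprints_pct = 100 * mf / (md + mf))
  }
  rows <- list()
  for (k in 0:1) {
    if (any(y == k)) rows[[length(rows) + 1L]] <-
        one_row(which(y == k), ALLODYN_CLASSES[k + 1L])
  }
  # the "average" row averages the per-class percentages when both classes
  # are present, falling back to the pooled summary otherwise
  if (length(rows) == 2L) {
    avg <- dplyr::bind_rows(rows)
    rows[[3L]] <- dplyr::mutate(
      dplyr::summarise(avg, dplyr::across(dplyr::where(is.numeric), mean)),
      class = "average", .before = 1L)
  } else {
    rows[[length(rows) + 1L]] <- one_row(seq_along(y), "average")
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "n_steps") <- attributions[[1]]$n_steps
  attr(out, "baseline_spec") <- attributions[[1]]$baseline_spec
  class(out) <- c("allodyn_attribution", class(out))
  out
}
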