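#' Loss configuration
#'
#' Parameters of the training objective: a dynamic focal loss whose
#' focusing parameter follows the epoch schedule
#' `gamma = min(gamma_max, gamma_rate * epoch)` (reaching its cap of 2.0
#' at epoch 10 under the defaults, with epochs counted from 0), plus an
#' entropy regularizer `lambda * H(p)` that penalizes indecisive output
#' distributions. `lambda` has no published reference value; the package
#' default is 0.1 and the value used is recorded in every training log.
#'
#' @param gamma_max cap of the focusing parameter (default 2.0).
#' @param gamma_rate per-epoch increase of gamma (default 0.2).
#' @param lambda entropy-regularization weight (>= 0, default 0.1).
#' @param eps probability floor applied before logarithms (default 1e-12).
#' @return an object of class `allodyn_loss_config`.
#' @export
loss_config <- function(gamma_max = 2.0, gamma_rate = 0.2, lambda = 0.1,
                        eps = 1e-12) {
  structure(list(
    gamma_max = assert_number(gamma_max, "gamma_max", min = 0),
    gamma_rate = assert_number(gamma_rate, "gamma_rate", min = 0),
    lambda = assert_number(lambda, "lambda", min = 0),
    eps = assert_number(eps, "eps", min = 0, max = 1e-3)
  ), class = "allodyn_loss_config")
}

#' Focusing parameter at a given epoch
#'
#' `gamma = min(gamma_max, gamma_rate * epoch)`, with epochs counted from
#' 0 so the default schedule ramps linearly over the first 10 epochs and
#' stays at 2.0 afterwards.
#'
#' @param epoch integer epoch index (>= 0; the first epoch is 0).
#' @param config an [loss_config()].
#' @return the focusing parameter gamma.
#' @export
gamma_at_epoch <- function(epoch, config = loss_config()) {
  if (any(epoch < 0) || any(!is.finite(epoch))) {
    abort("`epoch` must be >= 0")
  }
  pmin(config$gamma_max, config$gamma_rate * epoch)
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

#' Focal loss
#'
#' `FL(y, p; gamma) = -y (1-p)^gamma log(p) - (1-y) p^gamma log(1-p)`,
#' where `p` is the predicted probability of the positive (allosteric)
#' class. At `gamma = 0` this reduces to binary cross-entropy. Vectorized
#' over samples; returns per-sample values.
#'
#' @param y true labels in \{0, 1\} (vectorized).
#' @param y_hat predicted positive-class probabilities.
#' @param gamma focusing parameter (>= 0).
#' @param eps probability floor.
#' @return numeric vector of per-sample losses (>= 0).
#' @export
focal_loss <- function(y, y_hat, gamma, eps = 1e-12) {
  if (!all(y %in% c(0, 1))) abort("`y` must be 0 or 1")
  if (gamma < 0) abort("`gamma` must be >= 0")
  p <- clamp_prob(y_hat, eps)
  -y * (1 - p)^gamma * log(p) - (1 - y) * p^gamma * log(1 - p)
}

#' Shannon entropy of a predictive distribution
#'
#' `H(p) = -sum(p log p)` in nats; 0 for one-hot distributions and `ln 2`
#' at the two-class uniform. Accepts a probability vector or a matrix with
#' one distribution per column.
#'
#' @param y_hat_dist probability vector, or matrix with distributions in
#'   columns.
#' @param eps probability floor.
#' @param tol tolerance on the sum-to-one check.
#' @return entropy in nats (vector of length `ncol` for matrix input).
#' @export
entropy_term <- function(y_hat_dist, eps = 1e-12, tol = 1e-6) {
  if (is.matrix(y_hat_dist)) {
    sums <- colSums(y_hat_dist)
    if (any(abs(sums - 1) > tol) || any(y_hat_dist < -tol)) {
      abort("columns of `y_hat_dist` must be probability distributions")
    }
    p <- clamp_prob(y_hat_dist, eps)
    return(-colSums(p * log(p)))
  }
  if (abs(sum(y_hat_dist) - 1) > tol || any(y_hat_dist < -tol)) {
    abort("`y_hat_dist` must sum to 1 with non-negative entries")
  }
  p <- clamp_prob(y_hat_dist, eps)
  -sum(p * log(p))
}

#' Total training loss
#'
#' `L = FL(y, p; gamma(epoch)) + lambda * H(p)`, averaged over the batch.
#' `y_hat_dist` holds the two-class softmax output (orthosteric,
#' allosteric) per column; the focal term consumes the allosteric
#' (positive-class) probability.
#'
#' @param y true labels in \{0, 1\}.
#' @param y_hat_dist length-2 probability vector or 2 x batch matrix.
#' @param epoch epoch index for the gamma schedule.
#' @param config an [loss_config()].
#' @return scalar batch-mean loss.
#' @export
total_loss <- function(y, y_hat_dist, epoch, config = loss_config()) {
  comp <- loss_components(y, y_hat_dist, epoch, config)
  comp$loss
}

# batch-mean focal, entropy and combined terms (used by the trainer's log)
loss_components <- function(y, y_hat_dist, epoch, config) {
  if (!is.matrix(y_hat_dist)) y_hat_dist <- matrix(y_hat_dist, ncol = 1)
  stopifnot(nrow(y_hat_dist) == 2L, length(y) == ncol(y_hat_dist))
  g <- gamma_at_epoch(epoch, config)
  fl <- mean(focal_loss(y, y_hat_dist[2, ], g, config$eps))
  h <- mean(entropy_term(y_hat_dist, config$eps))
  list(loss = fl + config$lambda * h, fl = fl, entropy = h, gamma = g)
}

# gradient of the batch-mean total loss w.r.t. the two logits (2 x B)
loss_grad_logits <- function(y, logits, gamma, lambda, eps = 1e-12) {
  B <- ncol(logits)
  p <- softmax_probs(logits)
  ph <- clamp_prob(p[2, ], eps)
  if (gamma == 0) {
    dfl_dp <- ifelse(y == 1, -1 / ph, 1 / (1 - ph))
  } else {
    dfl_dp <- ifelse(
      y == 1,
      gamma * (1 - ph)^(gamma - 1) * log(ph) - (1 - ph)^gamma / ph,
      -gamma * ph^(gamma - 1) * log(1 - ph) + ph^gamma / (1 - ph))
  }
  dz_fl <- rbind(-dfl_dp * ph * (1 - ph), dfl_dp * ph * (1 - ph))
  pc <- clamp_prob(p, eps)
  H <- -colSums(pc * log(pc))
  dz_h <- -pc * (log(pc) + rep(H, each = 2L))
  (dz_fl + lambda * dz_h) / B
}
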