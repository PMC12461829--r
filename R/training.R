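#' Classifier training configuration
#'
#' AdaBelief with decoupled weight decay, mini-batches of 32, a max-norm
#' constraint of 3.0 applied after every update, and Kaiming-normal
#' initialization; 200 epochs by default.
#'
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps_opt optimizer stability constant.
#' @param weight_decay decoupled weight-decay coefficient.
#' @param epochs number of epochs (epoch index starts at 0).
#' @param batch_size mini-batch size.
#' @param maxnorm max-norm threshold on conv/dense weight rows.
#' @param seed training seed (initialization, shuffling, dropout).
#' @return an object of class `allodyn_train_config`.
#' @export
train_config <- function(lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                         eps_opt = 1e-16, weight_decay = 1e-2,
                         epochs = 200L, batch_size = 32L, maxnorm = 3.0,
                         seed = 1L) {
  structure(list(
    lr = assert_number(lr, "lr", min = 1e-12),
    beta1 = assert_number(beta1, "beta1", 1e-12, 1 - 1e-12),
    beta2 = assert_number(beta2, "beta2", 1e-12, 1 - 1e-12),
    eps_opt = assert_number(eps_opt, "eps_opt", min = 0),
    weight_decay = assert_number(weight_decay, "weight_decay", min = 0),
    epochs = assert_count(epochs, "epochs"),
    batch_size = assert_count(batch_size, "batch_size"),
    maxnorm = assert_number(maxnorm, "maxnorm", min = 1e-12),
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "allodyn_train_config")
}

#' Imputer training configuration
#'
#' Adam on the mean squared error between imputed and temporal
#' embeddings; learning rate 1e-5 and (coupled) weight decay 1e-3.
#'
#' @param lr learning rate.
#' @param weight_decay L2 weight-decay coefficient.
#' @param epochs number of epochs.
#' @param batch_size mini-batch size.
#' @param seed training seed.
#' @return an object of class `allodyn_imputer_train_config`.
#' @export
imputer_train_config <- function(lr = 1e-5, weight_decay = 1e-3,
                                 epochs = 200L, batch_size = 32L, seed = 1L) {
  structure(list(
    lr = assert_number(lr, "lr", min = 1e-12),
    weight_decay = assert_number(weight_decay, "weight_decay", min = 0),
    epochs = assert_count(epochs, "epochs"),
    batch_size = assert_count(batch_size, "batch_size"),
    seed = assert_count(seed, "seed", min = 0L)
  ), class = "allodyn_imputer_train_config")
}

sample_tensors <- function(samples) {
  list(Xt = do.call(cbind, lapply(samples, `[[`, "matrix")),
       Xb = do.call(cbind, lapply(samples, function(s) as.numeric(s$fingerprint))),
       y = vapply(samples, `[[`, integer(1), "label"))
}

# eval-mode mean total loss over a sample set
eval_loss <- function(model, samples, epoch, loss_cfg, batch_size = 64L) {
  n <- length(samples)
  losses <- numeric(0); weights <- numeric(0)
  for (chunk in split(seq_len(n), ceiling(seq_len(n) / batch_size))) {
    te <- sample_tensors(samples[chunk])
    fwd <- classifier_forward(model, te$Xt, te$Xb, B = length(chunk),
                              training = FALSE)
    probs <- softmax_probs(fwd$logits)
    losses <- c(losses, total_loss(te$y, probs, epoch, loss_cfg))
    weights <- c(weights, length(chunk))
  }
  sum(losses * weights) / sum(weights)
}

#' Train the dual-branch classifier
#'
#' Full training loop: Kaiming initialization with the run seed,
#' mini-batches reshuffled each epoch, forward pass with batch-norm batch
#' statistics and dropout, dynamic focal loss with entropy regularization
#' (gamma follows the epoch schedule), backpropagation, AdaBelief update
#' with decoupled weight decay, and the max-norm constraint after every
#' update. Per-epoch focal, entropy, total and validation losses are
#' logged. Deterministic given the seed on a fixed BLAS configuration.
#'
#' @param samples flat sample list or dataset.
#' @param split an [grouped_split()]; training uses `split$train`,
#'   validation loss is logged on `split$val`.
#' @param model_cfg an [model_config()].
#' @param loss_cfg an [loss_config()].
#' @param train_cfg an [train_config()].
#' @param verbose print a line per epoch.
#' @return an object of class `allodyn_fit`: list with `model`, `log`
#'   (tibble: epoch, gamma, train_fl, train_entropy, train_loss,
#'   val_loss), the three configs and the seed.
#' @export
train_classifier <- function(samples, split, model_cfg = model_config(),
                             loss_cfg = loss_config(),
                             train_cfg = train_config(), verbose = FALSE) {
  train <- split_samples(samples, split, "train")
  val <- split_samples(samples, split, "val")
  if (length(train) == 0L) abort("the training split is empty")
  model <- build_classifier(model_cfg, init_seed = train_cfg$seed)
  state <- optim_init(model)
  set.seed(derive_seed(train_cfg$seed, 1L))
  n <- length(train)
  log <- vector("list", train_cfg$epochs)
  for (epoch in 0:(train_cfg$epochs - 1L)) {
    g <- gamma_at_epoch(epoch, loss_cfg)
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / train_cfg$batch_size))
    fl_sum <- 0; h_sum <- 0; l_sum <- 0; n_sum <- 0
    for (bi in batches) {
      te <- sample_tensors(train[bi])
      B <- length(bi)
      fwd <- classifier_forward(model, te$Xt, te$Xb, B = B, training = TRUE)
      model <- fwd$model
      probs <- softmax_probs(fwd$logits)
      comp <- loss_components(te$y, probs, epoch, loss_cfg)
      if (!is.finite(comp$loss)) {
        abort(sprintf("non-finite loss at epoch %d; aborting training", epoch))
      }
      dLogits <- loss_grad_logits(te$y, fwd$logits, g, loss_cfg$lambda,
                                  loss_cfg$eps)
      bwd <- classifier_backward(model, fwd, dLogits)
      step <- optim_step(model, bwd$grads, state, lr = train_cfg$lr,
                         beta1 = train_cfg$beta1, beta2 = train_cfg$beta2,
                         eps = train_cfg$eps_opt,
                         weight_decay = train_cfg$weight_decay,
                         method = "adabelief")
      model <- maxnorm_constrain(step$model, train_cfg$maxnorm)
      state <- step$state
      fl_sum <- fl_sum + comp$fl * B
      h_sum <- h_sum + comp$entropy * B
      l_sum <- l_sum + comp$loss * B
      n_sum <- n_sum + B
    }
    val_loss <- if (length(val)) eval_loss(model, val, epoch, loss_cfg) else NA_real_
    log[[epoch + 1L]] <- tibble::tibble(
      epoch = epoch, gamma = g, lambda = loss_cfg$lambda,
      train_fl = fl_sum / n_sum, train_entropy = h_sum / n_sum,
      train_loss = l_sum / n_sum, val_loss = val_loss)
    if (verbose) {
      message(sprintf("epoch %3d  gamma %.2f  train %.4f  val %s", epoch, g,
                      l_sum / n_sum,
                      if (is.na(val_loss)) "-" else sprintf("%.4f", val_loss)))
    }
  }
  structure(list(model = model, log = dplyr::bind_rows(log),
                 model_cfg = model_cfg, loss_cfg = loss_cfg,
                 train_cfg = train_cfg, split = split,
                 seed = train_cfg$seed),
            class = "allodyn_fit")
}

#' Train the fingerprint-to-embedding imputer
#'
#' Freezes the trained classifier, computes the temporal embeddings of the
#' training samples once (eval mode), and fits the imputer by minimizing
#' the mean squared error between imputed and temporal embeddings with
#' Adam.
#'
#' @param samples flat sample list or dataset.
#' @param fit an `allodyn_fit` (or bare `allodyn_model`).
#' @param split optional [grouped_split()]; when given, only `split$train`
#'   samples are used (defaults to the split stored in `fit`).
#' @param imputer_cfg an [imputer_config()].
#' @param imp_train_cfg an [imputer_train_config()].
#' @param verbose print a line every 20 epochs.
#' @return an object of class `allodyn_imputer_fit`: list with `imputer`,
#'   `log` (tibble: epoch, mse), `initial_mse` and `final_mse`.
#' @export
train_imputer <- function(samples, fit, split = NULL,
                          imputer_cfg = imputer_config(),
                          imp_train_cfg = imputer_train_config(),
                          verbose = FALSE) {
  model <- if (inherits(fit, "allodyn_fit")) fit$model else fit
  if (is.null(split) && inherits(fit, "allodyn_fit")) split <- fit$split
  samples <- dataset_samples(samples)
  train <- if (is.null(split)) samples else split_samples(samples, split, "train")
  if (length(train) == 0L) abort("the training split is empty")
  imputer_cfg$input_length <- model$config$fp_length
  imputer <- build_imputer(imputer_cfg, classifier = model,
                           init_seed = imp_train_cfg$seed)
  targets <- temporal_embed(model, lapply(train, `[[`, "matrix"))
  Xb_all <- do.call(cbind, lapply(train, function(s) as.numeric(s$fingerprint)))
  n <- length(train)
  state <- optim_init(imputer)
  set.seed(derive_seed(imp_train_cfg$seed, 2L))
  initial_mse <- mean((impute_embed(imputer, Xb_all) - targets)^2)
  log <- vector("list", imp_train_cfg$epochs)
  for (epoch in 0:(imp_train_cfg$epochs - 1L)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / imp_train_cfg$batch_size))
    for (bi in batches) {
      Xb <- Xb_all[, bi, drop = FALSE]
      tgt <- targets[, bi, drop = FALSE]
      fw <- net_forward(imputer$layers, Xb, length(bi), training = TRUE)
      err <- fw$out - tgt
      dOut <- 2 * err / length(err)
      bw <- net_backward(imputer$layers, fw$caches, dOut)
      step <- optim_step(imputer, list(net = bw$grads), state,
                         lr = imp_train_cfg$lr, beta1 = 0.9, beta2 = 0.999,
                         eps = 1e-8, weight_decay = imp_train_cfg$weight_decay,
                         method = "adam")
      imputer <- step$model
      state <- step$state
    }
    mse <- mean((impute_embed(imputer, Xb_all) - targets)^2)
    if (!is.finite(mse)) abort("non-finite imputer MSE; aborting")
    log[[epoch + 1L]] <- tibble::tibble(epoch = epoch, mse = mse)
    if (verbose && epoch %% 20L == 0L) {
      message(sprintf("imputer epoch %3d  mse %.5f", epoch, mse))
    }
  }
  log <- dplyr::bind_rows(log)
  structure(list(imputer = imputer, log = log, initial_mse = initial_mse,
                 final_mse = log$mse[nrow(log)],
                 imputer_cfg = imputer_cfg, imp_train_cfg = imp_train_cfg),
            class = "allodyn_imputer_fit")
}
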