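#' Kaiming-normal initialization
#'
#' Draws every convolutional and fully connected weight matrix from
#' N(0, 2/fan_in) (ReLU gain), sets all biases to zero, and resets batch
#' normalization to gamma = 1, beta = 0 with fresh running statistics.
#' Deterministic for a given seed.
#'
#' @param model an `allodyn_model` or `allodyn_imputer`.
#' @param seed integer seed.
#' @return the initialized model.
#' @export
init_parameters <- function(model, seed = 0L) {
  set.seed(seed)
  for (br in names(branch_list(model))) {
    layers <- branch_list(model)[[br]]
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      if (ly$type %in% c("conv", "dense")) {
        fan_in <- ncol(ly$W)
        ly$W <- matrix(rnorm(length(ly$W), sd = sqrt(2 / fan_in)),
                       nrow(ly$W), ncol(ly$W))
        ly$b <- numeric(length(ly$b))
      } else if (ly$type == "bn") {
        ly$gamma <- rep(1, ly$n); ly$beta <- numeric(ly$n)
        ly$running_mean <- numeric(ly$n); ly$running_var <- rep(1, ly$n)
      }
      layers[[i]] <- ly
    }
    model <- set_branch(model, br, layers)
  }
  model
}

#' Max-norm weight constraint
#'
#' Rescales every output-unit weight vector (row of a conv or dense weight
#' matrix) whose L2 norm exceeds the threshold back to the threshold,
#' preserving its direction; rows within the threshold are untouched.
#' Applied after every optimizer step during training.
#'
#' @param model an `allodyn_model` or `allodyn_imputer`.
#' @param threshold maximum row norm (default 3.0).
#' @return the constrained model.
#' @export
maxnorm_constrain <- function(model, threshold = 3.0) {
  if (threshold <= 0) abort("`threshold` must be positive")
  for (br in names(branch_list(model))) {
    layers <- branch_list(model)[[br]]
    for (i in seq_along(layers)) {
      ly <- layers[[i]]
      if (ly$type %in% c("conv", "dense")) {
        norms <- sqrt(rowSums(ly$W^2))
        over <- norms > threshold
        if (any(over)) {
          ly$W[over, ] <- ly$W[over, , drop = FALSE] * (threshold / norms[over])
        }
        layers[[i]] <- ly
      }
    }
    model <- set_branch(model, br, layers)
  }
  model
}

# maximum row norm over all conv/dense weight matrices (test/diagnostic)
max_weight_norm <- function(model) {
  mx <- 0
  for (layers in branch_list(model)) {
    for (ly in layers) {
      if (ly$type %in% c("conv", "dense")) {
        mx <- max(mx, sqrt(max(rowSums(ly$W^2))))
      }
    }
  }
  mx
}

# optimizer state mirroring the model's parameter structure
optim_init <- function(model) {
  state <- list(t = 0L, m = list(), s = list())
  for (br in names(branch_list(model))) {
    layers <- branch_list(model)[[br]]
    state$m[[br]] <- lapply(layers, function(ly)
      lapply(setNames(nm = layer_param_names(ly)), function(nm) {
        d <- dim(ly[[nm]])
        if (is.null(d)) numeric(length(ly[[nm]])) else matrix(0, d[1], d[2])
      }))
    state$s[[br]] <- state$m[[br]]
  }
  state
}

#' AdaBelief / Adam parameter update
#'
#' One optimizer step over all trainable parameters. `method =
#' "adabelief"` uses the belief term `s_t = beta2 s_{t-1} + (1 - beta2)
#' (g_t - m_t)^2 + eps` with bias-corrected moments and decoupled weight
#' decay (`theta <- theta - lr * wd * theta`). `method = "adam"` is
#' standard Adam with coupled L2 weight decay (`g <- g + wd * theta`), the
#' convention of common deep-learning Adam implementations, used for the
#' imputer.
#'
#' @param model model whose parameters are updated.
#' @param grads gradient structure as returned by the trainer's backward
#'   pass (per branch, per layer, per parameter).
#' @param state optimizer state from `optim_init()`.
#' @param lr learning rate.
#' @param beta1,beta2 moment decay rates.
#' @param eps stability constant.
#' @param weight_decay weight-decay coefficient.
#' @param method `"adabelief"` or `"adam"`.
#' @return list with the updated `model` and `state`.
#' @keywords internal
optim_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                       eps = 1e-16, weight_decay = 0,
                       method = c("adabelief", "adam")) {
  method <- match.arg(method)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (br in names(branch_list(model))) {
    layers <- branch_list(model)[[br]]
    gbr <- grads[[br]]
    if (is.null(gbr)) next
    for (i in seq_along(layers)) {
      pn <- layer_param_names(layers[[i]])
      if (!length(pn) || is.null(gbr[[i]])) next
      for (nm in pn) {
        g <- gbr[[i]][[nm]]
        p <- layers[[i]][[nm]]
        if (method == "adam" && weight_decay > 0) g <- g + weight_decay * p
        m <- beta1 * state$m[[br]][[i]][[nm]] + (1 - beta1) * g
        if (method == "adabelief") {
          s <- beta2 * state$s[[br]][[i]][[nm]] + (1 - beta2) * (g - m)^2 + eps
        } else {
          s <- beta2 * state$s[[br]][[i]][[nm]] + (1 - beta2) * g^2
        }
        state$m[[br]][[i]][[nm]] <- m
        state$s[[br]][[i]][[nm]] <- s
        upd <- lr * (m / bc1) / (sqrt(s / bc2) + eps)
        p <- p - upd
        if (method == "adabelief" && weight_decay > 0) {
          p <- p - lr * weight_decay * p
        }
        layers[[i]][[nm]] <- p
      }
    }
    model <- set_branch(model, br, layers)
  }
  list(model = model, state = state)
}
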