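# Minimal CPU neural-network engine.
#
# Representation conventions:
#   * convolutional stages carry activations as a (channels x length*batch)
#     matrix whose columns are per-sample contiguous blocks of `length`;
#   * dense stages carry (features x batch) matrices.
# Convolutions are evaluated as im2col matrix products so all heavy lifting
# goes through BLAS. Backward passes return both input gradients (needed by
# integrated gradients) and parameter gradients (needed by the optimizer).

layer_conv <- function(in_ch, out_ch, k, stride, pad = k %/% 2L) {
  list(type = "conv", in_ch = in_ch, out_ch = out_ch, k = as.integer(k),
       stride = as.integer(stride), pad = as.integer(pad),
       W = matrix(0, out_ch, in_ch * k), b = numeric(out_ch))
}

layer_bn <- function(n) {
  list(type = "bn", n = n, gamma = rep(1, n), beta = numeric(n),
       running_mean = numeric(n), running_var = rep(1, n),
       eps = 1e-5, momentum = 0.1)
}

layer_relu <- function() list(type = "relu")

layer_pool <- function(k = 2L, stride = 2L) {
  stopifnot(k == 2L, stride == 2L)
  list(type = "pool", k = 2L, stride = 2L)
}

layer_flatten <- function() list(type = "flatten")

layer_dense <- function(n_in, n_out) {
  list(type = "dense", n_in = n_in, n_out = n_out,
       W = matrix(0, n_out, n_in), b = numeric(n_out))
}

layer_dropout <- function(p) {
  stopifnot(p >= 0, p < 1)
  list(type = "dropout", p = p)
}

conv_out_len <- function(L, k, stride, pad) (L + 2L * pad - k) %/% stride + 1L

# im2col index vectors are pure functions of (k, stride, pad, L_in, B);
# cache them so the training loop does not rebuild them every batch
.conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(k, s, p, L_in, B) {
  key <- paste(k, s, p, L_in, B, sep = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  L_pad <- L_in + 2L * p
  L_out <- conv_out_len(L_in, k, s, p)
  if (L_out < 1L) {
    abort(sprintf("input length %d too short for conv kernel %d", L_in, k))
  }
  off <- (0:(B - 1L)) * L_pad
  cols_data <- as.vector(outer(p + seq_len(L_in), off, `+`))
  base_t <- as.vector(outer(seq_len(k), (0:(L_out - 1L)) * s, `+`))
  colidx <- as.vector(outer(base_t, off, `+`))
  colj <- lapply(seq_len(k), function(j)
    as.vector(outer((0:(L_out - 1L)) * s + j, off, `+`)))
  val <- list(L_pad = L_pad, L_out = L_out, cols_data = cols_data,
              colidx = colidx, colj = colj)
  if (length(.conv_idx_cache) > 64L) {
    rm(list = ls(.conv_idx_cache), envir = .conv_idx_cache)
  }
  .conv_idx_cache[[key]] <- val
  val
}

conv_forward <- function(layer, X, B, L_in) {
  C <- layer$in_ch; k <- layer$k
  ix <- conv_indices(k, layer$stride, layer$pad, L_in, B)
  Xp <- matrix(0, C, ix$L_pad * B)
  Xp[, ix$cols_data] <- X
  Xcol <- Xp[, ix$colidx]
  dim(Xcol) <- c(C * k, ix$L_out * B)
  out <- layer$W %*% Xcol + layer$b
  list(out = out, L_out = ix$L_out,
       cache = list(Xcol = Xcol, B = B, L_in = L_in, ix = ix))
}

conv_backward <- function(layer, cache, dY) {
  C <- layer$in_ch; k <- layer$k
  ix <- cache$ix
  dW <- tcrossprod(dY, cache$Xcol)
  db <- rowSums(dY)
  dXcol <- crossprod(layer$W, dY)
  dXp <- matrix(0, C, ix$L_pad * cache$B)
  for (j in seq_len(k)) {
    dXp[, ix$colj[[j]]] <- dXp[, ix$colj[[j]], drop = FALSE] +
      dXcol[(j - 1L) * C + seq_len(C), , drop = FALSE]
  }
  list(dX = dXp[, ix$cols_data, drop = FALSE],
       grads = list(W = dW, b = db))
}

pool_forward <- function(layer, X, B, L_in) {
  C <- nrow(X)
  L_out <- L_in %/% 2L
  if (L_out < 1L) abort("input length too short for max-pooling")
  if (L_in %% 2L == 1L) {
    keep <- as.vector(outer(seq_len(2L * L_out), (0:(B - 1L)) * L_in, `+`))
    X <- X[, keep, drop = FALSE]
  }
  o <- seq(1L, ncol(X), by = 2L)
  A1 <- X[, o, drop = FALSE]; A2 <- X[, o + 1L, drop = FALSE]
  M <- A1 >= A2
  out <- A2; out[M] <- A1[M]
  list(out = out, L_out = L_out,
       cache = list(M = M, B = B, L_in = L_in, L_out = L_out, C = C))
}

pool_backward <- function(layer, cache, dY) {
  C <- cache$C; B <- cache$B; L_in <- cache$L_in; L_out <- cache$L_out
  dXe <- matrix(0, C, 2L * L_out * B)
  o <- seq(1L, ncol(dXe), by = 2L)
  dXe[, o] <- dY * cache$M
  dXe[, o + 1L] <- dY * !cache$M
  if (L_in %% 2L == 1L) {
    dX <- matrix(0, C, L_in * B)
    keep <- as.vector(outer(seq_len(2L * L_out), (0:(B - 1L)) * L_in, `+`))
    dX[, keep] <- dXe
  } else {
    dX <- dXe
  }
  list(dX = dX, grads = NULL)
}

bn_forward <- function(layer, X, training) {
  if (training) {
    N <- ncol(X)
    mu <- rowMeans(X)
    xc <- X - mu
    v <- rowMeans(xc * xc)
    ivar <- 1 / sqrt(v + layer$eps)
    xhat <- xc * ivar
    out <- layer$gamma * xhat + layer$beta
    mom <- layer$momentum
    layer$running_mean <- (1 - mom) * layer$running_mean + mom * mu
    v_unb <- if (N > 1L) v * N / (N - 1L) else v
    layer$running_var <- (1 - mom) * layer$running_var + mom * v_unb
    list(out = out, layer = layer,
         cache = list(xhat = xhat, ivar = ivar, training = TRUE))
  } else {
    ivar <- 1 / sqrt(layer$running_var + layer$eps)
    xhat <- (X - layer$running_mean) * ivar
    out <- layer$gamma * xhat + layer$beta
    list(out = out, layer = layer,
         cache = list(xhat = xhat, scale = layer$gamma * ivar,
                      training = FALSE))
  }
}

bn_backward <- function(layer, cache, dY) {
  dgamma <- rowSums(dY * cache$xhat)
  dbeta <- rowSums(dY)
  if (cache$training) {
    N <- ncol(dY)
    dxhat <- dY * layer$gamma
    dX <- (cache$ivar / N) *
      (N * dxhat - rowSums(dxhat) - cache$xhat * rowSums(dxhat * cache$xhat))
  } else {
    dX <- dY * cache$scale
  }
  list(dX = dX, grads = list(gamma = dgamma, beta = dbeta))
}

relu_forward <- function(layer, X) {
  M <- X > 0
  list(out = X * M, cache = list(M = M))
}

dropout_forward <- function(layer, X, training) {
  if (!training || layer$p == 0) {
    return(list(out = X, cache = list(mask = NULL)))
  }
  keep <- 1 - layer$p
  mask <- matrix((runif(length(X)) < keep) / keep, nrow(X), ncol(X))
  list(out = X * mask, cache = list(mask = mask))
}

dense_forward <- function(layer, X) {
  list(out = layer$W %*% X + layer$b, cache = list(X = X))
}

dense_backward <- function(layer, cache, dY) {
  list(dX = crossprod(layer$W, dY),
       grads = list(W = tcrossprod(dY, cache$X), b = rowSums(dY)))
}

# Forward through a layer chain. X enters in conv layout (with length L0)
# when the chain starts with conv layers, otherwise dense layout.
net_forward <- function(layers, X, B, L0 = NULL, training = FALSE) {
  caches <- vector("list", length(layers))
  L <- L0
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    r <- switch(ly$type,
      conv = conv_forward(ly, X, B, L),
      pool = pool_forward(ly, X, B, L),
      bn = bn_forward(ly, X, training),
      relu = relu_forward(ly, X),
      dropout = dropout_forward(ly, X, training),
      dense = dense_forward(ly, X),
      flatten = {
        C <- nrow(X)
        list(out = matrix(X, C * L, B), cache = list(C = C, L = L))
      },
      abort(paste("unknown layer type:", ly$type)))
    X <- r$out
    if (!is.null(r$L_out)) L <- r$L_out
    if (!is.null(r$layer)) layers[[i]] <- r$layer
    caches[[i]] <- r$cache
  }
  list(out = X, caches = caches, layers = layers)
}

net_backward <- function(layers, caches, dOut) {
  grads <- vector("list", length(layers))
  dX <- dOut
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    ca <- caches[[i]]
    r <- switch(ly$type,
      conv = conv_backward(ly, ca, dX),
      pool = pool_backward(ly, ca, dX),
      bn = bn_backward(ly, ca, dX),
      relu = list(dX = dX * ca$M, grads = NULL),
      dropout = if (is.null(ca$mask)) list(dX = dX, grads = NULL)
                else list(dX = dX * ca$mask, grads = NULL),
      dense = dense_backward(ly, ca, dX),
      flatten = list(dX = matrix(dX, ca$C, ca$L * ncol(dX)), grads = NULL))
    dX <- r$dX
    grads[i] <- list(r$grads)  # keep NULL placeholders for param-free layers
  }
  list(dX = dX, grads = grads)
}

# names of trainable parameter fields per layer type
layer_param_names <- function(layer) {
  switch(layer$type,
         conv = c("W", "b"),
         dense = c("W", "b"),
         bn = c("gamma", "beta"),
         character())
}
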