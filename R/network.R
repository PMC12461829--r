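#' Classifier architecture configuration
#'
#' The dual-branch classifier: a temporal branch (two conv blocks of 32
#' and 64 filters, kernels 5 and 3, stride 2, each followed by batch
#' normalization, ReLU and 2/2 max-pooling, then fully connected layers of
#' 16 and 8 units with batch norm, ReLU and dropout), a binary branch
#' (fully connected 16 and 8 units with the same block structure), and a
#' shared head (concatenated 16-dimensional embedding, a fully connected
#' layer of 8 units with batch norm, ReLU and dropout, and a final
#' 2-logit output layer). Both branch embeddings are 8-dimensional so the
#' concatenation is 16-dimensional. The flatten width of the temporal
#' branch is derived from `n_frames`, never hard-coded.
#'
#' @param conv_filters numbers of filters of the two conv blocks.
#' @param conv_kernels kernel sizes of the two conv blocks.
#' @param conv_strides strides of the two conv blocks.
#' @param pool_size,pool_stride max-pooling kernel and stride.
#' @param temporal_fc fully connected widths of the temporal branch.
#' @param binary_fc fully connected widths of the binary branch.
#' @param head_fc width of the shared head's hidden layer.
#' @param n_classes number of output logits.
#' @param dropout_p dropout probability in all FC blocks.
#' @param n_descriptors rows of the descriptor matrix (16).
#' @param n_frames columns of the descriptor matrix.
#' @param fp_length fingerprint length.
#' @return an object of class `allodyn_model_config`.
#' @export
model_config <- function(conv_filters = c(32L, 64L),
                         conv_kernels = c(5L, 3L),
                         conv_strides = c(2L, 2L),
                         pool_size = 2L, pool_stride = 2L,
                         temporal_fc = c(16L, 8L),
                         binary_fc = c(16L, 8L),
                         head_fc = 8L,
                         n_classes = 2L,
                         dropout_p = 0.7,
                         n_descriptors = 16L,
                         n_frames = 2000L,
                         fp_length = 2048L) {
  stopifnot(length(conv_filters) == 2L, length(conv_kernels) == 2L,
            length(conv_strides) == 2L, length(temporal_fc) == 2L,
            length(binary_fc) == 2L)
  if (temporal_fc[2] != binary_fc[2]) {
    abort("branch embedding widths must match so concatenation is possible")
  }
  cfg <- list(conv_filters = as.integer(conv_filters),
              conv_kernels = as.integer(conv_kernels),
              conv_strides = as.integer(conv_strides),
              pool_size = as.integer(pool_size),
              pool_stride = as.integer(pool_stride),
              temporal_fc = as.integer(temporal_fc),
              binary_fc = as.integer(binary_fc),
              head_fc = assert_count(head_fc, "head_fc"),
              n_classes = assert_count(n_classes, "n_classes"),
              dropout_p = assert_number(dropout_p, "dropout_p", 0, 1 - 1e-9),
              n_descriptors = assert_count(n_descriptors, "n_descriptors"),
              n_frames = assert_count(n_frames, "n_frames"),
              fp_length = assert_count(fp_length, "fp_length"))
  structure(cfg, class = "allodyn_model_config")
}

# sequence length after the conv/pool stack; errors if T is too short
temporal_lengths <- function(cfg) {
  L <- cfg$n_frames
  for (i in 1:2) {
    L <- conv_out_len(L, cfg$conv_kernels[i], cfg$conv_strides[i],
                      cfg$conv_kernels[i] %/% 2L)
    L <- L %/% cfg$pool_stride
    if (L < 1L) {
      abort(sprintf(
        "n_frames = %d is too short for the conv/pool stack (block %d empty); need at least %d frames",
        cfg$n_frames, i, 4L^i))
    }
  }
  L
}

#' Build the dual-branch classifier
#'
#' Assembles the temporal, binary and head layer stacks from a
#' [model_config()] and Kaiming-initializes the weights (see
#' [init_parameters()]; call it again with the training seed for a
#' reproducible run).
#'
#' @param config an [model_config()].
#' @param init_seed seed for the initial Kaiming draw.
#' @return an object of class `allodyn_model`.
#' @export
build_classifier <- function(config = model_config(), init_seed = 0L) {
  L_flat <- temporal_lengths(config)
  flat_width <- config$conv_filters[2] * L_flat
  p <- config$dropout_p
  temporal <- list(
    layer_conv(config$n_descriptors, config$conv_filters[1],
               config$conv_kernels[1], config$conv_strides[1]),
    layer_bn(config$conv_filters[1]), layer_relu(), layer_pool(),
    layer_conv(config$conv_filters[1], config$conv_filters[2],
               config$conv_kernels[2], config$conv_strides[2]),
    layer_bn(config$conv_filters[2]), layer_relu(), layer_pool(),
    layer_flatten(),
    layer_dense(flat_width, config$temporal_fc[1]),
    layer_bn(config$temporal_fc[1]), layer_relu(), layer_dropout(p),
    layer_dense(config$temporal_fc[1], config$temporal_fc[2]),
    layer_bn(config$temporal_fc[2]), layer_relu(), layer_dropout(p))
  binary <- list(
    layer_dense(config$fp_length, config$binary_fc[1]),
    layer_bn(config$binary_fc[1]), layer_relu(), layer_dropout(p),
    layer_dense(config$binary_fc[1], config$binary_fc[2]),
    layer_bn(config$binary_fc[2]), layer_relu(), layer_dropout(p))
  head <- list(
    layer_dense(config$temporal_fc[2] + config$binary_fc[2], config$head_fc),
    layer_bn(config$head_fc), layer_relu(), layer_dropout(p),
    layer_dense(config$head_fc, config$n_classes))
  model <- structure(
    list(config = config, temporal = temporal, binary = binary, head = head),
    class = "allodyn_model")
  init_parameters(model, init_seed)
}

model_branches <- function(model) c("temporal", "binary", "head")

#' Count trainable parameters
#'
#' @param model an `allodyn_model` or `allodyn_imputer`.
#' @return total number of trainable scalars.
#' @export
n_parameters <- function(model) {
  layers <- unlist(lapply(branch_list(model), identity), recursive = FALSE)
  sum(vapply(layers, function(ly)
    sum(vapply(layer_param_names(ly), function(nm) length(ly[[nm]]),
               numeric(1))), numeric(1)))
}

branch_list <- function(model) {
  if (inherits(model, "allodyn_imputer")) return(list(net = model$layers))
  list(temporal = model$temporal, binary = model$binary, head = model$head)
}

set_branch <- function(model, name, layers) {
  if (inherits(model, "allodyn_imputer")) model$layers <- layers
  else model[[name]] <- layers
  model
}

# full forward pass; Xt is (16 x T*B) or NULL, Xb is (fp_length x B).
# When Xt is NULL the temporal embedding comes from the imputer.
classifier_forward <- function(model, Xt, Xb, B, training = FALSE,
                               imputer = NULL) {
  if (is.null(Xt)) {
    if (is.null(imputer)) abort("no descriptor matrix and no imputer supplied")
    ri <- net_forward(imputer$layers, Xb, B, training = FALSE)
    e_t <- ri$out
    ft <- NULL
  } else {
    ft <- net_forward(model$temporal, Xt, B, L0 = ncol(Xt) / B,
                      training = training)
    e_t <- ft$out
    model$temporal <- ft$layers
  }
  fb <- net_forward(model$binary, Xb, B, training = training)
  model$binary <- fb$layers
  fused <- rbind(e_t, fb$out)
  fh <- net_forward(model$head, fused, B, training = training)
  model$head <- fh$layers
  list(logits = fh$out, e_t = e_t, e_b = fb$out, model = model,
       caches = list(temporal = if (is.null(ft)) NULL else ft$caches,
                     binary = fb$caches, head = fh$caches),
       origin = if (is.null(Xt)) "imputed" else "temporal")
}

# backward from dLogits; returns gradients per branch and input gradients
classifier_backward <- function(model, fwd, dLogits) {
  bh <- net_backward(model$head, fwd$caches$head, dLogits)
  k <- model$config$temporal_fc[2]
  d_et <- bh$dX[seq_len(k), , drop = FALSE]
  d_eb <- bh$dX[k + seq_len(model$config$binary_fc[2]), , drop = FALSE]
  bb <- net_backward(model$binary, fwd$caches$binary, d_eb)
  bt <- if (!is.null(fwd$caches$temporal)) {
    net_backward(model$temporal, fwd$caches$temporal, d_et)
  } else NULL
  list(grads = list(temporal = if (is.null(bt)) NULL else bt$grads,
                    binary = bb$grads, head = bh$grads),
       dXt = if (is.null(bt)) NULL else bt$dX,
       dXb = bb$dX)
}

#' Temporal-branch embedding of descriptor matrices
#'
#' Runs the temporal branch in eval mode (batch-norm running statistics,
#' dropout off) and returns the 8-dimensional embedding that the shared
#' head consumes — also the target the imputer is trained to mimic.
#'
#' @param model an `allodyn_model`.
#' @param matrices one 16 x T matrix, or a list of them.
#' @return an 8 x n matrix of embeddings (origin `"temporal"`), columns in
#'   input order.
#' @export
temporal_embed <- function(model, matrices) {
  if (is.matrix(matrices)) matrices <- list(matrices)
  Tn <- model$config$n_frames
  ok <- vapply(matrices, function(m)
    is.matrix(m) && nrow(m) == model$config$n_descriptors && ncol(m) == Tn,
    logical(1))
  if (!all(ok)) {
    abort(sprintf("descriptor matrices must be %d x %d",
                  model$config$n_descriptors, Tn))
  }
  B <- length(matrices)
  Xt <- do.call(cbind, matrices)
  r <- net_forward(model$temporal, Xt, B, L0 = Tn, training = FALSE)
  structure(r$out, origin = "temporal")
}

#' Imputer architecture configuration
#'
#' Fully connected network mapping the 2048-bit fingerprint to the
#' 8-dimensional temporal embedding, with ReLU hidden layers.
#'
#' @param input_length fingerprint length.
#' @param output_length embedding width (must equal the classifier's
#'   temporal embedding width).
#' @param hidden_widths hidden layer widths.
#' @return an object of class `allodyn_imputer_config`.
#' @export
imputer_config <- function(input_length = 2048L, output_length = 8L,
                           hidden_widths = c(256L, 64L)) {
  structure(list(input_length = assert_count(input_length, "input_length"),
                 output_length = assert_count(output_length, "output_length"),
                 hidden_widths = as.integer(hidden_widths)),
            class = "allodyn_imputer_config")
}

#' Build the fingerprint-to-embedding imputer
#'
#' @param config an [imputer_config()].
#' @param classifier optional `allodyn_model`; when supplied, the imputer
#'   output width is checked against the classifier's temporal embedding
#'   width.
#' @param init_seed seed for the initial Kaiming draw.
#' @return an object of class `allodyn_imputer`.
#' @export
build_imputer <- function(config = imputer_config(), classifier = NULL,
                          init_seed = 0L) {
  if (!is.null(classifier) &&
      config$output_length != classifier$config$temporal_fc[2]) {
    abort(sprintf(
      "imputer output width %d does not match the classifier embedding width %d",
      config$output_length, classifier$config$temporal_fc[2]))
  }
  widths <- c(config$input_length, config$hidden_widths, config$output_length)
  layers <- list()
  for (i in seq_len(length(widths) - 1L)) {
    layers[[length(layers) + 1L]] <- layer_dense(widths[i], widths[i + 1L])
    if (i < length(widths) - 1L) layers[[length(layers) + 1L]] <- layer_relu()
  }
  imp <- structure(list(config = config, layers = layers),
                   class = "allodyn_imputer")
  init_parameters(imp, init_seed)
}

#' Imputed embedding from fingerprints
#'
#' @param imputer an `allodyn_imputer`.
#' @param fingerprints one 0/1 vector or a list of them (or a matrix with
#'   fingerprints in columns).
#' @return an `output_length x n` matrix of embeddings (origin
#'   `"imputed"`).
#' @export
impute_embed <- function(imputer, fingerprints) {
  Xb <- fingerprint_batch(fingerprints, imputer$config$input_length)
  r <- net_forward(imputer$layers, Xb, ncol(Xb), training = FALSE)
  structure(r$out, origin = "imputed")
}

fingerprint_batch <- function(fingerprints, fp_length) {
  if (is.matrix(fingerprints)) {
    Xb <- fingerprints
  } else if (is.list(fingerprints)) {
    Xb <- do.call(cbind, lapply(fingerprints, as.numeric))
  } else {
    Xb <- matrix(as.numeric(fingerprints), ncol = 1)
  }
  if (nrow(Xb) != fp_length) {
    abort(sprintf("fingerprints must have length %d", fp_length))
  }
  Xb
}

#' Classify one complex sample
#'
#' Routes the temporal input conditionally: when a descriptor matrix is
#' supplied the temporal branch embeds it; otherwise the imputer
#' reconstructs the embedding from the fingerprint. Either way the
#' embedding is concatenated with the binary-branch output and the shared
#' head produces the logits; the decision applies the softmax-threshold
#' abstention rule.
#'
#' @param model an `allodyn_model`.
#' @param fingerprint 0/1 vector (always required).
#' @param matrix optional 16 x T descriptor matrix.
#' @param imputer optional `allodyn_imputer` (required when `matrix` is
#'   absent).
#' @param threshold confidence threshold tau in `[0.5, 1]`.
#' @return a list with `probs` (named length-2 vector), `decision`
#'   (`"orthosteric"`, `"allosteric"` or `"uncertain"`), `origin`
#'   (`"temporal"` or `"imputed"`) and `threshold`.
#' @export
classify <- function(model, fingerprint, matrix = NULL, imputer = NULL,
                     threshold = 0.5) {
  Xb <- fingerprint_batch(fingerprint, model$config$fp_length)
  Xt <- if (is.null(matrix)) NULL else matrix
  fwd <- classifier_forward(model, Xt, Xb, B = 1L, training = FALSE,
                            imputer = imputer)
  probs <- drop(softmax_probs(fwd$logits))
  names(probs) <- ALLODYN_CLASSES
  list(probs = probs, decision = decide(probs, threshold),
       origin = fwd$origin, threshold = threshold)
}

#' Batch predictions for a sample list
#'
#' @param model an `allodyn_model`.
#' @param samples flat sample list or dataset.
#' @param imputer optional imputer used when `use_matrix = FALSE` (or a
#'   sample has no matrix).
#' @param threshold confidence threshold.
#' @param use_matrix use the stored descriptor matrices (`TRUE`) or force
#'   the imputed route (`FALSE`).
#' @param batch_size evaluation batch size.
#' @return a tibble with one row per sample: metadata, class
#'   probabilities, `decision` and `origin`.
#' @export
predict_samples <- function(model, samples, imputer = NULL, threshold = 0.5,
                            use_matrix = TRUE, batch_size = 64L) {
  samples <- dataset_samples(samples)
  info <- samples_info(samples)
  n <- length(samples)
  probs <- matrix(NA_real_, 2L, n)
  origin <- character(n)
  idx_chunks <- split(seq_len(n), ceiling(seq_len(n) / batch_size))
  for (chunk in idx_chunks) {
    Xb <- fingerprint_batch(lapply(samples[chunk], `[[`, "fingerprint"),
                            model$config$fp_length)
    Xt <- NULL
    if (use_matrix) {
      Xt <- do.call(cbind, lapply(samples[chunk], `[[`, "matrix"))
    }
    fwd <- classifier_forward(model, Xt, Xb, B = length(chunk),
                              training = FALSE, imputer = imputer)
    probs[, chunk] <- softmax_probs(fwd$logits)
    origin[chunk] <- fwd$origin
  }
  info$p_orthosteric <- probs[1, ]
  info$p_allosteric <- probs[2, ]
  info$decision <- decide_matrix(probs, threshold)
  info$origin <- origin
  info$threshold <- threshold
  info
}

#' Save / load a model checkpoint
#'
#' Single-file archive holding the classifier (and optionally the
#' imputer), their configurations, the training seed and a format version.
#'
#' @param model an `allodyn_model`.
#' @param path file path.
#' @param imputer optional `allodyn_imputer`.
#' @param seed training seed to record.
#' @export
save_checkpoint <- function(model, path, imputer = NULL, seed = NULL) {
  saveRDS(list(format = "allodyn_checkpoint_v1", model = model,
               imputer = imputer, seed = seed), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint()` returns a list with `model`, `imputer` and
#'   `seed`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  if (!is.list(ck) || !identical(ck$format, "allodyn_checkpoint_v1")) {
    abort("not an allodyn checkpoint")
  }
  ck
}
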