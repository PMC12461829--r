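# Dual-branch classifier, imputer, routing

test_that("forward pass produces two logits and 8-dimensional embeddings", {
  cfg <- tiny_model_config()
  m <- build_classifier(cfg, init_seed = 1)
  mat <- matrix(rnorm(16 * 128), 16, 128)
  fp <- rbinom(256, 1, 0.1)
  pred <- classify(m, fp, mat)
  expect_length(pred$probs, 2L)
  expect_equal(sum(pred$probs), 1, tolerance = 1e-6)
  expect_identical(pred$origin, "temporal")
  emb <- temporal_embed(m, mat)
  expect_equal(dim(emb), c(8L, 1L))
  # batch of n matrices: n embeddings, order preserved
  mats <- list(mat, mat * 0, mat + 1)
  embs <- temporal_embed(m, mats)
  expect_equal(dim(embs), c(8L, 3L))
  expect_equal(embs[, 1], as.vector(temporal_embed(m, mat)))
  expect_equal(embs[, 2], as.vector(temporal_embed(m, mat * 0)))
  expect_true(all(is.finite(embs)))
  expect_error(temporal_embed(m, matrix(0, 15, 128)), "16 x 128")
})

test_that("eval-mode inference is deterministic despite dropout", {
  m <- build_classifier(tiny_model_config(), init_seed = 2)
  mat <- matrix(rnorm(16 * 128), 16, 128)
  fp <- rbinom(256, 1, 0.1)
  p1 <- classify(m, fp, mat)$probs
  p2 <- classify(m, fp, mat)$probs
  expect_identical(p1, p2)
})

test_that("parameter count matches the closed-form count for the default config", {
  cfg <- model_config()  # 16 x 2000 input, 2048-bit fingerprints
  m <- build_classifier(cfg)
  # independent closed-form count
  L1 <- floor((2000 + 2 * 2 - 5) / 2) + 1   # conv1, pad 2
  P1 <- floor(L1 / 2)
  L2 <- floor((P1 + 2 * 1 - 3) / 2) + 1     # conv2, pad 1
  P2 <- floor(L2 / 2)
  flat <- 64 * P2
  count <- (32 * 16 * 5 + 32) + 2 * 32 +              # conv1 + bn
    (64 * 32 * 3 + 64) + 2 * 64 +                     # conv2 + bn
    (16 * flat + 16) + 2 * 16 + (8 * 16 + 8) + 2 * 8 + # temporal fc
    (16 * 2048 + 16) + 2 * 16 + (8 * 16 + 8) + 2 * 8 + # binary fc
    (8 * 16 + 8) + 2 * 8 + (2 * 8 + 2)                # head
  expect_identical(n_parameters(m), count)
  # the flatten width is derived, not hard-coded: a shorter input changes it
  m2 <- build_classifier(model_config(n_frames = 400L))
  expect_lt(n_parameters(m2), count)
})

test_that("too-short inputs are rejected with the minimum length", {
  expect_error(model_config(n_frames = 3L) |> build_classifier(), "frames")
})

test_that("temporal embedding equals a manual layer-by-layer recomputation", {
  cfg <- tiny_model_config(n_frames = 32L)
  m <- build_classifier(cfg, init_seed = 5)
  mat <- matrix(rnorm(16 * 32), 16, 32)
  got <- as.vector(temporal_embed(m, mat))
  # manual forward pass, written independently of net_forward
  conv1d <- function(x, W, b, k, s, pad) {
    C <- nrow(x); L <- ncol(x)
    xp <- cbind(matrix(0, C, pad), x, matrix(0, C, pad))
    L_out <- (L + 2 * pad - k) %/% s + 1
    out <- matrix(0, nrow(W), L_out)
    for (t in seq_len(L_out)) {
      patch <- xp[, (t - 1) * s + seq_len(k), drop = FALSE]
      out[, t] <- W %*% as.vector(patch) + b
    }
    out
  }
  bn_eval <- function(x, ly) ly$gamma * (x - ly$running_mean) /
    sqrt(ly$running_var + ly$eps) + ly$beta
  relu <- function(x) pmax(x, 0)
  pool <- function(x) {
    L <- ncol(x) %/% 2
    sapply(seq_len(L), function(t) apply(x[, c(2 * t - 1, 2 * t), drop = FALSE],
                                         1, max))
  }
  tl <- m$temporal
  h <- conv1d(mat, tl[[1]]$W, tl[[1]]$b, 5, 2, 2)
  h <- pool(relu(bn_eval(h, tl[[2]])))
  h <- conv1d(h, tl[[5]]$W, tl[[5]]$b, 3, 2, 1)
  h <- pool(relu(bn_eval(h, tl[[6]])))
  v <- as.vector(h)   # column-major: channels fastest, matches flatten
  v <- relu(bn_eval(tl[[10]]$W %*% v + tl[[10]]$b, tl[[11]]))
  v <- relu(bn_eval(tl[[14]]$W %*% v + tl[[14]]$b, tl[[15]]))
  expect_equal(got, drop(v), tolerance = 1e-10)
})

test_that("imputer maps fingerprints to embedding space and checks widths", {
  icfg <- imputer_config(input_length = 256L)
  imp <- build_imputer(icfg, init_seed = 3)
  fp <- rbinom(256, 1, 0.1)
  e <- impute_embed(imp, fp)
  expect_equal(dim(e), c(8L, 1L))
  expect_identical(attr(e, "origin"), "imputed")
  # batch determinism in eval mode
  fps <- replicate(4, rbinom(256, 1, 0.1), simplify = FALSE)
  expect_identical(impute_embed(imp, fps), impute_embed(imp, fps))
  # width mismatch against a classifier is rejected
  cls <- build_classifier(tiny_model_config())
  expect_error(build_imputer(imputer_config(input_length = 256L,
                                            output_length = 4L), cls),
               "width")
})

test_that("zero-input imputer forward equals the manual bias pathway", {
  # 4 -> 3 -> 2 toy: with zero input, layer1 out = b1, then relu, etc.
  icfg <- imputer_config(input_length = 4L, output_length = 2L,
                         hidden_widths = 3L)
  imp <- build_imputer(icfg, init_seed = 9)
  # put nonzero biases in to make the pathway informative
  imp$layers[[1]]$b <- c(0.5, -1, 2)
  imp$layers[[3]]$b <- c(0.25, -0.75)
  got <- as.vector(impute_embed(imp, c(0, 0, 0, 0)))
  manual <- imp$layers[[3]]$W %*% pmax(c(0.5, -1, 2), 0) + c(0.25, -0.75)
  expect_equal(got, drop(manual), tolerance = 1e-12)
})

test_that("conditional routing: imputed path used when the matrix is absent", {
  cfg <- tiny_model_config()
  m <- build_classifier(cfg, init_seed = 4)
  imp <- build_imputer(imputer_config(input_length = 256L), m, init_seed = 4)
  fp <- rbinom(256, 1, 0.2)
  pred <- classify(m, fp, matrix = NULL, imputer = imp)
  expect_identical(pred$origin, "imputed")
  expect_equal(sum(pred$probs), 1, tolerance = 1e-6)
  expect_error(classify(m, fp), "imputer")
})

test_that("routes coincide when the head ignores the temporal embedding", {
  # weight surgery: zero the head's weights on the temporal half
  cfg <- tiny_model_config()
  m <- build_classifier(cfg, init_seed = 6)
  m$head[[1]]$W[, 1:8] <- 0
  imp <- build_imputer(imputer_config(input_length = 256L), m, init_seed = 1)
  fp <- rbinom(256, 1, 0.2)
  mat <- matrix(rnorm(16 * 128), 16, 128)
  p_temporal <- classify(m, fp, mat)$probs
  p_imputed <- classify(m, fp, matrix = NULL, imputer = imp)$probs
  expect_equal(p_temporal, p_imputed, tolerance = 1e-12)
})

test_that("logits are finite and softmax sums to one on extreme inputs", {
  m <- build_classifier(tiny_model_config(), init_seed = 8)
  for (mat in list(matrix(0, 16, 128), matrix(1e3, 16, 128),
                   matrix(-1e3, 16, 128))) {
    pred <- classify(m, rep(1, 256), mat)
    expect_true(all(is.finite(pred$probs)))
    expect_equal(sum(pred$probs), 1, tolerance = 1e-6)
  }
})

test_that("checkpoints round-trip the model, imputer and seed", {
  m <- build_classifier(tiny_model_config(), init_seed = 10)
  imp <- build_imputer(imputer_config(input_length = 256L), m)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, imputer = imp, seed = 10L)
  ck <- load_checkpoint(path)
  expect_identical(ck$model, m)
  expect_identical(ck$imputer, imp)
  expect_identical(ck$seed, 10L)
  expect_error(load_checkpoint(withr::local_tempfile(fileext = ".rds") |>
                                 (\(p) { saveRDS(1, p); p })()),
               "checkpoint")
})
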