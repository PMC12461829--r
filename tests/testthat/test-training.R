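# Initialization, max-norm, AdaBelief, training loops

test_that("Kaiming initialization: zero biases, correct weight variance, seeded", {
  m <- build_classifier(tiny_model_config(), init_seed = 7)
  for (br in c("temporal", "binary", "head")) {
    for (ly in m[[br]]) {
      if (ly$type %in% c("conv", "dense")) expect_true(all(ly$b == 0))
      if (ly$type == "bn") {
        expect_true(all(ly$gamma == 1) && all(ly$beta == 0))
      }
    }
  }
  m2 <- build_classifier(tiny_model_config(), init_seed = 7)
  expect_identical(m, m2)
  expect_false(identical(m, build_classifier(tiny_model_config(),
                                             init_seed = 8)))
  # variance oracle on a large layer: Var(W) ~ 2 / fan_in within 5%
  big <- build_imputer(imputer_config(input_length = 1000L,
                                      hidden_widths = 1000L), init_seed = 1)
  W <- big$layers[[1]]$W  # 1000 x 1000
  expect_equal(var(as.vector(W)), 2 / 1000, tolerance = 0.05)
})

test_that("max-norm rescales only over-threshold rows and preserves direction", {
  imp <- build_imputer(imputer_config(input_length = 8L, output_length = 2L,
                                      hidden_widths = 4L))
  W <- rbind(c(6, 0, 0, 0, 0, 0, 0, 0),
             c(1, 1, 1, 1, 0, 0, 0, 0),
             rep(0.1, 8), rep(3, 8))
  imp$layers[[1]]$W <- W
  out <- maxnorm_constrain(imp, 3)$layers[[1]]$W
  expect_equal(sqrt(sum(out[1, ]^2)), 3)              # 6 -> 3
  expect_equal(out[1, ] / sqrt(sum(out[1, ]^2)), W[1, ] / 6)  # direction kept
  expect_identical(out[2, ], W[2, ])                  # norm 2: untouched
  expect_identical(out[3, ], W[3, ])
  expect_equal(sqrt(sum(out[4, ]^2)), 3)              # norm 8.49 -> 3
  # after constraining a random model, no row exceeds the threshold
  m <- build_classifier(tiny_model_config(), init_seed = 3)
  for (br in c("temporal", "binary", "head")) {
    for (i in seq_along(m[[br]])) {
      if (m[[br]][[i]]$type %in% c("conv", "dense")) {
        m[[br]][[i]]$W <- m[[br]][[i]]$W * 10
      }
    }
  }
  m <- maxnorm_constrain(m, 3)
  expect_lte(allodyn:::max_weight_norm(m), 3 + 1e-6)
  expect_error(maxnorm_constrain(m, -1), "positive")
})

test_that("AdaBelief reproduces hand-computed steps on a one-parameter problem", {
  # single dense 1 -> 1 layer, no bias gradient; constant gradient g
  imp <- build_imputer(imputer_config(input_length = 1L, output_length = 1L,
                                      hidden_widths = integer(0)))
  imp$layers[[1]]$W <- matrix(2)
  st <- allodyn:::optim_init(imp)
  lr <- 0.1; b1 <- 0.9; b2 <- 0.999; eps <- 1e-16; g <- 0.5
  # hand-computed AdaBelief (belief term, bias correction, no weight decay)
  th <- 2; m <- 0; s <- 0
  for (t in 1:3) {
    m <- b1 * m + (1 - b1) * g
    s <- b2 * s + (1 - b2) * (g - m)^2 + eps
    th <- th - lr * (m / (1 - b1^t)) / (sqrt(s / (1 - b2^t)) + eps)
    grads <- list(net = list(list(W = matrix(g), b = 0)))
    step <- allodyn:::optim_step(imp, grads, st, lr = lr, beta1 = b1,
                                 beta2 = b2, eps = eps, weight_decay = 0,
                                 method = "adabelief")
    imp <- step$model; st <- step$state
    expect_equal(imp$layers[[1]]$W[1, 1], th, tolerance = 1e-12)
  }
  # decoupled weight decay: with zero gradient and fresh state the update
  # reduces to the pure multiplicative shrink p * (1 - lr * wd)
  st0 <- allodyn:::optim_init(imp)
  step_wd <- allodyn:::optim_step(imp, list(net = list(list(W = matrix(0), b = 0))),
                                  st0, lr = lr, beta1 = b1, beta2 = b2,
                                  eps = eps, weight_decay = 0.1,
                                  method = "adabelief")
  expect_equal(step_wd$model$layers[[1]]$W[1, 1],
               imp$layers[[1]]$W[1, 1] * (1 - lr * 0.1), tolerance = 1e-12)
})

test_that("Adam with coupled L2 decay matches a hand-computed step", {
  imp <- build_imputer(imputer_config(input_length = 1L, output_length = 1L,
                                      hidden_widths = integer(0)))
  imp$layers[[1]]$W <- matrix(1.5)
  st <- allodyn:::optim_init(imp)
  lr <- 1e-2; wd <- 0.1; g_raw <- 0.3
  g <- g_raw + wd * 1.5
  m <- 0.1 * g; v <- 0.001 * g^2
  expected <- 1.5 - lr * (m / 0.1) / (sqrt(v / 0.001) + 1e-8)
  step <- allodyn:::optim_step(imp, list(net = list(list(W = matrix(g_raw), b = 0))),
                               st, lr = lr, beta1 = 0.9, beta2 = 0.999,
                               eps = 1e-8, weight_decay = wd, method = "adam")
  expect_equal(step$model$layers[[1]]$W[1, 1], expected, tolerance = 1e-12)
})

test_that("short training runs are reproducible and respect the max-norm invariant", {
  ds <- tiny_dataset()
  samples <- dataset_samples(ds)
  split <- grouped_split(samples, seed = 2)
  tc <- train_config(epochs = 3L, seed = 5L)
  mc <- tiny_model_config()
  f1 <- train_classifier(samples, split, mc, loss_config(), tc)
  f2 <- train_classifier(samples, split, mc, loss_config(), tc)
  expect_equal(f1$log$train_loss, f2$log$train_loss, tolerance = 1e-6)
  expect_identical(f1$model, f2$model)
  expect_lte(allodyn:::max_weight_norm(f1$model), 3 + 1e-6)
  # gamma column follows the schedule
  expect_equal(f1$log$gamma, c(0, 0.2, 0.4))
  # training log carries the entropy weight used
  expect_true(all(f1$log$lambda == 0.1))
  # the training loss decreases overall on this easy, tiny problem
  expect_lt(f1$log$train_loss[3], f1$log$train_loss[1])
})

test_that("gamma reaches its cap in the log when training past epoch 10", {
  ds <- tiny_dataset()
  samples <- dataset_samples(ds)
  split <- grouped_split(samples, seed = 2)
  f <- train_classifier(samples, split, tiny_model_config(),
                        train_cfg = train_config(epochs = 12L, seed = 1L))
  expect_equal(f$log$gamma[11:12], c(2, 2))
})

test_that("the imputer trains to lower MSE and an 8-wide output", {
  ds <- tiny_dataset()
  samples <- dataset_samples(ds)
  split <- grouped_split(samples, seed = 2)
  fit <- train_classifier(samples, split, tiny_model_config(),
                          train_cfg = train_config(epochs = 2L, seed = 5L))
  ifit <- train_imputer(samples, fit,
                        imputer_cfg = imputer_config(input_length = 256L),
                        imp_train_cfg = imputer_train_config(epochs = 30L,
                                                             lr = 1e-3,
                                                             seed = 2L))
  expect_lt(ifit$final_mse, ifit$initial_mse)
  expect_equal(nrow(ifit$log), 30L)
  emb <- impute_embed(ifit$imputer, samples[[1]]$fingerprint)
  expect_equal(dim(emb), c(8L, 1L))
})

test_that("an imputer fitting a constant embedding target drives MSE to ~0", {
  # all samples share one descriptor matrix -> one target embedding; the
  # optimum is the constant function and the MSE floor is 0
  ds <- tiny_dataset()
  samples <- dataset_samples(ds)
  shared <- samples[[1]]$matrix
  for (i in seq_along(samples)) samples[[i]]$matrix <- shared
  split <- grouped_split(samples, seed = 2)
  fit <- train_classifier(samples, split, tiny_model_config(),
                          train_cfg = train_config(epochs = 1L, seed = 5L))
  ifit <- train_imputer(samples, fit,
                        imputer_cfg = imputer_config(input_length = 256L),
                        imp_train_cfg = imputer_train_config(epochs = 150L,
                                                             lr = 1e-2,
                                                             weight_decay = 0,
                                                             seed = 2L))
  targets <- temporal_embed(fit$model,
                            lapply(allodyn:::dataset_samples(
                              split_samples(samples, fit$split, "train")),
                              `[[`, "matrix"))
  expect_lt(ifit$final_mse, 0.05 * mean((targets - rowMeans(targets))^2) + 1e-4)
})

test_that("training aborts cleanly on an empty split", {
  ds <- tiny_dataset()
  samples <- dataset_samples(ds)
  bad_split <- structure(list(train = character(), val = character(),
                              test = character(), ratio = c(.8, .1, .1),
                              seed = 1), class = "allodyn_split")
  expect_error(train_classifier(samples, bad_split, tiny_model_config()),
               "empty")
})
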