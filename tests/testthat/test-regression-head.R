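test_that("head architecture validates shapes and counts parameters correctly", {
  cfg <- head_config()
  model <- build_head(cfg, input_dim = 64, seed = 1)
  # forward pass returns exactly output_dim values per row
  out <- histexpr:::head_forward(model, matrix(rnorm(2 * 64), 2))
  expect_equal(dim(out), c(2L, 138L))
  expect_true(all(is.finite(out)))
  # closed-form parameter count, layer by layer, F = 64
  expect_equal(n_parameters(model),
               (5 * 1 * 256 + 256) +       # C1: 256 kernels of size 5
                 (1 * 256 * 512 + 512) +   # C2: 512 kernels of size 1
                 (1 * 512 * 512 + 512) +   # C3
                 (512 * 138 + 138))        # linear output layer
  # all-zero input with zero biases flows to the output bias
  z <- histexpr:::head_forward(model, matrix(0, 3, 64))
  expect_equal(z, matrix(rep(model$weights$dense$b, each = 3), 3),
               tolerance = 1e-12, ignore_attr = TRUE)
  # input shorter than the first kernel is a configuration error
  expect_error(build_head(cfg, input_dim = 4), "kernel size")
})

test_that("analytic gradients match finite differences in both orderings", {
  for (variant in c("pool_then_dense", "conv_out_then_pool")) {
    cfg <- head_config(conv_channels = c(4, 5), kernel_sizes = c(3, 1),
                       output_dim = 2, ordering_variant = variant)
    model <- build_head(cfg, input_dim = 8, seed = 2)
    set.seed(3)
    # nudge biases off zero: with zero biases and fully-rectified rows the
    # loss is kinked exactly at the initial point, where finite
    # differences and the (one-sided) analytic subgradient legitimately
    # disagree
    for (l in seq_along(model$weights$conv))
      model$weights$conv[[l]]$b <- rnorm(length(model$weights$conv[[l]]$b),
                                         sd = 0.1)
    model$weights$dense$b <- rnorm(length(model$weights$dense$b), sd = 0.1)
    X <- matrix(rnorm(3 * 8), 3)
    Y <- matrix(rnorm(3 * 2), 3)
    fw <- histexpr:::head_forward(model, X, keep_cache = TRUE)
    dout <- 2 * (fw$out - Y) / length(Y)
    grads <- histexpr:::head_backward(model, fw$cache, dout)
    loss_at <- function(m) histexpr:::mse(histexpr:::head_forward(m, X), Y)
    eps <- 1e-6
    check <- function(path_get, path_set, g, label) {
      w <- path_get(model)
      for (idx in sample(length(w), min(6, length(w)))) {
        m2 <- model; w2 <- w; w2[idx] <- w2[idx] + eps
        m2 <- path_set(m2, w2)
        num <- (loss_at(m2) - loss_at(model)) / eps
        expect_equal(num, g[idx], tolerance = 1e-3, label = label)
      }
    }
    check(function(m) m$weights$conv[[1]]$W,
          function(m, w) { m$weights$conv[[1]]$W <- w; m },
          grads$conv[[1]]$W, paste(variant, "conv1 W"))
    check(function(m) m$weights$conv[[2]]$b,
          function(m, w) { m$weights$conv[[2]]$b <- w; m },
          grads$conv[[2]]$b, paste(variant, "conv2 b"))
    check(function(m) m$weights$dense$W,
          function(m, w) { m$weights$dense$W <- w; m },
          grads$dense$W, paste(variant, "dense W"))
  }
})

test_that("early stopping halts after the stated patience and tracks the best epoch", {
  # strictly increasing monitored loss after epoch k halts at k + patience
  losses <- c(5, 3, 2, 2.5, 2.6, 2.7, 2.8, 2.9)
  es <- histexpr:::early_stop_epoch(losses, patience = 4)
  expect_equal(es$stop_epoch, 3 + 4)
  expect_equal(es$best_epoch, 3)
  # plateaus (no strict improvement) also count towards patience
  es2 <- histexpr:::early_stop_epoch(c(1, 1, 1, 1, 1), patience = 4)
  expect_equal(es2$stop_epoch, 5)
  expect_equal(es2$best_epoch, 1)
})

test_that("training is reproducible, aligned, and reports a consistent history", {
  co <- tiny_cohort()
  agg <- aggregate_cohort(co)
  tc <- train_config(seed = 4, max_epochs = 6)
  cfg <- head_config(conv_channels = c(8, 16, 16))
  f1 <- train_head(agg, co$expression, tc, cfg)
  f2 <- train_head(agg, co$expression, tc, cfg)
  expect_identical(f1$history, f2$history)
  # the best epoch's monitored loss is the series minimum
  expect_equal(f1$best_loss, min(f1$history$monitored))
  expect_equal(f1$best_epoch, which.min(f1$history$monitored))
  # raw-scale targets and misaligned ids are refused
  raw <- expr_matrix(abs(unclass(co$expression)), scale = "raw")
  expect_error(train_head(agg, raw, tc, cfg), "log2")
  agg_bad <- agg; rownames(agg_bad)[1] <- "P999"
  expect_error(train_head(agg_bad, co$expression, tc, cfg), "P999")
  # fewer patients than the batch size falls back to full batches
  expect_warning(
    train_head(agg[1:8, ],
               expr_matrix(unclass(co$expression)[1:8, ], scale = "log2p1"),
               train_config(seed = 1, max_epochs = 2,
                            validation_fraction = 0),
               cfg),
    "full-batch")
})

test_that("predictions are deterministic with the panel-sized output", {
  co <- tiny_cohort()
  agg <- aggregate_cohort(co)
  fit <- train_head(agg, co$expression,
                    train_config(seed = 4, max_epochs = 5),
                    head_config(conv_channels = c(8, 16, 16)))
  p1 <- predict(fit, agg)
  expect_identical(p1, predict(fit, agg))
  expect_equal(ncol(p1), ncol(co$expression))
  expect_equal(colnames(p1), colnames(co$expression))
  # single aggregated feature in, panel-length vector out
  single <- aggregate_features(co$features[[1]])
  expect_equal(dim(predict(fit, single)), c(1L, 6L))
  expect_error(predict(fit, matrix(0, 2, 5)), "dimension")
})

test_that("the head drives training error to near zero on a noiseless cohort", {
  co <- make_cohort(80, 5, 32, 20, noise_sd = 0, seed = 11)
  agg <- aggregate_cohort(co)
  fit <- train_head(agg, co$expression,
                    train_config(seed = 11, learning_rate = 0.003,
                                 validation_fraction = 0,
                                 early_stop_patience = 10,
                                 max_epochs = 200),
                    head_config())
  expect_lt(min(fit$history$train_loss), 1e-2)
})

test_that("held-out performance degrades monotonically with expression noise", {
  med_rho <- function(noise_sd) {
    per_seed <- vapply(1:5, function(s) {
      co <- make_cohort(45, 10, 16, 10, noise_sd = noise_sd, seed = s)
      agg <- aggregate_cohort(co)
      tr <- co$patient_ids[1:30]; te <- co$patient_ids[31:45]
      fit <- train_head(
        agg[tr, ],
        expr_matrix(unclass(co$expression)[tr, ], scale = "log2p1"),
        train_config(seed = s, learning_rate = 0.003, max_epochs = 60,
                     validation_fraction = 0, early_stop_patience = 6),
        head_config(conv_channels = c(32, 64, 64)))
      pred <- predict(fit, agg[te, ])
      median(evaluate_across_patients(
        pred, unclass(co$expression)[te, ])$rho)
    }, numeric(1))
    median(per_seed)
  }
  rhos <- vapply(c(0, 0.5, 2), med_rho, numeric(1))
  expect_true(all(diff(rhos) < 0))
})
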