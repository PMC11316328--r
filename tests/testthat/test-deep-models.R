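test_that("network specs are validated against the search grids", {
  expect_error(network_spec("mlp", first_units = 20), "outside grid")
  expect_error(network_spec("mlp", dropout = 0.5), "outside grid")
  expect_error(network_spec("cnn", n_hidden = 0), "outside grid")
  expect_error(network_spec("mlp", l1 = 0.5), "outside grid")
  s <- network_spec("cnn", first_units = 38, n_hidden = 2, activation = "tanh",
                    optimizer = "rmsprop", dropout = 0.15, l2 = 0.01)
  expect_s3_class(s, "network_spec")
})

test_that("sampled specs always fall inside the grids", {
  set.seed(70)
  for (arch in c("mlp", "cnn", "multi_input")) {
    for (i in 1:20) {
      s <- sample_network_spec(arch)
      expect_true(s$first_units %in% c(16, 38, 64, 128))
      expect_true(s$hidden_units %in% c(2, 4, 8, 16))
      expect_true(s$activation %in% c("relu", "tanh", "linear"))
      expect_true(s$optimizer %in% c("adam", "rmsprop", "sgd"))
      expect_true(s$dropout %in% c(0, 0.05, 0.1, 0.15, 0.2, 0.25, 0.3))
      expect_true(all(c(s$l1, s$l2) %in% c(0, 0.001, 0.01, 0.1)))
      if (arch == "cnn") expect_true(s$n_hidden %in% 1:3)
      else expect_true(s$n_hidden %in% 0:3)
    }
  }
})

test_that("1-D convolution matches the hand-computed feature map", {
  ly <- svgp:::layer_conv1d(2, 1, 1, "linear")
  ly$K[, 1] <- c(1, 1); ly$b <- 0
  out <- svgp:::layer_forward(ly, matrix(c(1, 2, 3, 4), 1, 4))$out
  expect_equal(drop(out), c(3, 5, 7))
  # zero kernel: all-zero feature map regardless of input
  ly$K[, 1] <- 0
  expect_equal(drop(svgp:::layer_forward(ly, matrix(rnorm(8), 2, 4))$out),
               matrix(0, 2, 3), ignore_attr = TRUE)
})

test_that("max pooling follows the window/stride convention", {
  A <- array(c(3, 5, 7), c(1, 3, 1))
  p1 <- svgp:::layer_forward(svgp:::layer_maxpool(2, 1), A)$out
  expect_equal(drop(p1), c(5, 7))   # windows (3,5), (5,7)
  p2 <- svgp:::layer_forward(svgp:::layer_maxpool(2, 2), A)$out
  expect_equal(drop(p2), 5)         # single stride-2 window (3,5)
})

test_that("relu activations follow the definition", {
  expect_equal(svgp:::act_fun(c(1, -1), "relu"), c(1, 0))
  ly <- svgp:::layer_dense(2, 2, "relu")
  ly$W <- diag(2); ly$b <- c(0, 0)
  out <- svgp:::layer_forward(ly, matrix(c(1, -1), 1, 2))$out
  expect_equal(drop(out), c(1, 0))
})

test_that("sigmoid outputs stay in (0, 1)", {
  spec <- network_spec("mlp", first_units = 16, n_hidden = 1, hidden_units = 4)
  m <- build_mlp(spec, 5, "binary", seed = 71)
  p <- predict(m, matrix(rnorm(50 * 5, sd = 10), 50, 5))
  expect_true(all(p > 0 & p < 1))
})

test_that("a linear MLP trained to convergence attains the OLS loss", {
  set.seed(72)
  n <- 50; X <- matrix(rnorm(n * 4), n, 4)
  y <- drop(X %*% c(1, -2, 0.5, 0)) + 0.05 * rnorm(n)
  spec <- network_spec("mlp", first_units = 16, n_hidden = 0,
                       activation = "linear", optimizer = "adam")
  tm <- train_network(build_mlp(spec, 4, "quantitative", seed = 73),
                      X, y, epochs = 500, batch_size = 16, seed = 74)
  ols_loss <- mean(lm(y ~ X)$residuals^2)
  expect_lt(tail(tm$history$train_loss, 1), ols_loss + 1e-3)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(75)
  X <- matrix(rnorm(15), 5, 3); y <- rnorm(5)
  spec <- network_spec("mlp", first_units = 16, n_hidden = 1, hidden_units = 4,
                       activation = "tanh", l1 = 0.001, l2 = 0.01)
  m <- build_mlp(spec, 3, "quantitative", seed = 76)
  lossf <- function(mm) {
    f <- svgp:::model_forward(mm, X, FALSE)
    mse(y, drop(f$yhat)) + svgp:::stack_penalty(mm$layers)
  }
  fw <- svgp:::model_forward(m, X, TRUE)
  dZ <- matrix(2 * (drop(fw$z) - y) / 5, 5, 1)
  gr <- svgp:::flatten_grads(m, svgp:::model_backward(m, fw$caches, dZ))
  p0 <- svgp:::model_params(m)
  for (key in c("L1.W", "L2.W", "L3.b")) {
    num <- p0[[key]] * 0
    for (i in seq_along(p0[[key]])) {
      pp <- p0; pp[[key]][i] <- pp[[key]][i] + 1e-6
      num[i] <- (lossf(svgp:::model_set_params(m, pp)) - lossf(m)) / 1e-6
    }
    expect_lt(max(abs(num - gr[[key]])), 1e-4)
  }
})

test_that("CNN gradients agree with finite differences", {
  set.seed(77)
  X <- matrix(rnorm(60), 5, 12); y <- rnorm(5)
  spec <- network_spec("cnn", first_units = 16, n_hidden = 1, hidden_units = 4,
                       activation = "tanh")
  m <- build_cnn(spec, 12, "quantitative", seed = 78)
  lossf <- function(mm) mse(y, predict(mm, X))
  fw <- svgp:::model_forward(m, X, TRUE)
  dZ <- matrix(2 * (drop(fw$z) - y) / 5, 5, 1)
  gr <- svgp:::flatten_grads(m, svgp:::model_backward(m, fw$caches, dZ))
  p0 <- svgp:::model_params(m)
  for (key in c("L1.K", "L1.b")) {
    num <- p0[[key]] * 0
    for (i in seq_along(p0[[key]])) {
      pp <- p0; pp[[key]][i] <- pp[[key]][i] + 1e-6
      num[i] <- (lossf(svgp:::model_set_params(m, pp)) - lossf(m)) / 1e-6
    }
    expect_lt(max(abs(num - gr[[key]])), 1e-4)
  }
})

test_that("the multi-input network concatenates six branches as specified", {
  spec <- network_spec("multi_input", first_units = 16, n_hidden = 1,
                       hidden_units = 4, activation = "linear")
  m <- build_multi_input(spec, rep(3L, 6L), "quantitative", seed = 79)
  # concatenated trunk input width = 6 branches x 16 units
  expect_equal(nrow(m$trunk[[1]]$W), 96L)
  expect_error(build_multi_input(spec, rep(3L, 5L)), "exactly 6")

  # forward pass equals an independent matrix-algebra computation
  blocks <- lapply(1:6, function(i) matrix(rnorm(12), 4, 3))
  yhat <- predict(m, blocks)
  concat <- do.call(cbind, lapply(1:6, function(b) {
    sweep(blocks[[b]] %*% m$branches[[b]][[1]]$W, 2,
          m$branches[[b]][[1]]$b, "+")
  }))
  h <- sweep(concat %*% m$trunk[[1]]$W, 2, m$trunk[[1]]$b, "+")
  out <- sweep(h %*% m$trunk[[2]]$W, 2, m$trunk[[2]]$b, "+")
  expect_equal(yhat, drop(out), tolerance = 1e-12)
})

test_that("an all-zero block contributes zero gradient to its branch", {
  spec <- network_spec("multi_input", first_units = 16, n_hidden = 1,
                       hidden_units = 4, activation = "linear")
  m <- build_multi_input(spec, rep(2L, 6L), "quantitative", seed = 80)
  blocks <- lapply(1:6, function(i) matrix(rnorm(10), 5, 2))
  blocks[[3]] <- matrix(0, 5, 2)
  fw <- svgp:::model_forward(m, blocks, TRUE)
  dZ <- matrix(1, 5, 1)
  gr <- svgp:::model_backward(m, fw$caches, dZ)
  expect_equal(max(abs(gr$branches[[3]][[1]]$W)), 0)
  expect_gt(max(abs(gr$branches[[1]][[1]]$W)), 0)
})

test_that("training is seed-reproducible and 0 epochs is a no-op", {
  set.seed(81)
  X <- matrix(rnorm(80), 20, 4); y <- rnorm(20)
  spec <- network_spec("mlp", first_units = 16, n_hidden = 1, hidden_units = 4)
  m <- build_mlp(spec, 4, "quantitative", seed = 82)
  t0 <- train_network(m, X, y, epochs = 0, seed = 83)
  expect_equal(nrow(t0$history), 0L)
  expect_identical(svgp:::model_params(t0$model), svgp:::model_params(m))
  t1 <- train_network(m, X, y, epochs = 5, seed = 84)
  t2 <- train_network(m, X, y, epochs = 5, seed = 84)
  expect_identical(t1$history, t2$history)
  expect_identical(predict(t1, X), predict(t2, X))
})

test_that("an overparameterized MLP interpolates 20 noiseless points", {
  set.seed(85)
  X <- matrix(rnorm(20 * 5), 20, 5)
  y <- drop(X %*% c(2, -1, 0.5, 1, -2))
  spec <- network_spec("mlp", first_units = 64, n_hidden = 0,
                       activation = "linear")
  tm <- train_network(build_mlp(spec, 5, "quantitative", seed = 86),
                      X, y, epochs = 600, batch_size = 20, seed = 87)
  expect_lt(tail(tm$history$train_loss, 1), 1e-3)
})

test_that("early stopping restores the best-epoch parameters", {
  set.seed(88)
  X <- matrix(rnorm(200), 50, 4); y <- rnorm(50)
  Xv <- matrix(rnorm(80), 20, 4); yv <- rnorm(20)
  spec <- network_spec("mlp", first_units = 16, n_hidden = 1, hidden_units = 8,
                       activation = "relu")
  tm <- train_network(build_mlp(spec, 4, "quantitative", seed = 89),
                      X, y, Xv, yv, epochs = 40, patience = 3, seed = 90)
  expect_equal(tm$best_val_loss, min(tm$history$val_loss), tolerance = 1e-12)
  expect_equal(mse(yv, predict(tm, Xv)), tm$best_val_loss, tolerance = 1e-10)
  expect_lte(nrow(tm$history), 40L)
})

test_that("dropout is disabled at evaluation time", {
  spec <- network_spec("mlp", first_units = 16, n_hidden = 1, hidden_units = 8,
                       dropout = 0.3)
  m <- build_mlp(spec, 6, "quantitative", seed = 91)
  X <- matrix(rnorm(60), 10, 6)
  expect_identical(predict(m, X), predict(m, X))
})

test_that("successive halving returns the argmin of a fixed loss table", {
  tab <- c(5, 3, 8, 1, 9, 2, 7, 6)
  sr <- hyperband_search("mlp", NULL, NULL, NULL, NULL, n_configs = 8L,
                         halving_factor = 2L, first_epochs = 1L, seed = 1L,
                         objective = function(spec, budget, cfg_seed) {
                           # identify the config by matching against the
                           # deterministic seed stream
                           for (i in 1:8) {
                             if (cfg_seed == derive_seed(1L, paste0("cfg", i)))
                               return(tab[i])
                           }
                           stop("unknown config")
                         })
  expect_equal(sr$best_config, which.min(tab))
  # bracket sizes 8, 4, 2, 1
  expect_equal(as.vector(table(sr$log$round)), c(8L, 4L, 2L, 1L))
  expect_equal(sr$log$loss[sr$log$round == 4], min(tab))
  # survivors of each round are the best half of the previous one
  r1 <- sr$log[sr$log$round == 1, ]
  expect_setequal(sr$log$config[sr$log$round == 2],
                  r1$config[order(r1$loss)][1:4])
})

test_that("the search is reproducible and its survivor minimizes the objective", {
  obj <- function(spec, budget, cfg_seed) {
    abs(spec$first_units - 128) / 128 + spec$dropout + spec$l1
  }
  s1 <- hyperband_search("mlp", NULL, NULL, NULL, NULL, n_configs = 8L,
                         seed = 5L, objective = obj)
  s2 <- hyperband_search("mlp", NULL, NULL, NULL, NULL, n_configs = 8L,
                         seed = 5L, objective = obj)
  expect_identical(s1$best_spec, s2$best_spec)
  # deterministic budget-independent objective: survivor = sampled argmin
  r1 <- s1$log[s1$log$round == 1, ]
  expect_equal(s1$best_config, r1$config[which.min(r1$loss)])
})

test_that("search budgets below one epoch are rejected", {
  expect_error(hyperband_search("mlp", NULL, NULL, NULL, NULL,
                                first_epochs = 0L), "budget")
  expect_error(hyperband_search("mlp", NULL, NULL, NULL, NULL,
                                halving_factor = 1L), "halving")
})

test_that("a tuned small network trains end-to-end on real features", {
  set.seed(92)
  n <- 60; X <- matrix(rnorm(n * 10), n, 10)
  y <- drop(X[, 1:2] %*% c(2, -2)) + 0.3 * rnorm(n)
  sr <- hyperband_search("mlp", X[1:40, ], y[1:40], X[41:60, ], y[41:60],
                         n_configs = 4L, first_epochs = 2L, max_epochs = 15L,
                         seed = 93)
  expect_s3_class(sr$model, "trained_model")
  expect_true(all(c("config", "round", "budget", "loss") %in% names(sr$log)))
  # retraining used exactly the returned spec
  expect_identical(sr$model$spec, sr$best_spec)
  expect_lt(mse(y[41:60], predict(sr$model, X[41:60, ])), var(y))
})
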