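test_that("lstm cell step matches closed forms at zero weights", {
  H <- 3
  D <- 4
  W0 <- matrix(0, H, H + D)
  w <- list(
    W_f = W0, W_i = W0, W_c = W0, W_o = W0,
    b_f = numeric(H), b_i = numeric(H), b_c = numeric(H), b_o = numeric(H)
  )
  st <- lstm_cell_step(rnorm(D), rnorm(H), numeric(H), w)
  expect_identical(st$c, numeric(H))
  expect_identical(st$h, numeric(H))

  cp <- c(0.8, -0.4, 0.2)
  st2 <- lstm_cell_step(rnorm(D), rnorm(H), cp, w)
  expect_equal(st2$c, 0.5 * cp)
  expect_equal(st2$h, 0.5 * tanh(0.5 * cp))

  expect_error(
    lstm_cell_step(rnorm(D + 1), rnorm(H), numeric(H), w), "W_f"
  )
})

test_that("lstm cell step matches a scalar oracle on random cells", {
  set.seed(41)
  worst <- 0
  for (i in 1:100) {
    H <- sample(1:4, 1)
    D <- sample(1:4, 1)
    w <- random_cell_weights(H, D)
    x <- rnorm(D)
    h0 <- rnorm(H)
    c0 <- rnorm(H)
    got <- lstm_cell_step(x, h0, c0, w)
    ref <- ref_lstm_cell(x, h0, c0, w)
    worst <- max(worst, max(abs(got$h - ref$h)), max(abs(got$c - ref$c)))
  }
  expect_lt(worst, 1e-12)
})

test_that("gates stay in their ranges along a batched forward pass", {
  set.seed(42)
  params <- snorescreen:::init_lstm_params(6, 5, 2)
  arr <- array(rnorm(10 * 6 * 3, sd = 2), c(10, 6, 3))
  fw <- snorescreen:::lstm_forward(arr, params, keep_cache = TRUE)
  for (cs in fw$cache) {
    expect_true(all(cs$f > 0 & cs$f < 1))
    expect_true(all(cs$i > 0 & cs$i < 1))
    expect_true(all(cs$o > 0 & cs$o < 1))
    expect_true(all(abs(cs$cbar) < 1))
    expect_true(all(abs(cs$tanh_c) < 1))
  }
  # the batched forward agrees with repeated single-cell steps
  w <- params$W
  hh <- 5
  split_w <- function(block) t(w[, (block - 1) * hh + seq_len(hh)])
  cellw <- list(
    W_f = split_w(1), W_i = split_w(2), W_c = split_w(3), W_o = split_w(4),
    b_f = params$b[1:5], b_i = params$b[6:10],
    b_c = params$b[11:15], b_o = params$b[16:20]
  )
  h <- numeric(hh)
  cc <- numeric(hh)
  for (t in 1:10) {
    st <- lstm_cell_step(arr[t, , 2], h, cc, cellw)
    h <- st$h
    cc <- st$c
  }
  expect_equal(as.numeric(fw$h[2, ]), h, tolerance = 1e-12)
})

test_that("analytic gradients match numeric gradients", {
  set.seed(43)
  ns <- asNamespace("snorescreen")
  # LSTM
  params <- ns$init_lstm_params(3, 3, 2)
  arr <- array(rnorm(4 * 3 * 2), c(4, 3, 2))
  y <- diag(2)
  for (pool in c("mean", "final")) {
    res <- ns$lstm_loss_grads(arr, y, params, pool)
    for (nm in names(params)) {
      for (idx in sample(length(params[[nm]]), min(4, length(params[[nm]])))) {
        eps <- 1e-6
        p1 <- params
        p1[[nm]][idx] <- p1[[nm]][idx] + eps
        p2 <- params
        p2[[nm]][idx] <- p2[[nm]][idx] - eps
        num <- (ns$lstm_loss_grads(arr, y, p1, pool)$loss -
          ns$lstm_loss_grads(arr, y, p2, pool)$loss) / (2 * eps)
        expect_equal(res$grads[[nm]][idx], num, tolerance = 1e-5)
      }
    }
  }
  # CNN (small custom blocks exercise conv, relu, ceil-mode pooling)
  blocks <- list(ns$conv_block(3L, 3L, 4L, 2L), ns$conv_block(2L, 2L, 3L, 1L))
  shape <- c(11L, 7L) # odd sizes force partial pooling windows
  cp <- ns$init_cnn_params(shape, blocks, 2L)
  ly <- ns$cnn_layouts(shape, blocks)
  batch <- list(
    matrix(rnorm(prod(shape)), shape[1]),
    matrix(rnorm(prod(shape)), shape[1])
  )
  resc <- ns$cnn_loss_grads(batch, y, cp, blocks, ly)
  for (nm in names(cp)) {
    for (idx in sample(length(cp[[nm]]), min(3, length(cp[[nm]])))) {
      eps <- 1e-6
      p1 <- cp
      p1[[nm]][idx] <- p1[[nm]][idx] + eps
      p2 <- cp
      p2[[nm]][idx] <- p2[[nm]][idx] - eps
      num <- (ns$cnn_loss_grads(batch, y, p1, blocks, ly)$loss -
        ns$cnn_loss_grads(batch, y, p2, blocks, ly)$loss) / (2 * eps)
      expect_equal(resc$grads[[nm]][idx], num, tolerance = 1e-5)
    }
  }
})

test_that("architectures carry their canonical convolution tables", {
  c3 <- model_config("cnn3")
  expect_length(c3$conv_blocks, 3)
  expect_identical(
    lapply(c3$conv_blocks, function(b) b$filter),
    list(c(20L, 8L), c(10L, 4L), c(5L, 2L))
  )
  expect_identical(
    vapply(c3$conv_blocks, function(b) b$stride, integer(1)), c(2L, 2L, 1L)
  )
  c5 <- model_config("cnn5")
  expect_length(c5$conv_blocks, 5)
  expect_identical(c5$conv_blocks[[4]]$filter, c(2L, 2L))
  expect_identical(c5$conv_blocks[[5]]$filter, c(2L, 2L))
  expect_identical(c5$conv_blocks[[4]]$stride, 1L)
  expect_true(all(vapply(
    c5$conv_blocks, function(b) b$n_filters, integer(1)
  ) == 64L))
  expect_error(
    model_config("cnn3", conv_blocks = c3$conv_blocks[1:2]), "canonical"
  )
  # the lstm path runs one recurrent step per input frame
  ns <- asNamespace("snorescreen")
  params <- ns$init_lstm_params(40, 8, 2)
  arr <- array(rnorm(298 * 40), c(298, 40, 1))
  fw <- ns$lstm_forward(arr, params, keep_cache = TRUE)
  expect_length(fw$cache, 298)
})

test_that("training separates a separable fixture and memorizes it", {
  ds <- separable_features(60, seed = 51)
  fit <- train_model(
    build_model(model_config("lstm", lstm_hidden = 16)),
    ds$features, ds$labels,
    train_config(epochs = 15, batch_size = 32, seed = 2, validation_fraction = 0)
  )
  hist <- tidy(fit)
  expect_gte(hist$accuracy[nrow(hist)], 0.99)
  pred <- predict(fit, ds$features)
  expect_gte(mean(pred$label == ds$labels), 0.99)
  # probabilities sum to one
  expect_equal(pred$prob_normal + pred$prob_abnormal, rep(1, nrow(pred)),
    tolerance = 1e-6
  )
  g <- glance(fit)
  expect_identical(g$architecture, "lstm")
  expect_gt(g$n_parameters, 0)
})

test_that("a small cnn also learns the separable fixture", {
  ds <- separable_features(30, t_len = 20, d = 8, sep = 3, seed = 52)
  fit <- train_model(
    build_model(model_config("cnn3", input_shape = c(20L, 8L))),
    ds$features, ds$labels,
    train_config(epochs = 10, batch_size = 20, seed = 3, validation_fraction = 0)
  )
  hist <- tidy(fit)
  expect_gte(hist$accuracy[nrow(hist)], 0.95)
  expect_lt(hist$loss[nrow(hist)], hist$loss[1])
})

test_that("degenerate label sets are rejected", {
  ds <- separable_features(3, seed = 53)
  expect_error(
    train_model(
      build_model(model_config("lstm")), ds$features,
      rep("normal", length(ds$features)),
      train_config(epochs = 1)
    ),
    "class"
  )
  expect_error(
    train_model(
      build_model(model_config("lstm")), ds$features,
      rep(c("cat", "dog"), length.out = length(ds$features)),
      train_config(epochs = 1)
    ),
    "labels"
  )
})

test_that("training is reproducible under a fixed seed", {
  ds <- separable_features(20, seed = 54)
  cfg <- train_config(epochs = 2, batch_size = 16, seed = 7)
  f1 <- train_model(build_model(model_config("lstm", lstm_hidden = 8)),
    ds$features, ds$labels, cfg
  )
  f2 <- train_model(build_model(model_config("lstm", lstm_hidden = 8)),
    ds$features, ds$labels, cfg
  )
  expect_identical(tidy(f1)$loss[1], tidy(f2)$loss[1])
  expect_identical(f1$params, f2$params)
  p1 <- predict(f1, ds$features)
  p2 <- predict(f2, ds$features)
  expect_identical(p1$prob_abnormal, p2$prob_abnormal)
})

test_that("the lstm is order sensitive and predictions are non-constant", {
  ds <- separable_features(20, seed = 55)
  fit <- train_model(build_model(model_config("lstm", lstm_hidden = 8)),
    ds$features, ds$labels,
    train_config(epochs = 3, batch_size = 16, seed = 8)
  )
  x <- ds$features[[1]]
  set.seed(9)
  xp <- x[sample(nrow(x)), ]
  p1 <- predict(fit, x)$prob_abnormal
  p2 <- predict(fit, xp)$prob_abnormal
  expect_false(isTRUE(all.equal(p1, p2)))
  probs <- predict(fit, ds$features)$prob_abnormal
  expect_gt(stats::sd(probs), 0)
  expect_error(predict(fit, matrix(0, 10, 3)), "coefficients")
})
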