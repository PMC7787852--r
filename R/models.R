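#' Model architecture configuration
#'
#' Three binary snore classifiers over `298 x 40` cepstral feature
#' matrices: a 3-block CNN, a 5-block CNN (blocks 4--5 add 2x2 filters at
#' stride 1), and an LSTM that consumes the 298 frames as a sequence of
#' 40-dimensional steps. Convolution blocks are fixed by architecture:
#' each convolution (with "same" spatial padding and a rectifier
#' activation) is followed by its 2x2 max-pool.
#'
#' @param architecture `"lstm"`, `"cnn3"` or `"cnn5"`.
#' @param lstm_hidden Hidden-state width of the LSTM cell.
#' @param lstm_pool Readout feeding the LSTM's output layer: `"mean"`
#'   (default) averages the hidden state over the 298 steps, `"final"`
#'   uses only the last step's hidden state. Mean pooling is essential
#'   when the informative episode occupies a fraction of the clip: a
#'   final-state readout must carry it across every trailing
#'   background frame and in practice memorizes instead.
#' @param n_classes Number of output classes (fixed at 2).
#' @param input_shape `c(n_frames, n_coeffs)` of the feature matrices.
#' @param conv_blocks Optional list of conv blocks (each a list with
#'   `filter = c(h, w)`, `n_filters`, `stride`, `pool = c(2, 2)`); must
#'   match the architecture's canonical table if supplied.
#' @return A `model_config` object.
#' @export
model_config <- function(architecture = c("lstm", "cnn3", "cnn5"),
                         lstm_hidden = 64L, lstm_pool = c("mean", "final"),
                         n_classes = 2L,
                         input_shape = c(298L, 40L), conv_blocks = NULL) {
  architecture <- match.arg(architecture)
  lstm_pool <- match.arg(lstm_pool)
  if (n_classes != 2) stop_input("`n_classes` is fixed at 2")
  canonical <- canonical_conv_blocks(architecture)
  if (is.null(conv_blocks)) {
    conv_blocks <- canonical
  } else if (!is.null(canonical) && !identical(unname(conv_blocks), unname(canonical))) {
    stop_input("`conv_blocks` must match the canonical ", architecture, " layout")
  }
  if (lstm_hidden < 1) stop_input("`lstm_hidden` must be >= 1")
  structure(
    list(
      architecture = architecture, lstm_hidden = as.integer(lstm_hidden),
      lstm_pool = lstm_pool, n_classes = 2L,
      input_shape = as.integer(input_shape), conv_blocks = conv_blocks
    ),
    class = "model_config"
  )
}

conv_block <- function(h, w, n_filters, stride) {
  list(filter = c(h, w), n_filters = n_filters, stride = stride, pool = c(2L, 2L))
}

canonical_conv_blocks <- function(architecture) {
  base3 <- list(
    conv_block(20L, 8L, 64L, 2L),
    conv_block(10L, 4L, 64L, 2L),
    conv_block(5L, 2L, 64L, 1L)
  )
  switch(architecture,
    cnn3 = base3,
    cnn5 = c(base3, list(
      conv_block(2L, 2L, 64L, 1L),
      conv_block(2L, 2L, 64L, 1L)
    )),
    NULL
  )
}

#' Training configuration
#'
#' Defaults: Adam with learning rate 1e-3, batches of 64, 12 epochs, a
#' 10% validation split, and a seed that fixes every stochastic choice
#' (weight initialization and shuffling), making training reproducible on
#' one platform.
#'
#' @param epochs,batch_size,learning_rate,validation_fraction,seed
#'   Positive scalars.
#' @return A `train_config` object.
#' @export
train_config <- function(epochs = 12L, batch_size = 64L, learning_rate = 1e-3,
                         seed = 42L, validation_fraction = 0.1) {
  stopifnot(
    epochs >= 1, batch_size >= 1, learning_rate > 0,
    validation_fraction >= 0, validation_fraction < 1
  )
  structure(
    list(
      epochs = as.integer(epochs), batch_size = as.integer(batch_size),
      learning_rate = learning_rate, seed = as.integer(seed),
      validation_fraction = validation_fraction
    ),
    class = "train_config"
  )
}

#' One LSTM cell step
#'
#' The gated recurrence on the concatenated vector `[h_prev, x_t]`:
#' \deqn{f_t = \sigma(W_f [h_{t-1}, x_t] + b_f)}
#' \deqn{i_t = \sigma(W_i [h_{t-1}, x_t] + b_i)}
#' \deqn{\tilde C_t = \tanh(W_c [h_{t-1}, x_t] + b_c)}
#' \deqn{C_t = f_t \odot C_{t-1} + i_t \odot \tilde C_t}
#' \deqn{O_t = \sigma(W_o [h_{t-1}, x_t] + b_o)}
#' \deqn{h_t = O_t \odot \tanh(C_t)}
#'
#' @param x_t Input vector (length `input_size`).
#' @param h_prev,c_prev Previous hidden and cell state vectors (length
#'   `hidden_size`).
#' @param weights List with matrices `W_f`, `W_i`, `W_c`, `W_o` (each
#'   `hidden_size x (hidden_size + input_size)`) and bias vectors `b_f`,
#'   `b_i`, `b_c`, `b_o`.
#' @return List with `h` and `c`, the new hidden and cell states.
#' @export
lstm_cell_step <- function(x_t, h_prev, c_prev, weights) {
  z <- c(h_prev, x_t)
  hs <- length(h_prev)
  for (nm in c("W_f", "W_i", "W_c", "W_o")) {
    if (!all(dim(weights[[nm]]) == c(hs, length(z)))) {
      stop_input(nm, " must be ", hs, " x ", length(z))
    }
  }
  f <- sigmoid(drop(weights$W_f %*% z) + weights$b_f)
  i <- sigmoid(drop(weights$W_i %*% z) + weights$b_i)
  cbar <- tanh(drop(weights$W_c %*% z) + weights$b_c)
  cc <- f * c_prev + i * cbar
  o <- sigmoid(drop(weights$W_o %*% z) + weights$b_o)
  list(h = o * tanh(cc), c = cc)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Build an untrained model
#'
#' Validates the configuration and returns an untrained model
#' specification; [train_model()] initializes and fits the weights.
#'
#' @param config A [model_config()].
#' @return A `snore_model_spec` object.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  if (config$architecture %in% c("cnn3", "cnn5")) {
    # fail early if the conv chain collapses the input
    dims <- cnn_chain_dims(config$input_shape, config$conv_blocks)
    if (any(unlist(dims) < 1)) stop_input("conv chain collapses the input")
  }
  structure(list(config = config), class = "snore_model_spec")
}

#' @export
print.snore_model_spec <- function(x, ...) {
  cat(sprintf("<untrained %s model, input %d x %d>\n",
    x$config$architecture, x$config$input_shape[1], x$config$input_shape[2]))
  invisible(x)
}

# ---- parameter initialization -------------------------------------------

glorot <- function(nrow, ncol) {
  lim <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

init_lstm_params <- function(input_size, hidden, n_classes) {
  # combined gate matrix, column blocks ordered [f, i, c, o]
  w <- glorot(hidden + input_size, 4 * hidden)
  b <- numeric(4 * hidden)
  b[seq_len(hidden)] <- 1 # forget-gate bias at 1: remember by default
  list(
    W = w, b = b,
    W_out = glorot(hidden, n_classes), b_out = numeric(n_classes)
  )
}

init_cnn_params <- function(input_shape, blocks, n_classes) {
  params <- list()
  in_c <- 1L
  hw <- input_shape
  for (j in seq_along(blocks)) {
    bl <- blocks[[j]]
    patch <- bl$filter[1] * bl$filter[2] * in_c
    params[[paste0("W", j)]] <- glorot(patch, bl$n_filters)
    params[[paste0("b", j)]] <- numeric(bl$n_filters)
    hw <- ceiling(ceiling(hw / bl$stride) / bl$pool)
    in_c <- bl$n_filters
  }
  flat <- hw[1] * hw[2] * in_c
  params$W_out <- glorot(flat, n_classes)
  params$b_out <- numeric(n_classes)
  params
}

cnn_chain_dims <- function(input_shape, blocks) {
  hw <- input_shape
  out <- list()
  for (bl in blocks) {
    hw <- ceiling(hw / bl$stride) # "same"-padded conv
    hw <- ceiling(hw / bl$pool) # ceil-mode 2x2 max-pool
    out[[length(out) + 1]] <- hw
  }
  out
}

# ---- batched LSTM forward/backward --------------------------------------

# arr: T x D x B array; returns the final hidden state (B x H), the
# time-averaged hidden state, and per-step caches
lstm_forward <- function(arr, params, keep_cache = FALSE) {
  tt <- dim(arr)[1]
  dd <- dim(arr)[2]
  bb <- dim(arr)[3]
  hh <- ncol(params$W) / 4
  h <- matrix(0, bb, hh)
  cc <- matrix(0, bb, hh)
  hsum <- matrix(0, bb, hh)
  cache <- if (keep_cache) vector("list", tt) else NULL
  ih <- seq_len(hh)
  bmat <- rep(params$b, each = bb)
  for (t in seq_len(tt)) {
    xt <- t(matrix(arr[t, , ], nrow = dd))
    z <- cbind(h, xt)
    g <- z %*% params$W + bmat
    f <- sigmoid(g[, ih, drop = FALSE])
    i <- sigmoid(g[, ih + hh, drop = FALSE])
    cbar <- tanh(g[, ih + 2 * hh, drop = FALSE])
    o <- sigmoid(g[, ih + 3 * hh, drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * cbar
    tc <- tanh(cc)
    h <- o * tc
    hsum <- hsum + h
    if (keep_cache) {
      cache[[t]] <- list(z = z, f = f, i = i, cbar = cbar, o = o,
                         c_prev = c_prev, tanh_c = tc)
    }
  }
  list(h = h, h_mean = hsum / tt, cache = cache)
}

# dh_final: B x H gradient wrt the final hidden state; dh_each: gradient
# reaching every step's hidden state (mean pooling), or NULL
lstm_backward <- function(dh_final, cache, params, dh_each = NULL) {
  tt <- length(cache)
  hh <- ncol(dh_final)
  bb <- nrow(dh_final)
  dW <- matrix(0, nrow(params$W), ncol(params$W))
  db <- numeric(length(params$b))
  dh <- dh_final
  dc <- matrix(0, bb, hh)
  ih <- seq_len(hh)
  for (t in rev(seq_len(tt))) {
    cs <- cache[[t]]
    if (!is.null(dh_each)) dh <- dh + dh_each
    dc <- dc + dh * cs$o * (1 - cs$tanh_c^2)
    do <- dh * cs$tanh_c
    df <- dc * cs$c_prev
    di <- dc * cs$cbar
    dcbar <- dc * cs$i
    dg <- cbind(
      df * cs$f * (1 - cs$f),
      di * cs$i * (1 - cs$i),
      dcbar * (1 - cs$cbar^2),
      do * cs$o * (1 - cs$o)
    )
    dW <- dW + crossprod(cs$z, dg)
    db <- db + colSums(dg)
    dz <- tcrossprod(dg, params$W)
    dh <- dz[, ih, drop = FALSE]
    dc <- dc * cs$f
  }
  list(W = dW, b = db)
}

lstm_loss_grads <- function(arr, y_onehot, params, pool = "mean") {
  fw <- lstm_forward(arr, params, keep_cache = TRUE)
  hfeat <- if (pool == "mean") fw$h_mean else fw$h
  logits <- hfeat %*% params$W_out + rep(params$b_out, each = nrow(hfeat))
  sm <- softmax_xent(logits, y_onehot)
  dh <- tcrossprod(sm$dlogits, params$W_out)
  if (pool == "mean") {
    zero <- matrix(0, nrow(dh), ncol(dh))
    gr <- lstm_backward(zero, fw$cache, params, dh_each = dh / dim(arr)[1])
  } else {
    gr <- lstm_backward(dh, fw$cache, params)
  }
  gr$W_out <- crossprod(hfeat, sm$dlogits)
  gr$b_out <- colSums(sm$dlogits)
  list(loss = sm$loss, grads = gr, probs = sm$probs)
}

softmax_xent <- function(logits, y_onehot) {
  m <- apply(logits, 1, max)
  e <- exp(logits - m)
  probs <- e / rowSums(e)
  eps <- 1e-12
  loss <- -mean(log(pmax(rowSums(probs * y_onehot), eps)))
  list(loss = loss, probs = probs, dlogits = (probs - y_onehot) / nrow(logits))
}

# ---- CNN forward/backward (im2col) --------------------------------------

# precompute padded-geometry and patch indices for one conv or pool layer
conv_layout <- function(in_h, in_w, in_c, kh, kw, stride) {
  out_h <- ceiling(in_h / stride)
  out_w <- ceiling(in_w / stride)
  pad_h <- max((out_h - 1) * stride + kh - in_h, 0)
  pad_w <- max((out_w - 1) * stride + kw - in_w, 0)
  top <- pad_h %/% 2
  left <- pad_w %/% 2
  hp <- in_h + pad_h
  wp <- in_w + pad_w
  oh <- rep(seq_len(out_h) - 1, times = out_w)
  ow <- rep(seq_len(out_w) - 1, each = out_h)
  # patch offsets ordered (dkh, dkw, channel), dkh fastest
  dkh <- rep(seq_len(kh) - 1, times = kw * in_c)
  dkw <- rep(rep(seq_len(kw) - 1, each = kh), times = in_c)
  dch <- rep(seq_len(in_c) - 1, each = kh * kw)
  rows <- outer(oh * stride, dkh, "+") # npos x patchlen
  cols <- outer(ow * stride, dkw, "+")
  idx <- rows + cols * hp + rep(dch * hp * wp, each = length(oh)) + 1
  list(
    idx = idx, in_h = in_h, in_w = in_w, in_c = in_c,
    hp = hp, wp = wp, top = top, left = left,
    out_h = out_h, out_w = out_w, npos = out_h * out_w,
    patchlen = kh * kw * in_c
  )
}

pad_input <- function(x, ly, fill = 0) {
  # x: (in_h, in_w, in_c) array -> padded vector of length hp*wp*in_c
  xp <- array(fill, dim = c(ly$hp, ly$wp, ly$in_c))
  xp[ly$top + seq_len(ly$in_h), ly$left + seq_len(ly$in_w), ] <- x
  as.numeric(xp)
}

im2col <- function(x, ly, fill = 0) {
  xp <- pad_input(x, ly, fill)
  `dim<-`(xp[ly$idx], dim(ly$idx))
}

col2im <- function(dcols, ly) {
  dxp <- numeric(ly$hp * ly$wp * ly$in_c)
  for (p in seq_len(ncol(ly$idx))) {
    ip <- ly$idx[, p]
    dxp[ip] <- dxp[ip] + dcols[, p]
  }
  dxp <- array(dxp, dim = c(ly$hp, ly$wp, ly$in_c))
  dxp[ly$top + seq_len(ly$in_h), ly$left + seq_len(ly$in_w), , drop = FALSE]
}

cnn_layouts <- function(input_shape, blocks) {
  layouts <- vector("list", length(blocks))
  hw <- input_shape
  in_c <- 1L
  for (j in seq_along(blocks)) {
    bl <- blocks[[j]]
    conv <- conv_layout(hw[1], hw[2], in_c, bl$filter[1], bl$filter[2], bl$stride)
    hw <- c(conv$out_h, conv$out_w)
    pool <- conv_layout(hw[1], hw[2], bl$n_filters, 2L, 2L, 2L)
    # pooling is per-channel: rebuild index with kh=kw=2 over each channel
    layouts[[j]] <- list(conv = conv, pool = pool)
    hw <- c(pool$out_h, pool$out_w)
    in_c <- bl$n_filters
  }
  layouts
}

# 2x2 stride-2 ceil-mode max-pooling: x is (h, w, c)
pool2_forward <- function(x) {
  h <- dim(x)[1]; w <- dim(x)[2]; cc <- dim(x)[3]
  oh <- ceiling(h / 2); ow <- ceiling(w / 2)
  xp <- array(-Inf, dim = c(2 * oh, 2 * ow, cc))
  xp[seq_len(h), seq_len(w), ] <- x
  n <- oh * ow * cc
  base_r <- rep(2 * (seq_len(oh) - 1), times = ow * cc)
  base_c <- rep(rep(2 * (seq_len(ow) - 1), each = oh), times = cc)
  base_ch <- rep(seq_len(cc) - 1, each = oh * ow)
  lin0 <- base_r + base_c * (2 * oh) + base_ch * (4 * oh * ow) + 1
  offs <- c(0, 1, 2 * oh, 2 * oh + 1) # (dr, dc) in {0,1}^2
  vals <- matrix(0, n, 4)
  xpv <- as.numeric(xp)
  for (k in 1:4) vals[, k] <- xpv[lin0 + offs[k]]
  amax <- max.col(vals, ties.method = "first")
  out <- vals[cbind(seq_len(n), amax)]
  list(
    out = array(out, dim = c(oh, ow, cc)),
    argmax_lin = lin0 + offs[amax],
    padded_dim = c(2 * oh, 2 * ow, cc), in_dim = c(h, w, cc)
  )
}

pool2_backward <- function(dout, cache) {
  dxp <- numeric(prod(cache$padded_dim))
  dxp[cache$argmax_lin] <- as.numeric(dout)
  dxp <- array(dxp, dim = cache$padded_dim)
  dxp[seq_len(cache$in_dim[1]), seq_len(cache$in_dim[2]), , drop = FALSE]
}

# forward one sample through the conv stack; returns flat features + cache
cnn_forward_sample <- function(x, params, blocks, layouts, keep_cache = FALSE) {
  a <- array(x, dim = c(nrow(x), ncol(x), 1))
  cache <- list()
  for (j in seq_along(blocks)) {
    ly <- layouts[[j]]$conv
    cols <- im2col(a, ly)
    pre <- cols %*% params[[paste0("W", j)]] +
      rep(params[[paste0("b", j)]], each = nrow(cols))
    act <- pmax(pre, 0)
    conv_out <- array(act, dim = c(ly$out_h, ly$out_w, blocks[[j]]$n_filters))
    pf <- pool2_forward(conv_out)
    if (keep_cache) {
      cache[[j]] <- list(cols = cols, pre = pre, pool = pf, ly = ly)
    }
    a <- pf$out
  }
  list(flat = as.numeric(a), cache = cache, out_dim = dim(a))
}

cnn_loss_grads <- function(batch, y_onehot, params, blocks, layouts) {
  bb <- length(batch)
  fwd <- vector("list", bb)
  flat <- NULL
  for (s in seq_len(bb)) {
    fwd[[s]] <- cnn_forward_sample(batch[[s]], params, blocks, layouts, TRUE)
    if (is.null(flat)) flat <- matrix(0, bb, length(fwd[[s]]$flat))
    flat[s, ] <- fwd[[s]]$flat
  }
  logits <- flat %*% params$W_out + rep(params$b_out, each = bb)
  sm <- softmax_xent(logits, y_onehot)
  grads <- lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  grads$W_out <- crossprod(flat, sm$dlogits)
  grads$b_out <- colSums(sm$dlogits)
  dflat <- tcrossprod(sm$dlogits, params$W_out)
  for (s in seq_len(bb)) {
    da <- array(dflat[s, ], dim = fwd[[s]]$out_dim)
    for (j in rev(seq_along(blocks))) {
      cs <- fwd[[s]]$cache[[j]]
      dconv <- pool2_backward(da, cs$pool)
      dpre <- `dim<-`(as.numeric(dconv), dim(cs$pre)) * (cs$pre > 0)
      grads[[paste0("W", j)]] <- grads[[paste0("W", j)]] +
        crossprod(cs$cols, dpre)
      grads[[paste0("b", j)]] <- grads[[paste0("b", j)]] + colSums(dpre)
      if (j > 1) {
        dcols <- tcrossprod(dpre, params[[paste0("W", j)]])
        da <- col2im(dcols, cs$ly)
      }
    }
  }
  list(loss = sm$loss, grads = grads, probs = sm$probs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cnn_predict_flat <- function(batch, params, blocks, layouts) {
  bb <- length(batch)
  flat <- NULL
  for (s in seq_len(bb)) {
    f <- cnn_forward_sample(batch[[s]], params, blocks, layouts, FALSE)$flat
    if (is.null(flat)) flat <- matrix(0, bb, length(f))
    flat[s, ] <- f
  }
  flat %*% params$W_out + rep(params$b_out, each = bb)
}

# ---- training ------------------------------------------------------------

adam_update <- function(params, grads, state, lr, t, beta1 = 0.9,
                        beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

normalize_features <- function(x, norm) {
  sweep(sweep(x, 2, norm$mean, "-"), 2, norm$sd, "/")
}

#' Train a snore classifier
#'
#' Minimizes the softmax cross-entropy with Adam. Input features are
#' standardized per coefficient (zero mean, unit variance) using
#' training-split statistics that are stored with the model and applied
#' identically at inference. With a fixed `cfg$seed` the initialization,
#' shuffling and final weights are reproducible on one platform.
#'
#' @param model A [build_model()] specification (or a [model_config()]).
#' @param features List of `n_frames x n_coeffs` feature matrices.
#' @param labels Character/factor vector, `"normal"` or `"abnormal"`,
#'   one per feature matrix; both classes must be present.
#' @param cfg A [train_config()].
#' @return A fitted `snore_model` with elements `config`, `params`,
#'   `norm`, `history` (per-epoch tibble), `classes` and `feature_kind`.
#' @export
train_model <- function(model, features, labels, cfg = train_config()) {
  if (inherits(model, "model_config")) model <- build_model(model)
  stopifnot(inherits(model, "snore_model_spec"), inherits(cfg, "train_config"))
  config <- model$config
  labels <- as.character(labels)
  if (length(features) != length(labels)) {
    stop_input("`features` and `labels` lengths differ")
  }
  classes <- c("normal", "abnormal")
  if (!all(labels %in% classes)) {
    stop_input("labels must be 'normal' or 'abnormal'")
  }
  if (length(unique(labels)) < 2 || min(table(labels)) < 2) {
    stop_input("need at least 2 examples of each class")
  }
  feature_kind <- attr(features[[1]], "feature_kind") %||% NA_character_
  set.seed(cfg$seed)
  n <- length(features)
  perm <- sample.int(n)
  n_val <- floor(cfg$validation_fraction * n)
  val_idx <- if (n_val > 0) perm[seq_len(n_val)] else integer(0)
  tr_idx <- setdiff(perm, val_idx)
  y <- as.integer(labels == "abnormal") + 1L # 1 = normal, 2 = abnormal

  # per-coefficient standardization from the training split only
  tr_stack <- do.call(rbind, lapply(features[tr_idx], unclass))
  norm <- list(mean = colMeans(tr_stack), sd = pmax(apply(tr_stack, 2, sd), 1e-8))
  rm(tr_stack)
  feats <- lapply(features, function(f) normalize_features(unclass(f), norm))

  dd <- ncol(feats[[1]])
  is_lstm <- config$architecture == "lstm"
  if (is_lstm) {
    params <- init_lstm_params(dd, config$lstm_hidden, 2L)
    layouts <- NULL
  } else {
    params <- init_cnn_params(
      c(nrow(feats[[1]]), dd), config$conv_blocks, 2L
    )
    layouts <- cnn_layouts(c(nrow(feats[[1]]), dd), config$conv_blocks)
  }
  state <- list(
    m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
    v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p)))
  )
  history <- vector("list", cfg$epochs)
  step <- 0L
  for (epoch in seq_len(cfg$epochs)) {
    order_ep <- sample(tr_idx)
    batches <- split(order_ep, ceiling(seq_along(order_ep) / cfg$batch_size))
    ep_loss <- 0
    ep_correct <- 0
    for (bi in batches) {
      yb <- y[bi]
      y1h <- matrix(0, length(bi), 2)
      y1h[cbind(seq_along(bi), yb)] <- 1
      if (is_lstm) {
        arr <- array(unlist(feats[bi]), dim = c(nrow(feats[[1]]), dd, length(bi)))
        res <- lstm_loss_grads(arr, y1h, params, config$lstm_pool)
      } else {
        res <- cnn_loss_grads(feats[bi], y1h, params, config$conv_blocks, layouts)
      }
      step <- step + 1L
      upd <- adam_update(params, res$grads, state, cfg$learning_rate, step)
      params <- upd$params
      state <- upd$state
      ep_loss <- ep_loss + res$loss * length(bi)
      ep_correct <- ep_correct + sum(max.col(res$probs) == yb)
    }
    val <- c(loss = NA_real_, acc = NA_real_)
    if (length(val_idx) > 0) {
      vp <- model_probs(feats[val_idx], params, config, layouts)
      y1h <- matrix(0, length(val_idx), 2)
      y1h[cbind(seq_along(val_idx), y[val_idx])] <- 1
      val["loss"] <- -mean(log(pmax(rowSums(vp * y1h), 1e-12)))
      val["acc"] <- mean(max.col(vp) == y[val_idx])
    }
    history[[epoch]] <- tibble::tibble(
      epoch = epoch,
      loss = ep_loss / length(tr_idx),
      accuracy = ep_correct / length(tr_idx),
      val_loss = val[["loss"]], val_accuracy = val[["acc"]]
    )
  }
  structure(
    list(
      config = config, params = params, norm = norm,
      history = do.call(rbind, history), classes = classes,
      feature_kind = feature_kind, layouts = layouts
    ),
    class = "snore_model"
  )
}

# probabilities for a list of already-normalized feature matrices
model_probs <- function(feats, params, config, layouts, chunk = 256L) {
  n <- length(feats)
  probs <- matrix(0, n, 2)
  for (start in seq(1, n, by = chunk)) {
    ii <- start:min(start + chunk - 1, n)
    if (config$architecture == "lstm") {
      arr <- array(
        unlist(feats[ii]),
        dim = c(nrow(feats[[1]]), ncol(feats[[1]]), length(ii))
      )
      fw <- lstm_forward(arr, params)
      h <- if (identical(config$lstm_pool, "final")) fw$h else fw$h_mean
      logits <- h %*% params$W_out + rep(params$b_out, each = nrow(h))
    } else {
      logits <- cnn_predict_flat(feats[ii], params, config$conv_blocks, layouts)
    }
    m <- apply(logits, 1, max)
    e <- exp(logits - m)
    probs[ii, ] <- e / rowSums(e)
  }
  probs
}

#' @export
print.snore_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<snore_model: %s on %s features; %d epochs, train acc %.3f%s>\n",
    x$config$architecture, x$feature_kind, nrow(x$history), h$accuracy,
    if (!is.na(h$val_accuracy)) sprintf(", val acc %.3f", h$val_accuracy) else ""
  ))
  invisible(x)
}

#' Classify feature matrices
#'
#' Applies the stored per-coefficient normalization and the fitted
#' network; class probabilities sum to 1.
#'
#' @param object A fitted `snore_model`.
#' @param newdata A single feature matrix or a list of them, shaped as
#'   the training features.
#' @param ... Unused.
#' @return A tibble with one row per input: `label` (argmax class),
#'   `prob_abnormal`, `prob_normal`.
#' @export
predict.snore_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) newdata <- list(newdata)
  dtrain <- length(object$norm$mean)
  for (f in newdata) {
    if (ncol(f) != dtrain) {
      stop_input("feature matrix has ", ncol(f), " coefficients, model expects ", dtrain)
    }
  }
  feats <- lapply(newdata, function(f) normalize_features(unclass(f), object$norm))
  probs <- model_probs(feats, object$params, object$config, object$layouts)
  tibble::tibble(
    label = object$classes[max.col(probs)],
    prob_normal = probs[, 1], prob_abnormal = probs[, 2]
  )
}

#' Evaluate a classifier on labeled features
#'
#' Convention follows the evaluation in the source protocol: the
#' positive class is normal snoring.
#'
#' @param model A fitted `snore_model`.
#' @param features List of feature matrices.
#' @param labels True labels (`"normal"`/`"abnormal"`).
#' @param positive The class counted as positive (default `"normal"`).
#' @return List with `counts` (a [confusion_counts()]) and `metrics`
#'   (a [compute_metrics()] tibble).
#' @export
evaluate_model <- function(model, features, labels, positive = "normal") {
  pred <- predict(model, features)$label
  counts <- count_confusion(as.character(labels), pred, positive = positive)
  list(counts = counts, metrics = compute_metrics(counts))
}
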