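# Independent reference implementations used as oracles. These are coded
# from the defining formulas with plain loops, deliberately sharing no
# code with the package internals.

rms <- function(x) sqrt(mean(x^2))

# reference MFCC: per-frame loops, own filterbank construction
ref_mfcc <- function(x, sr = 16000, flen = 480, shift = 160, alpha = 0.97,
                     n_fft = 512, M = 40, L = 40, floor_c = 1e-10,
                     f_min = 0, f_max = 8000) {
  y <- numeric(length(x))
  y[1] <- x[1]
  for (n in 2:length(x)) y[n] <- x[n] - alpha * x[n - 1]
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(f_min), mel(f_max), length.out = M + 2))
  bins <- (0:(n_fft / 2)) * sr / n_fft
  H <- matrix(0, M, n_fft / 2 + 1)
  for (m in 1:M) {
    for (k in seq_along(bins)) {
      f <- bins[k]
      if (f >= edges[m] && f <= edges[m + 1]) {
        H[m, k] <- (f - edges[m]) / (edges[m + 1] - edges[m])
      } else if (f > edges[m + 1] && f <= edges[m + 2]) {
        H[m, k] <- (edges[m + 2] - f) / (edges[m + 2] - edges[m + 1])
      }
    }
  }
  w <- 0.54 - 0.46 * cos(2 * pi * (0:(flen - 1)) / (flen - 1))
  n_frames <- floor((length(x) - flen) / shift) + 1
  out <- matrix(0, n_frames, L)
  for (i in seq_len(n_frames)) {
    seg <- y[((i - 1) * shift + 1):((i - 1) * shift + flen)] * w
    spec <- Mod(fft(c(seg, numeric(n_fft - flen))))^2
    p <- spec[1:(n_fft / 2 + 1)]
    s <- numeric(M)
    for (m in 1:M) s[m] <- log(max(sum(p * H[m, ]), floor_c))
    for (n in 1:L) {
      out[i, n] <- sum(s * cos(pi * n * ((1:M) - 0.5) / M))
    }
  }
  out
}

# brute-force cepstral recursion, literal translation of the three branches
ref_lpcc <- function(a, L) {
  p <- length(a)
  cc <- numeric(L)
  for (n in 1:L) {
    if (n == 1) {
      cc[1] <- a[1]
    } else if (n <= p) {
      s <- a[n]
      for (k in 1:(n - 1)) s <- s + (1 - k / n) * a[k] * cc[n - k]
      cc[n] <- s
    } else {
      s <- 0
      for (k in 1:p) s <- s + (1 - k / n) * a[k] * cc[n - k]
      cc[n] <- s
    }
  }
  cc
}

# scalar LSTM cell: one unit at a time, no matrix ops
ref_lstm_cell <- function(x, h_prev, c_prev, w) {
  sig <- function(v) 1 / (1 + exp(-v))
  z <- c(h_prev, x)
  H <- length(h_prev)
  h <- numeric(H)
  cc <- numeric(H)
  for (u in 1:H) {
    f <- sig(sum(w$W_f[u, ] * z) + w$b_f[u])
    i <- sig(sum(w$W_i[u, ] * z) + w$b_i[u])
    cb <- tanh(sum(w$W_c[u, ] * z) + w$b_c[u])
    cc[u] <- f * c_prev[u] + i * cb
    o <- sig(sum(w$W_o[u, ] * z) + w$b_o[u])
    h[u] <- o * tanh(cc[u])
  }
  list(h = h, c = cc)
}

# metrics recomputed by expanding counts into label vectors and tabulating
ref_metrics <- function(tp, fn, tn, fp) {
  truth <- c(rep("pos", tp + fn), rep("neg", tn + fp))
  pred <- c(
    rep("pos", tp), rep("neg", fn),
    rep("neg", tn), rep("pos", fp)
  )
  acc <- mean(truth == pred)
  prec <- if (sum(pred == "pos") > 0) {
    sum(truth == "pos" & pred == "pos") / sum(pred == "pos")
  } else {
    NA_real_
  }
  sens <- if (sum(truth == "pos") > 0) {
    sum(truth == "pos" & pred == "pos") / sum(truth == "pos")
  } else {
    NA_real_
  }
  spec <- if (sum(truth == "neg") > 0) {
    sum(truth == "neg" & pred == "neg") / sum(truth == "neg")
  } else {
    NA_real_
  }
  f1 <- if (!is.na(prec) && !is.na(sens) && prec + sens > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    NA_real_
  }
  c(accuracy = acc, precision = prec, sensitivity = sens,
    specificity = spec, f1 = f1)
}

# random LSTM cell weights for oracle comparisons
random_cell_weights <- function(H, D) {
  mk <- function() matrix(rnorm(H * (H + D), sd = 0.5), H, H + D)
  list(
    W_f = mk(), W_i = mk(), W_c = mk(), W_o = mk(),
    b_f = rnorm(H), b_i = rnorm(H), b_c = rnorm(H), b_o = rnorm(H)
  )
}

# small separable sequence dataset for training sanity checks:
# class means differ on half the coordinates
separable_features <- function(n_per_class, t_len = 20, d = 8, sep = 2,
                               seed = 1) {
  set.seed(seed)
  feats <- list()
  labels <- character(0)
  for (i in seq_len(2 * n_per_class)) {
    cls <- if (i <= n_per_class) "normal" else "abnormal"
    m <- matrix(rnorm(t_len * d), t_len, d)
    if (cls == "abnormal") m[, seq_len(d / 2)] <- m[, seq_len(d / 2)] + sep
    feats[[i]] <- m
    labels <- c(labels, cls)
  }
  list(features = feats, labels = labels)
}
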