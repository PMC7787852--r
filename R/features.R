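#' Feature-extraction configuration
#'
#' Defaults give the pipeline's canonical 40-coefficient cepstral features:
#' 40 mel filters, 40 output coefficients (so each 3 s clip maps to a
#' 298 x 40 matrix), LPC order 12 (standard for 16 kHz audio), mel band
#' 0--8000 Hz, and a small positive floor under the log to keep all
#' outputs finite.
#'
#' @param n_mel_filters Number of mel triangular filters (M).
#' @param n_coeffs Number of cepstral coefficients per frame (L); at most
#'   `n_mel_filters` for the mel-based extractors.
#' @param lpc_order All-pole model order p (>= 1).
#' @param log_floor Positive floor applied inside the natural log.
#' @param f_min,f_max Mel filterbank band edges in Hz.
#' @return A `feature_config` object.
#' @export
feature_config <- function(n_mel_filters = 40L, n_coeffs = 40L,
                           lpc_order = 12L, log_floor = 1e-10,
                           f_min = 0, f_max = 8000) {
  if (n_coeffs > n_mel_filters) {
    stop_input("`n_coeffs` must be <= `n_mel_filters` for mel-based features")
  }
  if (lpc_order < 1) stop_input("`lpc_order` must be >= 1")
  if (log_floor <= 0) stop_input("`log_floor` must be positive")
  structure(
    list(
      n_mel_filters = as.integer(n_mel_filters),
      n_coeffs = as.integer(n_coeffs),
      lpc_order = as.integer(lpc_order),
      log_floor = log_floor, f_min = f_min, f_max = f_max
    ),
    class = "feature_config"
  )
}

#' Mel scale conversions
#'
#' `mel(f) = 2595 * log10(1 + f/700)` and its inverse.
#'
#' @param f Frequency in Hz.
#' @param m Frequency in mel.
#' @return Converted frequency.
#' @export
hz_to_mel <- function(f) 2595 * log10(1 + f / 700)

#' @rdname hz_to_mel
#' @export
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Build a mel-scale triangular filterbank
#'
#' M triangular filters with unit peaks, their center frequencies equally
#' spaced on the mel scale between `f_min` and `f_max`, sampled at the
#' `n_fft/2 + 1` non-redundant transform bins.
#'
#' @param n_filters Number of filters M (>= 1).
#' @param sample_rate Sampling frequency in Hz.
#' @param n_fft Transform length the filterbank is sampled on.
#' @param f_min,f_max Band edges in Hz; `f_max <= sample_rate/2`.
#' @return A `mel_filterbank`: list with `weights`
#'   (`M x (n_fft/2 + 1)` matrix), `centers_hz`, and the construction
#'   parameters.
#' @export
build_mel_filterbank <- function(n_filters = 40L, sample_rate = SNORE_SR,
                                 n_fft = 512L, f_min = 0, f_max = sample_rate / 2) {
  if (n_filters < 1) stop_input("`n_filters` must be >= 1")
  if (f_min >= f_max) stop_input("need f_min < f_max")
  if (f_max > sample_rate / 2) stop_input("`f_max` must be <= sample_rate/2")
  edges_mel <- seq(hz_to_mel(f_min), hz_to_mel(f_max), length.out = n_filters + 2)
  edges_hz <- mel_to_hz(edges_mel)
  bin_hz <- (0:(n_fft / 2)) * sample_rate / n_fft
  weights <- matrix(0, n_filters, n_fft / 2 + 1)
  for (m in seq_len(n_filters)) {
    lo <- edges_hz[m]
    cen <- edges_hz[m + 1]
    hi <- edges_hz[m + 2]
    up <- (bin_hz - lo) / (cen - lo)
    down <- (hi - bin_hz) / (hi - cen)
    weights[m, ] <- pmax(0, pmin(up, down))
  }
  structure(
    list(
      weights = weights, centers_hz = edges_hz[2:(n_filters + 1)],
      n_filters = as.integer(n_filters), n_fft = as.integer(n_fft),
      sample_rate = sample_rate, f_min = f_min, f_max = f_max
    ),
    class = "mel_filterbank"
  )
}

#' Log mel-band energies
#'
#' For each frame and filter m, `s(m) = ln(max(sum_k P(k) * H_m(k),
#' log_floor))`: the power spectrum is pooled through each triangular
#' filter and the natural log taken with a positive floor.
#'
#' @param power_spec `n_frames x (n_fft/2 + 1)` power-spectrum matrix.
#' @param fb A [build_mel_filterbank()] result with matching `n_fft`.
#' @param log_floor Positive floor under the log.
#' @return An `n_frames x M` matrix of log energies.
#' @export
log_mel_energies <- function(power_spec, fb, log_floor = 1e-10) {
  if (ncol(power_spec) != ncol(fb$weights)) {
    stop_input(
      "power spectrum has ", ncol(power_spec), " bins but filterbank expects ",
      ncol(fb$weights)
    )
  }
  energies <- power_spec %*% t(fb$weights)
  log(pmax(energies, log_floor))
}

# DCT-II basis restricted to orders n = 1..L over M mel bands:
# D[n, m] = cos(pi * n * (m + 0.5) / M), m = 0..M-1
dct_basis <- function(n_coeffs, n_bands) {
  n <- seq_len(n_coeffs)
  m <- seq_len(n_bands) - 1
  outer(n, m, function(n, m) cos(pi * n * (m + 0.5) / n_bands))
}

new_feature_matrix <- function(values, feature_kind, frame_params) {
  stopifnot(all(is.finite(values)))
  structure(values,
    feature_kind = feature_kind, frame_params = frame_params,
    class = c("snore_features", "matrix", "array")
  )
}

#' @export
print.snore_features <- function(x, ...) {
  cat(sprintf(
    "<snore_features [%s]: %d frames x %d coefficients>\n",
    attr(x, "feature_kind"), nrow(x), ncol(x)
  ))
  invisible(x)
}

# shared time-domain front end: preemphasis -> framing -> Hamming
preprocess_frames <- function(signal, params) {
  emph <- preemphasize(signal, params$preemph_alpha)
  apply_hamming(frame_signal(emph, params))
}

#' Mel-frequency cepstral coefficients (MFCC)
#'
#' Full chain: pre-emphasis, 0.03 s / 0.01 s framing, Hamming window,
#' power spectrum, mel filterbank log energies, then the discrete cosine
#' transform `C(n) = sum_m s(m) * cos(pi * n * (m + 0.5) / M)` for
#' `n = 1..L`. A 3 s clip at 16 kHz yields a 298 x 40 matrix with the
#' default configuration.
#'
#' @param signal An [audio_signal()] at 16 kHz.
#' @param params A [frame_params()].
#' @param config A [feature_config()].
#' @return A `snore_features` matrix (`n_frames x n_coeffs`) tagged
#'   `"mfcc"`.
#' @export
mfcc <- function(signal, params = frame_params(), config = feature_config()) {
  frames <- preprocess_frames(signal, params)
  pspec <- power_spectrum(frames, params$n_fft)
  fb <- build_mel_filterbank(
    config$n_mel_filters, signal$sample_rate, params$n_fft,
    config$f_min, config$f_max
  )
  s <- log_mel_energies(pspec, fb, config$log_floor)
  coeffs <- s %*% t(dct_basis(config$n_coeffs, config$n_mel_filters))
  new_feature_matrix(coeffs, "mfcc", params)
}

#' Linear predictive coding by the autocorrelation method
#'
#' Fits the all-pole model `x[n] ~ sum_{k=1..p} a_k x[n-k]` by solving the
#' autocorrelation normal equations with the Levinson-Durbin recursion,
#' which guarantees a minimum-phase (stable) synthesis filter.
#'
#' @param frame Numeric vector of (windowed) frame samples.
#' @param order Model order p; must be less than the frame length.
#' @return An `lpc_model`: list with `coeffs` (a_1..a_p), `order`, `gain`
#'   (square root of the final prediction-error power) and
#'   `prediction_error`.
#' @export
lpc <- function(frame, order = 12L) {
  x <- as_samples(frame)
  if (order < 1) stop_input("`order` must be >= 1")
  if (order >= length(x)) stop_input("`order` must be < frame length")
  if (all(x == 0)) stop_input("degenerate all-zero frame")
  # biased autocorrelation r[0..p]
  n <- length(x)
  r <- vapply(0:order, function(k) sum(x[1:(n - k)] * x[(1 + k):n]), numeric(1))
  a <- numeric(0)
  err <- r[1]
  for (i in seq_len(order)) {
    acc <- r[i + 1]
    if (i > 1) acc <- acc - sum(a * r[i:2])
    k <- acc / err
    a_new <- k
    if (i > 1) a_new <- c(a - k * rev(a), k)
    a <- a_new
    err <- err * (1 - k^2)
    if (err <= 0) { # numerically singular; clamp
      err <- .Machine$double.eps * r[1]
    }
  }
  structure(
    list(
      coeffs = a, order = as.integer(order),
      gain = sqrt(err), prediction_error = err
    ),
    class = "lpc_model"
  )
}

#' Cepstral coefficients from an LPC model (LPCC)
#'
#' Recursive conversion of prediction coefficients to cepstral
#' coefficients: `c(1) = a(1)`; for `1 < n <= p`,
#' `c(n) = a(n) + sum_{k=1..n-1} (1 - k/n) a_k c(n-k)`; for `n > p`,
#' `c(n) = sum_{k=1..p} (1 - k/n) a_k c(n-k)`.
#'
#' @param model An [lpc()] model, or a bare numeric vector of prediction
#'   coefficients a_1..a_p.
#' @param n_coeffs Number of cepstral coefficients L (>= 1).
#' @return Numeric vector `c(1)..c(L)`.
#' @export
lpcc <- function(model, n_coeffs = 40L) {
  if (n_coeffs < 1) stop_input("`n_coeffs` must be >= 1")
  a <- if (inherits(model, "lpc_model")) model$coeffs else as.numeric(model)
  p <- length(a)
  cc <- numeric(n_coeffs)
  for (n in seq_len(n_coeffs)) {
    if (n == 1) {
      cc[1] <- a[1]
    } else {
      k <- seq_len(min(n - 1, p))
      acc <- sum((1 - k / n) * a[k] * cc[n - k])
      if (n <= p) acc <- acc + a[n]
      cc[n] <- acc
    }
  }
  cc
}

#' LPCC feature matrix
#'
#' Per frame: pre-emphasis + Hamming preprocessing, LPC fit of order p,
#' then the [lpcc()] recursion to L coefficients. All-zero (silent)
#' frames yield all-zero rows. Shape matches [mfcc()] (298 x 40 for a
#' 3 s clip with defaults).
#'
#' @inheritParams mfcc
#' @return A `snore_features` matrix tagged `"lpcc"`.
#' @export
lpcc_features <- function(signal, params = frame_params(),
                          config = feature_config()) {
  frames <- preprocess_frames(signal, params)
  out <- matrix(0, nrow(frames), config$n_coeffs)
  for (i in seq_len(nrow(frames))) {
    fr <- frames[i, ]
    if (any(fr != 0)) {
      out[i, ] <- lpcc(lpc(fr, config$lpc_order), config$n_coeffs)
    }
  }
  new_feature_matrix(out, "lpcc", params)
}

# per-frame LPC coefficient matrix (n_frames x order); zero rows for
# degenerate frames
lpc_coef_matrix <- function(frames, order) {
  out <- matrix(0, nrow(frames), order)
  for (i in seq_len(nrow(frames))) {
    fr <- frames[i, ]
    if (any(fr != 0)) out[i, ] <- lpc(fr, order)$coeffs
  }
  out
}

#' Mel cepstrum of the LPC spectrum (LPMFCC)
#'
#' Hybrid feature: per frame the LPC coefficients a_1..a_p are zero-padded
#' to `n_fft` points and Fourier-transformed to a discrete spectrum; its
#' squared magnitude is pooled through the mel filterbank and logged
#' (`Za(m)`), and a discrete cosine transform
#' `Ca(n) = sum_m Za(m) * cos(pi * n * (m + 0.5) / M)` gives L
#' coefficients per frame.
#'
#' @inheritParams mfcc
#' @return A `snore_features` matrix tagged `"lpmfcc"`.
#' @export
lpmfcc <- function(signal, params = frame_params(), config = feature_config()) {
  frames <- preprocess_frames(signal, params)
  acoef <- lpc_coef_matrix(frames, config$lpc_order)
  pspec <- lpc_power_spectrum(acoef, params$n_fft)
  fb <- build_mel_filterbank(
    config$n_mel_filters, signal$sample_rate, params$n_fft,
    config$f_min, config$f_max
  )
  za <- log_mel_energies(pspec, fb, config$log_floor)
  coeffs <- za %*% t(dct_basis(config$n_coeffs, config$n_mel_filters))
  # silent frames carry no model: zero their rows (constant-floor rows
  # already DCT to zero for n >= 1, but keep the rule explicit)
  silent <- rowSums(abs(acoef)) == 0
  coeffs[silent, ] <- 0
  new_feature_matrix(coeffs, "lpmfcc", params)
}

# squared-magnitude DFT of each row of coefficients zero-padded to n_fft
lpc_power_spectrum <- function(acoef, n_fft) {
  padded <- matrix(0, nrow = n_fft, ncol = nrow(acoef))
  padded[seq_len(ncol(acoef)), ] <- t(acoef)
  spec <- Mod(stats::mvfft(padded))^2
  t(spec[seq_len(n_fft / 2 + 1), , drop = FALSE])
}

#' Extract features by kind
#'
#' Dispatcher over the three extractors.
#'
#' @inheritParams mfcc
#' @param kind One of `"mfcc"`, `"lpcc"`, `"lpmfcc"`.
#' @return A `snore_features` matrix.
#' @export
extract_features <- function(signal, kind = c("mfcc", "lpcc", "lpmfcc"),
                             params = frame_params(),
                             config = feature_config()) {
  kind <- match.arg(kind)
  switch(kind,
    mfcc = mfcc(signal, params, config),
    lpcc = lpcc_features(signal, params, config),
    lpmfcc = lpmfcc(signal, params, config)
  )
}
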