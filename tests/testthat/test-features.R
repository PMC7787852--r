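test_that("mel scale and filterbank have the defining properties", {
  expect_equal(hz_to_mel(1000), 1000, tolerance = 1e-3)
  expect_identical(hz_to_mel(0), 0)
  expect_equal(mel_to_hz(hz_to_mel(432.1)), 432.1)

  fb <- build_mel_filterbank(40, 16000, 512, 0, 8000)
  expect_identical(dim(fb$weights), c(40L, 257L))
  expect_true(all(fb$weights >= 0))
  expect_true(all(fb$weights <= 1))
  expect_true(all(diff(fb$centers_hz) > 0))
  # each filter is unimodal: rises then falls
  for (m in c(1, 10, 25, 40)) {
    w <- fb$weights[m, ]
    peak <- which.max(w)
    expect_true(all(diff(w[1:peak]) >= 0))
    expect_true(all(diff(w[peak:length(w)]) <= 0))
  }
  expect_error(build_mel_filterbank(0, 16000, 512), "n_filters")
  expect_error(build_mel_filterbank(40, 16000, 512, 4000, 1000), "f_min")
})

test_that("log mel energies floor zeros and respect the log identity", {
  fb <- build_mel_filterbank(40, 16000, 512)
  zero <- matrix(0, 3, 257)
  expect_true(all(log_mel_energies(zero, fb, 1e-10) == log(1e-10)))

  spec <- matrix(abs(rnorm(257))^2 + 0.1, 1, 257)
  s1 <- log_mel_energies(spec, fb)
  s2 <- log_mel_energies(2 * spec, fb)
  expect_equal(as.numeric(s2 - s1), rep(log(2), 40), tolerance = 1e-10)

  # spectrum equal to one filter's own weights maximizes that filter
  spec_f <- matrix(fb$weights[20, ], 1)
  e <- exp(log_mel_energies(spec_f, fb))
  expect_equal(e[1, 20], sum(fb$weights[20, ]^2))
  expect_identical(which.max(e[1, ]), 20L)

  expect_error(log_mel_energies(matrix(0, 2, 100), fb), "bins")
})

test_that("mfcc returns 298 x 40 and matches an independent reference", {
  set.seed(5)
  t <- (0:47999) / 16000
  x <- 0.5 * sin(2 * pi * 220 * t) + 0.3 * sin(2 * pi * 1300 * t) +
    rnorm(48000, sd = 0.01)
  m <- mfcc(audio_signal(x, 16000))
  expect_identical(dim(unclass(m)), c(298L, 40L))
  expect_identical(attr(m, "feature_kind"), "mfcc")

  ref <- ref_mfcc(x)
  expect_lt(max(abs(unclass(m) - ref)), 1e-4)
})

test_that("mfcc of silence has zero coefficients for n >= 1", {
  sil <- mfcc(audio_signal(rep(0, 48000), 16000))
  expect_lt(max(abs(sil)), 1e-9)
  # every frame identical
  expect_equal(unclass(sil)[1, ], unclass(sil)[298, ])
})

test_that("mfcc coefficients n >= 1 are invariant to waveform gain", {
  set.seed(8)
  x <- rnorm(48000) * 0.1
  m1 <- mfcc(audio_signal(x, 16000))
  m2 <- mfcc(audio_signal(5 * x, 16000))
  expect_lt(max(abs(unclass(m1) - unclass(m2))), 1e-6)
})

test_that("lpc recovers known processes", {
  set.seed(11)
  ar1 <- as.numeric(stats::arima.sim(list(ar = 0.9), 48000))
  m <- lpc(ar1, 1)
  expect_equal(m$coeffs, 0.9, tolerance = 0.02)

  wn <- rnorm(48000)
  m12 <- lpc(wn, 12)
  expect_true(all(abs(m12$coeffs) < 0.1))
  expect_gt(m12$prediction_error, 0)

  # order 1 closed form a1 = r(1)/r(0)
  fr <- rnorm(480)
  r0 <- sum(fr^2)
  r1 <- sum(fr[-1] * fr[-480])
  expect_equal(lpc(fr, 1)$coeffs, r1 / r0, tolerance = 1e-12)

  expect_error(lpc(rep(0, 480), 12), "zero")
  expect_error(lpc(rnorm(10), 12), "order")
})

test_that("lpc agrees with the Yule-Walker fit", {
  set.seed(12)
  for (ord in c(2, 8, 12)) {
    fr <- as.numeric(stats::arima.sim(list(ar = c(0.5, -0.3)), 2000))
    a_yw <- stats::ar(fr,
      aic = FALSE, order.max = ord,
      method = "yule-walker", demean = FALSE
    )$ar
    expect_equal(lpc(fr, ord)$coeffs, as.numeric(a_yw), tolerance = 1e-8)
  }
})

test_that("lpc models are minimum phase on random frames", {
  set.seed(13)
  worst <- 0
  for (i in 1:1000) {
    fr <- rnorm(480)
    a <- lpc(fr, 12)$coeffs
    poles <- polyroot(c(-rev(a), 1))
    worst <- max(worst, max(Mod(poles)))
  }
  expect_lt(worst, 1)
})

test_that("lpcc recursion matches hand values and a brute-force oracle", {
  a <- 0.7
  cc <- lpcc(a, 2)
  expect_equal(cc, c(0.7, 0.7^2 / 2))
  expect_equal(lpcc(rep(0, 5), 10), rep(0, 10))
  expect_error(lpcc(a, 0), "n_coeffs")

  set.seed(14)
  for (i in 1:50) {
    p <- sample(1:5, 1)
    L <- sample(p:20, 1)
    # draw stable coefficient sets via reflection coefficients
    k <- runif(p, -0.9, 0.9)
    a <- k[1]
    if (p > 1) for (j in 2:p) a <- c(a - k[j] * rev(a), k[j])
    expect_equal(lpcc(a, L), ref_lpcc(a, L), tolerance = 1e-12)
  }
})

test_that("lpcc_features has canonical shape and the degenerate-frame rule", {
  sil <- lpcc_features(audio_signal(rep(0, 48000), 16000))
  expect_identical(dim(unclass(sil)), c(298L, 40L))
  expect_true(all(sil == 0))

  set.seed(15)
  x <- as.numeric(stats::arima.sim(list(ar = c(1.3, -0.6)), 8000)) * 0.05
  sig <- audio_signal(x, 16000)
  f <- lpcc_features(sig)
  expect_identical(attr(f, "feature_kind"), "lpcc")
  expect_true(all(is.finite(f)))

  # compositional oracle: row i equals lpcc(lpc(frame i))
  frames <- apply_hamming(frame_signal(preemphasize(sig, 0.97)))
  for (i in c(1, 7, 40)) {
    expect_equal(
      as.numeric(f[i, ]), lpcc(lpc(frames[i, ], 12), 40),
      tolerance = 1e-12
    )
  }
})

test_that("lpmfcc has canonical shape and matches its explicit chain", {
  sil <- lpmfcc(audio_signal(rep(0, 48000), 16000))
  expect_identical(dim(unclass(sil)), c(298L, 40L))
  expect_true(all(sil == 0))

  set.seed(16)
  x <- as.numeric(stats::arima.sim(list(ar = c(0.8, -0.2)), 8000)) * 0.05
  sig <- audio_signal(x, 16000)
  f <- lpmfcc(sig)
  expect_identical(attr(f, "feature_kind"), "lpmfcc")

  # oracle: transform -> square -> filter -> log -> DCT, coded explicitly
  frames <- apply_hamming(frame_signal(preemphasize(sig, 0.97)))
  fb <- build_mel_filterbank(40, 16000, 512)
  for (i in c(3, 25)) {
    a <- lpc(frames[i, ], 12)$coeffs
    spec <- Mod(fft(c(a, numeric(512 - 12))))^2
    za <- numeric(40)
    for (m in 1:40) {
      za[m] <- log(max(sum(spec[1:257] * fb$weights[m, ]), 1e-10))
    }
    ca <- numeric(40)
    for (n in 1:40) ca[n] <- sum(za * cos(pi * n * ((1:40) - 0.5) / 40))
    expect_equal(as.numeric(f[i, ]), ca, tolerance = 1e-10)
  }
})

test_that("all extractors return finite 298 x 40 matrices on real-ish input", {
  clip <- gen_snore_clip("normal", seed = 77)
  for (kind in c("mfcc", "lpcc", "lpmfcc")) {
    f <- extract_features(clip$audio, kind)
    expect_identical(dim(unclass(f)), c(298L, 40L))
    expect_true(all(is.finite(f)))
    expect_identical(attr(f, "feature_kind"), kind)
  }
})

test_that("feature archives round-trip bit-identically", {
  clip <- gen_snore_clip("normal", seed = 78)
  f1 <- mfcc(clip$audio)
  f2 <- mfcc(gen_snore_clip("abnormal_gasp", seed = 79)$audio)
  p <- withr::local_tempfile(fileext = ".snf")
  write_features(list(f1, f2), p, labels = c("normal", "abnormal"))
  back <- read_features(p)
  expect_identical(back$labels, c("normal", "abnormal"))
  expect_identical(unclass(back$features[[1]])[, ], unclass(f1)[, ])
  expect_identical(unclass(back$features[[2]])[, ], unclass(f2)[, ])
  expect_identical(attr(back$features[[1]], "feature_kind"), "mfcc")
})
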