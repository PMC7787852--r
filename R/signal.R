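#' Construct an audio signal
#'
#' The pipeline's raw input: a mono, real-valued waveform with its sample
#' rate. Amplitudes are dimensionless and nominally in `[-1, 1]`.
#'
#' @param samples Numeric vector of sample amplitudes.
#' @param sample_rate Sampling frequency in Hz (positive).
#' @return An object of class `audio_signal` with fields `samples` and
#'   `sample_rate`.
#' @examples
#' x <- audio_signal(sin(2 * pi * 100 * seq(0, 1, by = 1 / 16000)), 16000)
#' duration(x)
#' @export
audio_signal <- function(samples, sample_rate) {
  if (!is.numeric(samples) || length(samples) == 0) {
    stop_input("`samples` must be a non-empty numeric vector")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1 || sample_rate <= 0) {
    stop_input("`sample_rate` must be a single positive number")
  }
  structure(
    list(samples = as.numeric(samples), sample_rate = as.numeric(sample_rate)),
    class = "audio_signal"
  )
}

#' @export
print.audio_signal <- function(x, ...) {
  cat(sprintf(
    "<audio_signal: %d samples @ %g Hz (%.3f s), range [%.3g, %.3g]>\n",
    length(x$samples), x$sample_rate, duration(x),
    min(x$samples), max(x$samples)
  ))
  invisible(x)
}

#' Duration of an audio signal in seconds
#' @param x An `audio_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(x) {
  stopifnot(inherits(x, "audio_signal"))
  length(x$samples) / x$sample_rate
}

as_samples <- function(x) {
  if (inherits(x, "audio_signal")) x$samples else as.numeric(x)
}

#' Framing and preprocessing parameters
#'
#' Defaults follow the pipeline's canonical analysis setup: 0.03 s frames
#' shifted by 0.01 s, pre-emphasis coefficient 0.97, and a 512-point
#' transform (the smallest power of two holding a 480-sample frame at
#' 16 kHz).
#'
#' @param frame_len_s Frame length in seconds.
#' @param shift_s Frame shift (hop) in seconds; must satisfy
#'   `0 < shift_s <= frame_len_s`.
#' @param preemph_alpha Pre-emphasis coefficient in `[0, 1)`.
#' @param n_fft Transform length in points; must be at least one frame of
#'   samples at the signal's rate.
#' @return A `frame_params` object.
#' @export
frame_params <- function(frame_len_s = 0.03, shift_s = 0.01,
                         preemph_alpha = 0.97, n_fft = 512L) {
  if (!(shift_s > 0 && shift_s <= frame_len_s)) {
    stop_input("need 0 < shift_s <= frame_len_s")
  }
  if (preemph_alpha < 0 || preemph_alpha >= 1) {
    stop_input("`preemph_alpha` must be in [0, 1)")
  }
  if (n_fft < 1) stop_input("`n_fft` must be a positive integer")
  structure(
    list(
      frame_len_s = frame_len_s, shift_s = shift_s,
      preemph_alpha = preemph_alpha, n_fft = as.integer(n_fft)
    ),
    class = "frame_params"
  )
}

#' Read a PCM WAV file
#'
#' Reads RIFF/WAVE audio (8/16/24/32-bit integer PCM or 32/64-bit float),
#' scales samples to `[-1, 1]`, averages multichannel input to mono, and
#' resamples to the pipeline-canonical 16 kHz when the file rate differs
#' (band-limited polyphase resampling; the conversion is reported via
#' `message()`).
#'
#' @param path Path to a WAV file.
#' @param target_rate Canonical sample rate in Hz (default 16000).
#' @return An [audio_signal()].
#' @export
read_wav <- function(path, target_rate = SNORE_SR) {
  if (!file.exists(path)) stop_input("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF") || !identical(wave, "WAVE")) {
    stop_input("not a RIFF/WAVE file: ", path)
  }
  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      body <- readBin(con, "raw", sz)
      u16 <- function(i) sum(as.integer(body[i:(i + 1)]) * c(1, 256))
      u32 <- function(i) sum(as.integer(body[i:(i + 3)]) * c(1, 256, 65536, 16777216))
      fmt <- list(
        audio_format = u16(1), n_channels = u16(3),
        sample_rate = u32(5), bits = u16(15)
      )
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", sz)
    } else {
      invisible(readBin(con, "raw", sz))
    }
    if (sz %% 2 == 1) invisible(readBin(con, "raw", 1)) # chunk padding
    if (!is.null(fmt) && !is.null(data_raw)) break
  }
  if (is.null(fmt) || is.null(data_raw)) {
    stop_input("missing fmt/data chunk in WAV file: ", path)
  }
  fmt_code <- fmt$audio_format
  if (fmt_code == 65534 && length(data_raw) > 0) fmt_code <- 1 # WAVE_FORMAT_EXTENSIBLE: assume PCM
  x <- switch(as.character(fmt_code),
    "1" = switch(as.character(fmt$bits),
      "8" = (as.integer(readBin(data_raw, "integer", length(data_raw), 1,
        signed = FALSE
      )) - 128) / 128,
      "16" = readBin(data_raw, "integer", length(data_raw) %/% 2, 2,
        signed = TRUE, endian = "little"
      ) / 32768,
      "24" = {
        n <- length(data_raw) %/% 3
        b <- matrix(as.integer(data_raw[seq_len(3 * n)]), nrow = 3)
        v <- b[1, ] + b[2, ] * 256 + b[3, ] * 65536
        v <- ifelse(v >= 8388608, v - 16777216, v)
        v / 8388608
      },
      "32" = readBin(data_raw, "integer", length(data_raw) %/% 4, 4,
        signed = TRUE, endian = "little"
      ) / 2147483648,
      stop_input("unsupported PCM bit depth: ", fmt$bits)
    ),
    "3" = readBin(data_raw, "double", length(data_raw) %/% (fmt$bits %/% 8),
      fmt$bits %/% 8,
      endian = "little"
    ),
    stop_input("unsupported WAV format code: ", fmt$audio_format)
  )
  if (fmt$n_channels > 1) {
    n <- length(x) %/% fmt$n_channels
    x <- rowMeans(matrix(x[seq_len(n * fmt$n_channels)],
      ncol = fmt$n_channels, byrow = TRUE
    ))
  }
  if (fmt$sample_rate != target_rate) {
    message(sprintf(
      "read_wav: resampling %s from %d Hz to %d Hz",
      basename(path), fmt$sample_rate, target_rate
    ))
    x <- resample_signal(x, fmt$sample_rate, target_rate)
  }
  audio_signal(x, target_rate)
}

# band-limited rational-rate resampling via the signal package
resample_signal <- function(x, from_rate, to_rate) {
  gcd <- function(a, b) if (b == 0) a else gcd(b, a %% b)
  from <- as.integer(round(from_rate))
  to <- as.integer(round(to_rate))
  g <- gcd(to, from)
  as.numeric(signal::resample(x, to %/% g, from %/% g))
}

#' Write an audio signal to a PCM WAV file
#'
#' @param signal An [audio_signal()].
#' @param path Output path.
#' @param bit_depth 16 (integer PCM, default) or 32 (IEEE float).
#' @return `path`, invisibly.
#' @export
write_wav <- function(signal, path, bit_depth = 16) {
  stopifnot(inherits(signal, "audio_signal"), bit_depth %in% c(16, 32))
  x <- pmin(pmax(signal$samples, -1), 1)
  sr <- as.integer(round(signal$sample_rate))
  n <- length(x)
  bytes_per <- bit_depth / 8
  data_size <- n * bytes_per
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + data_size), con, 4, endian = "little")
  writeChar("WAVE", con, eos = NULL)
  writeChar("fmt ", con, eos = NULL)
  writeBin(16L, con, 4, endian = "little")
  fmt_code <- if (bit_depth == 16) 1L else 3L
  writeBin(fmt_code, con, 2, endian = "little")
  writeBin(1L, con, 2, endian = "little") # mono
  writeBin(sr, con, 4, endian = "little")
  writeBin(as.integer(sr * bytes_per), con, 4, endian = "little")
  writeBin(as.integer(bytes_per), con, 2, endian = "little")
  writeBin(as.integer(bit_depth), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(data_size), con, 4, endian = "little")
  if (bit_depth == 16) {
    writeBin(as.integer(round(x * 32767)), con, 2, endian = "little")
  } else {
    writeBin(x, con, 4, endian = "little")
  }
  invisible(path)
}

#' Pre-emphasis high-pass filter
#'
#' First-difference filter `y[n] = x[n] - alpha * x[n-1]` (with
#' `y[1] = x[1]`) that lifts high-frequency content before spectral
#' analysis.
#'
#' @param signal An [audio_signal()] or numeric vector.
#' @param alpha Filter coefficient in `[0, 1)` (boundary value 1 is
#'   permitted for diagnostic use).
#' @return Same type as the input, same length.
#' @export
preemphasize <- function(signal, alpha = 0.97) {
  if (alpha < 0 || alpha > 1) stop_input("`alpha` must be in [0, 1]")
  x <- as_samples(signal)
  y <- x - alpha * c(0, x[-length(x)])
  y[1] <- x[1]
  if (inherits(signal, "audio_signal")) audio_signal(y, signal$sample_rate) else y
}

#' Slice a signal into overlapping frames
#'
#' Gathers consecutive windows of `frame_len_s` seconds every `shift_s`
#' seconds. Trailing samples that do not fill a complete frame are
#' dropped, so `n_frames = floor((n_samples - frame_len) / shift) + 1`
#' (a 3 s clip at 16 kHz with 0.03 s / 0.01 s framing gives exactly
#' 298 frames).
#'
#' @param signal An [audio_signal()].
#' @param params A [frame_params()].
#' @return A `frame_matrix`: an `n_frames x frame_len` numeric matrix with
#'   the framing parameters and sample rate stored as attributes.
#' @export
frame_signal <- function(signal, params = frame_params()) {
  stopifnot(inherits(signal, "audio_signal"), inherits(params, "frame_params"))
  sr <- signal$sample_rate
  flen <- round(params$frame_len_s * sr)
  shift <- round(params$shift_s * sr)
  x <- signal$samples
  if (length(x) < flen) {
    stop_input("signal shorter than one frame (", flen, " samples)")
  }
  n_frames <- floor((length(x) - flen) / shift) + 1
  starts <- (seq_len(n_frames) - 1) * shift
  idx <- outer(starts, seq_len(flen), "+")
  frames <- matrix(x[idx], nrow = n_frames)
  structure(frames,
    params = params, sample_rate = sr,
    class = c("frame_matrix", "matrix", "array")
  )
}

#' Hamming window of length n
#'
#' `w[k] = 0.54 - 0.46 * cos(2*pi*k/(N-1))`, `k = 0..N-1`.
#'
#' @param n Window length in samples.
#' @return Numeric vector of length `n`.
#' @export
hamming_window <- function(n) {
  if (n == 1) return(1)
  k <- seq_len(n) - 1
  0.54 - 0.46 * cos(2 * pi * k / (n - 1))
}

#' Apply a Hamming window to every frame
#'
#' @param frames A `frame_matrix` from [frame_signal()].
#' @return A `frame_matrix` of the same shape with each row multiplied
#'   elementwise by the Hamming taper.
#' @export
apply_hamming <- function(frames) {
  stopifnot(inherits(frames, "frame_matrix"))
  w <- hamming_window(ncol(frames))
  out <- frames * rep(w, each = nrow(frames))
  attributes(out) <- attributes(frames)
  out
}

#' Per-frame power spectrum
#'
#' Zero-pads each (already windowed) frame to `n_fft` points, applies the
#' discrete Fourier transform, and returns the squared magnitude of the
#' non-redundant half.
#'
#' @param frames A `frame_matrix` (rows are frames).
#' @param n_fft Transform length; must be at least the frame length.
#' @return An `n_frames x (n_fft/2 + 1)` matrix of non-negative reals.
#' @export
power_spectrum <- function(frames, n_fft = 512L) {
  fr <- unclass(frames)
  if (n_fft < ncol(fr)) stop_input("`n_fft` must be >= frame length")
  padded <- matrix(0, nrow = n_fft, ncol = nrow(fr))
  padded[seq_len(ncol(fr)), ] <- t(fr)
  spec <- Mod(stats::mvfft(padded))^2
  t(spec[seq_len(n_fft / 2 + 1), , drop = FALSE])
}
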