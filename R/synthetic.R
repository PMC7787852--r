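#' Acoustic parameters for a synthetic snore
#'
#' A snore is emulated as a harmonic pulse train at fundamental `f0`
#' whose harmonic amplitudes roll off at `spectral_tilt` dB per octave,
#' amplitude-modulated at `burst_rate` cycles per second (the breathing
#' rhythm), with background noise added by the caller. The acoustics are
#' a deliberately simple stand-in for upper-airway sound: parameters were
#' chosen to make the normal/abnormal classes separable but overlapping,
#' not to be physiologically accurate.
#'
#' @param f0 Fundamental frequency in Hz, in `[40, 400]`.
#' @param n_harmonics Number of harmonics of `f0` summed.
#' @param spectral_tilt Harmonic roll-off in dB/octave (negative).
#' @param amplitude Peak amplitude in `(0, 1]`.
#' @param burst_rate Amplitude-modulation cycles per second.
#' @param duration_s Duration in seconds.
#' @return A `snore_acoustics` object.
#' @export
snore_acoustics <- function(f0 = 110, n_harmonics = 12L, spectral_tilt = -6,
                            amplitude = 0.5, burst_rate = 0.35,
                            duration_s = CLIP_LEN_S) {
  if (f0 < 40 || f0 > 400) stop_input("`f0` must be in [40, 400] Hz")
  if (amplitude <= 0 || amplitude > 1) stop_input("`amplitude` must be in (0, 1]")
  if (duration_s <= 0) stop_input("`duration_s` must be positive")
  structure(
    list(
      f0 = f0, n_harmonics = as.integer(n_harmonics),
      spectral_tilt = spectral_tilt, amplitude = amplitude,
      burst_rate = burst_rate, duration_s = duration_s
    ),
    class = "snore_acoustics"
  )
}

# harmonic pulse train with drifting f0, tilted harmonics and a
# breathing-rhythm envelope; gasps add an irregular tremor and a
# broadband turbulence burst. Consumes the current RNG stream.
synth_snore_wave <- function(n, sr, ac, gasp = FALSE) {
  t <- (seq_len(n) - 1) / sr
  drift <- 1 + 0.02 * sin(2 * pi * 0.3 * t + stats::runif(1, 0, 2 * pi))
  phase <- 2 * pi * cumsum(ac$f0 * drift) / sr
  x <- numeric(n)
  for (h in seq_len(ac$n_harmonics)) {
    w <- 10^(ac$spectral_tilt * log2(h) / 20)
    x <- x + w * sin(h * phase + stats::runif(1, 0, 2 * pi))
  }
  env <- abs(sin(pi * ac$burst_rate * t + stats::runif(1, 0, pi)))^1.5 + 0.05
  if (gasp) {
    tremor <- 1 + 0.45 * sin(2 * pi * stats::runif(1, 5, 9) * t +
      stats::runif(1, 0, 2 * pi))
    env <- env * tremor
    onset <- stats::runif(1, 0.05, 0.3) * n / sr
    turb_env <- exp(-pmax(t - onset, 0) / stats::runif(1, 0.3, 0.6)) *
      (t >= onset)
    x <- x * env + stats::rnorm(n) * 0.6 * turb_env
  } else {
    x <- x * env
  }
  x / max(abs(x)) * ac$amplitude
}

# per-kind acoustic draws; consumes the current RNG stream. Durations are
# snore-episode lengths (a clip holds one episode plus context, mirroring
# endpoint-detected 3 s cases cut from a recording).
draw_acoustics <- function(kind) {
  switch(kind,
    normal = snore_acoustics(
      f0 = stats::runif(1, 90, 140), n_harmonics = 12L,
      spectral_tilt = stats::runif(1, -8, -5),
      amplitude = stats::runif(1, 0.4, 0.7),
      burst_rate = stats::runif(1, 0.3, 0.45),
      duration_s = stats::runif(1, 0.9, 1.5)
    ),
    abnormal_faint = snore_acoustics(
      f0 = stats::runif(1, 60, 100), n_harmonics = 8L,
      spectral_tilt = stats::runif(1, -11, -7),
      amplitude = stats::runif(1, 0.05, 0.15),
      burst_rate = stats::runif(1, 0.2, 0.35),
      duration_s = stats::runif(1, 0.8, 1.4)
    ),
    abnormal_gasp = snore_acoustics(
      f0 = stats::runif(1, 100, 180), n_harmonics = 10L,
      spectral_tilt = stats::runif(1, -5, -2),
      amplitude = stats::runif(1, 0.8, 1),
      burst_rate = stats::runif(1, 0.35, 0.55),
      duration_s = stats::runif(1, 0.8, 1.5)
    ),
    stop_input("unknown snore kind: ", kind)
  )
}

# linear fade-in/fade-out taper to avoid placement clicks
edge_taper <- function(m, sr, ramp_s = 0.02) {
  ramp <- min(round(ramp_s * sr), floor(m / 2))
  c(seq(0, 1, length.out = ramp), rep(1, m - 2 * ramp),
    seq(1, 0, length.out = ramp))
}

#' Generate one labeled 3 s snore clip
#'
#' A clip emulates one endpoint-detected case cut from a recording: a
#' single snore episode (roughly 0.8--1.5 s) near the clip center,
#' surrounded by background-noise context at `noise_rms` (drawn from
#' `U(0.004, 0.015)` when `NULL`). Three kinds mirror the phenomenology
#' of apnea-related snoring: `"normal"` snores (moderate level, f0
#' 90--140 Hz), `"abnormal_faint"` in-apnea snores (amplitude
#' 0.05--0.15, lower f0) and `"abnormal_gasp"` post-apnea gasps (level
#' at least 0.8, irregular harmonics plus a broadband turbulence burst).
#' Deterministic for a fixed seed.
#'
#' @param kind `"normal"`, `"abnormal_faint"` or `"abnormal_gasp"`.
#' @param acoustics Optional [snore_acoustics()]; drawn per kind when
#'   `NULL`.
#' @param seed Integer seed fixing the clip exactly.
#' @param noise_rms Background-noise RMS, or `NULL` to draw it.
#' @param sample_rate Sampling frequency in Hz.
#' @return A [snore_clip()] of exactly 3 s with `label` `"normal"` or
#'   `"abnormal"`.
#' @export
gen_snore_clip <- function(kind = c("normal", "abnormal_faint", "abnormal_gasp"),
                           acoustics = NULL, seed = 1L, noise_rms = NULL,
                           sample_rate = SNORE_SR) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (is.null(acoustics)) acoustics <- draw_acoustics(kind)
  stopifnot(inherits(acoustics, "snore_acoustics"))
  n <- round(CLIP_LEN_S * sample_rate)
  if (is.null(noise_rms)) noise_rms <- stats::runif(1, 0.004, 0.015)
  x <- stats::rnorm(n) * noise_rms
  dur <- min(acoustics$duration_s, CLIP_LEN_S)
  m <- round(dur * sample_rate)
  wave <- synth_snore_wave(m, sample_rate, acoustics,
    gasp = kind == "abnormal_gasp"
  )
  # episode near the clip center, jittered as peak-centering would leave it
  jitter <- if (m < n) stats::runif(1, -0.3, 0.3) * sample_rate else 0
  i0 <- max(1, min(n - m + 1, round((n - m) / 2 + jitter) + 1))
  idx <- i0:(i0 + m - 1)
  x[idx] <- x[idx] + wave * edge_taper(m, sample_rate)
  x <- pmin(pmax(x, -1), 1)
  label <- if (kind == "normal") "normal" else "abnormal"
  snore_clip(audio_signal(x, sample_rate), label = label)
}

#' Generate a balanced labeled clip dataset
#'
#' `n_per_class` normal clips and `n_per_class` abnormal clips (an even
#' alternation of faint and gasp kinds). Per-clip seeds are derived from
#' the master seed, so the whole dataset is a pure function of
#' `(n_per_class, seed)`.
#'
#' @param n_per_class Clips per class (>= 1).
#' @param seed Master seed.
#' @return List with `clips` (list of [snore_clip()]), `labels`
#'   (character vector) and `manifest` (tibble with `index`, `label`,
#'   `kind`, `seed`).
#' @export
gen_clip_dataset <- function(n_per_class, seed = 1L) {
  if (n_per_class < 1) stop_input("`n_per_class` must be >= 1")
  kinds <- c(
    rep("normal", n_per_class),
    rep(c("abnormal_faint", "abnormal_gasp"), length.out = n_per_class)
  )
  seeds <- (as.integer(seed) + 7919L * seq_along(kinds)) %% 2147483647L
  clips <- mapply(
    function(k, s) gen_snore_clip(k, seed = s),
    kinds, seeds,
    SIMPLIFY = FALSE, USE.NAMES = FALSE
  )
  labels <- vapply(clips, function(cl) cl$label, character(1))
  list(
    clips = clips, labels = labels,
    manifest = tibble::tibble(
      index = seq_along(kinds), label = labels, kind = kinds, seed = seeds
    )
  )
}

#' Specification of a synthetic overnight session
#'
#' @param hours Session duration in hours.
#' @param events_per_hour Target apnea-event rate (the true AHI scale).
#' @param noise_level Background-noise RMS.
#' @param seed Seed fixing the entire session.
#' @param normal_snore_rate Normal snores per minute outside apnea
#'   events.
#' @return A `session_spec` object.
#' @export
session_spec <- function(hours = 1, events_per_hour = 20, noise_level = 0.005,
                         seed = 1L, normal_snore_rate = 6) {
  if (hours <= 0) stop_input("`hours` must be positive")
  if (events_per_hour < 0) stop_input("`events_per_hour` must be >= 0")
  # each event occupies ~10 s plus a 30 s enforced gap
  if (events_per_hour * 45 > 3600) {
    stop_input("`events_per_hour` too dense for non-overlapping 10 s events")
  }
  structure(
    list(
      hours = hours, events_per_hour = events_per_hour,
      noise_level = noise_level, seed = as.integer(seed),
      normal_snore_rate = normal_snore_rate
    ),
    class = "session_spec"
  )
}

#' Generate a synthetic overnight session with planted apnea events
#'
#' Background noise at `noise_level` RMS; apnea events arrive with
#' exponential inter-arrival times at `events_per_hour` (subject to a
#' 30 s minimum gap so events never overlap). Each event is a roughly
#' 10 s interval that silences normal snoring and contains one faint
#' abnormal snore near its center, followed by one gasp snore just after
#' its end -- two abnormal snores per event, matching the AHI
#' bookkeeping of [compute_ahi()]. Normal snores are placed at
#' `normal_snore_rate` per minute outside events. All planted snores are
#' returned as exact annotations.
#'
#' @param spec A [session_spec()].
#' @param sample_rate Sampling frequency in Hz.
#' @return List with `audio` (an [audio_signal()]), `annotations`
#'   (tibble: `start_s`, `end_s`, `label`, `kind`), `events` (tibble of
#'   apnea-event intervals), `true_ahi` (planted events per hour) and
#'   `n_events`.
#' @export
gen_session <- function(spec = session_spec(), sample_rate = SNORE_SR) {
  stopifnot(inherits(spec, "session_spec"))
  set.seed(spec$seed)
  total_s <- spec$hours * 3600
  n <- round(total_s * sample_rate)
  x <- stats::rnorm(n) * spec$noise_level
  min_gap <- 30

  # ---- apnea events ----
  ev_start <- numeric(0)
  ev_end <- numeric(0)
  if (spec$events_per_hour > 0) {
    rate <- spec$events_per_hour / 3600
    t <- stats::runif(1, 5, 30)
    while (TRUE) {
      dur <- stats::runif(1, 8, 12)
      if (t + dur + 8 > total_s) break
      ev_start <- c(ev_start, t)
      ev_end <- c(ev_end, t + dur)
      t <- t + dur + max(min_gap, stats::rexp(1, rate))
    }
  }
  n_events <- length(ev_start)

  ann_start <- numeric(0)
  ann_end <- numeric(0)
  ann_kind <- character(0)
  place <- function(t0, dur, kind) {
    ac <- draw_acoustics(kind)
    ac$duration_s <- dur
    m <- round(dur * sample_rate)
    i0 <- round(t0 * sample_rate) + 1
    if (i0 + m - 1 > n) return(FALSE)
    wave <- synth_snore_wave(m, sample_rate, ac, gasp = kind == "abnormal_gasp")
    x[i0:(i0 + m - 1)] <<- x[i0:(i0 + m - 1)] + wave * edge_taper(m, sample_rate)
    ann_start <<- c(ann_start, t0)
    ann_end <<- c(ann_end, t0 + dur)
    ann_kind <<- c(ann_kind, kind)
    TRUE
  }

  for (i in seq_len(n_events)) {
    mid <- (ev_start[i] + ev_end[i]) / 2
    dur_f <- stats::runif(1, 0.8, 1.4)
    place(mid - dur_f / 2, dur_f, "abnormal_faint")
    gasp_t <- ev_end[i] + stats::runif(1, 0.2, 0.6)
    place(gasp_t, stats::runif(1, 0.8, 1.5), "abnormal_gasp")
  }

  # ---- normal snores outside (padded) event windows ----
  if (spec$normal_snore_rate > 0) {
    pad_lo <- ev_start - 3
    pad_hi <- ev_end + 4 # covers the trailing gasp
    period <- 60 / spec$normal_snore_rate
    t <- stats::runif(1, 1, period)
    while (t + 2 < total_s) {
      dur <- stats::runif(1, 0.9, 1.5)
      blocked <- n_events > 0 && any(t < pad_hi & (t + dur) > pad_lo)
      if (!blocked) place(t, dur, "normal")
      t <- t + period * stats::runif(1, 0.7, 1.3)
    }
  }

  x <- pmin(pmax(x, -1), 1)
  ord <- order(ann_start)
  list(
    audio = audio_signal(x, sample_rate),
    annotations = tibble::tibble(
      start_s = ann_start[ord], end_s = ann_end[ord],
      label = ifelse(ann_kind[ord] == "normal", "normal", "abnormal"),
      kind = ann_kind[ord]
    ),
    events = tibble::tibble(start_s = ev_start, end_s = ev_end),
    true_ahi = n_events / spec$hours,
    n_events = n_events
  )
}
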