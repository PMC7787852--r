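#' Segmentation parameters for endpoint detection
#'
#' Dual-threshold energy/zero-crossing endpoint detection. Energy
#' thresholds are multiplicative relative to the recording's noise floor
#' (the 10th percentile of frame energies). The zero-crossing extension
#' threshold defaults to 300 crossings per 480-sample frame so that the
#' ZCR branch only engages for strongly fricative content above the
#' broadband-noise expectation (about 240 crossings per frame for an
#' uncorrelated noise floor, independent of its level).
#'
#' @param energy_high Seed threshold as a multiple of the noise floor;
#'   frames above it start a candidate event.
#' @param energy_low Extension threshold (multiple of the noise floor);
#'   must satisfy `energy_high >= energy_low > 0`.
#' @param zcr_threshold Crossings per frame above which a frame also
#'   extends an event.
#' @param min_event_s Minimum kept event duration in seconds.
#' @param merge_gap_s Events closer than this many seconds are merged.
#' @param clip_len_s Extracted clip length in seconds (canonical 3 s).
#' @return A `segmentation_params` object.
#' @export
segmentation_params <- function(energy_high = 8, energy_low = 2,
                                zcr_threshold = 300, min_event_s = 0.3,
                                merge_gap_s = 0.2, clip_len_s = CLIP_LEN_S) {
  if (!(energy_high >= energy_low && energy_low > 0)) {
    stop_input("need energy_high >= energy_low > 0")
  }
  if (min_event_s <= 0) stop_input("`min_event_s` must be positive")
  structure(
    list(
      energy_high = energy_high, energy_low = energy_low,
      zcr_threshold = zcr_threshold, min_event_s = min_event_s,
      merge_gap_s = merge_gap_s, clip_len_s = clip_len_s
    ),
    class = "segmentation_params"
  )
}

#' Short-time energy per frame
#'
#' Mean of squared samples within each frame.
#'
#' @param frames A `frame_matrix` from [frame_signal()].
#' @return Numeric vector of non-negative per-frame energies.
#' @export
short_time_energy <- function(frames) {
  rowMeans(unclass(frames)^2)
}

#' Zero-crossing rate per frame
#'
#' Counts sign changes between consecutive samples within each frame;
#' zeros are treated as positive.
#'
#' @param frames A `frame_matrix` from [frame_signal()].
#' @return Integer-valued vector of per-frame crossing counts.
#' @export
zero_crossing_rate <- function(frames) {
  fr <- unclass(frames)
  s <- ifelse(fr >= 0, 1, -1)
  rowSums(s[, -1, drop = FALSE] != s[, -ncol(s), drop = FALSE])
}

# per-frame energy and ZCR over a long signal without materializing the
# frame matrix (cumulative-sum sliding windows)
frame_stats_fast <- function(x, sr, params = frame_params()) {
  flen <- round(params$frame_len_s * sr)
  shift <- round(params$shift_s * sr)
  n_frames <- floor((length(x) - flen) / shift) + 1
  starts <- (seq_len(n_frames) - 1) * shift + 1
  csq <- c(0, cumsum(x^2))
  energy <- (csq[starts + flen] - csq[starts]) / flen
  s <- x >= 0
  flips <- c(0, cumsum(s[-1] != s[-length(s)]))
  zcr <- flips[starts + flen - 1] - flips[starts]
  list(
    energy = energy, zcr = zcr, starts = starts,
    flen = flen, shift = shift, n_frames = n_frames
  )
}

#' Detect acoustic events in a recording
#'
#' Classic dual-threshold endpoint detection: the noise floor is the 10th
#' percentile of short-time frame energies; frames exceeding
#' `energy_high x floor` seed candidate events, which are extended
#' outward over contiguous frames whose energy exceeds
#' `energy_low x floor` or whose zero-crossing count exceeds
#' `zcr_threshold`. Events closer than `merge_gap_s` are merged and
#' events shorter than `min_event_s` discarded. Deterministic; an empty
#' result is valid.
#'
#' @param signal An [audio_signal()] of at least 3 s.
#' @param params A [segmentation_params()].
#' @param fparams A [frame_params()] controlling the analysis framing.
#' @return A tibble with columns `start_s`, `end_s`, sorted and
#'   non-overlapping.
#' @export
detect_events <- function(signal, params = segmentation_params(),
                          fparams = frame_params()) {
  stopifnot(inherits(signal, "audio_signal"))
  if (duration(signal) < params$clip_len_s) {
    stop_input("recording shorter than ", params$clip_len_s, " s")
  }
  st <- frame_stats_fast(signal$samples, signal$sample_rate, fparams)
  floor_e <- max(stats::quantile(st$energy, 0.1, names = FALSE), 1e-12)
  seed <- st$energy > params$energy_high * floor_e
  keep <- (st$energy > params$energy_low * floor_e) |
    (st$zcr > params$zcr_threshold)
  if (!any(seed)) {
    return(tibble::tibble(start_s = numeric(0), end_s = numeric(0)))
  }
  # runs of extendable frames that contain at least one seed frame
  r <- rle(keep)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1
  ok <- r$values & vapply(
    seq_along(r$values),
    function(i) r$values[i] && any(seed[run_start[i]:run_end[i]]),
    logical(1)
  )
  sr <- signal$sample_rate
  starts_s <- (st$starts[run_start[ok]] - 1) / sr
  ends_s <- (st$starts[run_end[ok]] - 1 + st$flen) / sr
  # merge events separated by less than merge_gap_s
  if (length(starts_s) > 1) {
    merged_s <- starts_s[1]
    merged_e <- ends_s[1]
    for (i in 2:length(starts_s)) {
      if (starts_s[i] - merged_e[length(merged_e)] < params$merge_gap_s) {
        merged_e[length(merged_e)] <- ends_s[i]
      } else {
        merged_s <- c(merged_s, starts_s[i])
        merged_e <- c(merged_e, ends_s[i])
      }
    }
    starts_s <- merged_s
    ends_s <- merged_e
  }
  long_enough <- (ends_s - starts_s) >= params$min_event_s
  tibble::tibble(
    start_s = starts_s[long_enough],
    end_s = pmin(ends_s[long_enough], duration(signal))
  )
}

#' A fixed-length snore clip
#'
#' @param audio An [audio_signal()] of exactly `clip_len_s` seconds.
#' @param label Optional class label, `"normal"` or `"abnormal"`.
#' @param source_start_s,source_end_s Optional provenance: the detected
#'   event interval the clip was cut around.
#' @return A `snore_clip` object.
#' @export
snore_clip <- function(audio, label = NA_character_,
                       source_start_s = NA_real_, source_end_s = NA_real_) {
  stopifnot(inherits(audio, "audio_signal"))
  structure(
    list(
      audio = audio, label = label,
      source_start_s = source_start_s, source_end_s = source_end_s
    ),
    class = "snore_clip"
  )
}

#' @export
print.snore_clip <- function(x, ...) {
  cat(sprintf(
    "<snore_clip: %.1f s @ %g Hz, label=%s, source=[%.2f, %.2f] s>\n",
    duration(x$audio), x$audio$sample_rate,
    ifelse(is.na(x$label), "?", x$label), x$source_start_s, x$source_end_s
  ))
  invisible(x)
}

#' Cut fixed-length clips around detected events
#'
#' For each event a window of `clip_len_s` seconds is centered on the
#' event's peak-energy frame, shifted inward at the recording edges so
#' that every clip is padded with real recording context (never zeros)
#' and has exactly `clip_len_s * sample_rate` samples.
#'
#' @param signal The source [audio_signal()].
#' @param events A tibble of events from [detect_events()] (columns
#'   `start_s`, `end_s`).
#' @param clip_len_s Clip length in seconds.
#' @param fparams A [frame_params()] used to locate the peak-energy frame.
#' @return A list of [snore_clip()] objects, one per event.
#' @export
extract_clips <- function(signal, events, clip_len_s = CLIP_LEN_S,
                          fparams = frame_params()) {
  stopifnot(inherits(signal, "audio_signal"))
  sr <- signal$sample_rate
  n <- length(signal$samples)
  clip_n <- round(clip_len_s * sr)
  if (n < clip_n) stop_input("recording shorter than one clip")
  flen <- round(fparams$frame_len_s * sr)
  shift <- round(fparams$shift_s * sr)
  csq <- c(0, cumsum(signal$samples^2))
  out <- vector("list", nrow(events))
  for (i in seq_len(nrow(events))) {
    a <- max(1, floor(events$start_s[i] * sr) + 1)
    b <- min(n, ceiling(events$end_s[i] * sr))
    # peak-energy frame within the event
    fr_starts <- seq(a, max(a, b - flen + 1), by = shift)
    fr_e <- (csq[pmin(fr_starts + flen, n + 1)] - csq[fr_starts])
    peak_center <- fr_starts[which.max(fr_e)] + flen %/% 2
    start <- peak_center - clip_n %/% 2
    start <- min(max(start, 1), n - clip_n + 1)
    clip <- signal$samples[start:(start + clip_n - 1)]
    out[[i]] <- snore_clip(
      audio_signal(clip, sr),
      source_start_s = events$start_s[i], source_end_s = events$end_s[i]
    )
  }
  out
}

#' Read and write event annotations
#'
#' Tab-separated annotation files with columns `start_s`, `end_s`,
#' `label`, compatible with common audio-annotation tooling.
#'
#' @param events A tibble with columns `start_s`, `end_s` and optionally
#'   `label`.
#' @param path File path.
#' @return `write_annotations()` returns `path` invisibly;
#'   `read_annotations()` returns a tibble.
#' @export
write_annotations <- function(events, path) {
  df <- as.data.frame(events)
  if (is.null(df$label)) df$label <- NA_character_
  utils::write.table(df[, c("start_s", "end_s", "label")], path,
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  tibble::as_tibble(utils::read.table(path,
    header = TRUE, sep = "\t",
    colClasses = c("numeric", "numeric", "character")
  ))
}
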