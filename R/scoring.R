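#' Confusion counts
#'
#' Container for the four cells of a binary confusion matrix. By the
#' evaluation convention used throughout the package, TP counts positive
#' samples identified as positive, FN positives missed, TN negatives
#' identified as negative and FP negatives called positive.
#'
#' @param tp,fn,tn,fp Non-negative integer counts.
#' @return A `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fn, tn, fp) {
  v <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(v < 0) || any(v != round(v))) {
    stop_input("counts must be non-negative integers")
  }
  structure(as.list(v), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf(
    "<confusion_counts: TP=%d FN=%d TN=%d FP=%d>\n",
    x$tp, x$fn, x$tn, x$fp
  ))
  invisible(x)
}

#' Count confusion cells from label vectors
#'
#' @param truth,predicted Character vectors of class labels.
#' @param positive The label treated as the positive class.
#' @return A [confusion_counts()] object.
#' @export
count_confusion <- function(truth, predicted, positive = "normal") {
  stopifnot(length(truth) == length(predicted))
  tpos <- truth == positive
  ppos <- predicted == positive
  confusion_counts(
    tp = sum(tpos & ppos), fn = sum(tpos & !ppos),
    tn = sum(!tpos & !ppos), fp = sum(!tpos & ppos)
  )
}

#' Classification metrics from confusion counts
#'
#' accuracy = (TP+TN)/(TP+TN+FP+FN); precision = TP/(TP+FP);
#' sensitivity = recall = TP/(TP+FN); specificity = TN/(TN+FP);
#' F1 = 2 * precision * recall / (precision + recall). A metric whose
#' denominator is zero is undefined and reported as `NA` rather than 0,
#' so that averages are never silently inflated.
#'
#' @param counts A [confusion_counts()] object.
#' @return A one-row tibble with columns `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f1`.
#' @export
compute_metrics <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  tp <- counts$tp; fn <- counts$fn; tn <- counts$tn; fp <- counts$fp
  total <- tp + fn + tn + fp
  if (total == 0) stop_input("all counts are zero")
  safe_div <- function(num, den) if (den > 0) num / den else NA_real_
  precision <- safe_div(tp, tp + fp)
  sensitivity <- safe_div(tp, tp + fn)
  f1 <- if (!is.na(precision) && !is.na(sensitivity) &&
    precision + sensitivity > 0) {
    2 * precision * sensitivity / (precision + sensitivity)
  } else {
    NA_real_
  }
  tibble::tibble(
    accuracy = (tp + tn) / total,
    precision = precision,
    sensitivity = sensitivity,
    specificity = safe_div(tn, tn + fp),
    f1 = f1
  )
}

#' Apnea-hypopnea index from an abnormal-snore count
#'
#' `AHI = (AB / snores_per_event) / SH`: each apnea event contributes a
#' fixed number of apnea-related snores (by default 2 -- one faint snore
#' during the event and one gasp after it), so the abnormal-snore count
#' AB divided by that constant estimates the number of events, and
#' dividing by the sleep duration SH in hours gives events per hour.
#'
#' @param ab_count Number of abnormal (apnea-related) snores detected.
#' @param sleep_hours Sleep duration in hours (positive).
#' @param snores_per_event Abnormal snores per apnea event (default 2).
#' @return AHI in events per hour.
#' @export
compute_ahi <- function(ab_count, sleep_hours, snores_per_event = 2) {
  if (any(sleep_hours <= 0)) stop_input("`sleep_hours` must be positive")
  if (any(ab_count < 0)) stop_input("`ab_count` must be non-negative")
  (ab_count / snores_per_event) / sleep_hours
}

#' OSAHS severity grade from AHI
#'
#' Standard clinical bands: AHI <= 5 normal (degree 0);
#' 5 < AHI <= 15 slight (1); 15 < AHI <= 30 moderate (2);
#' AHI > 30 serious (3).
#'
#' @param ahi Numeric vector of AHI values (events/hour, non-negative).
#' @return A tibble with columns `ahi`, `degree` (integer 0--3) and
#'   `degree_name`.
#' @export
grade_severity <- function(ahi) {
  if (any(ahi < 0)) stop_input("`ahi` must be non-negative")
  degree <- ifelse(ahi > 30, 3L, ifelse(ahi > 15, 2L, ifelse(ahi > 5, 1L, 0L)))
  tibble::tibble(
    ahi = ahi, degree = degree,
    degree_name = c("normal", "slight", "moderate", "serious")[degree + 1L]
  )
}

#' Discrepancy between reference and estimated AHI
#'
#' Reports the quarter-scaled absolute difference
#' `|ahi_ref - ahi_est| / 4` -- the scoring rule that reproduces every
#' printed discrepancy cell of the source protocol's subject table --
#' together with the plain absolute difference. The scaled form is a
#' reverse-engineered convention, not a standard statistic; prefer
#' `abs_diff` for interpretation.
#'
#' @param ahi_ref,ahi_est Non-negative AHI values (events/hour).
#' @return A tibble with columns `sqrt_ahi` (the scaled score) and
#'   `abs_diff`.
#' @export
ahi_discrepancy <- function(ahi_ref, ahi_est) {
  if (any(ahi_ref < 0) || any(ahi_est < 0)) {
    stop_input("AHI values must be non-negative")
  }
  d <- abs(ahi_ref - ahi_est)
  tibble::tibble(sqrt_ahi = d / 4, abs_diff = d)
}

#' Oracle classifier from ground-truth annotations
#'
#' A reference "classifier" that labels a detected clip by overlap with
#' planted ground-truth annotations instead of running a model. Used to
#' isolate the AHI bookkeeping of the screening pipeline from model
#' error: screening a generated session with the oracle returns the
#' generator's true AHI exactly when detection is perfect.
#'
#' @param annotations A tibble with columns `start_s`, `end_s`, `label`
#'   (e.g. from [gen_session()]).
#' @return An `oracle_classifier` object accepted by
#'   [screen_recording()].
#' @export
oracle_classifier <- function(annotations) {
  stopifnot(all(c("start_s", "end_s", "label") %in% names(annotations)))
  structure(list(annotations = annotations), class = "oracle_classifier")
}

oracle_labels <- function(oracle, events) {
  ab <- oracle$annotations[oracle$annotations$label == "abnormal", ]
  mid <- (ab$start_s + ab$end_s) / 2
  vapply(seq_len(nrow(events)), function(i) {
    hit <- any(mid >= events$start_s[i] & mid <= events$end_s[i])
    if (hit) "abnormal" else "normal"
  }, character(1))
}

#' Screen a whole-night recording for OSAHS
#'
#' Full pipeline: detect snore events by endpoint detection, cut 3 s
#' clips around each, extract the model's feature kind, classify every
#' clip, count the abnormal-labeled clips (AB), convert to
#' `AHI = (AB/2)/SH` and grade severity. Per-clip decisions are kept in
#' the report for audit.
#'
#' @param audio An [audio_signal()] of at least 3 s.
#' @param model A fitted `snore_model`, or an [oracle_classifier()].
#' @param feature_kind Feature kind for classification; defaults to the
#'   kind the model was trained on.
#' @param sleep_hours Sleep duration SH in hours; defaults to the
#'   recording duration.
#' @param seg_params A [segmentation_params()].
#' @param fparams A [frame_params()].
#' @param config A [feature_config()].
#' @return A `screening_report`: list with `ab_count`, `sleep_hours`,
#'   `ahi`, `degree`, `degree_name`, `n_events` and a `decisions` tibble
#'   (one row per detected clip).
#' @export
screen_recording <- function(audio, model, feature_kind = NULL,
                             sleep_hours = NULL,
                             seg_params = segmentation_params(),
                             fparams = frame_params(),
                             config = feature_config()) {
  stopifnot(inherits(audio, "audio_signal"))
  if (is.null(sleep_hours)) sleep_hours <- duration(audio) / 3600
  is_oracle <- inherits(model, "oracle_classifier")
  if (is.null(feature_kind)) {
    feature_kind <- if (is_oracle) "mfcc" else model$feature_kind
  }
  if (!is_oracle && !is.na(model$feature_kind) &&
    !identical(feature_kind, model$feature_kind)) {
    stop_input(
      "model was trained on ", model$feature_kind,
      " features, not ", feature_kind
    )
  }
  events <- detect_events(audio, seg_params, fparams)
  if (nrow(events) == 0) {
    decisions <- tibble::tibble(
      start_s = numeric(0), end_s = numeric(0), clip_start_s = numeric(0),
      label = character(0), prob_abnormal = numeric(0)
    )
  } else {
    clips <- extract_clips(audio, events, seg_params$clip_len_s, fparams)
    if (is_oracle) {
      labels <- oracle_labels(model, events)
      probs <- as.numeric(labels == "abnormal")
    } else {
      feats <- lapply(clips, function(cl) {
        extract_features(cl$audio, feature_kind, fparams, config)
      })
      pred <- predict(model, feats)
      labels <- pred$label
      probs <- pred$prob_abnormal
    }
    decisions <- tibble::tibble(
      start_s = events$start_s, end_s = events$end_s,
      clip_start_s = vapply(clips, function(cl) cl$source_start_s, numeric(1)),
      label = labels, prob_abnormal = probs
    )
  }
  ab <- sum(decisions$label == "abnormal")
  ahi <- compute_ahi(ab, sleep_hours)
  grade <- grade_severity(ahi)
  structure(
    list(
      ab_count = ab, sleep_hours = sleep_hours, ahi = ahi,
      degree = grade$degree, degree_name = grade$degree_name,
      n_events = nrow(events), feature_kind = feature_kind,
      decisions = decisions
    ),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("OSAHS screening report\n")
  cat(sprintf("  sleep duration : %.2f h\n", x$sleep_hours))
  cat(sprintf("  snore events   : %d detected\n", x$n_events))
  cat(sprintf("  abnormal (AB)  : %d\n", x$ab_count))
  cat(sprintf("  AHI            : %.2f events/hour\n", x$ahi))
  cat(sprintf("  severity       : degree %d (%s)\n", x$degree, x$degree_name))
  invisible(x)
}

#' Write a screening report to disk
#'
#' Writes a human-readable summary (`<stem>.txt`), a machine-readable
#' key-value file (`<stem>.tsv`) and the per-clip decisions as an
#' annotation file (`<stem>_decisions.tsv`).
#'
#' @param report A `screening_report`.
#' @param stem Output path stem (without extension).
#' @return The stem, invisibly.
#' @export
write_report <- function(report, stem) {
  txt <- file.path(paste0(stem, ".txt"))
  con <- file(txt, "w")
  sink(con)
  print(report)
  sink()
  close(con)
  kv <- data.frame(
    key = c("ab_count", "sleep_hours", "ahi", "degree", "degree_name"),
    value = c(
      report$ab_count, report$sleep_hours, report$ahi,
      report$degree, report$degree_name
    )
  )
  utils::write.table(kv, paste0(stem, ".tsv"),
    sep = "\t", row.names = FALSE, quote = FALSE
  )
  dec <- report$decisions
  dec$label <- as.character(dec$label)
  write_annotations(dec, paste0(stem, "_decisions.tsv"))
  invisible(stem)
}
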