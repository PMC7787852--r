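# Published per-subject screening table used as a fixed reference:
# AHI from polysomnography, AHI from the audio test, the printed
# quarter-scaled discrepancy, and both severity-degree columns.
subject_table <- data.frame(
  ahi_psg = c(5, 4.7, 1.7, 2.8, 1.5, 41.9, 25.3, 7.2, 31.7, 8.6),
  ahi_test = c(2, 0.37, 6, 1.7, 1.7, 50.3, 28.1, 8, 31.4, 41),
  sqrt_ahi = c(0.75, 1.08, 1.07, 0.28, 0.05, 2.1, 0.7, 0.2, 0.075, 8.1),
  degree_psg = c(0, 0, 0, 0, 0, 3, 2, 1, 3, 1),
  degree_test = c(0, 0, 1, 0, 0, 3, 2, 1, 3, 3)
)

test_that("metrics match hand-computed confusion examples", {
  m <- compute_metrics(confusion_counts(25, 25, 25, 25))
  expect_equal(as.numeric(m), rep(0.5, 5))

  perfect <- compute_metrics(confusion_counts(10, 0, 15, 0))
  expect_equal(as.numeric(perfect), rep(1, 5))

  m2 <- compute_metrics(confusion_counts(tp = 40, fn = 10, tn = 45, fp = 5))
  expect_equal(m2$accuracy, 0.85)
  expect_equal(m2$precision, 8 / 9)
  expect_equal(m2$sensitivity, 0.8)
  expect_equal(m2$specificity, 0.9)
  expect_equal(m2$f1, 2 * (8 / 9) * 0.8 / (8 / 9 + 0.8), tolerance = 1e-12)

  expect_error(compute_metrics(confusion_counts(0, 0, 0, 0)), "zero")
  expect_error(confusion_counts(-1, 0, 0, 0), "non-negative")

  # undefined denominators surface as NA, never 0
  no_pred_pos <- compute_metrics(confusion_counts(0, 5, 10, 0))
  expect_true(is.na(no_pred_pos$precision))
  expect_identical(no_pred_pos$sensitivity, 0)
})

test_that("metrics agree with an independent tabulation on random counts", {
  set.seed(61)
  for (i in 1:1000) {
    v <- stats::rpois(4, 12) + c(1, 0, 1, 0) # keep totals positive
    got <- compute_metrics(confusion_counts(v[1], v[2], v[3], v[4]))
    ref <- ref_metrics(v[1], v[2], v[3], v[4])
    for (nm in names(got)) {
      if (is.na(ref[[nm]])) {
        expect_true(is.na(got[[nm]]))
      } else {
        expect_equal(got[[nm]], unname(ref[[nm]]), tolerance = 1e-12)
      }
    }
  }
})

test_that("count_confusion tallies label vectors", {
  truth <- c("normal", "normal", "abnormal", "abnormal", "normal")
  pred <- c("normal", "abnormal", "abnormal", "normal", "normal")
  cts <- count_confusion(truth, pred, positive = "normal")
  expect_identical(cts$tp, 2L)
  expect_identical(cts$fn, 1L)
  expect_identical(cts$tn, 1L)
  expect_identical(cts$fp, 1L)
})

test_that("AHI follows the two-snores-per-event bookkeeping", {
  expect_identical(compute_ahi(0, 8), 0)
  expect_identical(compute_ahi(16, 8), 1)
  expect_identical(compute_ahi(480, 8), 30)
  expect_error(compute_ahi(10, 0), "sleep_hours")
  expect_error(compute_ahi(-1, 8), "ab_count")
  # linear in the count, inversely proportional to duration
  set.seed(62)
  for (i in 1:50) {
    ab <- sample(0:500, 1)
    sh <- runif(1, 1, 12)
    k <- sample(2:5, 1)
    expect_equal(compute_ahi(k * ab, sh), k * compute_ahi(ab, sh))
    expect_equal(compute_ahi(ab, k * sh), compute_ahi(ab, sh) / k)
  }
})

test_that("severity grading matches the clinical bands and both table columns", {
  expect_identical(grade_severity(5)$degree, 0L)
  expect_identical(grade_severity(0)$degree, 0L)
  expect_identical(grade_severity(6)$degree, 1L)
  expect_identical(grade_severity(15)$degree, 1L)
  expect_identical(grade_severity(28.1)$degree, 2L)
  expect_identical(grade_severity(30)$degree, 2L)
  expect_identical(grade_severity(50.3)$degree, 3L)
  expect_error(grade_severity(-1), "non-negative")

  expect_identical(
    grade_severity(subject_table$ahi_psg)$degree,
    as.integer(subject_table$degree_psg)
  )
  expect_identical(
    grade_severity(subject_table$ahi_test)$degree,
    as.integer(subject_table$degree_test)
  )
})

test_that("the quarter-scaled discrepancy reproduces all printed values", {
  d <- ahi_discrepancy(subject_table$ahi_psg, subject_table$ahi_test)
  expect_true(all(abs(d$sqrt_ahi - subject_table$sqrt_ahi) <= 0.00501))
  expect_equal(d$abs_diff, abs(subject_table$ahi_psg - subject_table$ahi_test))
  expect_identical(ahi_discrepancy(7.3, 7.3)$sqrt_ahi, 0)
  expect_error(ahi_discrepancy(-1, 2), "non-negative")
})

test_that("screening silence yields an all-clear report", {
  set.seed(63)
  quiet <- audio_signal(rnorm(16000 * 60) * 0.003, 16000)
  rep <- screen_recording(quiet, oracle_classifier(
    tibble::tibble(start_s = numeric(0), end_s = numeric(0), label = character(0))
  ), sleep_hours = 1)
  expect_identical(rep$ab_count, 0L)
  expect_identical(rep$ahi, 0)
  expect_identical(rep$degree, 0L)
  expect_identical(rep$degree_name, "normal")
})

test_that("report severity is always consistent with its AHI", {
  ses <- gen_session(session_spec(hours = 0.2, events_per_hour = 25, seed = 64))
  rep <- screen_recording(ses$audio, oracle_classifier(ses$annotations))
  expect_identical(rep$degree, grade_severity(rep$ahi)$degree)
  expect_identical(rep$ab_count, sum(rep$decisions$label == "abnormal"))
  g <- glance(rep)
  expect_identical(g$ahi, rep$ahi)
  expect_identical(nrow(tidy(rep)), rep$n_events)
})

test_that("screening reports serialize to text files", {
  ses <- gen_session(session_spec(hours = 0.1, events_per_hour = 20, seed = 65))
  rep <- screen_recording(ses$audio, oracle_classifier(ses$annotations))
  stem <- file.path(withr::local_tempdir(), "report")
  write_report(rep, stem)
  expect_true(file.exists(paste0(stem, ".txt")))
  kv <- utils::read.table(paste0(stem, ".tsv"), header = TRUE, sep = "\t")
  expect_equal(as.numeric(kv$value[kv$key == "ahi"]), rep$ahi)
  dec <- read_annotations(paste0(stem, "_decisions.tsv"))
  expect_identical(nrow(dec), nrow(rep$decisions))
})
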