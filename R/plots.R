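#' Tidy and glance methods
#'
#' `tidy()` on a fitted model returns its per-epoch training history;
#' `glance()` returns a one-row summary. On a screening report, `tidy()`
#' returns the per-clip decisions and `glance()` the one-row screening
#' summary.
#'
#' @param x A `snore_model` or `screening_report`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy snore_model
#' @export
tidy.snore_model <- function(x, ...) {
  x$history
}

#' @rdname tidy.snore_model
#' @method glance snore_model
#' @export
glance.snore_model <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  n_par <- sum(vapply(x$params, length, integer(1)))
  tibble::tibble(
    architecture = x$config$architecture,
    feature_kind = x$feature_kind,
    epochs = nrow(x$history),
    n_parameters = n_par,
    train_loss = h$loss, train_accuracy = h$accuracy,
    val_loss = h$val_loss, val_accuracy = h$val_accuracy
  )
}

#' @rdname tidy.snore_model
#' @method tidy screening_report
#' @export
tidy.screening_report <- function(x, ...) {
  x$decisions
}

#' @rdname tidy.snore_model
#' @method glance screening_report
#' @export
glance.screening_report <- function(x, ...) {
  tibble::tibble(
    ab_count = x$ab_count, sleep_hours = x$sleep_hours,
    ahi = x$ahi, degree = x$degree, degree_name = x$degree_name,
    n_events = x$n_events
  )
}

#' Plot a feature matrix as a heat map
#'
#' @param object A `snore_features` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snore_features
#' @export
autoplot.snore_features <- function(object, ...) {
  fp <- attr(object, "frame_params")
  df <- expand.grid(
    frame = seq_len(nrow(object)), coefficient = seq_len(ncol(object))
  )
  df$value <- as.numeric(object)
  df$time_s <- (df$frame - 1) * fp$shift_s
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_s, y = .data$coefficient, fill = .data$value
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(
      x = "time (s)", y = "coefficient",
      title = paste(toupper(attr(object, "feature_kind")), "features"),
      fill = NULL
    )
}

#' Plot training history
#'
#' Loss and accuracy per epoch for the training split and, when a
#' validation split was held out, the validation split.
#'
#' @param object A fitted `snore_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot snore_model
#' @export
autoplot.snore_model <- function(object, ...) {
  h <- object$history
  long <- rbind(
    data.frame(epoch = h$epoch, metric = "loss", split = "train", value = h$loss),
    data.frame(
      epoch = h$epoch, metric = "accuracy", split = "train",
      value = h$accuracy
    ),
    data.frame(
      epoch = h$epoch, metric = "loss", split = "validation",
      value = h$val_loss
    ),
    data.frame(
      epoch = h$epoch, metric = "accuracy", split = "validation",
      value = h$val_accuracy
    )
  )
  long <- long[!is.na(long$value), ]
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$epoch, y = .data$value, colour = .data$split
  )) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL)
}

#' Plot a screening timeline
#'
#' Detected clips along the night, colored by the classifier's decision,
#' with the report's AHI and severity in the title.
#'
#' @param object A `screening_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot screening_report
#' @export
autoplot.screening_report <- function(object, ...) {
  d <- object$decisions
  ggplot2::ggplot(d, ggplot2::aes(
    x = .data$start_s / 3600, y = .data$prob_abnormal, colour = .data$label
  )) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey50") +
    ggplot2::labs(
      x = "time (h)", y = "P(abnormal)",
      title = sprintf(
        "AHI %.1f events/h - degree %d (%s)",
        object$ahi, object$degree, object$degree_name
      ),
      colour = NULL
    ) +
    ggplot2::ylim(0, 1)
}

#' @importFrom rlang .data
NULL
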