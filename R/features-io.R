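#' Save and load feature matrices
#'
#' A simple versioned binary container for a set of feature matrices:
#' a one-line text header (`SNF1 <kind> <n_matrices> <n_frames> <n_coeffs>
#' <frame_len_s> <shift_s>`), one label line, then the matrices as
#' little-endian doubles in column-major order. `write_feature_csv()`
#' exports a single matrix as plain CSV for inspection.
#'
#' @param features List of `snore_features` matrices of equal shape.
#' @param path File path.
#' @param labels Optional character vector of labels (stored as `NA`
#'   when absent).
#' @return `write_features()` returns `path` invisibly;
#'   `read_features()` returns a list with `features` and `labels`.
#' @export
write_features <- function(features, path, labels = NULL) {
  if (is.matrix(features)) features <- list(features)
  stopifnot(length(features) > 0)
  kind <- attr(features[[1]], "feature_kind") %||% "unknown"
  fp <- attr(features[[1]], "frame_params") %||% frame_params()
  dims <- dim(features[[1]])
  if (is.null(labels)) labels <- rep(NA_character_, length(features))
  stopifnot(length(labels) == length(features))
  con <- file(path, "wb")
  on.exit(close(con))
  header <- sprintf(
    "SNF1 %s %d %d %d %g %g\n", kind, length(features),
    dims[1], dims[2], fp$frame_len_s, fp$shift_s
  )
  writeChar(header, con, eos = NULL)
  writeChar(paste0(paste(labels, collapse = ","), "\n"), con, eos = NULL)
  for (f in features) {
    stopifnot(all(dim(f) == dims))
    writeBin(as.numeric(f), con, size = 8, endian = "little")
  }
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readLines(con, 1)
  parts <- strsplit(header, " ")[[1]]
  if (parts[1] != "SNF1") stop_input("not a feature archive: ", path)
  kind <- parts[2]
  n_mat <- as.integer(parts[3])
  n_frames <- as.integer(parts[4])
  n_coeffs <- as.integer(parts[5])
  fp <- frame_params(
    frame_len_s = as.numeric(parts[6]),
    shift_s = as.numeric(parts[7])
  )
  labels <- strsplit(readLines(con, 1), ",")[[1]]
  labels[labels == "NA"] <- NA_character_
  features <- vector("list", n_mat)
  for (i in seq_len(n_mat)) {
    vals <- readBin(con, "double", n_frames * n_coeffs, size = 8, endian = "little")
    features[[i]] <- new_feature_matrix(
      matrix(vals, n_frames, n_coeffs), kind, fp
    )
  }
  list(features = features, labels = labels)
}

#' @rdname write_features
#' @param feature A single feature matrix.
#' @export
write_feature_csv <- function(feature, path) {
  utils::write.table(unclass(feature), path,
    sep = ",", row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}
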