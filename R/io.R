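#' Construct a landmark sequence
#'
#' A landmark sequence is the raw input of the pipeline: a time-ordered
#' series of frames, each holding 100 facial landmarks (x, y in image
#' pixels; z in depth units), with one binary expression label per frame
#' (1 = expression present, 0 = absent).
#'
#' @param points Numeric array of dimension `c(n_frames, 100, 3)`
#'   (frame x point x coordinate).
#' @param labels Integer/logical vector of per-frame labels, length
#'   `n_frames`, values 0/1.
#' @param subject_id Subject identifier (e.g. 1 or 2).
#' @param expression Expression name (one of [gfe_expressions()], or any
#'   string for ad-hoc data).
#' @param timestamps Optional numeric per-frame timestamps.
#' @return Object of class `landmark_sequence`.
#' @export
landmark_sequence <- function(points, labels, subject_id = NA,
                              expression = NA_character_,
                              timestamps = NULL) {
  if (length(dim(points)) != 3L || dim(points)[2] != 100L || dim(points)[3] != 3L) {
    stopf("`points` must be an array of dimension (n_frames, 100, 3), got (%s)",
          paste(dim(points), collapse = ", "))
  }
  n <- dim(points)[1]
  if (length(labels) != n) {
    stopf("label/frame length mismatch: %d labels for %d frames", length(labels), n)
  }
  labels <- as.integer(labels)
  if (n > 0 && !all(labels %in% c(0L, 1L))) {
    stopf("labels must be binary 0/1")
  }
  if (n > 0 && !all(is.finite(points))) {
    stopf("landmark coordinates must be finite (NA/NaN/Inf found)")
  }
  if (!is.null(timestamps) && length(timestamps) != n) {
    stopf("timestamps length %d does not match %d frames", length(timestamps), n)
  }
  structure(list(points = points, labels = labels,
                 subject_id = subject_id, expression = expression,
                 timestamps = timestamps),
            class = "landmark_sequence")
}

#' @export
print.landmark_sequence <- function(x, ...) {
  cat(sprintf("<landmark_sequence> subject=%s expression=%s: %d frames, %d positive\n",
              as.character(x$subject_id), x$expression,
              length(x$labels), sum(x$labels)))
  invisible(x)
}

#' Number of frames in a landmark sequence
#' @param seq A `landmark_sequence`.
#' @return Integer frame count.
#' @export
n_frames <- function(seq) dim(seq$points)[1]

split_fields <- function(line) {
  out <- strsplit(trimws(line), "[,[:space:]]+")[[1]]
  out[nzchar(out)]
}

#' Read a landmark-stream file pair
#'
#' The data file carries one frame per line: an optional leading timestamp
#' token followed by 300 numeric fields, x/y/z interleaved per point
#' (x0 y0 z0 x1 y1 z1 ...), separated by whitespace and/or commas. The two
#' dialects (300 or 301 fields per line) are auto-detected from the field
#' count; a file must use one dialect consistently. The label file holds
#' one 0/1 token per line, aligned 1:1 with the frames.
#'
#' @param path Data file path.
#' @param label_path Label file path.
#' @param subject_id,expression Metadata attached to the sequence.
#' @return A [landmark_sequence()].
#' @export
read_landmark_file <- function(path, label_path, subject_id = NA,
                               expression = NA_character_) {
  if (!file.exists(path)) stopf("data file not found: %s", path)
  if (!file.exists(label_path)) stopf("label file not found: %s", label_path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  lab_lines <- readLines(label_path)
  lab_lines <- trimws(lab_lines[nzchar(trimws(lab_lines))])
  if (length(lab_lines) != n) {
    stopf("alignment error: %d frames in %s but %d labels in %s",
          n, path, length(lab_lines), label_path)
  }
  if (!all(lab_lines %in% c("0", "1"))) {
    bad <- which(!lab_lines %in% c("0", "1"))[1]
    stopf("label file %s line %d: expected 0 or 1, got '%s'",
          label_path, bad, lab_lines[bad])
  }
  labels <- as.integer(lab_lines)
  points <- array(NA_real_, dim = c(n, 100L, 3L))
  timestamps <- NULL
  has_ts <- NA
  for (i in seq_len(n)) {
    f <- suppressWarnings(as.numeric(split_fields(lines[i])))
    if (anyNA(f)) stopf("parse error in %s line %d: non-numeric field", path, i)
    if (is.na(has_ts)) {
      if (length(f) == 301L) { has_ts <- TRUE; timestamps <- numeric(n) }
      else if (length(f) == 300L) has_ts <- FALSE
      else stopf("parse error in %s line %d: expected 300 or 301 fields, got %d",
                 path, i, length(f))
    }
    expect <- if (has_ts) 301L else 300L
    if (length(f) != expect) {
      stopf("parse error in %s line %d: expected %d fields, got %d",
            path, i, expect, length(f))
    }
    if (has_ts) { timestamps[i] <- f[1]; f <- f[-1] }
    points[i, , ] <- matrix(f, nrow = 100L, ncol = 3L, byrow = TRUE)
  }
  landmark_sequence(points, labels, subject_id = subject_id,
                    expression = expression, timestamps = timestamps)
}

#' Write a landmark-stream file pair
#'
#' Inverse of [read_landmark_file()]: emits one frame per line with 300
#' space-separated numeric fields (x/y/z interleaved per point), preceded
#' by a timestamp field when the sequence carries timestamps, and a
#' parallel label file with one 0/1 per line. Values are written with 15
#' significant digits, so a read/write round trip reproduces coordinates
#' to well below 1e-9.
#'
#' @param seq A [landmark_sequence()]; sequences containing non-finite
#'   coordinates are refused.
#' @param path,label_path Output file paths.
#' @return Invisibly, `c(path, label_path)`.
#' @export
write_landmark_file <- function(seq, path, label_path) {
  stopifnot(inherits(seq, "landmark_sequence"))
  n <- n_frames(seq)
  if (n > 0 && !all(is.finite(seq$points))) {
    stopf("refusing to write sequence with non-finite coordinates")
  }
  lines <- character(n)
  for (i in seq_len(n)) {
    f <- format(as.vector(t(seq$points[i, , ])), digits = 15, trim = TRUE,
                scientific = FALSE)
    if (!is.null(seq$timestamps)) {
      f <- c(format(seq$timestamps[i], digits = 15, trim = TRUE,
                    scientific = FALSE), f)
    }
    lines[i] <- paste(f, collapse = " ")
  }
  writeLines(lines, path)
  writeLines(as.character(seq$labels), label_path)
  invisible(c(path, label_path))
}
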