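#' Label a window from its per-frame labels
#'
#' Policies: `"majority"` — positive when at least half of the frames are
#' positive (ties count as positive); `"last"` — the label of the final
#' frame; `"all"` — positive only when every frame is positive.
#'
#' @param frame_labels 0/1 vector of length `sw`.
#' @param rule Policy name.
#' @return 0 or 1.
#' @export
window_label <- function(frame_labels, rule = c("majority", "last", "all")) {
  if (length(rule) != 1L || !rule %in% c("majority", "last", "all")) {
    stopf("unknown window label rule: %s", paste(rule, collapse = ", "))
  }
  switch(rule,
    majority = as.integer(2L * sum(frame_labels) >= length(frame_labels)),
    last = as.integer(frame_labels[length(frame_labels)]),
    all = as.integer(all(frame_labels == 1L))
  )
}

# Near-equal three-way split lengths of a vector of length n:
# ceiling-first, so e.g. 7 -> (3, 2, 2). When the window size is a
# multiple of 3 this coincides with the frame-aligned thirds.
perspective_lengths <- function(n) {
  n1 <- ceiling(n / 3)
  n2 <- ceiling((n - n1) / 2)
  c(n1, n2, n - n1 - n2)
}

#' Split a flattened window vector into the three perspectives
#'
#' The three "perspectives" are contiguous, ordered, non-overlapping
#' slices of the flattened window feature vector. When the window size is
#' divisible by 3 the slices are exactly the frame-aligned thirds (frames
#' t..t+sw/3-1, the next third, the last third); otherwise the slices are
#' as equal in length as possible (longer slices first), preserving order.
#' Concatenating the parts always reproduces the input.
#'
#' @param flat Numeric vector of length `sw * per_frame_len`.
#' @param sw Window size in frames (optional, used only to validate the
#'   length).
#' @param per_frame_len Features per frame (optional, see `sw`).
#' @return List with vectors `p1`, `p2`, `p3`.
#' @export
split_perspectives <- function(flat, sw = NULL, per_frame_len = NULL) {
  if (!is.null(sw) && !is.null(per_frame_len) &&
      length(flat) != sw * per_frame_len) {
    stopf("split_perspectives: length %d != sw (%d) * per_frame_len (%d)",
          length(flat), sw, per_frame_len)
  }
  n <- perspective_lengths(length(flat))
  list(p1 = flat[seq_len(n[1])],
       p2 = flat[seq_len(n[2]) + n[1]],
       p3 = flat[seq_len(n[3]) + n[1] + n[2]])
}

new_windowed_dataset <- function(x, labels, t, sequence_id, sw, stride,
                                 feature_names) {
  colnames(x) <- feature_names
  n <- perspective_lengths(ncol(x))
  slices <- list(p1 = seq_len(n[1]),
                 p2 = seq_len(n[2]) + n[1],
                 p3 = seq_len(n[3]) + n[1] + n[2])
  structure(list(x = x, labels = as.integer(labels), t = as.integer(t),
                 sequence_id = sequence_id, sw = as.integer(sw),
                 stride = as.integer(stride), slices = slices,
                 feature_names = feature_names),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset> %d windows (sw=%d, stride=%d), %d features (p1/p2/p3 = %d/%d/%d), %d positive\n",
              nrow(x$x), x$sw, x$stride, ncol(x$x),
              length(x$slices$p1), length(x$slices$p2), length(x$slices$p3),
              sum(x$labels)))
  invisible(x)
}

#' Number of windows in a windowed dataset
#' @param ds A `windowed_dataset`.
#' @return Integer sample count.
#' @export
n_windows <- function(ds) nrow(ds$x)

track_frame_matrix <- function(track) {
  M <- cbind(track$distances, track$angles, track$depths)
  if (is.null(colnames(M)) && ncol(M) > 0) {
    colnames(M) <- paste0("v", seq_len(ncol(M)) - 1L)
  }
  M
}

window_starts <- function(sfe, sw, stride) {
  if (sfe <= sw) {
    stopf("sequence of %d frames is too short for window size %d (need sfe > sw)",
          sfe, sw)
  }
  # starts are 0-based; the index set runs to sfe - sw - 1, matching the
  # sliding-window sample count sfe - sw at stride 1 (the final frame is
  # deliberately never the start of a window)
  seq.int(0L, sfe - sw - 1L, by = stride)
}

#' Build sliding-window perspective samples from a feature track
#'
#' Slides a window of `cfg$window_size` frames over the track with stride
#' `cfg$window_stride`. Each window's flattened feature vector is the
#' per-frame concatenation (distances_t, angles_t, depths_t,
#' distances_t+1, ...) in frame order, its label comes from
#' [window_label()] under `cfg$label_rule`, and the vector is split into
#' perspectives p1/p2/p3 (see [split_perspectives()]). At stride 1 a track
#' of `sfe` frames yields exactly `sfe - sw` windows.
#'
#' @param track A `feature_track` from [extract_features()].
#' @param labels Per-frame 0/1 labels; defaults to the labels carried by
#'   the track.
#' @param cfg A [gfe_config()].
#' @param sw Window size override (used by the cross-subject protocol's
#'   per-expression sizes); default `cfg$window_size`.
#' @param stride Stride override; default `cfg$window_stride`.
#' @return A `windowed_dataset`.
#' @export
build_windows <- function(track, labels = track$labels, cfg, sw = NULL,
                          stride = NULL) {
  M <- track_frame_matrix(track)
  sfe <- nrow(M)
  if (length(labels) != sfe) {
    stopf("build_windows: %d labels for %d frames", length(labels), sfe)
  }
  if (is.null(sw)) sw <- cfg$window_size
  if (is.null(stride)) stride <- cfg$window_stride
  starts <- window_starts(sfe, sw, stride)
  pfl <- ncol(M)
  X <- matrix(0, length(starts), sw * pfl)
  wl <- integer(length(starts))
  for (i in seq_along(starts)) {
    t0 <- starts[i]
    X[i, ] <- as.vector(t(M[t0 + seq_len(sw), , drop = FALSE]))
    wl[i] <- window_label(labels[t0 + seq_len(sw)], cfg$label_rule)
  }
  fn <- as.vector(vapply(seq_len(sw) - 1L,
                         function(k) paste0(colnames(M), "_f", k),
                         character(pfl)))
  new_windowed_dataset(X, wl, starts, rep(track$sequence_id, length(starts)),
                       sw, stride, fn)
}

#' Build descriptor windows (doubt-expression variant)
#'
#' Instead of concatenating per-frame features across the window, each
#' per-frame base feature — distances, angles, enclosed areas and
#' principal-axes ratios (depths are not part of this variant) — is
#' summarized over the window by the seven statistical descriptors of
#' [statistical_descriptors()]. The descriptor vector (7 values per base
#' feature, feature-major) is then split into the three perspectives by
#' the same near-equal rule as [split_perspectives()].
#'
#' @inheritParams build_windows
#' @return A `windowed_dataset`.
#' @export
build_descriptor_windows <- function(track, labels = track$labels, cfg,
                                     sw = NULL, stride = NULL) {
  if (is.null(track$areas) || is.null(track$eccentricities)) {
    stopf("descriptor windows need shape features; run extract_features(..., shape = TRUE)")
  }
  B <- cbind(track$distances, track$angles, track$areas, track$eccentricities)
  sfe <- nrow(B)
  if (length(labels) != sfe) {
    stopf("build_descriptor_windows: %d labels for %d frames", length(labels), sfe)
  }
  if (is.null(sw)) sw <- cfg$window_size
  if (is.null(stride)) stride <- cfg$window_stride
  starts <- window_starts(sfe, sw, stride)
  nb <- ncol(B)
  X <- matrix(0, length(starts), nb * 7L)
  wl <- integer(length(starts))
  for (i in seq_along(starts)) {
    rows <- starts[i] + seq_len(sw)
    X[i, ] <- as.vector(vapply(seq_len(nb),
                               function(j) statistical_descriptors(B[rows, j]),
                               numeric(7)))
    wl[i] <- window_label(labels[rows], cfg$label_rule)
  }
  stat_names <- c("mean", "sd", "max", "min", "median", "q25", "q75")
  fn <- as.vector(vapply(colnames(B),
                         function(nm) paste0(nm, "_", stat_names),
                         character(7)))
  new_windowed_dataset(X, wl, starts, rep(track$sequence_id, length(starts)),
                       sw, stride, fn)
}

#' Combine windowed datasets with identical feature layout
#'
#' Used to pool windows from several sequences (e.g. both subjects, or the
#' multiple videos of one expression) into one training set. Windows never
#' cross sequence boundaries; this only stacks already-built windows.
#'
#' @param ds_list List of `windowed_dataset` objects.
#' @return A `windowed_dataset`.
#' @export
combine_windows <- function(ds_list) {
  stopifnot(length(ds_list) >= 1L)
  ref <- ds_list[[1]]
  for (ds in ds_list[-1]) {
    if (!identical(ds$feature_names, ref$feature_names) ||
        ds$sw != ref$sw) {
      stopf("combine_windows: datasets have mismatched feature layouts")
    }
  }
  new_windowed_dataset(do.call(rbind, lapply(ds_list, `[[`, "x")),
                       unlist(lapply(ds_list, `[[`, "labels")),
                       unlist(lapply(ds_list, `[[`, "t")),
                       unlist(lapply(ds_list, `[[`, "sequence_id")),
                       ref$sw, ref$stride, ref$feature_names)
}

subset_windows <- function(ds, idx) {
  new_windowed_dataset(ds$x[idx, , drop = FALSE], ds$labels[idx], ds$t[idx],
                       ds$sequence_id[idx], ds$sw, ds$stride,
                       ds$feature_names)
}

#' Write / read a windowed dataset as delimited text
#'
#' Columns are the perspective-prefixed feature names (`p1_*`, `p2_*`,
#' `p3_*`) followed by `label`, `sequence_id` and `t` (0-based window
#' start), tab-separated with a header row.
#'
#' @param ds A `windowed_dataset`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_windows <- function(ds, path) {
  pfx <- character(ncol(ds$x))
  for (p in names(ds$slices)) pfx[ds$slices[[p]]] <- p
  df <- as.data.frame(ds$x)
  names(df) <- paste0(pfx, "_", ds$feature_names)
  df$label <- ds$labels
  df$sequence_id <- ds$sequence_id
  df$t <- ds$t
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_windows
#' @param sw,stride Window geometry to record on the reconstructed object
#'   (the text format does not carry them).
#' @return For `read_windows`, a `windowed_dataset`.
#' @export
read_windows <- function(path, sw = 10L, stride = 1L) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  meta <- c("label", "sequence_id", "t")
  feat <- setdiff(names(df), meta)
  fn <- sub("^p[123]_", "", feat)
  new_windowed_dataset(as.matrix(df[feat]), df$label, df$t, df$sequence_id,
                       sw, stride, fn)
}
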