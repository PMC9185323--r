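#' Per-frame geometric features for one landmark frame
#'
#' Composes the three per-frame feature families: Euclidean distances over
#' the configured pair list, inter-segment angles over the triple list,
#' and depths of the distinct pair-list landmarks (in that order).
#'
#' @param frame A 100 x 3 landmark matrix.
#' @param cfg A [gfe_config()].
#' @return List with numeric vectors `distances`, `angles`, `depths`.
#' @export
frame_features <- function(frame, cfg) {
  frame <- as.matrix(frame)
  if (nrow(frame) != 100L || ncol(frame) != 3L) {
    stopf("frame_features: frame must be 100 x 3")
  }
  idx <- c(unlist(cfg$pair_list), unlist(cfg$triple_list))
  if (length(idx) && any(idx < 0L | idx > 99L)) {
    stopf("frame_features: landmark index out of 0..99")
  }
  d <- vapply(cfg$pair_list, function(p)
    euclidean_distance(frame[p[1] + 1L, 1:2], frame[p[2] + 1L, 1:2]),
    numeric(1))
  a <- vapply(cfg$triple_list, function(p)
    segment_angle(frame[p[1] + 1L, 1:2], frame[p[2] + 1L, 1:2],
                  frame[p[3] + 1L, 1:2]),
    numeric(1))
  list(distances = d, angles = a, depths = depth_features(frame, cfg$pair_list))
}

#' Feature track: per-frame derived features for a whole sequence
#'
#' Vectorized evaluation of [frame_features()] over every frame of a
#' sequence, optionally adding the shape features (enclosed polygon area
#' and principal-axes ratio per configured landmark group) used by the
#' doubt-expression descriptor windows.
#'
#' @param seq A [landmark_sequence()].
#' @param cfg A [gfe_config()].
#' @param shape Also compute per-group area/eccentricity features.
#' @return Object of class `feature_track`: a list of per-frame matrices
#'   `distances` (n x l), `angles` (n x m), `depths` (n x ll) and, when
#'   `shape = TRUE`, `areas` and `eccentricities` (n x groups), plus the
#'   per-frame labels carried through from the sequence.
#' @export
extract_features <- function(seq, cfg, shape = FALSE) {
  stopifnot(inherits(seq, "landmark_sequence"))
  n <- n_frames(seq)
  P <- seq$points
  l <- length(cfg$pair_list); m <- length(cfg$triple_list)

  dmat <- matrix(0, n, l)
  for (k in seq_len(l)) {
    p <- cfg$pair_list[[k]] + 1L
    dmat[, k] <- sqrt((P[, p[1], 1] - P[, p[2], 1])^2 +
                      (P[, p[1], 2] - P[, p[2], 2])^2)
  }
  amat <- matrix(0, n, m)
  for (j in seq_len(m)) {
    p <- cfg$triple_list[[j]] + 1L
    a1 <- atan2(P[, p[1], 2] - P[, p[2], 2], P[, p[1], 1] - P[, p[2], 1])
    a2 <- atan2(P[, p[2], 2] - P[, p[3], 2], P[, p[2], 1] - P[, p[3], 1])
    amat[, j] <- wrap_line_angle(a1 - a2)
  }
  zidx <- unique(unlist(cfg$pair_list, use.names = FALSE))
  zmat <- if (length(zidx)) P[, zidx + 1L, 3, drop = FALSE][, , 1, drop = TRUE] else
    matrix(0, n, 0)
  zmat <- matrix(zmat, nrow = n)

  colnames(dmat) <- if (l) paste0("d", seq_len(l) - 1L) else NULL
  colnames(amat) <- if (m) paste0("a", seq_len(m) - 1L) else NULL
  colnames(zmat) <- if (length(zidx)) paste0("z", seq_along(zidx) - 1L) else NULL

  track <- list(distances = dmat, angles = amat, depths = zmat,
                labels = seq$labels, sequence_id = sequence_id(seq))
  if (shape) {
    g <- length(cfg$shape_groups)
    areas <- matrix(0, n, g); ecc <- matrix(0, n, g)
    for (k in seq_len(g)) {
      gi <- cfg$shape_groups[[k]] + 1L
      for (i in seq_len(n)) {
        pts <- P[i, gi, 1:2]
        areas[i, k] <- polygon_area(pts)
        ecc[i, k] <- principal_axes_ratio(pts, collinear = cfg$collinear)
      }
    }
    colnames(areas) <- paste0("area_", names(cfg$shape_groups))
    colnames(ecc) <- paste0("ecc_", names(cfg$shape_groups))
    track$areas <- areas
    track$eccentricities <- ecc
  }
  structure(track, class = "feature_track")
}

sequence_id <- function(seq) {
  paste0("s", as.character(seq$subject_id), "_", seq$expression)
}

#' Fit/apply per-feature z-score normalization
#'
#' Standardizes each feature column to zero mean and unit standard
#' deviation. When `stats` is `NULL` the transform is fitted on `x`
#' (training data); otherwise the supplied, previously fitted statistics
#' are applied unchanged — normalization is never refitted on test data.
#' Zero-variance columns are centered only (scale fixed at 1).
#'
#' @param x Numeric matrix, samples x features.
#' @param stats `NULL`, or the `stats` element of a previous fit.
#' @return List with the transformed `matrix` and the fitted `stats`
#'   (list of `center` and `scale` vectors).
#' @export
normalize_features <- function(x, stats = NULL) {
  x <- as.matrix(x)
  if (is.null(stats)) {
    center <- colMeans(x)
    scale <- apply(x, 2, stats::sd)
    scale[!is.finite(scale) | scale == 0] <- 1
    stats <- list(center = center, scale = scale)
  }
  if (length(stats$center) != ncol(x)) {
    stopf("normalize_features: fitted stats have %d features, data has %d",
          length(stats$center), ncol(x))
  }
  out <- sweep(sweep(x, 2, stats$center, "-"), 2, stats$scale, "/")
  list(matrix = out, stats = stats)
}
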