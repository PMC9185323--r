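#' Euclidean distance between two image-plane points
#'
#' Distance features use only the x and y coordinates of a landmark pair;
#' depth enters the feature set separately (see [depth_features()]).
#'
#' @param p,q Numeric length-2 vectors (x, y).
#' @return Non-negative scalar distance.
#' @export
euclidean_distance <- function(p, q) {
  if (length(p) < 2L || length(q) < 2L ||
      !all(is.finite(p[1:2])) || !all(is.finite(q[1:2]))) {
    stopf("euclidean_distance: points must be finite length-2 vectors")
  }
  sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)
}

# Wrap an angle difference into (-pi/2, pi/2], the principal value of the
# angle between two undirected lines.
wrap_line_angle <- function(d) {
  d <- d %% pi               # [0, pi)
  d[d > pi / 2] <- d[d > pi / 2] - pi
  # boundary: exactly -pi/2 maps to +pi/2 so the range is (-pi/2, pi/2]
  d[d == -pi / 2] <- pi / 2
  d
}

#' Signed angle between two consecutive landmark segments
#'
#' For points p1, p2, p3 this is the signed acute angle between line
#' p1-p2 and line p2-p3, i.e. `atan((s12 - s23) / (1 + s12 * s23))` in
#' terms of the two segment slopes wherever both slopes exist. It is
#' computed from the segment direction vectors with `atan2`, which agrees
#' with the slope form on its domain but is also defined for vertical
#' segments. The result lies in (-pi/2, pi/2]; collinear points give 0.
#'
#' @param p1,p2,p3 Numeric length-2 (x, y) points; p1 != p2 and p2 != p3.
#' @return Angle in radians.
#' @export
segment_angle <- function(p1, p2, p3) {
  pts <- rbind(p1[1:2], p2[1:2], p3[1:2])
  if (!all(is.finite(pts))) stopf("segment_angle: non-finite coordinates")
  if (all(p1[1:2] == p2[1:2]) || all(p2[1:2] == p3[1:2])) {
    stopf("segment_angle: coincident points give an undefined segment")
  }
  a1 <- atan2(p1[2] - p2[2], p1[1] - p2[1])
  a2 <- atan2(p2[2] - p3[2], p2[1] - p3[1])
  wrap_line_angle(a1 - a2)
}

#' Depth features referenced by a distance pair list
#'
#' The depth (z) feature set consists of the z coordinate of each distinct
#' landmark index appearing in the pair list, taken in first-occurrence
#' order; repeated indices contribute once, so its length is at most twice
#' the number of pairs.
#'
#' @param frame A 100 x 3 landmark matrix (one frame).
#' @param pair_list List of 2-element 0-based index vectors.
#' @return Numeric vector of depths.
#' @export
depth_features <- function(frame, pair_list) {
  idx <- unique(unlist(pair_list, use.names = FALSE))
  if (length(idx) == 0L) return(numeric(0))
  if (any(idx < 0L | idx > 99L)) stopf("depth_features: index out of 0..99")
  frame[idx + 1L, 3]
}

#' Enclosed area of an ordered polygon
#'
#' Absolute shoelace area of the closed polygon through the points in the
#' given order; orientation-independent.
#'
#' @param pts Numeric matrix (>= 3 rows) of (x, y) vertices.
#' @return Non-negative area in squared coordinate units.
#' @export
polygon_area <- function(pts) {
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stopf("polygon_area: need at least 3 points")
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  abs(sum(x * yn - xn * y)) / 2
}

#' Principal-axes ratio (eccentricity) of a 2D point set
#'
#' Ratio of the major to the minor principal axis of the point cloud,
#' `sqrt(lambda_max / lambda_min)` of the 2x2 covariance matrix of the
#' coordinates. Equal to 1 for isotropic sets and invariant under rotation
#' and translation. Always >= 1 (major/minor convention).
#'
#' @param pts Numeric matrix (>= 3 rows) of (x, y) points.
#' @param collinear For (near-)collinear inputs, where the minor axis
#'   degenerates: `"error"` (default) or `"inf"` to return `Inf`.
#' @return Scalar >= 1.
#' @export
principal_axes_ratio <- function(pts, collinear = c("error", "inf")) {
  collinear <- match.arg(collinear)
  pts <- as.matrix(pts)
  if (nrow(pts) < 3L) stopf("principal_axes_ratio: need at least 3 points")
  ev <- eigen(stats::cov(pts[, 1:2, drop = FALSE]), symmetric = TRUE,
              only.values = TRUE)$values
  if (ev[2] <= .Machine$double.eps * max(ev[1], 1)) {
    if (collinear == "inf") return(Inf)
    stopf("principal_axes_ratio: points are (near-)collinear; minor axis degenerate")
  }
  sqrt(ev[1] / ev[2])
}

#' Seven-number statistical summary of a feature over a window
#'
#' Returns, in order: mean, standard deviation, maximum, minimum, median,
#' 25th percentile, 75th percentile. The standard deviation uses the
#' population convention (divisor n) and the percentiles use linear
#' interpolation (R quantile type 7); both conventions are fixed.
#'
#' @param values Non-empty numeric vector.
#' @return Named numeric vector of length 7.
#' @export
statistical_descriptors <- function(values) {
  if (length(values) == 0L) stopf("statistical_descriptors: empty input")
  if (!all(is.finite(values))) stopf("statistical_descriptors: non-finite values")
  m <- mean(values)
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(mean = m,
    sd = sqrt(mean((values - m)^2)),
    max = max(values),
    min = min(values),
    median = q[2],
    q25 = q[1],
    q75 = q[3])
}
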