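# Independent oracles used across the suite. Each is a direct, brute-force
# evaluation of the defining formula, kept free of package internals.

# Signed acute angle between lines p1p2 and p2p3 via the slope-difference
# formula (defined only when neither segment is vertical).
oracle_slope_angle <- function(p1, p2, p3) {
  s12 <- (p1[2] - p2[2]) / (p1[1] - p2[1])
  s23 <- (p2[2] - p3[2]) / (p2[1] - p3[1])
  atan((s12 - s23) / (1 + s12 * s23))
}

# Unsigned acute angle between the two segment directions.
oracle_acute_angle <- function(p1, p2, p3) {
  u <- p1 - p2; v <- p2 - p3
  acos(min(1, abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))))
}

# Shoelace area written out term by term.
oracle_shoelace <- function(pts) {
  n <- nrow(pts); s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    s <- s + pts[i, 1] * pts[j, 2] - pts[j, 1] * pts[i, 2]
  }
  abs(s) / 2
}

# Major/minor axis ratio from the singular values of the centered cloud.
oracle_axes_ratio_svd <- function(pts) {
  c_pts <- sweep(pts, 2, colMeans(pts))
  sv <- svd(c_pts)$d
  sv[1] / sv[2]
}

# Per-class weighted sum, max taken by explicit loop (lowest index wins).
oracle_soft_vote <- function(probs, weights) {
  nc <- length(probs[[1]])
  fused <- numeric(nc)
  for (i in seq_len(nc)) {
    for (j in 1:3) fused[i] <- fused[i] + weights[j] * probs[[j]][i]
  }
  best <- 1L
  for (i in seq_len(nc)) if (fused[i] > fused[best]) best <- i
  list(fused = fused, label = best)
}

# Confusion-matrix F1/accuracy and exhaustive pairwise-rank AUC.
oracle_metrics <- function(y_true, y_score, y_pred) {
  tp <- sum(y_true == 1 & y_pred == 1)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  prec <- if (tp + fp == 0) 0 else tp / (tp + fp)
  rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
  pos <- y_score[y_true == 1]; neg <- y_score[y_true == 0]
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  c(f1 = f1, accuracy = mean(y_true == y_pred),
    roc_auc = s / (length(pos) * length(neg)))
}

oracle_descriptors <- function(x) {
  n <- length(x)
  sx <- sort(x)
  qt <- function(p) {
    h <- (n - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    sx[lo] + (h - lo) * (sx[hi] - sx[lo])
  }
  m <- sum(x) / n
  c(m, sqrt(sum((x - m)^2) / n), max(x), min(x), qt(0.5), qt(0.25), qt(0.75))
}
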