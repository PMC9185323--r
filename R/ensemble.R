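#' Weighted soft vote over member class probabilities
#'
#' Fuses the per-class probability vectors of the three perspective
#' classifiers: the fused score of class i is `sum_j w_j * p_ij` and the
#' predicted label is its argmax. Ties at the argmax resolve to the lowest
#' class index, so predictions are deterministic. Weights need only be
#' non-negative and not all zero; rescaling all weights by a positive
#' constant never changes the decision.
#'
#' @param member_probs List of 3 numeric per-class probability vectors
#'   (identical lengths, each summing to 1), or a 3 x C matrix.
#' @param weights 3 non-negative weights, default uniform.
#' @return List with `fused_scores` (per class), `label` (1-based argmax
#'   class index) and `member_probs`.
#' @export
soft_vote <- function(member_probs, weights = c(1, 1, 1) / 3) {
  if (is.matrix(member_probs)) {
    member_probs <- lapply(seq_len(nrow(member_probs)),
                           function(j) member_probs[j, ])
  }
  if (length(member_probs) != 3L) stopf("soft_vote: need exactly 3 members")
  nc <- vapply(member_probs, length, integer(1))
  if (length(unique(nc)) != 1L) {
    stopf("soft_vote: members disagree on class count (%s)",
          paste(nc, collapse = ", "))
  }
  for (p in member_probs) {
    if (abs(sum(p) - 1) > 1e-9 || any(p < -1e-12)) {
      stopf("soft_vote: member probabilities must be non-negative and sum to 1")
    }
  }
  if (length(weights) != 3L || any(weights < 0) || sum(weights) <= 0) {
    stopf("soft_vote: weights must be 3 non-negative values, not all zero")
  }
  fused <- numeric(nc[1])
  for (j in 1:3) fused <- fused + weights[j] * member_probs[[j]]
  list(fused_scores = fused,
       label = which.max(fused),  # which.max takes the first (lowest) index on ties
       member_probs = member_probs)
}

rf_fit <- function(x, y, params, seed) {
  args <- c(list(x = as.data.frame(x),
                 y = factor(y, levels = c(0L, 1L)),
                 probability = TRUE,
                 num.threads = 1L,
                 seed = seed),
            params)
  do.call(ranger::ranger, args)
}

rf_prob <- function(model, x) {
  p <- stats::predict(model, data = as.data.frame(x),
                      num.threads = 1L)$predictions
  p[, c("0", "1"), drop = FALSE]
}

check_two_classes <- function(labels) {
  present <- sort(unique(labels))
  if (!identical(present, c(0L, 1L))) {
    missing <- setdiff(c(0L, 1L), present)
    stopf("training data contains a single class: class %s has no samples",
          paste(missing, collapse = ", "))
  }
}

#' Fit the three-perspective soft-vote ensemble
#'
#' Trains one probabilistic random-forest classifier per perspective
#' (member j sees only the perspective-j feature columns, all members
#' share the window labels) and records the soft-vote weights. Training is
#' seeded from `cfg$seed`, so repeated fits are reproducible; classifier
#' hyperparameters come from `cfg$classifier_params`.
#'
#' @param ds A `windowed_dataset` with both classes present. Feature
#'   matrices are used as given; normalization is the caller's
#'   responsibility (the evaluation protocols fit it on training folds).
#' @param cfg A [gfe_config()].
#' @return Object of class `soft_vote_ensemble`.
#' @export
fit_soft_vote <- function(ds, cfg = gfe_config()) {
  stopifnot(inherits(ds, "windowed_dataset"))
  if (n_windows(ds) == 0L) stopf("fit_soft_vote: empty dataset")
  check_two_classes(ds$labels)
  members <- lapply(1:3, function(j) {
    rf_fit(ds$x[, ds$slices[[j]], drop = FALSE], ds$labels,
           cfg$classifier_params, seed = derive_seed(cfg$seed, j))
  })
  structure(list(members = members,
                 weights = cfg$weights,
                 classes = c(0L, 1L),
                 slices = ds$slices,
                 feature_names = ds$feature_names,
                 version = 1L),
            class = "soft_vote_ensemble")
}

#' @export
print.soft_vote_ensemble <- function(x, ...) {
  cat(sprintf("<soft_vote_ensemble> 3 members on %d/%d/%d features, weights %s\n",
              length(x$slices$p1), length(x$slices$p2), length(x$slices$p3),
              paste(signif(x$weights, 3), collapse = "/")))
  invisible(x)
}

#' Predict with a soft-vote ensemble
#'
#' Each member predicts class probabilities from its own perspective
#' columns; the rows are fused by [soft_vote()]. The fused positive-class
#' score (column `score_pos`) is the quantity used for ROC analysis.
#'
#' @param object A `soft_vote_ensemble`.
#' @param ds A `windowed_dataset` with the training feature layout.
#' @param ... Unused.
#' @return Data frame with one row per window: `score_neg`, `score_pos`,
#'   `label` (0/1). Member probability matrices are attached as the
#'   `member_probs` attribute.
#' @export
predict.soft_vote_ensemble <- function(object, ds, ...) {
  stopifnot(inherits(ds, "windowed_dataset"))
  if (!identical(ds$feature_names, object$feature_names)) {
    stopf("feature layout of the dataset does not match the ensemble's training layout")
  }
  n <- n_windows(ds)
  if (n == 0L) {
    out <- data.frame(score_neg = numeric(0), score_pos = numeric(0),
                      label = integer(0))
    attr(out, "member_probs") <- list()
    return(out)
  }
  probs <- lapply(1:3, function(j) {
    rf_prob(object$members[[j]], ds$x[, object$slices[[j]], drop = FALSE])
  })
  w <- object$weights / sum(object$weights)
  fused <- w[1] * probs[[1]] + w[2] * probs[[2]] + w[3] * probs[[3]]
  label <- object$classes[max.col(fused, ties.method = "first")]
  out <- data.frame(score_neg = fused[, 1], score_pos = fused[, 2],
                    label = as.integer(label))
  attr(out, "member_probs") <- probs
  out
}

#' Fit the flat-aggregation baseline
#'
#' The conventional alternative to perspective fusion: a single
#' probabilistic random-forest over the full flattened window vector
#' (p1, p2 and p3 concatenated). Used only for comparison reports.
#'
#' @inheritParams fit_soft_vote
#' @return Object of class `aggregated_baseline`.
#' @export
fit_aggregated_baseline <- function(ds, cfg = gfe_config()) {
  stopifnot(inherits(ds, "windowed_dataset"))
  if (n_windows(ds) == 0L) stopf("fit_aggregated_baseline: empty dataset")
  check_two_classes(ds$labels)
  model <- rf_fit(ds$x, ds$labels, cfg$classifier_params,
                  seed = derive_seed(cfg$seed, 0L))
  structure(list(model = model, classes = c(0L, 1L),
                 feature_names = ds$feature_names, version = 1L),
            class = "aggregated_baseline")
}

#' @export
predict.aggregated_baseline <- function(object, ds, ...) {
  stopifnot(inherits(ds, "windowed_dataset"))
  if (!identical(ds$feature_names, object$feature_names)) {
    stopf("feature layout of the dataset does not match the model's training layout")
  }
  if (n_windows(ds) == 0L) {
    return(data.frame(score_neg = numeric(0), score_pos = numeric(0),
                      label = integer(0)))
  }
  p <- rf_prob(object$model, ds$x)
  label <- object$classes[max.col(p, ties.method = "first")]
  data.frame(score_neg = p[, 1], score_pos = p[, 2], label = as.integer(label))
}

#' Save / load a fitted model
#'
#' Thin versioned wrappers around R serialization for `soft_vote_ensemble`
#' and `aggregated_baseline` objects (the `version` field guards against
#' reading archives written by an incompatible package release).
#'
#' @param model A fitted model object.
#' @param path Archive path.
#' @return `write_model` returns `path` invisibly; `read_model` the model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, c("soft_vote_ensemble", "aggregated_baseline")))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, c("soft_vote_ensemble", "aggregated_baseline")) ||
      !identical(model$version, 1L)) {
    stopf("not a recognized model archive: %s", path)
  }
  model
}
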