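#' Binary classification metrics
#'
#' Computes the three reported metrics: F1 of the positive class
#' (2PR/(P+R), with F1 = 0 when no positive is predicted or present),
#' accuracy, and ROC-AUC of the positive-class score (rank statistic with
#' midrank tie handling, via [pROC::roc()]). When `y_true` contains a
#' single class the ROC-AUC is undefined and returned as `NaN` with a
#' warning.
#'
#' @param y_true 0/1 truth vector.
#' @param y_score Positive-class scores (e.g. fused soft-vote scores).
#' @param y_pred 0/1 predicted labels.
#' @return Named numeric vector `c(f1, accuracy, roc_auc)`.
#' @export
compute_metrics <- function(y_true, y_score, y_pred) {
  stopifnot(length(y_true) == length(y_score),
            length(y_true) == length(y_pred))
  y_true <- as.integer(y_true); y_pred <- as.integer(y_pred)
  tp <- sum(y_true == 1L & y_pred == 1L)
  fp <- sum(y_true == 0L & y_pred == 1L)
  fn <- sum(y_true == 1L & y_pred == 0L)
  f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  acc <- mean(y_true == y_pred)
  if (length(unique(y_true)) < 2L) {
    warning("ROC-AUC undefined: y_true contains a single class", call. = FALSE)
    auc <- NaN
  } else {
    auc <- as.numeric(pROC::auc(pROC::roc(
      response = y_true, predictor = as.numeric(y_score),
      levels = c(0, 1), direction = "<", quiet = TRUE)))
  }
  c(f1 = f1, accuracy = acc, roc_auc = auc)
}

#' Balance classes by random undersampling
#'
#' Subsamples the larger class by uniform random elimination of windows
#' until both classes have exactly the minority count; the minority class
#' is never touched. Deterministic under `seed`; the retained windows keep
#' their original order.
#'
#' @param ds A `windowed_dataset` with both classes present.
#' @param seed Integer seed.
#' @return A `windowed_dataset` with equal class counts.
#' @export
balance_classes <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "windowed_dataset"))
  check_two_classes(ds$labels)
  idx_pos <- which(ds$labels == 1L)
  idx_neg <- which(ds$labels == 0L)
  n <- min(length(idx_pos), length(idx_neg))
  keep <- with_local_seed(seed, {
    c(if (length(idx_pos) > n) sample(idx_pos, n) else idx_pos,
      if (length(idx_neg) > n) sample(idx_neg, n) else idx_neg)
  })
  subset_windows(ds, sort(keep))
}

#' Windows for one sequence under the configured pipeline
#'
#' Extracts the feature track and builds windows; the doubt expression
#' uses the statistical-descriptor variant with shape features when
#' `cfg$doubt_descriptors` is set.
#'
#' @param seq A [landmark_sequence()].
#' @param cfg A [gfe_config()].
#' @param sw Optional window-size override.
#' @param stride Optional stride override.
#' @return A `windowed_dataset`.
#' @export
sequence_windows <- function(seq, cfg, sw = NULL, stride = NULL) {
  use_desc <- cfg$doubt_descriptors &&
    identical(seq$expression, "doubt_question")
  track <- extract_features(seq, cfg, shape = use_desc)
  if (use_desc) build_descriptor_windows(track, cfg = cfg, sw = sw, stride = stride)
  else build_windows(track, cfg = cfg, sw = sw, stride = stride)
}

task_windows <- function(seqs, cfg, sw = NULL, stride = NULL) {
  combine_windows(lapply(seqs, sequence_windows, cfg = cfg, sw = sw,
                         stride = stride))
}

# The experiments slide windows so that consecutive windows overlap by a
# single frame: stride sw - 1 (for sw = 2 this coincides with stride 1).
# The dense stride-1 indexing remains available through cfg$window_stride.
overlap_one_stride <- function(sw) max(1L, as.integer(sw) - 1L)

fit_predict <- function(train, test, cfg, seed, model = "ensemble") {
  norm <- NULL
  if (cfg$normalization == "zscore") {
    fitted <- normalize_features(train$x)
    train$x <- fitted$matrix
    norm <- fitted$stats
    test$x <- normalize_features(test$x, stats = norm)$matrix
  }
  cfg$seed <- seed
  fit_fun <- if (model == "ensemble") fit_soft_vote else fit_aggregated_baseline
  m <- fit_fun(train, cfg)
  list(pred = stats::predict(m, test), norm_stats = norm)
}

#' Stratified k-fold cross-validation of one binary expression task
#'
#' The within-subject evaluation protocol: stratified k-fold at window
#' level, class balancing applied once up front (default) or inside each
#' training fold, z-normalization fitted on each training fold only, and
#' metrics computed once over the pooled out-of-fold predictions (micro
#' pooling).
#'
#' @param ds A `windowed_dataset` for one expression task.
#' @param cfg A [gfe_config()].
#' @param k Number of folds, default 10.
#' @param seed Integer seed for balancing, fold assignment and training.
#' @param model `"ensemble"` (soft-vote) or `"baseline"` (flat
#'   aggregation).
#' @param balance `"once"` (before CV, the default) or `"per_fold"`
#'   (inside each training fold, leaving test folds imbalanced).
#' @return Named metric vector as [compute_metrics()], with the pooled
#'   predictions in the `predictions` attribute and per-fold train indices
#'   and normalization statistics in the `folds` attribute.
#' @export
kfold_protocol <- function(ds, cfg = gfe_config(), k = 10L, seed = 1L,
                           model = c("ensemble", "baseline"),
                           balance = c("once", "per_fold")) {
  model <- match.arg(model); balance <- match.arg(balance)
  if (balance == "once") ds <- balance_classes(ds, derive_seed(seed, 11L))
  counts <- table(factor(ds$labels, levels = c(0L, 1L)))
  if (any(counts < k)) {
    stopf("too few samples for %d-fold CV: class counts %s",
          k, paste(counts, collapse = "/"))
  }
  folds <- with_local_seed(derive_seed(seed, 12L),
                           caret::createFolds(factor(ds$labels), k = k))
  y_true <- integer(0); y_score <- numeric(0); y_pred <- integer(0)
  fold_info <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- folds[[f]]
    train_idx <- setdiff(seq_len(n_windows(ds)), test_idx)
    train <- subset_windows(ds, train_idx)
    if (balance == "per_fold") {
      train <- balance_classes(train, derive_seed(seed, 100L + f))
    }
    res <- fit_predict(train, subset_windows(ds, test_idx), cfg,
                       seed = derive_seed(seed, 200L + f), model = model)
    y_true <- c(y_true, ds$labels[test_idx])
    y_score <- c(y_score, res$pred$score_pos)
    y_pred <- c(y_pred, res$pred$label)
    fold_info[[f]] <- list(train_idx = train_idx, test_idx = test_idx,
                           norm_stats = res$norm_stats)
  }
  out <- compute_metrics(y_true, y_score, y_pred)
  attr(out, "predictions") <- data.frame(y_true = y_true, y_score = y_score,
                                         y_pred = y_pred)
  attr(out, "folds") <- fold_info
  out
}

#' Cross-subject evaluation of one binary expression task
#'
#' The subject-independent protocol: all windows of the training subject
#' form the training set and all windows of the test subject the test
#' set. Classes are balanced on each side (so F1 is computed at the same
#' class prior as the within-subject protocols). Feature standardization
#' is per subject: each side is z-scored with its own feature statistics,
#' an unsupervised calibration that never touches labels. This is what
#' lets the features transfer across subjects at all — a new subject's
#' head sits at a different position and depth, and per-subject centering
#' removes exactly that rigid offset (the within-subject CV protocol, by
#' contrast, fits normalization on training folds only).
#'
#' @param train_seqs,test_seqs Lists of [landmark_sequence()] objects for
#'   one expression from two disjoint subjects.
#' @param cfg A [gfe_config()] (typically with the user-independent
#'   landmark selection).
#' @param sw Window size for this expression (the protocol uses
#'   per-expression sizes, see `cfg$cross_subject_sw`).
#' @param stride Window stride; defaults to windows overlapping by one
#'   frame (`sw - 1`).
#' @param seed Integer seed.
#' @param model `"ensemble"` or `"baseline"`.
#' @return Named metric vector as [compute_metrics()].
#' @export
cross_subject_protocol <- function(train_seqs, test_seqs, cfg = gfe_config("user_independent"),
                                   sw = cfg$window_size,
                                   stride = overlap_one_stride(sw), seed = 1L,
                                   model = c("ensemble", "baseline")) {
  model <- match.arg(model)
  tr_subj <- unique(vapply(train_seqs, function(s) as.character(s$subject_id),
                           character(1)))
  te_subj <- unique(vapply(test_seqs, function(s) as.character(s$subject_id),
                           character(1)))
  if (length(intersect(tr_subj, te_subj))) {
    stopf("cross-subject protocol requires disjoint subjects; both sides contain subject %s",
          paste(intersect(tr_subj, te_subj), collapse = ", "))
  }
  train <- balance_classes(task_windows(train_seqs, cfg, sw = sw, stride = stride),
                           derive_seed(seed, 21L))
  test <- balance_classes(task_windows(test_seqs, cfg, sw = sw, stride = stride),
                          derive_seed(seed, 22L))
  if (cfg$normalization == "zscore") {
    train$x <- normalize_features(train$x)$matrix
    test$x <- normalize_features(test$x)$matrix   # per-subject calibration
  }
  cfg_fit <- cfg
  cfg_fit$normalization <- "none"
  res <- fit_predict(train, test, cfg_fit, seed = derive_seed(seed, 23L),
                     model = model)
  out <- compute_metrics(test$labels, res$pred$score_pos, res$pred$label)
  attr(out, "predictions") <- data.frame(y_true = test$labels,
                                         y_score = res$pred$score_pos,
                                         y_pred = res$pred$label)
  out
}

study_sequences <- function(study) {
  if (inherits(study, "gfe_study")) study$sequences else study
}

#' Run one of the four evaluation protocols over a study
#'
#' Protocols: `"subj1-cv"`, `"subj2-cv"` (within-subject 10-fold CV on one
#' subject), `"pooled-cv"` (both subjects pooled, 10-fold CV) and
#' `"cross-subject"` (train on subject 1, test on subject 2, with
#' per-expression window sizes). Each of the nine expressions is an
#' independent binary task; the report carries per-expression F1, accuracy
#' and ROC-AUC plus their arithmetic means.
#'
#' @param study A `gfe_study` from [simulate_study()], or a list of
#'   [landmark_sequence()] objects covering the expressions.
#' @param protocol Protocol name (see above).
#' @param cfg A [gfe_config()]; defaults to the user-dependent selection
#'   for the CV protocols and the user-independent selection for the
#'   cross-subject protocol.
#' @param seed Integer seed.
#' @param k CV folds for the within-subject protocols.
#' @param model `"ensemble"` or `"baseline"`.
#' @param stride Window stride used by the protocols; the default `NULL`
#'   makes consecutive windows overlap by one frame (stride `sw - 1`, the
#'   experimental setting — it also keeps the k-fold splits honest, since
#'   heavily overlapping windows on both sides of a random fold split
#'   would share most of their frames). Pass `1` for the dense indexing.
#' @return An `eval_report`.
#' @export
evaluate_study <- function(study,
                           protocol = c("subj1-cv", "subj2-cv", "pooled-cv",
                                        "cross-subject"),
                           cfg = NULL, seed = 1L, k = 10L,
                           model = c("ensemble", "baseline"),
                           stride = NULL) {
  protocol <- match.arg(protocol)
  model <- match.arg(model)
  if (is.null(cfg)) {
    cfg <- if (protocol == "cross-subject") gfe_config("user_independent")
           else gfe_config("user_dependent")
  }
  seqs <- study_sequences(study)
  exprs <- gfe_expressions()
  labels <- attr(exprs, "labels")
  subj_of <- vapply(seqs, function(s) as.character(s$subject_id), character(1))
  expr_of <- vapply(seqs, function(s) s$expression, character(1))
  rows <- vector("list", length(exprs))
  for (i in seq_along(exprs)) {
    ex <- exprs[i]
    ex_seed <- derive_seed(seed, 1000L + i)
    met <- if (protocol == "cross-subject") {
      sw <- cfg$cross_subject_sw[[ex]]
      cross_subject_protocol(seqs[subj_of == "1" & expr_of == ex],
                             seqs[subj_of == "2" & expr_of == ex],
                             cfg, sw = sw,
                             stride = if (is.null(stride)) overlap_one_stride(sw) else stride,
                             seed = ex_seed, model = model)
    } else {
      take <- switch(protocol,
                     `subj1-cv` = subj_of == "1",
                     `subj2-cv` = subj_of == "2",
                     `pooled-cv` = rep(TRUE, length(seqs))) & expr_of == ex
      if (!any(take)) stopf("study has no sequences for expression '%s'", ex)
      task_stride <- if (is.null(stride)) overlap_one_stride(cfg$window_size) else stride
      kfold_protocol(task_windows(seqs[take], cfg, stride = task_stride),
                     cfg, k = k, seed = ex_seed, model = model)
    }
    rows[[i]] <- data.frame(expression = ex, label = labels[i],
                            f1 = met[["f1"]], accuracy = met[["accuracy"]],
                            roc_auc = met[["roc_auc"]],
                            n = nrow(attr(met, "predictions")))
  }
  tab <- do.call(rbind, rows)
  structure(list(protocol = protocol,
                 table = tab,
                 averages = c(f1 = mean(tab$f1), accuracy = mean(tab$accuracy),
                              roc_auc = mean(tab$roc_auc)),
                 seed = as.integer(seed), k = as.integer(k), model = model,
                 config_digest = config_digest(cfg)),
            class = "eval_report")
}

config_digest <- function(cfg) {
  sprintf("sel[%s]-sw%d-st%d-%s-%s-pairs%d-triples%d",
          paste(names(cfg$selection), collapse = ","),
          cfg$window_size, cfg$window_stride, cfg$label_rule,
          cfg$normalization, length(cfg$pair_list), length(cfg$triple_list))
}

#' @export
print.eval_report <- function(x, digits = 4, ...) {
  cat(sprintf("Evaluation report — protocol %s (model: %s, seed %d)\n",
              x$protocol, x$model, x$seed))
  tab <- x$table
  tab$f1 <- round(tab$f1, digits)
  tab$accuracy <- round(tab$accuracy, digits)
  tab$roc_auc <- round(tab$roc_auc, digits)
  print(tab[c("label", "f1", "accuracy", "roc_auc")], row.names = FALSE)
  cat(sprintf("Average      f1=%.4f accuracy=%.4f roc_auc=%.4f\n",
              x$averages[["f1"]], x$averages[["accuracy"]],
              x$averages[["roc_auc"]]))
  invisible(x)
}

#' Write an evaluation report as delimited text
#'
#' One row per expression plus a final `Average` row, tab-separated.
#'
#' @param report An `eval_report`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  tab <- report$table[c("label", "f1", "accuracy", "roc_auc")]
  avg <- data.frame(label = "Average",
                    f1 = report$averages[["f1"]],
                    accuracy = report$averages[["accuracy"]],
                    roc_auc = report$averages[["roc_auc"]])
  utils::write.table(rbind(tab, avg), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
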