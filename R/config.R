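#' Landmark index selections for the two experimental regimes
#'
#' Returns the face-landmark indices used to derive geometric features.
#' Indices are 0-based (0-99), matching the convention of the landmark
#' streams themselves: the published point lists cite index 0 (left eye)
#' and index 89 (nose), so the whole package indexes points from 0.
#'
#' The `"user_dependent"` selection is used for within-subject protocols;
#' `"user_independent"` for the cross-subject protocol.
#'
#' @param which `"user_dependent"` or `"user_independent"`.
#' @return Named list of integer vectors, one per face region, in the order
#'   the regions are consumed when building feature pair/triple lists.
#' @export
landmark_selection <- function(which = c("user_dependent", "user_independent")) {
  which <- match.arg(which)
  if (which == "user_dependent") {
    list(
      left_eyebrow  = c(18L, 22L, 24L),
      right_eyebrow = c(31L, 34L),
      left_eye      = c(3L, 6L),
      nose          = c(39L, 42L, 44L),
      mouth         = c(49L, 56L, 59L, 60L, 62L, 63L, 64L, 66L)
    )
  } else {
    list(
      left_eyebrow  = c(17L, 22L, 24L),
      right_eyebrow = c(27L, 31L, 32L, 34L),
      left_eye      = c(0L, 2L, 6L),
      right_eye     = c(8L, 9L, 10L, 14L, 15L),
      nose          = 89L,
      mouth         = c(60L, 61L, 62L, 63L, 64L, 66L, 67L)
    )
  }
}

#' Landmark groups used for the doubt-expression shape descriptors
#'
#' The interrogative-doubt expression shows only a slight contraction of
#' the eyes and mouth, so distance/angle features barely move; enclosed
#' polygon area and principal-axes ratio of these three landmark groups
#' are added as extra features for that expression. Indices are 0-based.
#'
#' @return Named list of integer vectors.
#' @export
doubt_shape_groups <- function() {
  list(
    left_eyebrow = c(90L, 91L, 92L, 93L, 94L, 21L, 22L, 23L, 24L, 25L),
    mouth        = 48:59,
    left_eye     = 0:7
  )
}

# Consecutive disjoint pairs/triples of an index vector, in listed order.
# Trailing leftovers that do not complete a pair/triple are dropped.
consecutive_pairs <- function(idx) {
  n <- (length(idx) %/% 2L) * 2L
  if (n == 0L) return(list())
  lapply(seq_len(n / 2L), function(k) idx[c(2L * k - 1L, 2L * k)])
}

consecutive_triples <- function(idx) {
  n <- (length(idx) %/% 3L) * 3L
  if (n == 0L) return(list())
  lapply(seq_len(n / 3L), function(k) idx[c(3L * k - 2L, 3L * k - 1L, 3L * k)])
}

#' Canonical expression names and report labels
#'
#' The nine grammatical facial expressions, in the row order used by the
#' evaluation reports (wh question first, focus/emphasis last).
#'
#' @return Character vector of canonical (machine) names; the display
#'   labels are attached as the `labels` attribute.
#' @export
gfe_expressions <- function() {
  x <- c("wh_question", "yn_question", "doubt_question", "negative",
         "affirmative", "conditional", "relative", "topic", "emphasis")
  attr(x, "labels") <- c("Wh question", "Y/N question", "Doubt question",
                         "Negative", "Affirmative", "Conditional",
                         "Relative", "Topic", "Focus")
  x
}

default_cross_subject_sw <- function() {
  c(affirmative = 4L, conditional = 10L, doubt_question = 5L, emphasis = 10L,
    relative = 10L, topic = 10L, wh_question = 2L, negative = 6L,
    yn_question = 10L)
}

#' Build a run configuration
#'
#' Central configuration object consumed by feature extraction, windowing,
#' the soft-vote ensemble and the evaluation protocols. All landmark
#' indices are 0-based (see [landmark_selection()]).
#'
#' By default the distance pair list is formed from consecutive disjoint
#' pairs of the flattened landmark selection (in listed region order), and
#' the angle triple list from consecutive disjoint triples; both can be
#' overridden explicitly.
#'
#' @param selection `"user_dependent"` (default) or `"user_independent"`,
#'   or a named list of index vectors like [landmark_selection()] returns.
#' @param pair_list List of 2-element integer vectors (distance endpoints);
#'   `NULL` derives it from `selection`.
#' @param triple_list List of 3-element integer vectors (angle point
#'   triples); `NULL` derives it from `selection`.
#' @param window_size Sliding-window length in frames (`sw`), default 10.
#' @param window_stride Window stride in frames, default 1 (slide one
#'   frame at a time).
#' @param label_rule Window labeling policy: `"majority"` (ties count as
#'   positive), `"last"`, or `"all"`.
#' @param normalization `"zscore"` (per-feature standardization, fitted on
#'   training data only) or `"none"`.
#' @param seed Integer seed controlling every stochastic step downstream.
#' @param classifier_params Named list passed to the random-forest backend
#'   ([ranger::ranger()]); defaults to 300 trees.
#' @param weights Soft-vote weights for the three perspective classifiers;
#'   default uniform.
#' @param doubt_descriptors Use the statistical-descriptor window variant
#'   (with area/eccentricity shape features) for the doubt expression.
#' @param shape_groups Landmark groups for the shape features, default
#'   [doubt_shape_groups()].
#' @param cross_subject_sw Named integer vector of per-expression window
#'   sizes for the cross-subject protocol.
#' @param collinear How [principal_axes_ratio()] treats (near-)collinear
#'   point sets: `"error"` or `"inf"`.
#' @return Object of class `gfe_config` (a validated named list).
#' @export
gfe_config <- function(selection = "user_dependent",
                       pair_list = NULL,
                       triple_list = NULL,
                       window_size = 10L,
                       window_stride = 1L,
                       label_rule = c("majority", "last", "all"),
                       normalization = c("zscore", "none"),
                       seed = 1L,
                       classifier_params = list(num.trees = 300L),
                       weights = c(1, 1, 1) / 3,
                       doubt_descriptors = TRUE,
                       shape_groups = doubt_shape_groups(),
                       cross_subject_sw = default_cross_subject_sw(),
                       collinear = c("error", "inf")) {
  if (is.character(selection)) selection <- landmark_selection(selection)
  if (!is.list(selection) || is.null(names(selection))) {
    stopf("`selection` must be a selection name or a named list of index vectors")
  }
  flat <- unlist(selection, use.names = FALSE)
  if (is.null(pair_list)) pair_list <- consecutive_pairs(flat)
  if (is.null(triple_list)) triple_list <- consecutive_triples(flat)
  cfg <- structure(list(
    selection = lapply(selection, as.integer),
    pair_list = lapply(pair_list, as.integer),
    triple_list = lapply(triple_list, as.integer),
    window_size = as.integer(window_size),
    window_stride = as.integer(window_stride),
    label_rule = match.arg(label_rule),
    normalization = match.arg(normalization),
    seed = as.integer(seed),
    classifier_params = classifier_params,
    weights = as.numeric(weights),
    doubt_descriptors = isTRUE(doubt_descriptors),
    shape_groups = lapply(shape_groups, as.integer),
    cross_subject_sw = cross_subject_sw,
    collinear = match.arg(collinear)
  ), class = "gfe_config")
  validate_config(cfg)
}

validate_config <- function(cfg) {
  bad <- character(0)
  chk <- function(cond, key) if (!cond) bad <<- c(bad, key)
  chk(is_count(cfg$window_size, 1L), "window_size (must be >= 1)")
  chk(is_count(cfg$window_stride, 1L), "window_stride (must be >= 1)")
  all_idx <- c(unlist(cfg$selection), unlist(cfg$pair_list),
               unlist(cfg$triple_list), unlist(cfg$shape_groups))
  chk(all(all_idx >= 0L & all_idx <= 99L), "landmark indices (must lie in 0..99)")
  chk(all(vapply(cfg$pair_list, function(p)
    length(p) == 2L && !anyDuplicated(p), logical(1))),
    "pair_list (entries must be 2 distinct indices)")
  chk(all(vapply(cfg$triple_list, function(p)
    length(p) == 3L && !anyDuplicated(p), logical(1))),
    "triple_list (entries must be 3 distinct indices)")
  chk(length(cfg$weights) == 3L && all(cfg$weights >= 0) &&
        sum(cfg$weights) > 0, "weights (3 non-negative, not all zero)")
  chk(all(gfe_expressions() %in% names(cfg$cross_subject_sw)) &&
        all(cfg$cross_subject_sw >= 1),
      "cross_subject_sw (needs one size >= 1 per expression)")
  chk(is.list(cfg$classifier_params), "classifier_params (must be a list)")
  if (length(bad)) {
    stopf("invalid configuration: %s", paste(bad, collapse = "; "))
  }
  cfg
}

#' Load a run configuration from a YAML file
#'
#' Reads a YAML mapping whose keys are the arguments of [gfe_config()] and
#' merges it over the defaults. Unknown keys are an error (they are listed
#' in the message), so typos never pass silently. An empty file yields the
#' full default configuration.
#'
#' `pair_list` / `triple_list` entries are given as YAML sequences of
#' 2- or 3-element index sequences (0-based).
#'
#' @param path Path to a YAML config file.
#' @return A `gfe_config` object.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file not found: %s", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stopf("config file must be a YAML mapping: %s", path)
  known <- names(formals(gfe_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stopf("unknown config keys: %s (known keys: %s)",
          paste(unknown, collapse = ", "), paste(known, collapse = ", "))
  }
  if (!is.null(raw$cross_subject_sw)) {
    raw$cross_subject_sw <- unlist(raw$cross_subject_sw)
  }
  if (!is.null(raw$weights)) raw$weights <- as.numeric(unlist(raw$weights))
  do.call(gfe_config, raw)
}

#' @export
print.gfe_config <- function(x, ...) {
  cat("<gfe_config>\n")
  cat(sprintf("  regions: %s\n", paste(names(x$selection), collapse = ", ")))
  cat(sprintf("  features/frame: %d distances, %d angles (plus depths)\n",
              length(x$pair_list), length(x$triple_list)))
  cat(sprintf("  window: sw=%d stride=%d label_rule=%s\n",
              x$window_size, x$window_stride, x$label_rule))
  cat(sprintf("  normalization: %s  seed: %d\n", x$normalization, x$seed))
  invisible(x)
}
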