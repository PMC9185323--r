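#' Region map of the synthetic 100-point face template
#'
#' Index layout (0-based) of [base_face()], chosen so that every landmark
#' index cited by the feature selections and shape groups falls in a
#' plausible face region: left eye 0-7, right eye 8-15, left eyebrow
#' 16-25 with its upper edge 90-94, right eyebrow 26-35, nose 36-47 with
#' tip 89, outer mouth 48-59, inner mouth 60-67, face contour 68-88,
#' forehead 95-99. The sets are disjoint and cover 0..99.
#'
#' @return Named list of 0-based integer index vectors.
#' @export
face_regions <- function() {
  list(
    left_eye       = 0:7,
    right_eye      = 8:15,
    left_eyebrow   = 16:25,
    right_eyebrow  = 26:35,
    nose           = 36:47,
    mouth_outer    = 48:59,
    mouth_inner    = 60:67,
    contour        = 68:88,
    nose_tip       = 89L,
    left_eyebrow_upper = 90:94,
    forehead       = 95:99
  )
}

ellipse_points <- function(cx, cy, rx, ry, n, phase = 0) {
  th <- phase + 2 * pi * (seq_len(n) - 1) / n
  cbind(cx + rx * cos(th), cy + ry * sin(th))
}

arc_points <- function(x0, x1, y, n, bow = 6) {
  x <- seq(x0, x1, length.out = n)
  u <- (x - (x0 + x1) / 2) / ((x1 - x0) / 2)
  cbind(x, y - bow * (1 - u^2))
}

#' Neutral synthetic face template
#'
#' A deterministic 100-point neutral face in image coordinates (x, y in
#' pixels, origin top-left so larger y is lower on the face; z in depth
#' units around 1000). Two calls always return the identical template.
#'
#' @return A 100 x 3 numeric matrix (one landmark per row).
#' @export
base_face <- function() {
  P <- matrix(0, 100L, 3L)
  r <- face_regions()
  set_xy <- function(idx, xy, z) {
    P[idx + 1L, 1:2] <<- xy
    P[idx + 1L, 3] <<- z
  }
  set_xy(r$left_eye,  ellipse_points(270, 230, 18, 9, 8), 980)
  set_xy(r$right_eye, ellipse_points(370, 230, 18, 9, 8), 980)
  set_xy(r$left_eyebrow,  arc_points(238, 302, 205, 10), 985)
  set_xy(r$right_eyebrow, arc_points(338, 402, 205, 10), 985)
  set_xy(r$left_eyebrow_upper, arc_points(243, 297, 196, 5), 986)
  # nose: bridge down the midline then nostril flare
  set_xy(r$nose, cbind(c(seq(320, 320, length.out = 6), 300, 308, 316, 324, 332, 340),
                       c(seq(225, 275, length.out = 6), rep(285, 6))), 955)
  set_xy(r$nose_tip, c(320, 282), 930)
  set_xy(r$mouth_outer, ellipse_points(320, 330, 40, 16, 12), 965)
  set_xy(r$mouth_inner, ellipse_points(320, 330, 25, 8, 8), 968)
  set_xy(r$contour, ellipse_points(320, 260, 110, 140, 21, phase = pi / 2), 1050)
  set_xy(r$forehead, cbind(seq(290, 350, length.out = 5), rep(160, 5)), 1000)
  P
}

group_contract <- function(P, idx, rate) {
  ctr <- colMeans(P[idx + 1L, 1:2, drop = FALSE])
  off <- matrix(0, 100L, 3L)
  off[idx + 1L, 1:2] <- -rate * sweep(P[idx + 1L, 1:2, drop = FALSE], 2, ctr)
  off
}

#' Unit deformation template for an expression
#'
#' Translates the qualitative description of each grammatical expression
#' into per-landmark displacement directions on the neutral face: e.g.
#' raised eyebrows for relative/topic/yes-no questions, lowered mouth
#' corners and brows for negation, head motion as a rigid component, and
#' a contraction of the eyes and mouth for interrogative doubt (which is
#' what makes the area/eccentricity shape features informative there).
#' The returned matrix is the displacement applied per unit of
#' `effect_size` (roughly 1 px of peak motion per unit).
#'
#' @param expression One of [gfe_expressions()].
#' @param base The neutral template from [base_face()].
#' @return A 100 x 3 displacement matrix.
#' @export
expression_template <- function(expression, base = base_face()) {
  r <- face_regions()
  brows <- c(r$left_eyebrow, r$right_eyebrow, r$left_eyebrow_upper)
  mouth <- c(r$mouth_outer, r$mouth_inner)
  off <- matrix(0, 100L, 3L)
  add_y <- function(idx, dy) off[idx + 1L, 2] <<- off[idx + 1L, 2] + dy
  add_x <- function(idx, dx) off[idx + 1L, 1] <<- off[idx + 1L, 1] + dx
  add_z <- function(idx, dz) off[idx + 1L, 3] <<- off[idx + 1L, 3] + dz
  all_idx <- 0:99
  # raised brows pull the upper eyelids up and drop the lower lids a
  # little (the eye aperture widens with the brow)
  upper_lids <- c(5:7, 13:15); lower_lids <- c(1:3, 9:11)
  raise_brows <- function(amount) {
    add_y(brows, -amount)
    add_y(upper_lids, -0.4 * amount); add_y(lower_lids, 0.2 * amount)
  }
  switch(expression,
    affirmative = {              # head nod: face drops and tips forward
      add_y(all_idx, 0.8); add_z(all_idx, -0.5); add_y(brows, 0.3)
    },
    conditional = {              # raised brows + head tilts toward the sensor
      raise_brows(1)
      ctr <- c(320, 260)
      rel <- sweep(base[, 1:2], 2, ctr)
      off[, 1] <- off[, 1] - 0.004 * rel[, 2]
      off[, 2] <- off[, 2] + 0.004 * rel[, 1]
      add_z(all_idx, -0.4)
    },
    doubt_question = {           # slight contraction of eyes and mouth
      off <- off + group_contract(base, r$left_eye, 0.03) +
        group_contract(base, r$right_eye, 0.03) +
        group_contract(base, mouth, 0.03)
      add_y(brows, 0.3); add_z(all_idx, 0.3)
    },
    emphasis = {                 # brows up, mouth opens, slight lean in
      raise_brows(1)
      lower <- mouth[base[mouth + 1L, 2] > 330]
      add_y(lower, 0.8); add_z(all_idx, -0.3)
    },
    negative = {                 # mouth corners/brows down, head turns aside
      corners <- c(48L, 54L)     # outer-mouth ellipse extremes
      add_y(corners, 1); add_y(mouth, 0.3); add_y(brows, 0.6)
      off[, 3] <- off[, 3] + 0.004 * (base[, 1] - 320)  # yaw: depth gradient
    },
    relative = {                 # raised brows, head eases back
      raise_brows(1); add_z(all_idx, 0.4)
    },
    topic = {                    # raised brows + head up and back
      raise_brows(0.8); add_y(all_idx, -0.4); add_z(all_idx, 0.4)
    },
    wh_question = {              # furrowed brows, head toward the sensor
      add_y(brows, 0.8)
      add_x(r$left_eyebrow, 0.4); add_x(r$left_eyebrow_upper, 0.4)
      add_x(r$right_eyebrow, -0.4)
      add_z(all_idx, -0.8)
    },
    yn_question = {              # raised brows, head toward the sensor
      raise_brows(1); add_z(all_idx, -0.8)
    },
    stopf("unknown expression '%s'", expression)
  )
  off
}

rigid_subject_transform <- function(P, angle = 0.05,
                                    shift = c(15, -10, 30),
                                    center = c(320, 260)) {
  rel <- sweep(P[, 1:2], 2, center)
  rot <- cbind(cos(angle) * rel[, 1] - sin(angle) * rel[, 2],
               sin(angle) * rel[, 1] + cos(angle) * rel[, 2])
  out <- P
  out[, 1:2] <- sweep(rot, 2, center, "+")
  sweep(out, 2, shift, "+")
}

# Strong non-rigid subject deformation: a short-wavelength sinusoidal
# image-plane warp (different facial proportions) combined with a
# saturating compression of the depth profile (a much flatter face, which
# attenuates depth responses landmark-dependently). Unlike a rigid
# offset, this distorts the relationships between features, so
# per-feature standardization cannot fully absorb it and cross-subject
# transfer genuinely degrades.
nonlinear_subject_transform <- function(P, amplitude = 8, depth_scale = 15) {
  out <- P
  out[, 1] <- P[, 1] + amplitude * sin(P[, 2] / 15)
  out[, 2] <- P[, 2] + amplitude * sin(P[, 1] / 20)
  out[, 3] <- 1000 + depth_scale * tanh((P[, 3] - 1000) / depth_scale) +
    0.25 * amplitude * sin((P[, 1] + P[, 2]) / 25)
  out
}

#' Episode amplitude profile
#'
#' Amplitude of the expression deformation along an episode of `duration`
#' frames: ramps linearly up over the first two frames and down over the
#' last two (1/3, 2/3, 1, ..., 1, 2/3, 1/3), so windows straddling an
#' episode boundary see genuinely ambiguous frames.
#'
#' @param duration Episode length in frames (>= 1).
#' @return Numeric vector of length `duration` in (0, 1].
#' @export
episode_ramp <- function(duration) {
  i <- seq_len(duration)
  pmin(1, i / 3, (duration + 1 - i) / 3)
}

#' Specification of one simulated landmark sequence
#'
#' @param expression One of [gfe_expressions()].
#' @param n_frames Sequence length in frames (default 2700, ninety seconds of
#'   30 fps video).
#' @param episodes Data frame with 0-based `start` and `duration` columns;
#'   episodes must lie within the sequence and not overlap. Frames inside
#'   an episode are labeled positive.
#' @param effect_size Peak deformation amplitude in coordinate units
#'   (pixels), default 10.
#' @param noise_sd Standard deviation of iid Gaussian jitter added to
#'   every coordinate, default 1.5.
#' @param subject 1 or 2; subject 2 is viewed under a subject transform.
#' @param subject_deform `"none"`, `"rigid"` (translation + small in-plane
#'   rotation) or `"nonlinear"` (smooth sinusoidal warp).
#' @param seed Integer seed.
#' @return Object of class `sim_spec`.
#' @export
sim_spec <- function(expression, n_frames = 2700L,
                     episodes = default_episodes(n_frames),
                     effect_size = 10, noise_sd = 1.0,
                     subject = 1L,
                     subject_deform = c("none", "rigid", "nonlinear"),
                     seed = 1L) {
  subject_deform <- match.arg(subject_deform)
  stopifnot(is_count(n_frames, 2L), effect_size >= 0, noise_sd >= 0)
  episodes <- as.data.frame(episodes)
  if (!all(c("start", "duration") %in% names(episodes))) {
    stopf("episodes must have 'start' and 'duration' columns")
  }
  if (nrow(episodes)) {
    ok <- episodes$start >= 0 & episodes$duration >= 1 &
      episodes$start + episodes$duration <= n_frames
    if (!all(ok)) {
      stopf("episode schedule out of range for %d frames (rows %s)",
            n_frames, paste(which(!ok), collapse = ", "))
    }
    ord <- order(episodes$start)
    ends <- episodes$start[ord] + episodes$duration[ord]
    if (nrow(episodes) > 1 && any(ends[-nrow(episodes)] > episodes$start[ord][-1])) {
      stopf("episode schedule has overlapping episodes")
    }
  }
  structure(list(expression = expression, n_frames = as.integer(n_frames),
                 episodes = episodes, effect_size = effect_size,
                 noise_sd = noise_sd, subject = as.integer(subject),
                 subject_deform = subject_deform, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Default episode schedule
#'
#' Expression episodes of 40 frames each (about 1.3 s of expression at
#' 30 fps; shorter when the sequence cannot hold them), one per ~125
#' frames of video so the positive-frame fraction sits near 0.3, spread
#' with a small seeded start jitter. Episodes never overlap: each lives
#' in its own equal slot of the sequence and the jitter is capped by the
#' slack in the slot.
#'
#' @param n_frames Sequence length.
#' @param n_episodes Number of episodes; defaults to one per 125 frames
#'   (at least 3).
#' @param duration Episode duration in frames; `NULL` picks 40 or half
#'   the per-episode slot, whichever is smaller.
#' @param jitter Maximum absolute start jitter in frames.
#' @param seed Seed for the jitter.
#' @return Data frame with `start` and `duration`.
#' @export
default_episodes <- function(n_frames = 2700L,
                             n_episodes = max(3L, round(n_frames / 125)),
                             duration = NULL,
                             jitter = 8L, seed = 1L) {
  slot <- n_frames %/% n_episodes
  if (is.null(duration)) duration <- max(1L, min(40L, slot %/% 2L))
  if (duration > slot) stopf("duration %d does not fit %d episodes in %d frames",
                             duration, n_episodes, n_frames)
  jitter <- min(jitter, (slot - duration) %/% 2L)
  base <- (seq_len(n_episodes) - 1L) * slot + (slot - duration) %/% 2L
  j <- if (jitter > 0L) {
    with_local_seed(seed,
                    sample.int(2L * jitter + 1L, n_episodes, replace = TRUE) - jitter - 1L)
  } else rep(0L, n_episodes)
  start <- pmin(pmax(base + j, 0L), n_frames - duration)
  data.frame(start = as.integer(start), duration = as.integer(duration))
}

#' Simulate one labeled landmark sequence
#'
#' Frames are the neutral [base_face()] plus the expression's deformation
#' template scaled by `effect_size` and the [episode_ramp()] amplitude
#' (zero outside episodes), passed through the subject transform, plus iid
#' Gaussian coordinate noise. Labels are positive exactly on episode
#' frames. Fully deterministic under the spec's seed.
#'
#' @param spec A [sim_spec()].
#' @return A [landmark_sequence()].
#' @export
simulate_sequence <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  base <- base_face()
  tmpl <- expression_template(spec$expression, base)
  amp <- numeric(spec$n_frames)
  labels <- integer(spec$n_frames)
  for (e in seq_len(nrow(spec$episodes))) {
    st <- spec$episodes$start[e]; du <- spec$episodes$duration[e]
    idx <- st + seq_len(du)
    amp[idx] <- episode_ramp(du)
    labels[idx] <- 1L
  }
  transform <- switch(spec$subject_deform,
                      none = identity,
                      rigid = rigid_subject_transform,
                      nonlinear = nonlinear_subject_transform)
  noise <- with_local_seed(spec$seed,
                           array(stats::rnorm(spec$n_frames * 300L, sd = spec$noise_sd),
                                 dim = c(spec$n_frames, 100L, 3L)))
  pts <- array(0, dim = c(spec$n_frames, 100L, 3L))
  for (i in seq_len(spec$n_frames)) {
    P <- base + spec$effect_size * amp[i] * tmpl
    pts[i, , ] <- transform(P) + noise[i, , ]
  }
  landmark_sequence(pts, labels, subject_id = spec$subject,
                    expression = spec$expression)
}

#' Simulate a full two-subject study
#'
#' Generates the 18 labeled sequences the evaluation protocols expect
#' (two virtual subjects x nine expressions), optionally writing each as
#' a landmark/label file pair plus a JSON manifest recording every
#' sequence's simulation spec, so a study can be regenerated exactly.
#'
#' @param seed Master seed; each sequence derives its own sub-seed.
#' @param n_frames,effect_size,noise_sd Per-sequence parameters (see
#'   [sim_spec()]).
#' @param subject_deform Transform applied to subject 2: `"rigid"`
#'   (default; subject 2 differs by a rigid offset) or `"nonlinear"`
#'   (strong smooth warp, a hard cross-subject condition).
#' @param out_dir Optional directory; when given, writes
#'   `subject<k>_<expression>_datapoints.txt` / `_targets.txt` pairs and
#'   `manifest.json`.
#' @return Object of class `gfe_study`: list with `sequences` (named list
#'   of 18 [landmark_sequence()]s) and `manifest` (data frame of specs).
#' @export
simulate_study <- function(seed = 1L, n_frames = 2700L, effect_size = 10,
                           noise_sd = 1.0,
                           subject_deform = c("rigid", "nonlinear"),
                           out_dir = NULL) {
  subject_deform <- match.arg(subject_deform)
  exprs <- gfe_expressions()
  sequences <- list()
  manifest <- list()
  counter <- 0L
  for (subject in 1:2) {
    for (ex in exprs) {
      counter <- counter + 1L
      sseed <- derive_seed(seed, counter)
      spec <- sim_spec(ex, n_frames = n_frames,
                       episodes = default_episodes(n_frames,
                                                   seed = derive_seed(sseed, 1L)),
                       effect_size = effect_size, noise_sd = noise_sd,
                       subject = subject,
                       subject_deform = if (subject == 2L) subject_deform else "none",
                       seed = sseed)
      seq <- simulate_sequence(spec)
      nm <- sprintf("subject%d_%s", subject, ex)
      sequences[[nm]] <- seq
      manifest[[nm]] <- data.frame(
        name = nm, subject = subject, expression = ex,
        n_frames = spec$n_frames, effect_size = spec$effect_size,
        noise_sd = spec$noise_sd, subject_deform = spec$subject_deform,
        seed = spec$seed,
        episodes = paste(sprintf("%d+%d", spec$episodes$start,
                                 spec$episodes$duration), collapse = ";"))
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  study <- structure(list(sequences = sequences, manifest = manifest,
                          seed = as.integer(seed)),
                     class = "gfe_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(sequences)) {
      write_landmark_file(sequences[[nm]],
                          file.path(out_dir, paste0(nm, "_datapoints.txt")),
                          file.path(out_dir, paste0(nm, "_targets.txt")))
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  }
  study
}

#' @export
print.gfe_study <- function(x, ...) {
  cat(sprintf("<gfe_study> %d sequences (2 subjects x %d expressions), seed %d\n",
              length(x$sequences), length(gfe_expressions()), x$seed))
  invisible(x)
}

#' Read a simulated study back from disk
#'
#' Loads the file pairs written by [simulate_study()] using its
#' `manifest.json`.
#'
#' @param dir Directory containing the study files and manifest.
#' @return A `gfe_study` (without regeneration seeds applied; sequences
#'   are read from the files).
#' @export
read_study <- function(dir) {
  mpath <- file.path(dir, "manifest.json")
  if (!file.exists(mpath)) stopf("no manifest.json in %s", dir)
  manifest <- jsonlite::fromJSON(mpath)
  sequences <- list()
  for (i in seq_len(nrow(manifest))) {
    nm <- manifest$name[i]
    sequences[[nm]] <- read_landmark_file(
      file.path(dir, paste0(nm, "_datapoints.txt")),
      file.path(dir, paste0(nm, "_targets.txt")),
      subject_id = manifest$subject[i],
      expression = manifest$expression[i])
  }
  structure(list(sequences = sequences, manifest = manifest,
                 seed = NA_integer_),
            class = "gfe_study")
}
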