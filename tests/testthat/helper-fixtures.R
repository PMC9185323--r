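# Small fixtures built in code at test time.

# A compact configuration over a handful of landmarks: 3 distance pairs
# with 4 distinct endpoints, 2 angle triples.
tiny_config <- function(...) {
  gfe_config(selection = list(probe = c(0L, 1L, 2L, 3L, 10L, 11L)),
             pair_list = list(c(0L, 1L), c(2L, 3L), c(0L, 2L)),
             triple_list = list(c(0L, 1L, 2L), c(1L, 2L, 3L)),
             ...)
}

random_frame <- function(seed = 1) {
  set.seed(seed)
  cbind(runif(100, 100, 500), runif(100, 100, 400), runif(100, 900, 1100))
}

# Hand-made feature track with controllable per-frame values.
toy_track <- function(dmat, amat, zmat, labels, id = "toy") {
  structure(list(distances = dmat, angles = amat, depths = zmat,
                 labels = labels, sequence_id = id),
            class = "feature_track")
}

# A windowed dataset with two well-separated classes: per-frame features
# shift by `delta` during labeled blocks. Non-overlapping windows.
separable_windows <- function(n_frames = 120, sw = 4, delta = 6, seed = 1,
                              noise = 0.5) {
  set.seed(seed)
  labels <- rep(rep(c(0L, 1L), each = 2 * sw), length.out = n_frames)
  shift <- delta * labels
  dmat <- matrix(rnorm(n_frames * 3, sd = noise), n_frames, 3) + shift
  amat <- matrix(rnorm(n_frames * 2, sd = noise), n_frames, 2) - shift
  zmat <- matrix(rnorm(n_frames * 2, sd = noise), n_frames, 2) + shift
  colnames(dmat) <- paste0("d", 0:2)
  colnames(amat) <- paste0("a", 0:1)
  colnames(zmat) <- paste0("z", 0:1)
  cfg <- tiny_config(window_size = sw, window_stride = sw,
                     classifier_params = list(num.trees = 100L))
  build_windows(toy_track(dmat, amat, zmat, labels), cfg = cfg)
}

fast_cfg <- function(...) gfe_config(classifier_params = list(num.trees = 100L), ...)

# A small simulated expression task, windowed with the one-frame-overlap
# protocol stride.
small_task <- function(expression = "relative", n_frames = 600, seed = 1,
                       effect_size = 10, noise_sd = 1, cfg = fast_cfg()) {
  s <- simulate_sequence(sim_spec(expression, n_frames = n_frames,
                                  effect_size = effect_size,
                                  noise_sd = noise_sd, seed = seed))
  sequence_windows(s, cfg, stride = cfg$window_size - 1L)
}
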