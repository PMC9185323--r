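test_that("window labels follow the documented policies", {
  expect_equal(window_label(c(1, 1, 1, 0, 0), "majority"), 1L)
  expect_equal(window_label(c(1, 0), "majority"), 1L)       # tie -> positive
  expect_equal(window_label(c(0, 0, 1, 0, 0), "majority"), 0L)
  expect_equal(window_label(c(0, 0, 0, 1), "last"), 1L)
  expect_equal(window_label(c(1, 1, 0), "all"), 0L)
  expect_equal(window_label(c(1, 1, 1), "all"), 1L)
  expect_error(window_label(c(1, 0), "mode"), "unknown")
})

test_that("every all-positive window is majority-positive (policy monotonicity)", {
  set.seed(21)
  for (i in 1:100) {
    lab <- rbinom(sample(2:12, 1), 1, 0.5)
    if (window_label(lab, "all") == 1L) {
      expect_equal(window_label(lab, "majority"), 1L)
    }
  }
})

test_that("perspective splits are contiguous near-equal thirds that rebuild the input", {
  s1 <- split_perspectives(1:36, sw = 9, per_frame_len = 4)
  expect_equal(lengths(s1), c(p1 = 12L, p2 = 12L, p3 = 12L))
  expect_equal(s1$p2[1], 13L)                       # boundary at frame 3
  s2 <- split_perspectives(1:90, sw = 10, per_frame_len = 9)
  expect_equal(lengths(s2), c(p1 = 30L, p2 = 30L, p3 = 30L))
  s3 <- split_perspectives(1:7)
  expect_equal(lengths(s3), c(p1 = 3L, p2 = 2L, p3 = 2L))
  expect_error(split_perspectives(1:10, sw = 3, per_frame_len = 4), "length")
  set.seed(13)
  for (i in 1:200) {
    v <- rnorm(sample(3:200, 1))
    sp <- split_perspectives(v)
    expect_identical(c(sp$p1, sp$p2, sp$p3), v)
    expect_lte(max(lengths(sp)) - min(lengths(sp)), 1L)
  }
})

test_that("window counts equal sfe - sw at stride 1", {
  set.seed(17)
  for (i in 1:30) {
    sfe <- sample(12:80, 1)
    sw <- sample(2:min(11, sfe - 1), 1)
    cfg <- tiny_config(window_size = sw, window_stride = 1L)
    track <- toy_track(matrix(rnorm(sfe * 3), sfe, 3),
                       matrix(rnorm(sfe * 2), sfe, 2),
                       matrix(rnorm(sfe * 2), sfe, 2),
                       rbinom(sfe, 1, 0.4))
    expect_equal(n_windows(build_windows(track, cfg = cfg)), sfe - sw)
  }
  cfg <- tiny_config(window_size = 10L)
  track <- toy_track(matrix(0, 11, 3), matrix(0, 11, 2), matrix(0, 11, 2),
                     rep(0L, 11))
  ds <- build_windows(track, cfg = cfg)
  expect_equal(n_windows(ds), 1L)
  expect_equal(ds$t, 0L)                            # covers frames 0..9
  short <- toy_track(matrix(0, 10, 3), matrix(0, 10, 2), matrix(0, 10, 2),
                     rep(0L, 10))
  expect_error(build_windows(short, cfg = cfg), "too short")
})

test_that("flattened windows interleave features per frame", {
  sfe <- 15
  dmat <- matrix(seq_len(sfe * 3), sfe, 3)          # distinctive values
  amat <- matrix(seq_len(sfe * 2) + 1000, sfe, 2)
  zmat <- matrix(seq_len(sfe * 2) + 2000, sfe, 2)
  colnames(dmat) <- paste0("d", 0:2)
  colnames(amat) <- paste0("a", 0:1)
  colnames(zmat) <- paste0("z", 0:1)
  cfg <- tiny_config(window_size = 10L)
  ds <- build_windows(toy_track(dmat, amat, zmat, rep(0L, sfe)), cfg = cfg)
  expect_equal(ncol(ds$x), 10 * (3 + 2 + 4 - 2))    # 3 d + 2 a + 2 z per frame
  w1 <- ds$x[1, ]
  manual <- as.vector(t(cbind(dmat, amat, zmat)[1:10, ]))
  expect_equal(unname(w1), manual)
  expect_equal(ds$feature_names[1:8],
               c("d0_f0", "d1_f0", "d2_f0", "a0_f0", "a1_f0", "z0_f0", "z1_f0",
                 "d0_f1"))
  # a window of 10 frames with 3 distances, 2 angles, 4 depths flattens to 90
  cfg4 <- gfe_config(selection = list(probe = 0:5),
                     pair_list = list(c(0L, 1L), c(2L, 3L), c(0L, 2L)),
                     triple_list = list(c(0L, 1L, 2L), c(1L, 2L, 3L)))
  expect_equal(length(cfg4$pair_list) + length(cfg4$triple_list) + 4, 9)
})

test_that("descriptor windows summarize each base feature with 7 statistics", {
  sfe <- 30
  cfg <- tiny_config(window_size = 5L, window_stride = 1L)
  dmat <- matrix(rnorm(sfe * 2), sfe, 2); colnames(dmat) <- c("d0", "d1")
  amat <- matrix(rnorm(sfe), sfe, 1); colnames(amat) <- "a0"
  areas <- matrix(7, sfe, 1); colnames(areas) <- "area_g"   # constant
  ecc <- matrix(rnorm(sfe) + 2, sfe, 1); colnames(ecc) <- "ecc_g"
  track <- toy_track(dmat, amat, matrix(0, sfe, 0), rbinom(sfe, 1, 0.5))
  expect_error(build_descriptor_windows(track, cfg = cfg), "shape")
  track$areas <- areas; track$eccentricities <- ecc
  ds <- build_descriptor_windows(track, cfg = cfg)
  expect_equal(ncol(ds$x), 5 * 7)                   # 5 base features x 7 stats
  expect_equal(n_windows(ds), sfe - 5)
  area_block <- ds$x[1, grepl("^area_g", ds$feature_names)]
  expect_equal(unname(area_block), c(7, 0, 7, 7, 7, 7, 7))
  d0_block <- ds$x[3, 1:7]                          # window frames 3..7 (1-based)
  expect_equal(unname(d0_block), unname(statistical_descriptors(dmat[3:7, 1])))
  # sw = 1 degenerates to per-frame singleton descriptors
  ds1 <- build_descriptor_windows(track, cfg = cfg, sw = 1L)
  expect_equal(unname(ds1$x[1, 1:7]),
               unname(statistical_descriptors(dmat[1, 1])))
})

test_that("combining and serializing windowed datasets preserves content", {
  ds <- separable_windows(n_frames = 64, sw = 4, seed = 2)
  both <- combine_windows(list(ds, ds))
  expect_equal(n_windows(both), 2 * n_windows(ds))
  expect_identical(both$feature_names, ds$feature_names)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_windows(ds, p)
  back <- read_windows(p, sw = ds$sw, stride = ds$stride)
  expect_equal(unname(back$x), unname(ds$x), tolerance = 1e-12)
  expect_identical(back$labels, ds$labels)
  expect_identical(back$slices, ds$slices)
})
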