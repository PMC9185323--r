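test_that("the neutral face template is fixed, complete and region-consistent", {
  expect_identical(base_face(), base_face())
  P <- base_face()
  expect_equal(dim(P), c(100L, 3L))
  expect_true(all(is.finite(P)))
  r <- face_regions()
  idx <- unlist(r)
  expect_equal(sort(unname(idx)), 0:99)                     # disjoint cover of 0..99
  # every landmark cited by the selections and shape groups is placed
  cited <- unique(c(unlist(landmark_selection("user_dependent")),
                    unlist(landmark_selection("user_independent")),
                    unlist(doubt_shape_groups())))
  expect_true(all(cited %in% idx))
  # the doubt shape groups are valid polygons on the template
  for (g in doubt_shape_groups()) {
    expect_gt(polygon_area(P[g + 1, 1:2]), 0)
  }
})

test_that("episode schedules stay in range, never overlap, and label exactly", {
  for (n in c(120, 300, 2700)) {
    ep <- default_episodes(n, seed = 2)
    expect_true(all(ep$start >= 0 & ep$start + ep$duration <= n))
    o <- order(ep$start)
    expect_true(all(ep$start[o][-1] >= (ep$start + ep$duration)[o][-nrow(ep)]))
    frac <- sum(ep$duration) / n
    expect_gte(frac, 0.2); expect_lte(frac, 0.8)
  }
  spec <- sim_spec("topic", n_frames = 200, seed = 5)
  s <- simulate_sequence(spec)
  lab <- integer(200)
  for (i in seq_len(nrow(spec$episodes))) {
    lab[spec$episodes$start[i] + seq_len(spec$episodes$duration[i])] <- 1L
  }
  expect_identical(s$labels, lab)
  expect_error(sim_spec("topic", n_frames = 50,
                        episodes = data.frame(start = 40, duration = 20)),
               "out of range")
  expect_error(sim_spec("topic", n_frames = 100,
                        episodes = data.frame(start = c(10, 20), duration = 15)),
               "overlapping")
})

test_that("simulation is deterministic and controlled by the effect size", {
  spec <- sim_spec("negative", n_frames = 80, seed = 9)
  expect_identical(simulate_sequence(spec)$points, simulate_sequence(spec)$points)
  # noiseless sequences deviate from the neutral face exactly by the template
  clean <- simulate_sequence(sim_spec("negative", n_frames = 80, noise_sd = 0,
                                      effect_size = 7, seed = 9))
  tmpl <- expression_template("negative")
  base <- base_face()
  neg_frame <- which(clean$labels == 0L)[1]
  expect_equal(clean$points[neg_frame, , ], base, tolerance = 1e-12)
  plateau <- which(clean$labels == 1L)
  plateau <- plateau[3:(length(plateau) - 3)][1]    # past the 2-frame ramp
  expect_equal(clean$points[plateau, , ], base + 7 * tmpl, tolerance = 1e-12)
  moved <- which(rowSums(abs(clean$points[plateau, , ] - base)) > 0)
  expect_true(all(rowSums(abs(tmpl))[moved] > 0))
  # zero effect: labeled frames are distributionally identical to unlabeled
  null <- simulate_sequence(sim_spec("negative", n_frames = 80, effect_size = 0,
                                     seed = 9))
  on_mean <- colMeans(null$points[null$labels == 1L, 20, ])
  off_mean <- colMeans(null$points[null$labels == 0L, 20, ])
  expect_lt(max(abs(on_mean - off_mean)), 1)
})

test_that("every expression template moves a selected landmark", {
  for (ex in gfe_expressions()) {
    tmpl <- expression_template(ex)
    expect_equal(dim(tmpl), c(100L, 3L))
    sel <- unique(c(unlist(landmark_selection("user_dependent")),
                    unlist(landmark_selection("user_independent"))))
    expect_gt(max(abs(tmpl[sel + 1, ])), 0)
  }
  expect_error(expression_template("smile"), "unknown expression")
})

test_that("a full study emits 18 parseable, byte-reproducible sequences", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  study <- simulate_study(seed = 4, n_frames = 60, out_dir = dir1)
  expect_length(study$sequences, 18)
  expect_equal(nrow(study$manifest), 18)
  subj <- vapply(study$sequences, `[[`, numeric(1), "subject_id")
  expect_equal(as.vector(table(subj)), c(9L, 9L))
  f1 <- list.files(dir1, pattern = "_datapoints\\.txt$")
  expect_length(f1, 18)
  back <- read_study(dir1)
  nm <- "subject2_topic"
  expect_equal(back$sequences[[nm]]$points, study$sequences[[nm]]$points,
               tolerance = 1e-9)
  expect_identical(back$sequences[[nm]]$labels, study$sequences[[nm]]$labels)
  simulate_study(seed = 4, n_frames = 60, out_dir = dir2)
  for (f in c(f1, "manifest.json")) {
    expect_identical(unname(tools::md5sum(file.path(dir1, f))),
                     unname(tools::md5sum(file.path(dir2, f))))
  }
})

test_that("recognition strengthens with effect size (generator monotonicity)", {
  cfg <- fast_cfg()
  med_f1 <- sapply(c(0, 0.5, 10), function(eff) {
    median(sapply(1:5, function(s) {
      st <- simulate_sequence(sim_spec("yn_question", n_frames = 450,
                                       effect_size = eff, seed = s))
      ds <- sequence_windows(st, cfg, stride = 9L)
      kfold_protocol(ds, cfg, k = 5, seed = s)[["f1"]]
    }))
  })
  expect_true(all(diff(med_f1) >= -1e-9))
  expect_lt(med_f1[1], 0.8)
  expect_gt(med_f1[3], 0.9)
})
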