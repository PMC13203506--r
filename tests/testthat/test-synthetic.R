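test_that("scene simulation is deterministic and respects the arena", {
  cfg <- scenario_config(n_targets = 5, n_frames = 100, seed = 2)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$gt, s2$gt)
  expect_equal(length(unique(s1$gt$id)), 5)
  expect_equal(max(s1$gt$frame), 100)
  expect_true(all(s1$gt$x >= 0 & s1$gt$x + s1$gt$w <= cfg$width + 1e-6))
  expect_true(all(s1$gt$y >= 0 & s1$gt$y + s1$gt$h <= cfg$height + 1e-6))
  # a different seed gives a different scene
  expect_false(identical(simulate_scene(scenario_config(n_targets = 5,
                                                        n_frames = 100,
                                                        seed = 3))$gt, s1$gt))
})

test_that("a single target never records occlusion", {
  s <- simulate_scene(scenario_config(n_targets = 1, n_frames = 200, seed = 4))
  expect_true(all(s$gt$hidden_frac == 0))
})

test_that("territory confinement keeps targets separated", {
  s <- simulate_scene(scenario_config(n_targets = 6, n_frames = 300,
                                      territories = TRUE, seed = 5))
  expect_true(all(s$gt$hidden_frac == 0))
  # minimum pairwise center distance stays positive and large
  for (fr in c(1, 150, 300)) {
    g <- s$gt[s$gt$frame == fr, ]
    cx <- g$x + g$w / 2; cy <- g$y + g$h / 2
    dmin <- min(dist(cbind(cx, cy)))
    expect_gt(dmin, 40)
  }
})

test_that("the reference 12-target scene contains sustained occlusion episodes", {
  s <- simulate_scene(scenario_config(seed = 1))
  occ <- s$gt$hidden_frac > 0.5
  # at least one occlusion interval of length >= 5 frames for some target
  runs <- tapply(occ, s$gt$id, function(v) {
    r <- rle(v); max(c(0, r$lengths[r$values]))
  })
  expect_gte(max(runs), 5)
})

test_that("noise-free emulation reproduces the ground truth exactly", {
  s <- simulate_scene(scenario_config(n_targets = 3, n_frames = 50, seed = 6))
  det <- emulate_detections(s, noise_config(base_miss = 0, occluded_miss = 0,
                                            jitter_sd = 0, fp_rate = 0,
                                            feature_dim = 0))
  expect_equal(nrow(det), nrow(s$gt))
  gt_sorted <- s$gt[order(s$gt$frame, s$gt$x), ]
  expect_equal(det$x, gt_sorted$x)
  expect_equal(det$y, gt_sorted$y)
  expect_equal(det$w, gt_sorted$w)
  expect_true(all(det$conf > 0 & det$conf <= 1))
})

test_that("fully hidden targets are dropped when the occluded miss rate is 1", {
  s <- simulate_scene(scenario_config(seed = 7, n_frames = 300))
  det <- emulate_detections(s, noise_config(base_miss = 0, occluded_miss = 1,
                                            jitter_sd = 0, fp_rate = 0,
                                            feature_dim = 0))
  n_occluded <- sum(s$gt$hidden_frac > 0.5)
  expect_gt(n_occluded, 0)
  expect_equal(nrow(det), nrow(s$gt) - n_occluded)
})

test_that("the confidence model hits its calibration targets", {
  draws <- withr::with_seed(8, draw_confidences(1e5))
  expect_lt(abs(mean(draws) - 0.87), 0.01)
  expect_lt(abs(mean(draws < 0.7) - 0.023), 0.005)
  expect_true(all(draws > 0 & draws <= 1))
})

test_that("emulated appearance features separate individuals but not observations", {
  s <- simulate_scene(scenario_config(n_targets = 6, n_frames = 100, seed = 9))
  det <- emulate_detections(s, noise_config(fp_rate = 0, base_miss = 0,
                                            occluded_miss = 0))
  truef <- attr(det, "true_features")
  expect_equal(length(truef), 6)
  # within-individual observation noise is well below between-individual spread
  between <- min(utils::combn(6, 2, function(ij) {
    cosine_distance(truef[[ij[1]]], truef[[ij[2]]])
  }))
  f_obs <- det$feature[1:50]
  expect_true(all(vapply(f_obs, function(f) abs(sum(f^2) - 1) < 1e-9, TRUE)))
  expect_gt(between, 0.02)
})

test_that("textured patches shift and unshift exactly", {
  p <- make_textured_patch(64, 11)
  expect_identical(shift_patch(p, 0, 0), p)
  expect_identical(shift_patch(shift_patch(p, 5, -3), -5, 3), p)
  expect_gt(sum(abs(diff(p))), 0)
  expect_identical(make_textured_patch(64, 11), p)
  expect_error(make_textured_patch(16), "at least 32")
})

test_that("ground truth survives a MOT write/read round trip byte-exactly", {
  s <- simulate_scene(scenario_config(n_targets = 3, n_frames = 30, seed = 12))
  f1 <- tempfile(fileext = ".txt"); f2 <- tempfile(fileext = ".txt")
  write_mot(s$gt, f1)
  back <- read_mot(f1)
  write_mot(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_equal(back$frame, s$gt$frame)
  expect_equal(back$x, s$gt$x, tolerance = 1e-4)
})
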