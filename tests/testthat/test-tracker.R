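# Orchestrator tests use small constructed detection streams; features are
# synthetic unit vectors so appearance matching is exercised without images.

steady_detections <- function(n_frames, cx0 = 100, cy0 = 100, vx = 0, vy = 0,
                              w = 40, h = 30, conf = 0.9, feat_seed = 1) {
  set.seed(feat_seed); f <- rnorm(16); f <- f / sqrt(sum(f^2))
  tibble::tibble(frame = seq_len(n_frames),
                 x = cx0 + vx * (seq_len(n_frames) - 1) - w / 2,
                 y = cy0 + vy * (seq_len(n_frames) - 1) - h / 2,
                 w = w, h = h, conf = conf,
                 feature = replicate(n_frames, f, simplify = FALSE))
}

test_that("a clean single-target stream keeps one identity with no filling", {
  det <- steady_detections(100, vx = 1.5)
  run <- track_detections(det)
  expect_equal(length(unique(run$results$id)), 1)
  expect_true(all(run$results$source == "detected"))
  # emission starts once the track is confirmed (n_init = 3)
  expect_equal(sort(unique(run$results$frame)), 3:100)
  g <- glance(run)
  expect_equal(g$n_filled, 0)
})

test_that("a brief detection gap is bridged by filling and the identity survives", {
  det <- steady_detections(100)
  det <- det[!(det$frame %in% 40:49), ]
  run <- track_detections(det, n_frames = 100)
  r <- run$results
  expect_equal(length(unique(r$id)), 1)
  expect_true(all(r$frame[r$source == "filled"] %in% 40:49))
  expect_equal(sum(r$source == "filled"), 10)
  # filled boxes stay on the stationary target
  filled <- r[r$source == "filled", ]
  expect_true(all(abs(filled$x + filled$w / 2 - 100) < 3))
  # the id before, during and after the gap is the same
  expect_equal(unique(r$id[r$frame < 40]), unique(r$id[r$frame > 49]))
  # fill counter resets after recovery: a later equal-length gap also bridged
  expect_true(all(r$conf[r$source == "filled"] == 0))
})

test_that("a gap longer than the fill budget kills the track and respawns a new id", {
  det <- steady_detections(100)
  det <- det[!(det$frame %in% 31:55), ]  # 25-frame gap > 20-frame budget
  run <- track_detections(det, n_frames = 100)
  r <- run$results
  ids <- unique(r$id)
  expect_equal(length(ids), 2)
  expect_true(any(run$events$event == "delete_fill_exhausted"))
  # exactly max_fill_frames filled outputs before deletion
  expect_equal(sum(r$source == "filled"), 20)
})

test_that("degraded fill without images equals the constant-velocity prediction", {
  det <- steady_detections(60, vx = 2)
  det <- det[det$frame != 31, ]
  run <- track_detections(det, n_frames = 60)
  filled <- run$results[run$results$source == "filled", ]
  expect_equal(nrow(filled), 1)
  # target moves 2 px/frame; the filled center continues the motion
  expect_lt(abs((filled$x + filled$w / 2) - (100 + 2 * 30)), 1)
})

test_that("resync accepts co-located in-gallery detections and rejects drifted or alien ones", {
  cfg <- duotrack_config()
  set.seed(21); f <- rnorm(16); f <- f / sqrt(sum(f^2))
  set.seed(22); f2 <- rnorm(16); f2 <- f2 / sqrt(sum(f2^2))
  track <- list(predicted_box = c(80, 85, 120, 115), gallery = list(f),
                status = "filling", fill_measured = TRUE)
  # detection exactly at the filled box with an in-gallery feature
  expect_true(resync(track, c(80, 85, 120, 115), f, cfg))
  # IoU ~0.1 against the filled box: below resync_iou = 0.3
  drifted <- c(80 + 33, 85, 120 + 33, 115)
  expect_lt(box_iou(track$predicted_box, drifted), 0.3)
  expect_false(resync(track, drifted, f, cfg))
  # co-located but alien appearance
  expect_false(resync(track, c(80, 85, 120, 115), f2, cfg))
  # featureless detections fall back to the position test alone
  expect_true(resync(track, c(82, 86, 122, 116), NULL, cfg))
  # in degraded (unmeasured) fill mode the position cutoff does not apply:
  # the Mahalanobis gate already validated position consistency
  track_deg <- track; track_deg$fill_measured <- FALSE
  expect_true(resync(track_deg, drifted, f, cfg))
  expect_false(resync(track_deg, drifted, f2, cfg))
})

test_that("recovery after a gap restores confirmed status and the detected flag", {
  det <- steady_detections(40)
  det <- det[!(det$frame %in% 20:29), ]
  run <- track_detections(det, n_frames = 40)
  r <- run$results
  expect_true(any(run$events$event == "resync"))
  expect_equal(unique(r$source[r$frame >= 30]), "detected")
  expect_equal(length(unique(r$id)), 1)
})

test_that("low-confidence matched detections are treated as detection failure", {
  det <- steady_detections(30)
  det$conf[15] <- 0.1  # below the 0.25 inference threshold
  run <- track_detections(det, n_frames = 30)
  r <- run$results
  expect_equal(r$source[r$frame == 15], "filled")
  expect_equal(length(unique(r$id)), 1)
})

test_that("conflict coverage removes the weaker of two duplicate lockers", {
  # two co-located detection streams emulate a duplicated identity
  a <- steady_detections(30, feat_seed = 1)
  b <- steady_detections(30, feat_seed = 2)
  b$x <- b$x + 3; b$conf <- 0.5
  b <- b[b$frame >= 10, ]
  det <- dplyr::bind_rows(a, b)
  det <- det[order(det$frame), ]
  run_on <- track_detections(det, n_frames = 30)
  # with the conflict pass the duplicate is culled quickly
  expect_true(any(run_on$events$event == "conflict_remove"))
  dup_on <- duotrack:::count_duplicate_events(run_on$results, 0.5)
  run_off <- track_detections(det, duotrack_config(conflict_enabled = FALSE),
                              n_frames = 30)
  dup_off <- duotrack:::count_duplicate_events(run_off$results, 0.5)
  expect_gt(dup_off, dup_on)
})

test_that("tracker output is deterministic", {
  set.seed(77)
  scene <- simulate_scene(scenario_config(n_targets = 4, n_frames = 60, seed = 3))
  det <- emulate_detections(scene)
  r1 <- track_detections(det, n_frames = 60)
  r2 <- track_detections(det, n_frames = 60)
  expect_identical(r1$results, r2$results)
})

test_that("track ids are never reused and grow monotonically", {
  scene <- simulate_scene(scenario_config(n_targets = 6, n_frames = 120, seed = 5))
  det <- emulate_detections(scene)
  run <- track_detections(det, n_frames = 120)
  spawns <- run$events$id[run$events$event == "spawn"]
  expect_false(any(duplicated(spawns)))
  expect_true(all(diff(spawns) > 0))
  # no frame emits the same id twice
  expect_false(any(duplicated(run$results[, c("frame", "id")])))
})

test_that("image-mode filling locks onto a stationary textured target", {
  # static scene: one textured target on a textured floor
  cfg <- scenario_config(n_targets = 1, n_frames = 45, width = 200, height = 160,
                         speed_range = c(0, 0), seed = 8)
  scene <- simulate_scene(cfg)
  tex <- scene_textures(scene)
  imgs <- lapply(seq_len(cfg$n_frames), function(fr) render_frame(scene, fr, tex))
  det <- emulate_detections(scene, noise_config(base_miss = 0, jitter_sd = 0.5,
                                                fp_rate = 0, feature_dim = 0))
  det <- det[!(det$frame %in% 21:40), ]
  run <- track_detections(det, images = imgs, n_frames = cfg$n_frames)
  filled <- run$results[run$results$source == "filled", ]
  expect_equal(nrow(filled), 20)
  truth <- scene$gt[scene$gt$frame == 1, ]
  expect_true(all(abs(filled$x + filled$w / 2 - (truth$x + truth$w / 2)) < 3))
  expect_true(all(abs(filled$y + filled$h / 2 - (truth$y + truth$h / 2)) < 3))
  expect_equal(length(unique(run$results$id)), 1)
})
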