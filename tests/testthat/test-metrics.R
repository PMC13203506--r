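perfect_scene <- function(n_frames = 20, n_ids = 3) {
  do.call(rbind, lapply(seq_len(n_ids), function(i) {
    tibble::tibble(frame = seq_len(n_frames), id = i,
                   x = 50 * i + seq_len(n_frames), y = 40 * i, w = 30, h = 24)
  }))
}

test_that("perfect predictions score perfectly", {
  gt <- perfect_scene()
  ev <- evaluate_tracking(gt, gt)
  expect_equal(ev$mota, 100)
  expect_equal(ev$motp, 100)
  expect_equal(ev$idf1, 100)
  expect_equal(ev$idsw, 0)
  expect_equal(ev$frag, 0)
  corr <- match_frames(gt, gt)
  expect_equal(nrow(corr$matches), nrow(gt))
})

test_that("empty predictions are all false negatives", {
  gt <- perfect_scene()
  corr <- match_frames(gt, gt[0, ])
  expect_equal(nrow(corr$matches), 0)
  cm <- clear_mot(corr)
  expect_equal(cm$fn, nrow(gt))
  expect_equal(cm$fp, 0)
  expect_error(clear_mot(match_frames(gt[0, ], gt)), "undefined")
})

test_that("the CLEAR-MOT counts follow the formula on constructed errors", {
  # 100 GT boxes; drop 5 (FN), add 3 spurious (FP), one mid-track id change
  gt <- perfect_scene(n_frames = 50, n_ids = 2)
  pred <- gt
  pred <- pred[-(1:5), ]                      # 5 FN
  pred$id[pred$id == 2 & pred$frame > 25] <- 9  # 1 IDSw on gt track 2
  fp <- tibble::tibble(frame = 1:3, id = 99, x = 500, y = 400, w = 30, h = 24)
  cm <- clear_mot(match_frames(gt, rbind(pred, fp)))
  expect_equal(cm$fn, 5)
  expect_equal(cm$fp, 3)
  expect_equal(cm$idsw, 1)
  expect_equal(cm$mota, 100 * (1 - (5 + 3 + 1) / 100))
  # the dropped opening frames also fragment nothing (gap is at the start)
  expect_equal(cm$frag, 0)
})

test_that("a mid-trajectory dropout counts as one fragmentation", {
  gt <- perfect_scene(n_frames = 30, n_ids = 1)
  pred <- gt[!(gt$frame %in% 10:12), ]
  cm <- clear_mot(match_frames(gt, pred))
  expect_equal(cm$frag, 1)
  expect_equal(cm$idsw, 0)
})

test_that("IDF1 matches hand-derivable cases and the exhaustive-bijection oracle", {
  gt <- perfect_scene(n_frames = 40, n_ids = 2)
  # ids swap halfway, equal lengths: the best bijection covers half the boxes
  pred <- gt
  sw <- pred$frame > 20
  pred$id[sw] <- 3 - pred$id[sw]
  expect_equal(idf1(gt, pred), 50)
  set.seed(33)
  for (k in 1:10) {
    sc <- random_metric_scene(k, n_ids = sample(2:4, 1), n_frames = 15)
    expect_equal(idf1(sc$gt, sc$pred), oracle_idf1(sc$gt, sc$pred),
                 tolerance = 1e-9)
  }
})

test_that("CLEAR-MOT agrees with the independent enumeration oracle on random scenes", {
  for (k in 1:10) {
    sc <- random_metric_scene(100 + k, n_ids = 3, n_frames = 20)
    cm <- clear_mot(match_frames(sc$gt, sc$pred))
    or <- oracle_clear_mot(sc$gt, sc$pred)
    expect_equal(cm$mota, or$mota, tolerance = 0.1)
    expect_equal(cm$motp, or$motp, tolerance = 0.1)
    expect_equal(cm$fp, or$fp)
    expect_equal(cm$fn, or$fn)
    expect_equal(cm$idsw, or$idsw)
  }
})

test_that("MOTA decreases monotonically as false positives are injected", {
  gt <- perfect_scene(n_frames = 40, n_ids = 3)
  motas <- vapply(c(0, 10, 25, 50), function(nfp) {
    set.seed(nfp + 1)
    fp <- tibble::tibble(frame = sample(1:40, nfp, replace = TRUE),
                         id = 50 + seq_len(nfp), x = runif(nfp, 300, 600),
                         y = runif(nfp, 200, 400), w = 30, h = 24)
    clear_mot(match_frames(gt, rbind(gt, fp)))$mota
  }, 0)
  expect_true(all(diff(motas) < 0))
})

test_that("locking statistics follow the run-length definitions", {
  one <- tibble::tibble(frame = 1:50, id = 1, x = 0, y = 0, w = 10, h = 10)
  ls <- lock_stats(one, fps = 10)
  expect_equal(ls$avg_frame, 50)
  expect_equal(ls$max_frame, 50)
  expect_equal(ls$avg_consecutive_frame, 50)
  expect_equal(ls$avg_lock_dur, 5)
  # broken presence: totals count all frames, runs only the longest stretch
  broken <- tibble::tibble(frame = c(1:10, 21:30), id = 1, x = 0, y = 0, w = 10, h = 10)
  ls2 <- lock_stats(broken, fps = 30)
  expect_equal(ls2$avg_frame, 20)
  expect_equal(ls2$avg_consecutive_frame, 10)
  two <- rbind(tibble::tibble(frame = 1:30, id = 1, x = 0, y = 0, w = 10, h = 10),
               tibble::tibble(frame = 1:50, id = 2, x = 90, y = 0, w = 10, h = 10))
  ls3 <- lock_stats(two, fps = 30)
  expect_equal(ls3$avg_frame, 40)
  expect_equal(ls3$max_frame, 50)
  expect_equal(lock_stats(two[0, ])$avg_frame, 0)
})

test_that("tracker comparison reproduces the delta arithmetic", {
  a <- list(mota = 95.34, idsw = 12)
  b <- list(mota = 90.48, idsw = 39)
  cmp <- compare_trackers(a, b)
  expect_equal(cmp$idsw_reduction_pct, 69.2)
  expect_equal(cmp$idsw_diff, 27)
  expect_equal(cmp$mota_abs_diff, 4.86)
  expect_equal(cmp$mota_rel_pct, 5.4)
  same <- compare_trackers(a, a)
  expect_equal(same$mota_abs_diff, 0)
  expect_equal(same$idsw_reduction_pct, 0)
  # zero baselines are undefined, not errors
  expect_true(is.na(compare_trackers(a, list(mota = 0, idsw = 0))$idsw_reduction_pct))
})
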