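test_that("assignment solves trivial and hand-enumerable cases", {
  r <- solve_assignment(matrix(0.1, 1, 1), max_cost = 1)
  expect_equal(r$matches, matrix(c(1L, 1L), 1))
  r2 <- solve_assignment(matrix(c(1, 10, 10, 1), 2, byrow = TRUE), max_cost = 20)
  expect_equal(r2$matches[order(r2$matches[, 1]), ],
               matrix(c(1L, 1L, 2L, 2L), 2, byrow = TRUE))
  # demotion above max_cost
  r3 <- solve_assignment(matrix(5, 1, 1), max_cost = 1)
  expect_equal(nrow(r3$matches), 0)
  expect_equal(r3$unmatched_tracks, 1L)
  expect_equal(r3$unmatched_detections, 1L)
})

test_that("assignment total cost matches the permutation-enumeration oracle", {
  set.seed(12)
  for (k in 1:30) {
    n <- sample(1:5, 1); m <- sample(1:5, 1)
    cost <- matrix(runif(n * m, 0, 10), n, m)
    r <- solve_assignment(cost, max_cost = 100)
    tot <- sum(cost[r$matches, drop = FALSE])
    if (nrow(r$matches) == 1) tot <- cost[r$matches[1, 1], r$matches[1, 2]]
    expect_equal(tot, oracle_assignment(cost)$cost, tolerance = 1e-9)
  }
})

test_that("assignment result always partitions tracks and detections", {
  set.seed(13)
  for (k in 1:40) {
    n <- sample(0:6, 1); m <- sample(0:6, 1)
    cost <- matrix(runif(n * m, 0, 2), n, m)
    cost[runif(n * m) < 0.3] <- Inf
    r <- solve_assignment(cost, max_cost = 1)
    t_seen <- sort(c(r$matches[, 1], r$unmatched_tracks))
    d_seen <- sort(c(r$matches[, 2], r$unmatched_detections))
    expect_equal(t_seen, seq_len(n))
    expect_equal(d_seen, seq_len(m))
    expect_false(any(duplicated(r$matches[, 1])))
    expect_false(any(duplicated(r$matches[, 2])))
  }
})

make_test_track <- function(id, cx, cy, w = 40, h = 30, feature = NULL,
                            tsu = 1L, status = "confirmed") {
  box <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  kf <- kf_predict(kf_init(duotrack:::box_to_xyah(box)))
  list(id = id, kf = kf, gallery = if (is.null(feature)) list() else list(feature),
       status = status, time_since_update = tsu, predicted_box = box)
}

unit_vec <- function(seed) {
  set.seed(seed); v <- rnorm(16); v / sqrt(sum(v^2))
}

test_that("cost matrix gates by Mahalanobis distance and appearance threshold", {
  cfg <- duotrack_config()
  f1 <- unit_vec(1); f2 <- unit_vec(2)
  tr <- list(make_test_track(1, 100, 100, feature = f1))
  det_boxes <- rbind(c(80, 85, 120, 115),   # at the track, same feature
                     c(500, 400, 540, 430), # far outside the gate
                     c(80, 85, 120, 115))   # at the track, alien feature
  C <- duotrack:::build_cost_matrix(tr, det_boxes, list(f1, f1, f2), cfg)
  expect_equal(C[1, 1], 0, tolerance = 1e-12)
  expect_equal(C[1, 2], INFEASIBLE_COST)
  expect_equal(C[1, 3], INFEASIBLE_COST)  # appearance above threshold
  # feasibility pattern equals per-entry recomputation
  meas <- t(apply(det_boxes, 1, duotrack:::box_to_xyah))
  g2 <- kf_gating_distance(tr[[1]]$kf, meas)
  for (j in 1:3) {
    feasible <- g2[j] <= cfg$gating_threshold &&
      cosine_distance(f1, list(f1, f1, f2)[[j]]) <= cfg$appearance_threshold
    expect_equal(C[1, j] < INFEASIBLE_COST, feasible)
  }
})

test_that("cascade prefers recently updated tracks and never double-assigns", {
  cfg <- duotrack_config()
  f <- unit_vec(3)
  fresh <- make_test_track(1, 100, 100, feature = f, tsu = 1L)
  stale <- make_test_track(2, 100, 100, feature = f, tsu = 10L)
  det_boxes <- rbind(c(80, 85, 120, 115))
  r <- duotrack:::matching_cascade(list(stale, fresh), det_boxes, list(f), cfg)
  expect_equal(nrow(r$matches), 1)
  expect_equal(r$matches[1, 1], 2L)  # the fresh track (index 2) wins
  # no detections: everything unmatched
  r0 <- duotrack:::matching_cascade(list(stale, fresh), NULL, NULL, cfg)
  expect_equal(nrow(r0$matches), 0)
  expect_equal(r0$unmatched_tracks, c(1L, 2L))
  # one nearby detection, one track
  r1 <- duotrack:::matching_cascade(list(fresh), det_boxes, list(f), cfg)
  expect_equal(nrow(r1$matches), 1)
})

test_that("cascade assigns each detection at most once over random scenes", {
  cfg <- duotrack_config()
  set.seed(14)
  for (k in 1:10) {
    n <- sample(2:5, 1); m <- sample(1:6, 1)
    tracks <- lapply(seq_len(n), function(i) {
      make_test_track(i, runif(1, 50, 590), runif(1, 50, 430),
                      feature = unit_vec(100 + i), tsu = sample(1:5, 1))
    })
    det_boxes <- cbind(runif(m, 30, 570), runif(m, 30, 410))
    det_boxes <- cbind(det_boxes, det_boxes[, 1] + 40, det_boxes[, 2] + 30)
    feats <- lapply(seq_len(m), function(j) unit_vec(100 + sample(1:8, 1)))
    r <- duotrack:::matching_cascade(tracks, det_boxes, feats, cfg)
    expect_false(any(duplicated(r$matches[, 2])))
    expect_false(any(duplicated(r$matches[, 1])))
    expect_equal(sort(c(r$matches[, 1], r$unmatched_tracks)), seq_len(n))
    expect_equal(sort(c(r$matches[, 2], r$unmatched_detections)), seq_len(m))
  }
})
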