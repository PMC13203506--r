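# The dual-locking orchestrator. Per frame: Kalman predict, cascade
# association, matched-track update (Kalman + gallery + auxiliary KCF
# template), gap filling of unmatched confirmed tracks via the auxiliary
# locker, tentative spawning, conflict coverage, lifecycle, emission.

#' Tracker configuration
#'
#' All tunable thresholds and weights of the dual-locking tracker, with their
#' defaults. Detection filtering uses confidence 0.25 and NMS IoU 0.4; the
#' conflict pass uses overlap threshold 0.5 and score weights
#' (0.4, 0.3, 0.3); gap filling is budgeted at 20 consecutive frames
#' (matching the occlusion horizon the mechanism targets); track lifecycle
#' uses 3 consecutive hits to confirm and 30 frames maximum coasting age.
#'
#' @param conf_threshold Minimum detection confidence; matched detections
#'   below it are treated as detection failure.
#' @param nms_iou NMS suppression threshold (used by [nms()]).
#' @param gating_threshold Chi-square Mahalanobis gate (0.95 quantile, 4 dof).
#' @param appearance_threshold Maximum admissible gallery cosine distance.
#' @param gallery_budget Appearance gallery size per track.
#' @param predefined_size Adaptive-resize target for appearance patches.
#' @param iou_match_threshold Max cost (1 - IoU) in the IoU fallback stage.
#' @param n_init Consecutive hits before a tentative track is confirmed.
#' @param max_age Maximum frames since update before deletion.
#' @param fill_enabled Enable auxiliary gap filling.
#' @param max_fill_frames Consecutive gap-fill budget.
#' @param fill_pseudo_update Feed filled boxes to the Kalman filter as
#'   pseudo-measurements.
#' @param fill_noise_inflation Measurement-noise inflation for pseudo-updates.
#' @param resync_iou Minimum IoU between the filled box and a candidate
#'   detection for re-synchronization.
#' @param conflict_enabled Enable the conflict-coverage pass.
#' @param conflict_theta Overlap threshold for conflicts.
#' @param conflict_weights `(alpha, beta, gamma)` score weights.
#' @param fill_conf_mode Confidence term of a filling locker: `"zero"`
#'   (no current detection) or `"last"` (last seen confidence).
#' @param kcf_enabled Use the KCF auxiliary locker when images are supplied.
#' @param kcf [kcf_params()].
#' @param feature_extractor Function (patch) -> unit feature vector, used in
#'   image mode; `NULL` disables extraction.
#' @param std_weight_pos,std_weight_vel Kalman noise weights.
#' @return Object of class `duotrack_config`.
#' @export
duotrack_config <- function(conf_threshold = 0.25, nms_iou = 0.4,
                            gating_threshold = GATING_THRESHOLD,
                            appearance_threshold = 0.2,
                            gallery_budget = 100L, predefined_size = 128L,
                            iou_match_threshold = 0.7,
                            n_init = 3L, max_age = 30L,
                            fill_enabled = TRUE, max_fill_frames = 20L,
                            fill_pseudo_update = TRUE, fill_noise_inflation = 10,
                            resync_iou = 0.3,
                            conflict_enabled = TRUE, conflict_theta = 0.5,
                            conflict_weights = c(0.4, 0.3, 0.3),
                            fill_conf_mode = c("zero", "last"),
                            kcf_enabled = TRUE, kcf = kcf_params(),
                            feature_extractor = extract_features,
                            std_weight_pos = 1 / 20, std_weight_vel = 1 / 160) {
  fill_conf_mode <- match.arg(fill_conf_mode)
  if (abs(sum(conflict_weights) - 1) > 1e-9 || any(conflict_weights < 0)) {
    stop("conflict_weights must be non-negative and sum to 1", call. = FALSE)
  }
  cfg <- list(conf_threshold = conf_threshold, nms_iou = nms_iou,
              gating_threshold = gating_threshold,
              appearance_threshold = appearance_threshold,
              gallery_budget = as.integer(gallery_budget),
              predefined_size = as.integer(predefined_size),
              iou_match_threshold = iou_match_threshold,
              n_init = as.integer(n_init), max_age = as.integer(max_age),
              fill_enabled = isTRUE(fill_enabled),
              max_fill_frames = as.integer(max_fill_frames),
              fill_pseudo_update = isTRUE(fill_pseudo_update),
              fill_noise_inflation = fill_noise_inflation,
              resync_iou = resync_iou,
              conflict_enabled = isTRUE(conflict_enabled),
              conflict_theta = conflict_theta,
              conflict_weights = conflict_weights,
              fill_conf_mode = fill_conf_mode,
              kcf_enabled = isTRUE(kcf_enabled), kcf = kcf,
              feature_extractor = feature_extractor,
              std_weight_pos = std_weight_pos, std_weight_vel = std_weight_vel)
  class(cfg) <- "duotrack_config"
  cfg
}

new_track <- function(id, box, conf, feature, config) {
  list(id = id,
       kf = kf_init(box_to_xyah(box), config$std_weight_pos, config$std_weight_vel),
       gallery = if (is.null(feature)) list() else list(feature),
       kcf = NULL,
       status = "tentative", hits = 1L, time_since_update = 0L,
       fill_count = 0L, n_tracked = 1L, n_total = 1L, n_frames = 1L,
       last_conf = conf, last_box = box,
       predicted_box = box, output_box = NULL, output_source = NA_character_)
}

#' Initialize an empty tracker state
#' @param config A [duotrack_config()].
#' @return Opaque tracker state for [tracker_step()].
#' @export
tracker_init <- function(config = duotrack_config()) {
  list(tracks = list(), next_id = 1L, frame = 0L, config = config)
}

#' Re-synchronization check after a detection gap
#'
#' A detection claiming a gap-filling track is accepted only if its box
#' overlaps the auxiliary locker's filled estimate (IoU at least
#' `config$resync_iou`) and, when appearance features are available, its
#' gallery cosine distance is within the appearance threshold.
#'
#' @param track A filling track (tracker internal).
#' @param det_box Candidate detection box (corner vector).
#' @param det_feature Optional feature vector.
#' @param config A [duotrack_config()].
#' @return TRUE if the detection re-locks the track.
#' @export
resync <- function(track, det_box, det_feature, config) {
  # the position test validates the auxiliary locker's filled location; in
  # degraded detection-only mode the filled box is the Kalman extrapolation
  # itself, whose position consistency the Mahalanobis gate has already
  # checked covariance-aware, so the fixed IoU cutoff applies only when the
  # KCF locker actually measured the filled position
  if (isTRUE(track$fill_measured) &&
      box_iou(track$predicted_box, det_box) < config$resync_iou) {
    return(FALSE)
  }
  if (!is.null(det_feature) && length(track$gallery) > 0 &&
      gallery_distance(track$gallery, det_feature) > config$appearance_threshold) {
    return(FALSE)
  }
  TRUE
}

#' Fill a detection gap with the auxiliary locker
#'
#' When an image is available and the track carries a trained KCF model, the
#' new center is the KCF response peak in a window around the predicted
#' position; otherwise the Kalman constant-velocity prediction is used
#' (degraded, detection-only mode). The box size is frozen at the last
#' detected size. The filled box is fed back to the Kalman filter as a
#' pseudo-measurement with inflated measurement noise.
#'
#' @param track A confirmed or filling track.
#' @param image Optional image for the current frame.
#' @param config A [duotrack_config()].
#' @return The updated track, with `output_box` the filled box.
#' @export
fill_gap <- function(track, image = NULL, config = duotrack_config()) {
  pb <- track$predicted_box
  cx <- (pb[1] + pb[3]) / 2; cy <- (pb[2] + pb[4]) / 2
  measured <- FALSE
  if (!is.null(image) && !is.null(track$kcf)) {
    win <- crop_window(image, cx, cy, track$kcf$win_h, track$kcf$win_w)
    loc <- tryCatch(kcf_detect(track$kcf, win), error = function(e) NULL)
    if (!is.null(loc)) { cx <- cx + loc$dx; cy <- cy + loc$dy; measured <- TRUE }
  }
  w <- track$last_box[3] - track$last_box[1]
  h <- track$last_box[4] - track$last_box[2]
  box <- c(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
  track$status <- "filling"
  track$fill_count <- track$fill_count + 1L
  # the filled box is fed back as a pseudo-measurement (inflated noise) only
  # when the auxiliary locker actually measured it; in degraded detection-only
  # mode the filled box IS the prediction, so an update would add no
  # information and only shrink the gate the eventual re-association needs
  track$fill_measured <- measured
  if (config$fill_pseudo_update && measured) {
    track$kf <- kf_update(track$kf, box_to_xyah(box), config$fill_noise_inflation)
  }
  track$output_box <- box
  track$output_source <- "filled"
  track
}

update_kcf_template <- function(track, image, det_box, config) {
  if (is.null(image) || !config$kcf_enabled) return(track)
  cx <- (det_box[1] + det_box[3]) / 2; cy <- (det_box[2] + det_box[4]) / 2
  w <- det_box[3] - det_box[1]; h <- det_box[4] - det_box[2]
  retrain <- is.null(track$kcf) ||
    w / track$kcf$target_w > 1.25 || w / track$kcf$target_w < 0.8 ||
    h / track$kcf$target_h > 1.25 || h / track$kcf$target_h < 0.8
  track$kcf <- tryCatch({
    if (retrain) {
      kcf_train(image, det_box, config$kcf)
    } else {
      win <- crop_window(image, cx, cy, track$kcf$win_h, track$kcf$win_w)
      kcf_update(track$kcf, win)
    }
  }, error = function(e) track$kcf)
  track
}

#' Advance the tracker by one frame
#'
#' @param state Tracker state from [tracker_init()] / a previous step.
#' @param detections Data frame of this frame's detections: columns `x`, `y`,
#'   `w`, `h`, `conf` and optionally a `feature` list-column (already NMS-
#'   and confidence-filtered).
#' @param image Optional image (matrix/array) enabling the KCF auxiliary
#'   locker and appearance extraction.
#' @return List with `state` (advanced), `result` (tibble of emitted boxes:
#'   `frame`, `id`, `x`, `y`, `w`, `h`, `conf`, `source`) and `events`
#'   (tibble of structured lifecycle events).
#' @export
tracker_step <- function(state, detections = NULL, image = NULL) {
  config <- state$config
  state$frame <- state$frame + 1L
  events <- list()
  log_event <- function(ev, id, detail = NA_real_) {
    events[[length(events) + 1L]] <<- list(frame = state$frame, event = ev,
                                           id = id, detail = detail)
  }

  # phase 1: predict
  for (k in seq_along(state$tracks)) {
    t <- state$tracks[[k]]
    t$kf <- kf_predict(t$kf)
    t$predicted_box <- xyah_to_box(t$kf$mean[1:4])
    t$time_since_update <- t$time_since_update + 1L
    t$n_frames <- t$n_frames + 1L
    t$n_total <- t$n_total + 1L
    t$output_box <- NULL
    t$output_source <- NA_character_
    state$tracks[[k]] <- t
  }

  # detections: drop malformed and low-confidence (treated as failure)
  det <- detections
  if (!is.null(det) && nrow(det) > 0) {
    if (any(det$w < 0 | det$h < 0) || any(!is.finite(det$x + det$y + det$w + det$h))) {
      stop("malformed detection boxes", call. = FALSE)
    }
    det <- det[det$conf >= config$conf_threshold, , drop = FALSE]
  }
  m <- if (is.null(det)) 0L else nrow(det)
  det_boxes <- if (m > 0) ltwh_to_corners(det) else NULL
  det_features <- NULL
  if (m > 0) {
    if (!is.null(det[["feature"]])) {
      det_features <- det$feature
    } else if (!is.null(image) && !is.null(config$feature_extractor)) {
      det_features <- lapply(seq_len(m), function(j) {
        b <- det_boxes[j, ]
        patch <- crop_window(image, (b[1] + b[3]) / 2, (b[2] + b[4]) / 2,
                             max(2, round(b[4] - b[2])), max(2, round(b[3] - b[1])))
        config$feature_extractor(adaptive_resize(patch, config$predefined_size))
      })
    }
  }

  # phase 2: association
  res <- matching_cascade(state$tracks, det_boxes, det_features, config)

  spawn_pool <- res$unmatched_detections
  unmatched_tracks <- res$unmatched_tracks

  # phase 3: matched tracks (with resync validation for filling tracks)
  if (nrow(res$matches)) {
    for (r in seq_len(nrow(res$matches))) {
      ti <- res$matches[r, 1]; j <- res$matches[r, 2]
      t <- state$tracks[[ti]]
      b <- det_boxes[j, ]
      f <- if (!is.null(det_features)) det_features[[j]] else NULL
      if (identical(t$status, "filling")) {
        if (!resync(t, b, f, config)) {
          log_event("resync_reject", t$id)
          spawn_pool <- sort(c(spawn_pool, j))
          unmatched_tracks <- sort(c(unmatched_tracks, ti))
          next
        }
        log_event("resync", t$id)
      }
      t$kf <- kf_update(t$kf, box_to_xyah(b))
      if (!is.null(f)) t$gallery <- gallery_add(t$gallery, f, config$gallery_budget)
      t <- update_kcf_template(t, image, b, config)
      if (identical(t$status, "tentative")) {
        t$hits <- t$hits + 1L
        if (t$hits >= config$n_init) {
          t$status <- "confirmed"
          log_event("confirm", t$id)
        }
      } else {
        t$status <- "confirmed"
      }
      t$time_since_update <- 0L
      t$fill_count <- 0L
      t$n_tracked <- t$n_tracked + 1L
      t$last_conf <- det$conf[j]
      t$last_box <- b
      if (identical(t$status, "confirmed")) {
        t$output_box <- b
        t$output_source <- "detected"
      }
      state$tracks[[ti]] <- t
    }
  }

  # phase 4: unmatched tracks — fill, coast or delete
  for (ti in unmatched_tracks) {
    t <- state$tracks[[ti]]
    if (identical(t$status, "tentative")) {
      t$status <- "deleted"
      state$tracks[[ti]] <- t
      next
    }
    if (config$fill_enabled) {
      if (t$fill_count < config$max_fill_frames) {
        t <- fill_gap(t, image, config)
        log_event("fill", t$id)
      } else {
        t$status <- "deleted"
        log_event("delete_fill_exhausted", t$id)
      }
    } else if (t$time_since_update > config$max_age) {
      t$status <- "deleted"
      log_event("delete_max_age", t$id)
    }
    state$tracks[[ti]] <- t
  }

  # phase 5: spawn tentative tracks
  for (j in spawn_pool) {
    f <- if (!is.null(det_features)) det_features[[j]] else NULL
    state$tracks[[length(state$tracks) + 1L]] <-
      new_track(state$next_id, det_boxes[j, ], det$conf[j], f, config)
    log_event("spawn", state$next_id)
    state$next_id <- state$next_id + 1L
  }

  # phase 6: conflict coverage over detection-backed lockers. Tentative
  # tracks are excluded (newborn duplicates must not kill mature tracks),
  # and gap-filling lockers neither trigger nor lose conflicts: a filled box
  # overlapping a detected one is the expected signature of occlusion, which
  # the fill mechanism exists to ride out, not a duplicate identity.
  if (config$conflict_enabled) {
    emit_idx <- which(vapply(state$tracks, function(t) {
      identical(t$status, "confirmed") && !is.null(t$output_box) &&
        identical(t$output_source, "detected")
    }, TRUE))
    if (length(emit_idx) >= 2) {
      boxes <- do.call(rbind, lapply(state$tracks[emit_idx], function(t) t$output_box))
      lockers <- cbind(corners_to_ltwh(boxes),
                       id = vapply(state$tracks[emit_idx], function(t) t$id, 0L))
      max_frames <- max(vapply(state$tracks[emit_idx], function(t) t$n_frames, 0L))
      scores <- lapply(state$tracks[emit_idx], function(t) {
        si <- compute_score_inputs(t, max_frames)
        conf <- if (config$fill_conf_mode == "last" && identical(t$status, "filling")) {
          t$last_conf
        } else {
          si$conf
        }
        score_locker(conf, si$stability, si$maturity, config$conflict_weights)
      })
      names(scores) <- as.character(lockers$id)
      losers <- resolve_conflicts(lockers, scores, config$conflict_theta)
      for (id in losers) {
        ki <- which(vapply(state$tracks, function(t) t$id == id, TRUE))
        state$tracks[[ki]]$status <- "deleted"
        state$tracks[[ki]]$output_box <- NULL
        log_event("conflict_remove", id)
      }
    }
  }

  # phase 7: drop deleted tracks
  state$tracks <- Filter(function(t) !identical(t$status, "deleted"), state$tracks)

  # phase 8: emit
  rows <- Filter(function(t) !is.null(t$output_box), state$tracks)
  result <- if (length(rows)) {
    boxes <- do.call(rbind, lapply(rows, function(t) t$output_box))
    n <- length(rows)
    tibble::new_tibble(list(
      frame = rep.int(state$frame, n),
      id = vapply(rows, function(t) as.integer(t$id), 0L),
      x = boxes[, 1], y = boxes[, 2],
      w = boxes[, 3] - boxes[, 1], h = boxes[, 4] - boxes[, 2],
      conf = vapply(rows, function(t) {
        if (identical(t$output_source, "filled")) 0 else t$last_conf
      }, 0),
      source = vapply(rows, function(t) t$output_source, "")), nrow = n)
  } else {
    empty_result()
  }
  events <- if (length(events)) {
    tibble::new_tibble(list(
      frame = vapply(events, `[[`, 0L, "frame"),
      event = vapply(events, `[[`, "", "event"),
      id = vapply(events, function(e) as.integer(e$id), 0L)),
      nrow = length(events))
  } else {
    tibble::new_tibble(list(frame = integer(0), event = character(0),
                            id = integer(0)), nrow = 0L)
  }
  list(state = state, result = result, events = events)
}

empty_result <- function() {
  tibble::tibble(frame = integer(0), id = integer(0), x = numeric(0),
                 y = numeric(0), w = numeric(0), h = numeric(0),
                 conf = numeric(0), source = character(0))
}

#' Track a detection stream
#'
#' Runs the dual-locking tracker over a full per-frame detection table and
#' returns the emitted trajectories. Frames are processed from 1 to
#' `max(detections$frame)` (frames absent from the table are detection
#' failures and exercise gap filling).
#'
#' @param detections Data frame with columns `frame`, `x`, `y`, `w`, `h`,
#'   `conf` and optionally a `feature` list-column. Should already be NMS-
#'   and confidence-filtered (see [nms()]).
#' @param config A [duotrack_config()].
#' @param images Optional list of per-frame images (or a function
#'   `frame -> image`) enabling the KCF auxiliary locker.
#' @param n_frames Number of frames to process (default: max frame index).
#' @return Object of class `duotrack_run`: list with `results` (tibble
#'   `frame`, `id`, `x`, `y`, `w`, `h`, `conf`, `source`), `events` and
#'   `config`. Supports `tidy()`, `glance()` and `autoplot()`.
#' @examples
#' det <- tibble::tibble(frame = rep(1:10, each = 1), x = 10 + 2 * (1:10),
#'                       y = 50, w = 40, h = 30, conf = 0.9)
#' run <- track_detections(det)
#' head(run$results)
#' @export
track_detections <- function(detections, config = duotrack_config(),
                             images = NULL, n_frames = NULL) {
  stopifnot(all(c("frame", "x", "y", "w", "h", "conf") %in% names(detections)))
  if (is.null(n_frames)) n_frames <- max(detections$frame, 0L)
  state <- tracker_init(config)
  by_frame <- split(tibble::as_tibble(detections), detections$frame)
  results <- vector("list", n_frames)
  events <- vector("list", n_frames)
  for (fr in seq_len(n_frames)) {
    det <- by_frame[[as.character(fr)]]
    img <- NULL
    if (!is.null(images)) {
      img <- if (is.function(images)) images(fr) else images[[fr]]
    }
    step <- tracker_step(state, det, img)
    state <- step$state
    results[[fr]] <- step$result
    events[[fr]] <- step$events
  }
  structure(list(results = dplyr::bind_rows(results),
                 events = dplyr::bind_rows(events),
                 config = config, n_frames = n_frames),
            class = "duotrack_run")
}

#' @export
print.duotrack_run <- function(x, ...) {
  cat("<duotrack_run> ", x$n_frames, " frames, ",
      length(unique(x$results$id)), " identities, ",
      sum(x$results$source == "filled"), " filled boxes\n", sep = "")
  invisible(x)
}
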