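# Tracking evaluation: CLEAR-MOT (MOTA, MOTP, identity switches,
# fragmentations), IDF1 via the globally optimal identity bijection, and
# locking-duration statistics. Inputs are MOT-style tables: one row per box,
# columns frame, id, x, y, w, h (left/top/width/height).

check_mot_table <- function(df, what) {
  stopifnot(all(c("frame", "id", "x", "y", "w", "h") %in% names(df)))
  dup <- duplicated(df[, c("frame", "id")])
  if (any(dup)) stop("duplicate ", what, " ids within a frame", call. = FALSE)
  tibble::as_tibble(df)
}

#' Frame-by-frame correspondence between ground truth and predictions
#'
#' CLEAR-MOT matching protocol: matches from the previous frame are kept
#' while their IoU stays at or above the threshold; the remaining boxes are
#' matched by minimum-cost assignment on `1 - IoU`, pairs below the
#' threshold being infeasible.
#'
#' @param gt,pred MOT tables (`frame`, `id`, `x`, `y`, `w`, `h`).
#' @param iou_threshold Minimum IoU for a valid correspondence (default 0.5).
#' @return Object of class `mot_correspondence`: `matches` tibble (`frame`,
#'   `gt_id`, `pred_id`, `iou`), plus the inputs and threshold.
#' @export
match_frames <- function(gt, pred, iou_threshold = 0.5) {
  gt <- check_mot_table(gt, "ground-truth")
  pred <- check_mot_table(pred, "prediction")
  frames <- sort(unique(c(gt$frame, pred$frame)))
  gt_by <- split(gt, gt$frame)
  pr_by <- split(pred, pred$frame)
  last_pair <- integer(0)  # names: gt id, values: last matched pred id
  out <- vector("list", length(frames))
  for (fi in seq_along(frames)) {
    fr <- frames[fi]
    g <- gt_by[[as.character(fr)]]
    p <- pr_by[[as.character(fr)]]
    ng <- if (is.null(g)) 0L else nrow(g)
    np <- if (is.null(p)) 0L else nrow(p)
    if (ng == 0 || np == 0) next
    gb <- ltwh_to_corners(g); pb <- ltwh_to_corners(p)
    iou <- iou_matrix(gb, pb)
    m_g <- integer(0); m_p <- integer(0); m_iou <- numeric(0)
    taken_p <- rep(FALSE, np)
    done_g <- rep(FALSE, ng)
    # persistence pass
    for (gi in order(g$id)) {
      pid <- last_pair[as.character(g$id[gi])]
      if (is.na(pid) || !length(pid)) next
      pj <- match(pid, p$id)
      if (!is.na(pj) && !taken_p[pj] && iou[gi, pj] >= iou_threshold) {
        m_g <- c(m_g, gi); m_p <- c(m_p, pj); m_iou <- c(m_iou, iou[gi, pj])
        taken_p[pj] <- TRUE; done_g[gi] <- TRUE
      }
    }
    # optimal pass on the remainder
    rg <- which(!done_g); rp <- which(!taken_p)
    if (length(rg) && length(rp)) {
      cost <- 1 - iou[rg, rp, drop = FALSE]
      cost[iou[rg, rp, drop = FALSE] < iou_threshold] <- Inf
      res <- solve_assignment(cost, max_cost = 1)
      if (nrow(res$matches)) {
        m_g <- c(m_g, rg[res$matches[, 1]])
        m_p <- c(m_p, rp[res$matches[, 2]])
        m_iou <- c(m_iou, iou[cbind(rg[res$matches[, 1]], rp[res$matches[, 2]])])
      }
    }
    if (length(m_g)) {
      last_pair[as.character(g$id[m_g])] <- p$id[m_p]
      out[[fi]] <- tibble::tibble(frame = fr, gt_id = g$id[m_g],
                                  pred_id = p$id[m_p], iou = m_iou)
    }
  }
  matches <- dplyr::bind_rows(out)
  if (nrow(matches) == 0) {
    matches <- tibble::tibble(frame = integer(0), gt_id = integer(0),
                              pred_id = integer(0), iou = numeric(0))
  }
  structure(list(matches = matches, gt = gt, pred = pred,
                 iou_threshold = iou_threshold),
            class = "mot_correspondence")
}

#' CLEAR-MOT metrics from a correspondence
#'
#' `MOTA = 100 (1 - (FN + FP + IDSw) / #GT boxes)`; `MOTP` is 100 times the
#' mean IoU over matched pairs; identity switches count changes of the
#' matched hypothesis id on a ground-truth trajectory; fragmentations count
#' interruptions of a tracked trajectory that later resumes.
#'
#' @param correspondence A [match_frames()] result.
#' @return Named list: `mota`, `motp`, `idsw`, `frag`, `fp`, `fn`, `n_gt`.
#' @export
clear_mot <- function(correspondence) {
  stopifnot(inherits(correspondence, "mot_correspondence"))
  m <- correspondence$matches
  gt <- correspondence$gt
  pred <- correspondence$pred
  n_gt <- nrow(gt)
  if (n_gt == 0) stop("no ground-truth boxes: MOTA undefined", call. = FALSE)
  fn <- n_gt - nrow(m)
  fp <- nrow(pred) - nrow(m)
  idsw <- 0L
  if (nrow(m)) {
    m_ord <- m[order(m$gt_id, m$frame), ]
    for (gid in unique(m_ord$gt_id)) {
      preds <- m_ord$pred_id[m_ord$gt_id == gid]
      idsw <- idsw + sum(preds[-1] != preds[-length(preds)])
    }
  }
  frag <- 0L
  for (gid in unique(gt$id)) {
    frs <- sort(gt$frame[gt$id == gid])
    tracked <- frs %in% m$frame[m$gt_id == gid]
    r <- rle(tracked)
    if (length(r$values) >= 3) {
      inner <- which(!r$values & seq_along(r$values) > 1 & seq_along(r$values) < length(r$values))
      frag <- frag + length(inner)
    }
  }
  list(mota = 100 * (1 - (fn + fp + idsw) / n_gt),
       motp = if (nrow(m)) 100 * mean(m$iou) else NA_real_,
       idsw = idsw, frag = frag, fp = fp, fn = fn, n_gt = n_gt)
}

#' IDF1: identity-preservation F1 score
#'
#' Computes the globally optimal one-to-one mapping between ground-truth and
#' predicted identities that maximizes the number of position-consistent
#' frame pairs (IoU at or above the threshold), then
#' `IDF1 = 100 * 2 IDTP / (2 IDTP + IDFP + IDFN)`.
#'
#' @param gt,pred MOT tables.
#' @param iou_threshold Position-consistency threshold (default 0.5).
#' @return IDF1 percentage.
#' @export
idf1 <- function(gt, pred, iou_threshold = 0.5) {
  gt <- check_mot_table(gt, "ground-truth")
  pred <- check_mot_table(pred, "prediction")
  if (nrow(gt) == 0) stop("no ground-truth boxes: IDF1 undefined", call. = FALSE)
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  overlap <- matrix(0, length(gids), length(pids),
                    dimnames = list(as.character(gids), as.character(pids)))
  frames <- intersect(unique(gt$frame), unique(pred$frame))
  gt_by <- split(gt, gt$frame); pr_by <- split(pred, pred$frame)
  for (fr in frames) {
    g <- gt_by[[as.character(fr)]]; p <- pr_by[[as.character(fr)]]
    iou <- iou_matrix(ltwh_to_corners(g), ltwh_to_corners(p))
    hit <- which(iou >= iou_threshold, arr.ind = TRUE)
    if (nrow(hit)) {
      gi <- as.character(g$id[hit[, 1]]); pj <- as.character(p$id[hit[, 2]])
      for (k in seq_len(nrow(hit))) overlap[gi[k], pj[k]] <- overlap[gi[k], pj[k]] + 1
    }
  }
  idtp <- 0
  if (length(gids) && length(pids)) {
    a <- hungarian(-overlap)
    for (i in seq_along(gids)) if (!is.na(a[i])) idtp <- idtp + overlap[i, a[i]]
  }
  idfn <- nrow(gt) - idtp
  idfp <- nrow(pred) - idtp
  100 * 2 * idtp / (2 * idtp + idfp + idfn)
}

#' Locking-duration statistics
#'
#' Per-identity totals over a prediction table: `avg_frame` / `max_frame`
#' are the mean and maximum number of frames an identity is locked;
#' `avg_consecutive_frame` is the mean longest unbroken run;
#' `avg_lock_dur` converts that run to seconds at `fps`.
#'
#' @param pred MOT table of tracker output.
#' @param fps Frame rate used to convert frames to seconds (default 30).
#' @return Named list `avg_frame`, `max_frame`, `avg_lock_dur`,
#'   `avg_consecutive_frame`.
#' @export
lock_stats <- function(pred, fps = 30) {
  stopifnot(fps > 0)
  if (nrow(pred) == 0) {
    return(list(avg_frame = 0, max_frame = 0, avg_lock_dur = 0,
                avg_consecutive_frame = 0))
  }
  pred <- check_mot_table(pred, "prediction")
  per_id <- dplyr::group_by(pred, .data$id)
  totals <- dplyr::summarise(per_id, n = dplyr::n(), .groups = "drop")$n
  longest <- vapply(split(pred$frame, pred$id), function(frs) {
    frs <- sort(frs)
    max(tapply(seq_along(frs), cumsum(c(1L, diff(frs) != 1L)), length))
  }, 0)
  list(avg_frame = mean(totals), max_frame = max(totals),
       avg_lock_dur = mean(longest) / fps,
       avg_consecutive_frame = mean(longest))
}

#' Full tracking evaluation
#'
#' @param gt,pred MOT tables.
#' @param iou_threshold Correspondence threshold (default 0.5).
#' @param fps Frame rate for duration statistics (default 30).
#' @return Object of class `mot_eval` with fields `mota`, `motp`, `idf1`,
#'   `idsw`, `frag`, `fp`, `fn`, `n_gt`, `avg_frame`, `max_frame`,
#'   `avg_lock_dur`, `avg_consecutive_frame`. Supports `tidy()`/`glance()`.
#' @export
evaluate_tracking <- function(gt, pred, iou_threshold = 0.5, fps = 30) {
  corr <- match_frames(gt, pred, iou_threshold)
  cm <- clear_mot(corr)
  ls <- lock_stats(pred, fps)
  structure(c(cm, list(idf1 = idf1(gt, pred, iou_threshold)), ls,
              list(iou_threshold = iou_threshold, fps = fps)),
            class = "mot_eval")
}

#' @export
print.mot_eval <- function(x, ...) {
  cat(sprintf("<mot_eval> MOTA %.2f%%  MOTP %.2f%%  IDF1 %.2f%%  IDSw %d  Frag %d  FP %d  FN %d\n",
              x$mota, x$motp, x$idf1, x$idsw, x$frag, x$fp, x$fn))
  invisible(x)
}

#' Compare two tracker evaluations
#'
#' Improvement deltas of tracker `a` over baseline `b` on the same ground
#' truth: absolute MOTA difference, relative MOTA change (percent, one
#' decimal), absolute identity-switch difference (baseline minus `a`) and
#' relative identity-switch reduction (percent, one decimal). Undefined
#' ratios (zero baseline) are reported as `NA`.
#'
#' @param a,b `mot_eval` objects, or any lists with `mota` and `idsw`.
#' @return One-row tibble: `mota_a`, `mota_b`, `mota_abs_diff`,
#'   `mota_rel_pct`, `idsw_a`, `idsw_b`, `idsw_diff`, `idsw_reduction_pct`.
#' @examples
#' compare_trackers(list(mota = 95.34, idsw = 12), list(mota = 90.48, idsw = 39))
#' @export
compare_trackers <- function(a, b) {
  tibble::tibble(
    mota_a = a$mota, mota_b = b$mota,
    mota_abs_diff = a$mota - b$mota,
    mota_rel_pct = if (b$mota == 0) NA_real_ else round(100 * (a$mota - b$mota) / b$mota, 1),
    idsw_a = a$idsw, idsw_b = b$idsw,
    idsw_diff = b$idsw - a$idsw,
    idsw_reduction_pct = if (b$idsw == 0) NA_real_ else round(100 * (b$idsw - a$idsw) / b$idsw, 1)
  )
}

# count of frame-wise pairs of emitted boxes overlapping beyond theta —
# the duplicate-identity events the conflict pass is meant to suppress
count_duplicate_events <- function(pred, theta = 0.5) {
  total <- 0L
  for (p in split(pred, pred$frame)) {
    if (nrow(p) < 2) next
    M <- iou_matrix(ltwh_to_corners(p), ltwh_to_corners(p))
    total <- total + sum(upper.tri(M) & M > theta)
  }
  total
}
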