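# Data association for the primary locker: gated appearance cost matrix,
# optimal one-to-one assignment (shortest augmenting path with dual
# potentials, O(n^3)), and the tiered matching cascade with IoU fallback.

#' Sentinel cost marking an infeasible track-detection pair
#' @export
INFEASIBLE_COST <- 1e5

# minimum-cost assignment; cost is an n x m matrix, returns an integer vector
# a of length n with a[i] = assigned column of row i (NA if unassigned; only
# possible when n > m). Classical Hungarian with potentials.
hungarian <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  if (n == 0 || m == 0) return(rep(NA_integer_, n))
  transposed <- FALSE
  if (n > m) { cost <- t(cost); transposed <- TRUE; tmp <- n; n <- m; m <- tmp }
  big <- max(cost[is.finite(cost)], 0) * n + 1
  cost[!is.finite(cost)] <- big + INFEASIBLE_COST
  INF <- Inf
  u <- numeric(n + 1); v <- numeric(m + 1)
  p <- integer(m + 1)   # p[j+1] = row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i; j0 <- 0L
    minv <- rep(INF, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]; delta <- INF; j1 <- 0L
      for (j in seq_len(m)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
          if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
        }
      }
      for (j in 0:m) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign_row <- rep(NA_integer_, n)
  for (j in seq_len(m)) if (p[j + 1] > 0L) assign_row[p[j + 1]] <- j
  if (transposed) {
    out <- rep(NA_integer_, m)
    for (i in seq_len(n)) if (!is.na(assign_row[i])) out[assign_row[i]] <- i
    out
  } else {
    assign_row
  }
}

#' Solve a gated assignment problem
#'
#' Minimum-total-cost one-to-one assignment between rows (tracks) and columns
#' (detections); any assigned pair whose cost exceeds `max_cost` is demoted
#' to unmatched.
#'
#' @param cost Numeric matrix (rows = tracks, columns = detections);
#'   infeasible entries may be `Inf` or [INFEASIBLE_COST].
#' @param max_cost Maximum admissible pair cost.
#' @return List of class `assignment_result`: `matches` (two-column integer
#'   matrix of track/detection indices), `unmatched_tracks`,
#'   `unmatched_detections`. The three collections partition the indices.
#' @examples
#' solve_assignment(matrix(c(1, 10, 10, 1), 2, byrow = TRUE), max_cost = 5)
#' @export
solve_assignment <- function(cost, max_cost = INFEASIBLE_COST - 1) {
  n <- nrow(cost); m <- ncol(cost)
  a <- hungarian(cost)
  matches <- NULL
  un_t <- integer(0); un_d <- setdiff(seq_len(m), a[!is.na(a)])
  for (i in seq_len(n)) {
    j <- a[i]
    if (!is.na(j) && is.finite(cost[i, j]) && cost[i, j] <= max_cost) {
      matches <- rbind(matches, c(i, j))
    } else {
      un_t <- c(un_t, i)
      if (!is.na(j)) un_d <- sort(c(un_d, j))
    }
  }
  if (is.null(matches)) matches <- matrix(integer(0), ncol = 2)
  structure(list(matches = matches, unmatched_tracks = un_t,
                 unmatched_detections = un_d),
            class = "assignment_result")
}

# Gated appearance cost between a list of tracks and a frame of detections.
# Entry (t, d) is the gallery cosine distance; pairs failing the chi-square
# Mahalanobis gate or exceeding the appearance threshold get the infeasible
# sentinel. When appearance is unavailable (no galleries or no detection
# features) the cost falls back to the gated, normalized Mahalanobis
# distance.
build_cost_matrix <- function(tracks, det_boxes, det_features, config) {
  n <- length(tracks); m <- nrow(det_boxes)
  cost <- matrix(INFEASIBLE_COST, n, m)
  if (n == 0 || m == 0) return(cost)
  meas <- t(apply(det_boxes, 1, box_to_xyah))
  have_appearance <- !is.null(det_features) &&
    all(vapply(tracks, function(t) length(t$gallery) > 0, TRUE))
  for (i in seq_len(n)) {
    g2 <- kf_gating_distance(tracks[[i]]$kf, meas)
    ok <- g2 <= config$gating_threshold
    if (!any(ok)) next
    if (have_appearance) {
      G <- do.call(rbind, tracks[[i]]$gallery)
      for (j in which(ok)) {
        d <- min(1 - drop(G %*% det_features[[j]]))
        cost[i, j] <- if (d <= config$appearance_threshold) d else INFEASIBLE_COST
      }
    } else {
      cost[i, ok] <- g2[ok] / config$gating_threshold
    }
  }
  cost
}

# DeepSORT-style matching cascade: confirmed (and filling) tracks are
# associated in ascending frames-since-update tiers so recently seen tracks
# get first claim; remaining tracks plus tentative ones then go through
# IoU matching (cost 1 - IoU, max cost config$iou_match_threshold).
# `tracks` is the full track list; returns indices into it.
matching_cascade <- function(tracks, det_boxes, det_features, config) {
  m <- if (is.null(det_boxes)) 0L else nrow(det_boxes)
  all_d <- seq_len(m)
  conf_idx <- which(vapply(tracks, function(t) t$status %in% c("confirmed", "filling"), TRUE))
  tent_idx <- which(vapply(tracks, function(t) t$status == "tentative", TRUE))
  matches <- matrix(integer(0), ncol = 2)
  un_d <- all_d
  matched_t <- integer(0)
  if (length(conf_idx) && m > 0) {
    ages <- vapply(tracks[conf_idx], function(t) t$time_since_update, 0)
    for (age in sort(unique(ages))) {
      if (!length(un_d)) break
      tier <- conf_idx[ages == age]
      cost <- build_cost_matrix(tracks[tier], det_boxes[un_d, , drop = FALSE],
                                det_features[un_d], config)
      max_cost <- if (is.null(det_features)) 1 else config$appearance_threshold
      res <- solve_assignment(cost, max_cost)
      if (nrow(res$matches)) {
        matches <- rbind(matches, cbind(tier[res$matches[, 1]], un_d[res$matches[, 2]]))
        matched_t <- c(matched_t, tier[res$matches[, 1]])
        un_d <- un_d[res$unmatched_detections]
      }
    }
  }
  # IoU fallback for tentative tracks and confirmed tracks missed exactly once
  iou_t <- c(tent_idx,
             setdiff(conf_idx[vapply(tracks[conf_idx], function(t) t$time_since_update == 1, TRUE)],
                     matched_t))
  iou_t <- sort(iou_t)
  if (length(iou_t) && length(un_d)) {
    tb <- do.call(rbind, lapply(tracks[iou_t], function(t) t$predicted_box))
    cost <- 1 - iou_matrix(tb, det_boxes[un_d, , drop = FALSE])
    res <- solve_assignment(cost, config$iou_match_threshold)
    if (nrow(res$matches)) {
      matches <- rbind(matches, cbind(iou_t[res$matches[, 1]], un_d[res$matches[, 2]]))
      matched_t <- c(matched_t, iou_t[res$matches[, 1]])
      un_d <- un_d[res$unmatched_detections]
    }
  }
  structure(list(matches = matches,
                 unmatched_tracks = setdiff(seq_along(tracks), matched_t),
                 unmatched_detections = un_d),
            class = "assignment_result")
}
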