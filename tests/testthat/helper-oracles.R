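# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: lattice counting for IoU, explicit dense matrix algebra
# for the Kalman filter, permutation enumeration for assignment, circulant
# matrix construction for KCF, exhaustive bijection for IDF1.

# IoU by counting a fine pixel lattice
oracle_iou_lattice <- function(b1, b2, step = 0.05) {
  xs <- seq(min(b1[1], b2[1]) + step / 2, max(b1[3], b2[3]), by = step)
  ys <- seq(min(b1[2], b2[2]) + step / 2, max(b1[4], b2[4]), by = step)
  in_box <- function(b, X, Y) X > b[1] & X < b[3] & Y > b[2] & Y < b[4]
  X <- rep(xs, times = length(ys)); Y <- rep(ys, each = length(xs))
  i1 <- in_box(b1, X, Y); i2 <- in_box(b2, X, Y)
  inter <- sum(i1 & i2); un <- sum(i1 | i2)
  if (un == 0) 0 else inter / un
}

# CIoU recomputed term by term
oracle_ciou <- function(pred, gt) {
  iou <- oracle_iou_exact(pred, gt)
  c1 <- c((pred[1] + pred[3]) / 2, (pred[2] + pred[4]) / 2)
  c2 <- c((gt[1] + gt[3]) / 2, (gt[2] + gt[4]) / 2)
  rho2 <- sum((c1 - c2)^2)
  cw <- max(pred[3], gt[3]) - min(pred[1], gt[1])
  ch <- max(pred[4], gt[4]) - min(pred[2], gt[2])
  v <- 4 / pi^2 * (atan((gt[3] - gt[1]) / (gt[4] - gt[2])) -
                     atan((pred[3] - pred[1]) / (pred[4] - pred[2])))^2
  alpha <- if (v == 0) 0 else v / (1 - iou + v)
  (1 - iou) + rho2 / (cw^2 + ch^2) + alpha * v
}

oracle_iou_exact <- function(b1, b2) {
  iw <- max(0, min(b1[3], b2[3]) - max(b1[1], b2[1]))
  ih <- max(0, min(b1[4], b2[4]) - max(b1[2], b2[2]))
  a1 <- (b1[3] - b1[1]) * (b1[4] - b1[2])
  a2 <- (b2[3] - b2[1]) * (b2[4] - b2[2])
  if (a1 + a2 - iw * ih <= 0) return(0)
  iw * ih / (a1 + a2 - iw * ih)
}

# dense-matrix Kalman oracle, written from the textbook equations
oracle_kf <- local({
  Fm <- diag(8); Fm[1:4, 5:8] <- diag(4)
  Hm <- cbind(diag(4), matrix(0, 4, 4))
  list(
    init = function(z, wp = 1 / 20, wv = 1 / 160) {
      h <- z[4]
      s <- c(2 * wp * h, 2 * wp * h, 1e-2, 2 * wp * h,
             10 * wv * h, 10 * wv * h, 1e-5, 10 * wv * h)
      list(m = c(z, 0, 0, 0, 0), P = diag(s^2), wp = wp, wv = wv)
    },
    predict = function(st) {
      h <- st$m[4]
      q <- c(st$wp * h, st$wp * h, 1e-2, st$wp * h,
             st$wv * h, st$wv * h, 1e-5, st$wv * h)
      list(m = as.vector(Fm %*% st$m), P = Fm %*% st$P %*% t(Fm) + diag(q^2),
           wp = st$wp, wv = st$wv)
    },
    update = function(st, z, infl = 1) {
      h <- st$m[4]
      r <- c(st$wp * h, st$wp * h, 1e-1, st$wp * h) * infl
      S <- Hm %*% st$P %*% t(Hm) + diag(r^2)
      K <- st$P %*% t(Hm) %*% solve(S)
      m <- st$m + as.vector(K %*% (z - Hm %*% st$m))
      P <- (diag(8) - K %*% Hm) %*% st$P
      list(m = m, P = P, wp = st$wp, wv = st$wv)
    },
    gate = function(st, z) {
      h <- st$m[4]
      r <- c(st$wp * h, st$wp * h, 1e-1, st$wp * h)
      S <- Hm %*% st$P %*% t(Hm) + diag(r^2)
      y <- z - as.vector(Hm %*% st$m)
      as.numeric(t(y) %*% solve(S) %*% y)
    }
  )
})

# minimum-cost assignment by enumerating all permutations (n, m <= 6)
oracle_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= 6, m <= 6)
  k <- min(n, m)
  rows <- seq_len(n); cols <- seq_len(m)
  best <- Inf; best_pairs <- NULL
  row_sets <- if (n == k) list(rows) else utils::combn(rows, k, simplify = FALSE)
  col_perms <- function(cs) {
    if (length(cs) == 1) return(list(cs))
    out <- list()
    for (i in seq_along(cs)) {
      for (p in col_perms(cs[-i])) out[[length(out) + 1]] <- c(cs[i], p)
    }
    out
  }
  col_sets <- if (m == k) list(cols) else utils::combn(cols, k, simplify = FALSE)
  for (rs in row_sets) for (cs in col_sets) for (p in col_perms(cs)) {
    tot <- sum(cost[cbind(rs, p)])
    if (tot < best - 1e-12) { best <- tot; best_pairs <- cbind(rs, p) }
  }
  list(cost = best, pairs = best_pairs)
}

# direct circulant-regression KCF oracle on a single-channel feature map:
# builds the full n1*n2 x n1*n2 kernel matrix over all circular shifts
oracle_kcf_alpha <- function(x, sigma, lambda, y) {
  n1 <- nrow(x); n2 <- ncol(x)
  shift2 <- function(m, dy, dx) {
    m[((seq_len(n1) - 1 - dy) %% n1) + 1, ((seq_len(n2) - 1 - dx) %% n2) + 1]
  }
  N <- n1 * n2
  shifts <- expand.grid(dy = 0:(n1 - 1), dx = 0:(n2 - 1))
  X <- matrix(0, N, N)
  for (k in seq_len(N)) {
    X[k, ] <- as.vector(shift2(x, shifts$dy[k], shifts$dx[k]))
  }
  D2 <- outer(rowSums(X^2), rowSums(X^2), `+`) - 2 * X %*% t(X)
  K <- exp(-pmax(0, D2 / N) / sigma^2)
  alpha <- solve(K + lambda * diag(N), as.vector(y))
  matrix(alpha, n1, n2)
}

# exhaustive IDF1 over all id bijections (<= 4 ids per side)
oracle_idf1 <- function(gt, pred, thr = 0.5) {
  gids <- sort(unique(gt$id)); pids <- sort(unique(pred$id))
  stopifnot(length(gids) <= 4, length(pids) <= 4)
  count_pair <- function(g, p) {
    total <- 0
    for (fr in intersect(gt$frame[gt$id == g], pred$frame[pred$id == p])) {
      a <- gt[gt$id == g & gt$frame == fr, ]
      b <- pred[pred$id == p & pred$frame == fr, ]
      if (oracle_iou_exact(c(a$x, a$y, a$x + a$w, a$y + a$h),
                           c(b$x, b$y, b$x + b$w, b$y + b$h)) >= thr) {
        total <- total + 1
      }
    }
    total
  }
  ov <- outer(seq_along(gids), seq_along(pids),
              Vectorize(function(i, j) count_pair(gids[i], pids[j])))
  k <- min(length(gids), length(pids))
  best <- 0
  if (k > 0) {
    perms <- function(v) {
      if (length(v) <= 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
      out
    }
    sel_r <- utils::combn(seq_along(gids), k, simplify = FALSE)
    sel_c <- utils::combn(seq_along(pids), k, simplify = FALSE)
    for (rs in sel_r) for (cs in sel_c) for (p in perms(cs)) {
      best <- max(best, sum(ov[cbind(rs, p)]))
    }
  }
  idtp <- best
  100 * 2 * idtp / (2 * idtp + (nrow(pred) - idtp) + (nrow(gt) - idtp))
}

# simple independent per-frame greedy-optimal matcher + CLEAR accumulation,
# for cross-checking clear_mot on tiny scenes (uses oracle_assignment)
oracle_clear_mot <- function(gt, pred, thr = 0.5) {
  frames <- sort(unique(c(gt$frame, pred$frame)))
  last <- integer(0)
  fp <- 0L; fn <- 0L; idsw <- 0L; n_gt <- nrow(gt); iou_sum <- 0; n_match <- 0L
  last_matched <- integer(0)
  for (fr in frames) {
    g <- gt[gt$frame == fr, ]; p <- pred[pred$frame == fr, ]
    if (nrow(g) == 0) { fp <- fp + nrow(p); next }
    if (nrow(p) == 0) { fn <- fn + nrow(g); next }
    iou <- matrix(0, nrow(g), nrow(p))
    for (i in seq_len(nrow(g))) for (j in seq_len(nrow(p))) {
      iou[i, j] <- oracle_iou_exact(c(g$x[i], g$y[i], g$x[i] + g$w[i], g$y[i] + g$h[i]),
                                    c(p$x[j], p$y[j], p$x[j] + p$w[j], p$y[j] + p$h[j]))
    }
    taken_p <- rep(FALSE, nrow(p)); done_g <- rep(FALSE, nrow(g))
    pairs <- NULL
    for (i in order(g$id)) {
      pid <- last[as.character(g$id[i])]
      if (!length(pid) || is.na(pid)) next
      j <- match(pid, p$id)
      if (!is.na(j) && !taken_p[j] && iou[i, j] >= thr) {
        pairs <- rbind(pairs, c(i, j)); taken_p[j] <- TRUE; done_g[i] <- TRUE
      }
    }
    rg <- which(!done_g); rp <- which(!taken_p)
    if (length(rg) && length(rp)) {
      cost <- 1 - iou[rg, rp, drop = FALSE]
      cost[cost > 1 - thr] <- 100
      sol <- oracle_assignment(cost)
      for (r in seq_len(nrow(sol$pairs))) {
        i <- rg[sol$pairs[r, 1]]; j <- rp[sol$pairs[r, 2]]
        if (iou[i, j] >= thr) pairs <- rbind(pairs, c(i, j))
      }
    }
    np <- if (is.null(pairs)) 0L else nrow(pairs)
    fn <- fn + nrow(g) - np
    fp <- fp + nrow(p) - np
    if (np) {
      for (r in seq_len(np)) {
        gid <- g$id[pairs[r, 1]]; pid <- p$id[pairs[r, 2]]
        prev <- last_matched[as.character(gid)]
        if (length(prev) && !is.na(prev) && prev != pid) idsw <- idsw + 1L
        last_matched[as.character(gid)] <- pid
        last[as.character(gid)] <- pid
        iou_sum <- iou_sum + iou[pairs[r, 1], pairs[r, 2]]
        n_match <- n_match + 1L
      }
    }
  }
  list(mota = 100 * (1 - (fn + fp + idsw) / n_gt),
       motp = if (n_match) 100 * iou_sum / n_match else NA,
       idsw = idsw, fp = fp, fn = fn)
}

# random small tracking scene for metric cross-checks: a few targets with
# linear motion, plus id swaps / dropouts injected into the "prediction"
random_metric_scene <- function(seed, n_ids = 3, n_frames = 25) {
  set.seed(seed)
  gt <- list()
  for (i in seq_len(n_ids)) {
    x0 <- runif(1, 0, 200); y0 <- runif(1, 0, 150)
    vx <- runif(1, -2, 2); vy <- runif(1, -2, 2)
    gt[[i]] <- tibble::tibble(frame = 1:n_frames, id = i,
                              x = x0 + vx * (1:n_frames),
                              y = y0 + vy * (1:n_frames), w = 30, h = 24)
  }
  gt <- do.call(rbind, gt)
  pred <- gt
  pred$x <- pred$x + rnorm(nrow(pred), 0, 1.5)
  pred$y <- pred$y + rnorm(nrow(pred), 0, 1.5)
  # random dropouts
  pred <- pred[runif(nrow(pred)) > 0.08, ]
  # one id swap halfway for a random pair
  if (n_ids >= 2) {
    sw <- sample(n_ids, 2)
    half <- pred$frame > n_frames / 2
    a <- pred$id == sw[1] & half; b <- pred$id == sw[2] & half
    pred$id[a] <- sw[2]; pred$id[b] <- sw[1]
  }
  list(gt = gt, pred = pred)
}
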