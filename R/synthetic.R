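# Synthetic pen scenes: ground-truth multi-target trajectories with
# geometric (z-order) occlusion, a detector-noise emulator calibrated to a
# reported confidence profile, and textured patches for correlation-filter
# tests. This is the package's no-download test substrate: it emulates the
# statistics of an overhead pen video (about a dozen slowly moving,
# similarly sized, visually homogeneous animals with frequent mutual
# occlusion), not its photometry.

#' Scenario configuration
#'
#' Defaults describe the reference pen scene: a 640 x 480 arena, 12 targets,
#' 2000 frames. Targets follow smooth heading-noise random walks with
#' occasional pauses and reflective walls; occlusion is geometric, from the
#' z-order overlap of target boxes.
#'
#' @param width,height Arena size in pixels.
#' @param n_targets Number of targets.
#' @param n_frames Number of frames.
#' @param w_range,h_range Per-target box size ranges (pixels).
#' @param speed_range Per-target cruise speed range (pixels/frame).
#' @param turn_sd Heading random-walk standard deviation (radians/frame).
#' @param pause_prob Per-frame probability of entering a pause.
#' @param pause_mean Mean pause length (frames, geometric).
#' @param territories If TRUE targets are confined to disjoint grid cells
#'   (well-separated scenes with no occlusion).
#' @param seed Scenario seed; fixes every random draw.
#' @return Object of class `scenario_config`.
#' @export
scenario_config <- function(width = 640, height = 480, n_targets = 12L,
                            n_frames = 2000L, w_range = c(60, 90),
                            h_range = c(40, 60), speed_range = c(0.5, 2.5),
                            turn_sd = 0.15, pause_prob = 0.005,
                            pause_mean = 50, territories = FALSE, seed = 1L) {
  stopifnot(width > 0, height > 0, n_targets >= 1, n_frames >= 1)
  if (n_targets * max(w_range) * max(h_range) > 4 * width * height) {
    stop("arena too small for the requested targets", call. = FALSE)
  }
  structure(list(width = width, height = height,
                 n_targets = as.integer(n_targets),
                 n_frames = as.integer(n_frames),
                 w_range = w_range, h_range = h_range,
                 speed_range = speed_range, turn_sd = turn_sd,
                 pause_prob = pause_prob, pause_mean = pause_mean,
                 territories = isTRUE(territories), seed = as.integer(seed)),
            class = "scenario_config")
}

#' Detection-noise configuration
#'
#' Emulates an imperfect detector: visibility-dependent misses, bounding-box
#' jitter, spurious detections, and a confidence model calibrated so that
#' draws have the configured mean with the configured fraction below the low
#' threshold (defaults: mean 0.87, 2.3% below 0.7 — the reported confidence
#' profile of the detector the tracker is designed around). Appearance
#' features emulate a re-identification embedding of visually homogeneous
#' animals: per-target unit vectors clustered around a common mean, observed
#' with noise.
#'
#' @param base_miss Miss probability for visible targets.
#' @param occluded_miss Miss probability once `hidden_threshold` is exceeded.
#' @param hidden_threshold Hidden-area fraction above which a target counts
#'   as occluded.
#' @param jitter_sd Box center/size jitter standard deviation (pixels).
#' @param conf_mean Target mean of emitted confidences.
#' @param conf_low_frac Target fraction of confidences below
#'   `conf_low_threshold`.
#' @param conf_low_threshold Low-confidence threshold.
#' @param fp_rate Expected spurious detections per frame (Poisson).
#' @param feature_dim Emulated embedding dimension (0 disables features).
#' @param feature_spread Norm of the per-target offset from the common mean
#'   direction (controls inter-individual separability).
#' @param feature_noise Norm of the per-detection observation noise.
#' @param gap_schedule Optional tibble (`id`, `start`, `len`) of forced
#'   detection gaps.
#' @return Object of class `noise_config`.
#' @export
noise_config <- function(base_miss = 0.02, occluded_miss = 0.9,
                         hidden_threshold = 0.5, jitter_sd = 2,
                         conf_mean = 0.87, conf_low_frac = 0.023,
                         conf_low_threshold = 0.7, fp_rate = 0.1,
                         feature_dim = 16L, feature_spread = 0.5,
                         feature_noise = 0.15, gap_schedule = NULL) {
  stopifnot(base_miss >= 0, base_miss <= 1, occluded_miss >= 0, occluded_miss <= 1)
  structure(list(base_miss = base_miss, occluded_miss = occluded_miss,
                 hidden_threshold = hidden_threshold, jitter_sd = jitter_sd,
                 conf_mean = conf_mean, conf_low_frac = conf_low_frac,
                 conf_low_threshold = conf_low_threshold, fp_rate = fp_rate,
                 feature_dim = as.integer(feature_dim),
                 feature_spread = feature_spread,
                 feature_noise = feature_noise,
                 gap_schedule = gap_schedule),
            class = "noise_config")
}

#' Simulate a ground-truth pen scene
#'
#' @param config A [scenario_config()].
#' @return Object of class `scenario`: list with `gt` (tibble `frame`, `id`,
#'   `x`, `y`, `w`, `h`, `hidden_frac`) and `config`. Deterministic given
#'   `config$seed`.
#' @export
simulate_scene <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  withr::with_seed(config$seed, {
    n <- config$n_targets; nf <- config$n_frames
    w <- runif(n, config$w_range[1], config$w_range[2])
    h <- runif(n, config$h_range[1], config$h_range[2])
    speed <- runif(n, config$speed_range[1], config$speed_range[2])
    if (config$territories) {
      ncol_ <- ceiling(sqrt(n)); nrow_ <- ceiling(n / ncol_)
      cw <- config$width / ncol_; ch <- config$height / nrow_
      cell <- seq_len(n) - 1L
      bounds <- cbind(xlo = (cell %% ncol_) * cw + w / 2 + 1,
                      xhi = (cell %% ncol_ + 1) * cw - w / 2 - 1,
                      ylo = (cell %/% ncol_) * ch + h / 2 + 1,
                      yhi = (cell %/% ncol_ + 1) * ch - h / 2 - 1)
      if (any(bounds[, "xhi"] <= bounds[, "xlo"]) ||
          any(bounds[, "yhi"] <= bounds[, "ylo"])) {
        stop("arena too small for separated territories", call. = FALSE)
      }
    } else {
      bounds <- cbind(xlo = w / 2 + 1, xhi = config$width - w / 2 - 1,
                      ylo = h / 2 + 1, yhi = config$height - h / 2 - 1)
    }
    cx <- runif(n, bounds[, "xlo"], bounds[, "xhi"])
    cy <- runif(n, bounds[, "ylo"], bounds[, "yhi"])
    heading <- runif(n, 0, 2 * pi)
    paused <- rep(FALSE, n)
    frames <- vector("list", nf)
    for (fr in seq_len(nf)) {
      toggle <- runif(n)
      paused <- ifelse(paused,
                       toggle > 1 / config$pause_mean,  # geometric pause length
                       toggle < config$pause_prob)
      heading <- heading + rnorm(n, 0, config$turn_sd)
      step_len <- ifelse(paused, 0, speed)
      cx <- cx + step_len * cos(heading)
      cy <- cy + step_len * sin(heading)
      # reflective walls (or territory borders)
      for (ax in 1:2) {
        pos <- if (ax == 1) cx else cy
        lo <- bounds[, if (ax == 1) "xlo" else "ylo"]
        hi <- bounds[, if (ax == 1) "xhi" else "yhi"]
        below <- pos < lo; above <- pos > hi
        pos[below] <- pmin(2 * lo[below] - pos[below], hi[below])
        pos[above] <- pmax(2 * hi[above] - pos[above], lo[above])
        if (ax == 1) {
          cx <- pos
          heading[below | above] <- pi - heading[below | above]
        } else {
          cy <- pos
          heading[below | above] <- -heading[below | above]
        }
      }
      boxes <- cbind(cx - w / 2, cy - h / 2, cx + w / 2, cy + h / 2)
      hidden <- numeric(n)
      if (n > 1) {
        M <- iou_matrix(boxes, boxes)  # reused for pairwise overlap test
        area <- w * h
        for (i in seq_len(n)) {
          above_i <- which(seq_len(n) > i)  # z-order: higher id on top
          if (!length(above_i)) next
          iw <- pmax(0, pmin(boxes[i, 3], boxes[above_i, 3]) - pmax(boxes[i, 1], boxes[above_i, 1]))
          ih <- pmax(0, pmin(boxes[i, 4], boxes[above_i, 4]) - pmax(boxes[i, 2], boxes[above_i, 2]))
          hidden[i] <- max(iw * ih) / area[i]
        }
      }
      frames[[fr]] <- tibble::tibble(frame = fr, id = seq_len(n),
                                     x = boxes[, 1], y = boxes[, 2],
                                     w = w, h = h, hidden_frac = hidden)
    }
    structure(list(gt = dplyr::bind_rows(frames), config = config),
              class = "scenario")
  })
}

#' @export
print.scenario <- function(x, ...) {
  cat("<scenario> ", x$config$n_targets, " targets, ", x$config$n_frames,
      " frames, ", x$config$width, "x", x$config$height,
      ", occluded-frame fraction ",
      round(mean(x$gt$hidden_frac > 0.5), 3), "\n", sep = "")
  invisible(x)
}

# Solve the (mu, sigma) of a normal truncated to (0, 1] so that the
# truncated mean and the probability below `thr` hit their targets.
solve_confidence_model <- function(mean = 0.87, low_frac = 0.023, thr = 0.7) {
  tmoments <- function(mu, sigma) {
    a <- (0 - mu) / sigma; b <- (1 - mu) / sigma
    Z <- pnorm(b) - pnorm(a)
    m <- mu + sigma * (dnorm(a) - dnorm(b)) / Z
    pl <- (pnorm((thr - mu) / sigma) - pnorm(a)) / Z
    c(m, pl)
  }
  obj <- function(par) {
    if (par[2] <= 1e-4) return(1e6)
    mm <- tmoments(par[1], par[2])
    (mm[1] - mean)^2 + (mm[2] - low_frac)^2
  }
  fit <- optim(c(mean, 0.08), obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 2000))
  list(mu = fit$par[1], sigma = fit$par[2])
}

rtrunc_conf <- function(k, mu, sigma) {
  a <- pnorm((0 - mu) / sigma); b <- pnorm((1 - mu) / sigma)
  qnorm(runif(k, a, b)) * sigma + mu
}

#' Draw detection confidences from the calibrated model
#'
#' @param k Number of draws.
#' @param noise A [noise_config()].
#' @return Numeric vector in (0, 1].
#' @export
draw_confidences <- function(k, noise = noise_config()) {
  par <- solve_confidence_model(noise$conf_mean, noise$conf_low_frac,
                                noise$conf_low_threshold)
  rtrunc_conf(k, par$mu, par$sigma)
}

random_unit <- function(d) {
  v <- rnorm(d)
  v / sqrt(sum(v^2))
}

#' Emulate noisy detections from a ground-truth scene
#'
#' Applies the visibility-dependent miss model, box jitter, the calibrated
#' confidence model, spurious detections, forced gaps, and (optionally)
#' emulated re-identification features.
#'
#' @param scene A [simulate_scene()] result.
#' @param noise A [noise_config()].
#' @param seed Seed for the detector-noise draws (independent of the scene
#'   seed; default `scene$config$seed + 1000`).
#' @return Detections tibble: `frame`, `x`, `y`, `w`, `h`, `conf` and a
#'   `feature` list-column when `feature_dim > 0`. With all noise terms
#'   zeroed the output equals the ground-truth boxes.
#' @export
emulate_detections <- function(scene, noise = noise_config(),
                               seed = scene$config$seed + 1000L) {
  stopifnot(inherits(scene, "scenario"))
  gt <- scene$gt
  cfgw <- scene$config$width; cfgh <- scene$config$height
  withr::with_seed(seed, {
    conf_par <- solve_confidence_model(noise$conf_mean, noise$conf_low_frac,
                                       noise$conf_low_threshold)
    n_targets <- scene$config$n_targets
    feats <- NULL
    if (noise$feature_dim > 0) {
      m <- rep(1, noise$feature_dim) / sqrt(noise$feature_dim)
      feats <- lapply(seq_len(n_targets), function(i) {
        v <- m + noise$feature_spread * random_unit(noise$feature_dim)
        v / sqrt(sum(v^2))
      })
    }
    miss_p <- ifelse(gt$hidden_frac > noise$hidden_threshold,
                     noise$occluded_miss, noise$base_miss)
    drop <- runif(nrow(gt)) < miss_p
    if (!is.null(noise$gap_schedule)) {
      gs <- noise$gap_schedule
      for (r in seq_len(nrow(gs))) {
        drop <- drop | (gt$id == gs$id[r] & gt$frame >= gs$start[r] &
                          gt$frame < gs$start[r] + gs$len[r])
      }
    }
    kept <- gt[!drop, , drop = FALSE]
    nk <- nrow(kept)
    det <- tibble::tibble(
      frame = kept$frame,
      x = kept$x + rnorm(nk, 0, noise$jitter_sd),
      y = kept$y + rnorm(nk, 0, noise$jitter_sd),
      w = pmax(4, kept$w + rnorm(nk, 0, noise$jitter_sd / 2)),
      h = pmax(4, kept$h + rnorm(nk, 0, noise$jitter_sd / 2)),
      conf = rtrunc_conf(nk, conf_par$mu, conf_par$sigma)
    )
    if (!is.null(feats)) {
      det$feature <- lapply(seq_len(nk), function(r) {
        v <- feats[[kept$id[r]]] + noise$feature_noise * random_unit(noise$feature_dim)
        v / sqrt(sum(v^2))
      })
    }
    n_fp <- rpois(max(gt$frame), noise$fp_rate)
    if (sum(n_fp) > 0) {
      fpf <- rep(seq_along(n_fp), n_fp)
      k <- length(fpf)
      fp <- tibble::tibble(
        frame = fpf,
        x = runif(k, 0, cfgw - 40), y = runif(k, 0, cfgh - 30),
        w = runif(k, min(scene$config$w_range), max(scene$config$w_range)),
        h = runif(k, min(scene$config$h_range), max(scene$config$h_range)),
        conf = rtrunc_conf(k, conf_par$mu, conf_par$sigma)
      )
      if (!is.null(feats)) {
        fp$feature <- lapply(seq_len(k), function(r) random_unit(noise$feature_dim))
      }
      det <- dplyr::bind_rows(det, fp)
    }
    det <- det[order(det$frame, det$x, det$y), , drop = FALSE]
    attr(det, "true_features") <- feats
    det
  })
}

#' Band-limited textured patch (and circular shifts) for tracker tests
#'
#' @param size Side length in pixels (at least 32).
#' @param seed Seed.
#' @return Matrix in \[0, 255\] with non-trivial gradients.
#' @export
make_textured_patch <- function(size = 64L, seed = 1L) {
  if (size < 32) stop("patch size must be at least 32", call. = FALSE)
  withr::with_seed(seed, {
    z <- matrix(rnorm(size * size), size, size)
    fx <- fft_shifted_index(size) / size
    mask <- outer(fx, fx, function(a, b) exp(-(a^2 + b^2) * 60))
    t <- Re(fft(fft(z) * mask, inverse = TRUE)) / (size * size)
    (t - min(t)) / (max(t) - min(t)) * 255
  })
}

#' Circularly shift a patch by whole pixels
#' @param patch Matrix.
#' @param dy,dx Downward / rightward shift in pixels.
#' @return Shifted matrix (`shift_patch(p, 0, 0)` is the identity).
#' @export
shift_patch <- function(patch, dy, dx) {
  n1 <- nrow(patch); n2 <- ncol(patch)
  patch[((seq_len(n1) - 1 - dy) %% n1) + 1, ((seq_len(n2) - 1 - dx) %% n2) + 1]
}

#' Render one frame of a scene as a textured image
#'
#' Targets are textured ellipses over a textured floor (z-ordered), giving
#' the correlation-filter locker gradients to lock onto. Intended for small
#' image-mode test scenes, not photorealism.
#'
#' @param scene A [simulate_scene()] result.
#' @param frame Frame index.
#' @param textures Optional pre-built textures from [scene_textures()].
#' @return `height x width` matrix in \[0, 255\].
#' @export
render_frame <- function(scene, frame, textures = scene_textures(scene)) {
  g <- scene$gt[scene$gt$frame == frame, , drop = FALSE]
  img <- textures$floor
  for (i in order(g$id)) {  # draw in z order: higher id on top
    id <- g$id[i]
    tx <- textures$targets[[id]]
    rows <- round(g$y[i]) + seq_len(nrow(tx)) - 1L
    cols <- round(g$x[i]) + seq_len(ncol(tx)) - 1L
    ok_r <- rows >= 1 & rows <= nrow(img)
    ok_c <- cols >= 1 & cols <= ncol(img)
    if (!any(ok_r) || !any(ok_c)) next
    sub <- img[rows[ok_r], cols[ok_c], drop = FALSE]
    mask <- textures$masks[[id]][ok_r, ok_c, drop = FALSE]
    sub[mask] <- tx[ok_r, ok_c, drop = FALSE][mask]
    img[rows[ok_r], cols[ok_c]] <- sub
  }
  img
}

#' Pre-build floor and target textures for [render_frame()]
#' @param scene A [simulate_scene()] result.
#' @return List with `floor`, `targets`, `masks`.
#' @export
scene_textures <- function(scene) {
  cfg <- scene$config
  side <- 2^ceiling(log2(max(cfg$width, cfg$height)))
  floor_tex <- make_textured_patch(side, cfg$seed + 500L)[seq_len(cfg$height), seq_len(cfg$width)] * 0.4
  first <- scene$gt[scene$gt$frame == 1, , drop = FALSE]
  targets <- list(); masks <- list()
  for (i in seq_len(nrow(first))) {
    w <- round(first$w[i]); h <- round(first$h[i])
    tex <- make_textured_patch(max(32, 2^ceiling(log2(max(w, h)))),
                               cfg$seed + 600L + first$id[i])
    tex <- tex[seq_len(h), seq_len(w)] * 0.5 + 80 + 8 * (first$id[i] %% 8)
    yy <- (seq_len(h) - (h + 1) / 2) / (h / 2)
    xx <- (seq_len(w) - (w + 1) / 2) / (w / 2)
    masks[[first$id[i]]] <- outer(yy^2, xx^2, `+`) <= 1
    targets[[first$id[i]]] <- tex
  }
  list(floor = floor_tex, targets = targets, masks = masks)
}
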