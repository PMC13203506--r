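# MOT-Challenge text interchange (the single format for ground truth,
# detections and results), config file round-trip, and the high-level run
# wrappers used by the command-line script.

#' Read a MOT-Challenge text file
#'
#' Parses `frame,id,x,y,w,h,conf[,...]` rows (1-based frames, left/top/
#' width/height in pixels). Detections conventionally carry `id = -1`; such
#' rows are parsed as id-less (`NA`).
#'
#' @param path File path.
#' @return Tibble `frame`, `id`, `x`, `y`, `w`, `h`, `conf`.
#' @export
read_mot <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(tibble::tibble(frame = integer(0), id = integer(0), x = numeric(0),
                          y = numeric(0), w = numeric(0), h = numeric(0),
                          conf = numeric(0)))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  bad <- which(vapply(parts, length, 0L) < 6)
  if (length(bad)) {
    stop("malformed MOT row at line ", bad[1], " of ", path, call. = FALSE)
  }
  num <- lapply(parts, function(p) suppressWarnings(as.numeric(p[1:7])))
  mat <- do.call(rbind, num)
  if (anyNA(mat[, 1:6])) {
    stop("non-numeric MOT field at line ",
         which(apply(is.na(mat[, 1:6]), 1, any))[1], " of ", path, call. = FALSE)
  }
  id <- as.integer(mat[, 2])
  id[id < 0] <- NA_integer_
  tibble::tibble(frame = as.integer(mat[, 1]), id = id,
                 x = mat[, 3], y = mat[, 4], w = mat[, 5], h = mat[, 6],
                 conf = ifelse(is.na(mat[, 7]), 1, mat[, 7]))
}

#' Write a MOT-Challenge text file
#'
#' Writes `frame,id,x,y,w,h,conf,-1,-1,-1` rows with deterministic (C-locale,
#' fixed-format) number formatting, so identical tables give byte-identical
#' files.
#'
#' @param df Tibble with `frame`, `x`, `y`, `w`, `h` and optionally `id`,
#'   `conf`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mot <- function(df, path) {
  id <- if (is.null(df[["id"]])) rep(-1L, nrow(df)) else ifelse(is.na(df$id), -1L, df$id)
  conf <- if (is.null(df[["conf"]])) rep(1, nrow(df)) else df$conf
  lines <- sprintf("%d,%d,%.4f,%.4f,%.4f,%.4f,%.4f,-1,-1,-1",
                   as.integer(df$frame), as.integer(id),
                   df$x, df$y, df$w, df$h, conf)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a tracker configuration as YAML
#'
#' A resolved-config snapshot makes every run reproducible from its output
#' directory. Function-valued entries (the feature-extractor plug-in) are
#' not serialized.
#'
#' @param config A [duotrack_config()].
#' @param path YAML path.
#' @return `path` invisibly / the restored `duotrack_config`.
#' @export
write_config <- function(config, path) {
  cfg <- config[!vapply(config, is.function, TRUE)]
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(duotrack_config))
  extra <- setdiff(names(vals), c(known, "kcf"))
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "),
                          call. = FALSE)
  if (!is.null(vals$kcf)) vals$kcf <- do.call(kcf_params, vals$kcf)
  if (!is.null(vals$conflict_weights)) vals$conflict_weights <- unlist(vals$conflict_weights)
  do.call(duotrack_config, vals)
}

#' Simulate a scenario and write its ground truth and detections
#'
#' @param config A [scenario_config()].
#' @param noise A [noise_config()].
#' @param dir Output directory (created if needed); `NULL` skips writing.
#' @return List with `scene`, `detections`, and written `paths`.
#' @export
run_simulate <- function(config = scenario_config(), noise = noise_config(),
                         dir = NULL) {
  scene <- simulate_scene(config)
  det <- emulate_detections(scene, noise)
  paths <- NULL
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    gt_path <- file.path(dir, "gt.txt")
    det_path <- file.path(dir, "det.txt")
    write_mot(scene$gt, gt_path)
    write_mot(det, det_path)
    paths <- c(gt = gt_path, det = det_path)
  }
  list(scene = scene, detections = det, paths = paths)
}

#' Run the tracker on a detection file or table
#'
#' @param detections Path to a MOT detection file, or a detections tibble.
#' @param config A [duotrack_config()].
#' @param out Optional output path for the MOT result file; a
#'   `<out>.sources` sidecar records the per-box source flag (detected vs
#'   filled) and `<out>.config.yaml` the resolved config.
#' @return The [track_detections()] run object.
#' @export
run_track <- function(detections, config = duotrack_config(), out = NULL) {
  det <- if (is.character(detections)) read_mot(detections) else detections
  run <- track_detections(det, config)
  if (!is.null(out)) {
    write_mot(run$results, out)
    writeLines(sprintf("%d,%d,%s", run$results$frame, run$results$id,
                       run$results$source), paste0(out, ".sources"))
    write_config(config, paste0(out, ".config.yaml"))
  }
  run
}

#' Evaluate a result file (or table) against ground truth
#'
#' @param gt,pred MOT paths or tables.
#' @param iou_threshold,fps Passed to [evaluate_tracking()].
#' @return A `mot_eval` object.
#' @export
run_evaluate <- function(gt, pred, iou_threshold = 0.5, fps = 30) {
  if (is.character(gt)) gt <- read_mot(gt)
  if (is.character(pred)) pred <- read_mot(pred)
  evaluate_tracking(gt, pred, iou_threshold, fps)
}

ablation_variants <- function(config) {
  list(
    full = config,
    no_fill = utils::modifyList(config, list(fill_enabled = FALSE)),
    no_conflict = utils::modifyList(config, list(conflict_enabled = FALSE))
  )
}

#' Component ablation over seeds
#'
#' Runs the full tracker and its fill-disabled and conflict-disabled
#' variants over `seeds` replicate scenarios and tabulates mean and standard
#' deviation of MOTA, IDF1, identity switches and duplicate-identity events.
#'
#' @param scenario A [scenario_config()] (its seed field is replaced by each
#'   replicate seed).
#' @param noise A [noise_config()].
#' @param config A [duotrack_config()] for the full system.
#' @param seeds Integer vector of replicate seeds.
#' @return Tibble: one row per (variant, seed) with the metric columns.
#' @export
run_ablate <- function(scenario = scenario_config(), noise = noise_config(),
                       config = duotrack_config(), seeds = 1:5) {
  variants <- ablation_variants(config)
  out <- list()
  for (s in seeds) {
    sc <- scenario; sc$seed <- as.integer(s)
    scene <- simulate_scene(sc)
    det <- emulate_detections(scene, noise)
    for (v in names(variants)) {
      cfg <- variants[[v]]
      class(cfg) <- "duotrack_config"
      run <- track_detections(det, cfg, n_frames = sc$n_frames)
      ev <- evaluate_tracking(scene$gt, run$results)
      out[[length(out) + 1L]] <- tibble::tibble(
        variant = v, seed = s, mota = ev$mota, motp = ev$motp,
        idf1 = ev$idf1, idsw = ev$idsw, frag = ev$frag,
        fp = ev$fp, fn = ev$fn,
        duplicates = count_duplicate_events(run$results, config$conflict_theta))
    }
  }
  dplyr::bind_rows(out)
}

#' Summarize an ablation table as mean +/- sd per variant
#' @param ablation Output of [run_ablate()].
#' @return Tibble with one row per variant.
#' @export
summarize_ablation <- function(ablation) {
  dplyr::summarise(
    dplyr::group_by(ablation, .data$variant),
    dplyr::across(c("mota", "idf1", "idsw", "duplicates"),
                  list(mean = mean, sd = stats::sd)),
    .groups = "drop")
}
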