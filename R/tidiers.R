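# broom-style tidiers and ggplot2 autoplot methods for run, evaluation and
# scenario objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a tracker run into one row per emitted box
#' @param x A `duotrack_run`.
#' @param ... Unused.
#' @return Tibble `frame`, `id`, `x`, `y`, `w`, `h`, `conf`, `source`.
#' @export
tidy.duotrack_run <- function(x, ...) {
  x$results
}

#' One-row summary of a tracker run
#' @param x A `duotrack_run`.
#' @param ... Unused.
#' @return Tibble with frame/identity/fill counts.
#' @export
glance.duotrack_run <- function(x, ...) {
  r <- x$results
  tibble::tibble(n_frames = x$n_frames,
                 n_ids = length(unique(r$id)),
                 n_boxes = nrow(r),
                 n_filled = sum(r$source == "filled"),
                 fill_fraction = if (nrow(r)) sum(r$source == "filled") / nrow(r) else 0,
                 n_conflict_removals = sum(x$events$event == "conflict_remove"),
                 n_resyncs = sum(x$events$event == "resync"))
}

#' Tidy an evaluation into a long metric table
#' @param x A `mot_eval`.
#' @param ... Unused.
#' @return Tibble `metric`, `value`.
#' @export
tidy.mot_eval <- function(x, ...) {
  keep <- c("mota", "motp", "idf1", "idsw", "frag", "fp", "fn",
            "avg_frame", "max_frame", "avg_lock_dur", "avg_consecutive_frame")
  tibble::tibble(metric = keep, value = vapply(keep, function(k) as.numeric(x[[k]]), 0))
}

#' One-row summary of an evaluation
#' @param x A `mot_eval`.
#' @param ... Unused.
#' @return One-row tibble of the headline metrics.
#' @export
glance.mot_eval <- function(x, ...) {
  tibble::tibble(mota = x$mota, motp = x$motp, idf1 = x$idf1,
                 idsw = x$idsw, frag = x$frag, fp = x$fp, fn = x$fn)
}

#' Plot emitted trajectories of a tracker run
#'
#' Box-center traces per identity, with gap-filled stretches drawn as open
#' points so detector dropouts are visible.
#'
#' @param object A `duotrack_run`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.duotrack_run <- function(object, ...) {
  r <- object$results
  r$cx <- r$x + r$w / 2
  r$cy <- r$y + r$h / 2
  ggplot2::ggplot(r, ggplot2::aes(x = .data$cx, y = .data$cy,
                                  group = factor(.data$id),
                                  color = factor(.data$id))) +
    ggplot2::geom_path(alpha = 0.6, linewidth = 0.4) +
    ggplot2::geom_point(data = r[r$source == "filled", , drop = FALSE],
                        shape = 1, size = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px, image down)", color = "track id",
                  title = "Tracked trajectories (open points = gap-filled)") +
    ggplot2::theme_minimal()
}

#' Plot an evaluation as a metric bar chart
#' @param object A `mot_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mot_eval <- function(object, ...) {
  d <- tidy.mot_eval(object)
  d <- d[d$metric %in% c("mota", "motp", "idf1"), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f", .data$value)),
                       vjust = -0.4, size = 3) +
    ggplot2::ylim(0, 105) +
    ggplot2::labs(x = NULL, y = "percent") +
    ggplot2::theme_minimal()
}

#' Plot ground-truth trajectories of a synthetic scenario
#' @param object A `scenario`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario <- function(object, ...) {
  g <- object$gt
  g$cx <- g$x + g$w / 2
  g$cy <- g$y + g$h / 2
  ggplot2::ggplot(g, ggplot2::aes(x = .data$cx, y = .data$cy,
                                  color = factor(.data$id))) +
    ggplot2::geom_path(alpha = 0.7, linewidth = 0.4) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "x (px)", y = "y (px)", color = "target",
                  title = "Synthetic pen scene: true trajectories") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
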