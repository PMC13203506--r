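# Pure-software model of the pan-tilt actuator interface: pixel-to-control
# mapping (32 px per X unit, 48 px per Y unit on a 640 x 480 frame),
# control-to-pulse/angle mapping (0.5-2.5 ms on a 20 ms cycle over 0-180
# degrees), '#X$Y\r\n' serial framing, and the byte-wise receive-buffer
# state machine (200-byte buffer, CR freeze, LF completion, reset on any
# malformed tail).

#' Construct a clamped gimbal control frame
#'
#' X control values live in 5..25 (full 0-180 degree horizontal range); Y in
#' 5..15 (the practical 0-90 degree vertical range). Out-of-range values are
#' clamped.
#'
#' @param x,y Integer control values.
#' @return Named integer vector of class `control_frame`.
#' @export
control_frame <- function(x, y) {
  structure(c(x = as.integer(min(max(round(x), 5L), 25L)),
              y = as.integer(min(max(round(y), 5L), 15L))),
            class = "control_frame")
}

#' Map a pixel coordinate to gimbal control values
#'
#' One X control unit per 32 pixels and one Y unit per 48 pixels, anchored
#' so the image origin maps to the range minimum:
#' `X = clamp(5 + round(cx/32), 5, 25)`, `Y = clamp(5 + round(cy/48), 5, 15)`.
#' Monotone non-decreasing in each coordinate.
#'
#' @param cx,cy Pixel coordinates in a 640 x 480 frame (values outside are
#'   clamped).
#' @return A [control_frame()].
#' @examples
#' pixel_to_control(320, 240) # frame center -> (15, 10)
#' @export
pixel_to_control <- function(cx, cy) {
  stopifnot(is.finite(cx), is.finite(cy))
  control_frame(5 + floor(cx / 32 + 0.5), 5 + floor(cy / 48 + 0.5))
}

#' Control value to servo pulse width and angle
#'
#' Control 5..25 maps linearly to 0.5..2.5 ms pulses (20 ms cycle) and
#' 0..180 degrees: `pulse = control/10` ms, `angle = (control - 5) * 9`.
#'
#' @param control Integer in \[5, 25\].
#' @return List with `pulse_ms` and `angle_deg`.
#' @export
control_to_pulse <- function(control) {
  if (control < 5 || control > 25) {
    stop("control value outside the 5..25 protocol range", call. = FALSE)
  }
  list(pulse_ms = control / 10, angle_deg = (control - 5) * 9)
}

#' Secondary Y-axis transform hook
#'
#' The vertical axis supports a pluggable correction applied after
#' [pixel_to_control()]; the default is the identity. Any plug-in's output
#' is clamped back to the valid 5..15 range.
#'
#' @param y_control Integer in \[5, 15\].
#' @param hook Function `integer -> numeric`, default identity.
#' @return Corrected y control in \[5, 15\].
#' @export
y_secondary_transform <- function(y_control, hook = identity) {
  as.integer(min(max(round(hook(y_control)), 5L), 15L))
}

#' Encode a control frame as serial bytes
#'
#' `'#'` marks the X field, `'$'` the Y field, and CR LF terminates the
#' frame: `(12, 8)` encodes as `"#12$8\r\n"`.
#'
#' @param frame A [control_frame()].
#' @return Raw vector.
#' @export
encode_frame <- function(frame) {
  charToRaw(sprintf("#%d$%d\r\n", frame[["x"]], frame[["y"]]))
}

#' Initialize the serial decoder state machine
#'
#' @param capacity Buffer capacity in bytes (default 200).
#' @return Object of class `decoder_state`.
#' @export
decoder_init <- function(capacity = 200L) {
  structure(list(buffer = integer(0), capacity = as.integer(capacity),
                 awaiting_lf = FALSE, completion_flag = 0L,
                 pending_x = NA_integer_, pending_y = NA_integer_,
                 rejected = 0L),
            class = "decoder_state")
}

parse_packet <- function(chars) {
  s <- paste(chars, collapse = "")
  if (grepl("^#[0-9]+\\$[0-9]+$", s)) {
    v <- regmatches(s, gregexpr("[0-9]+", s))[[1]]
    list(x = as.integer(v[1]), y = as.integer(v[2]))
  } else if (grepl("^#[0-9]+$", s)) {
    list(x = as.integer(sub("#", "", s)), y = NA_integer_)
  } else if (grepl("^\\$[0-9]+$", s)) {
    list(x = NA_integer_, y = as.integer(sub("\\$", "", s)))
  } else {
    NULL
  }
}

#' Feed bytes to the serial decoder
#'
#' Bytes are buffered until CR (0x0D) freezes the reception counter; a
#' following LF (0x0A) sets the completion flag and the packet is parsed by
#' its `#`/`$` field markers. Any non-LF byte after CR, or overflow past the
#' buffer capacity, discards the partial frame and resets the state.
#' Packets carrying a single axis are held until the complementary axis
#' arrives. Malformed digit fields are discarded and counted, never raised.
#'
#' The decoder is prefix-robust: splitting a byte stream at arbitrary
#' boundaries over successive calls yields the same frames.
#'
#' @param state A [decoder_state][decoder_init()] (carried across calls).
#' @param bytes Raw vector (or integer byte values).
#' @return List with `state` and `frames` (tibble `x`, `y`, one row per
#'   completed control frame).
#' @export
decode_bytes <- function(state, bytes) {
  if (is.raw(bytes)) bytes <- as.integer(bytes)
  frames <- list()
  for (b in bytes) {
    if (state$awaiting_lf) {
      if (b == 0x0A) {
        state$completion_flag <- 1L
        pkt <- parse_packet(intToUtf8(state$buffer, multiple = TRUE))
        if (is.null(pkt)) {
          state$rejected <- state$rejected + 1L
        } else {
          if (!is.na(pkt$x)) state$pending_x <- pkt$x
          if (!is.na(pkt$y)) state$pending_y <- pkt$y
          if (!is.na(state$pending_x) && !is.na(state$pending_y)) {
            frames[[length(frames) + 1L]] <-
              control_frame(state$pending_x, state$pending_y)
            state$pending_x <- NA_integer_
            state$pending_y <- NA_integer_
          }
        }
      } else {
        state$rejected <- state$rejected + 1L
      }
      state$buffer <- integer(0)
      state$awaiting_lf <- FALSE
      state$completion_flag <- 0L
    } else if (b == 0x0D) {
      state$awaiting_lf <- TRUE  # counter frozen, wait for LF
    } else {
      state$buffer <- c(state$buffer, b)
      if (length(state$buffer) > state$capacity) {
        state$buffer <- integer(0)  # overflow: drop everything received
        state$rejected <- state$rejected + 1L
      }
    }
  }
  frames_df <- if (length(frames)) {
    tibble::tibble(x = vapply(frames, `[[`, 0L, "x"),
                   y = vapply(frames, `[[`, 0L, "y"))
  } else {
    tibble::tibble(x = integer(0), y = integer(0))
  }
  list(state = state, frames = frames_df)
}

#' Encode tracker output for one target as a gimbal byte stream
#'
#' Converts the per-frame box centers of `target_id` in a tracker result to
#' control frames and concatenates their serial encodings — the continuous
#' locking instruction stream the actuator would receive.
#'
#' @param results Tracker results tibble (`frame`, `id`, `x`, `y`, `w`, `h`).
#' @param target_id Identity to stream.
#' @param y_hook Optional secondary Y transform hook.
#' @return Raw vector of encoded frames (frame order).
#' @export
gimbal_stream <- function(results, target_id, y_hook = identity) {
  r <- results[results$id == target_id, , drop = FALSE]
  r <- r[order(r$frame), , drop = FALSE]
  if (nrow(r) == 0) return(raw(0))
  out <- lapply(seq_len(nrow(r)), function(i) {
    cf <- pixel_to_control(r$x[i] + r$w[i] / 2, r$y[i] + r$h[i] / 2)
    cf <- control_frame(cf[["x"]], y_secondary_transform(cf[["y"]], y_hook))
    encode_frame(cf)
  })
  do.call(c, out)
}
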