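test_that("pixel-to-control mapping anchors, scales and clamps as specified", {
  expect_equal(pixel_to_control(0, 0)[["x"]], 5L)
  cf <- pixel_to_control(320, 240)
  expect_equal(cf[["x"]], 15L)
  expect_equal(cf[["y"]], 10L)
  expect_equal(pixel_to_control(10000, 0)[["x"]], 25L)
  expect_equal(pixel_to_control(0, 10000)[["y"]], 15L)
  # monotone non-decreasing in each coordinate
  xs <- vapply(seq(0, 640, by = 8), function(cx) pixel_to_control(cx, 0)[["x"]], 0L)
  ys <- vapply(seq(0, 480, by = 8), function(cy) pixel_to_control(0, cy)[["y"]], 0L)
  expect_true(all(diff(xs) >= 0))
  expect_true(all(diff(ys) >= 0))
})

test_that("control values map linearly onto pulses and angles", {
  expect_equal(control_to_pulse(5), list(pulse_ms = 0.5, angle_deg = 0))
  expect_equal(control_to_pulse(25), list(pulse_ms = 2.5, angle_deg = 180))
  expect_equal(control_to_pulse(15), list(pulse_ms = 1.5, angle_deg = 90))
  expect_error(control_to_pulse(4), "range")
  expect_error(control_to_pulse(26), "range")
})

test_that("the secondary Y transform defaults to identity and clamps plug-ins", {
  expect_equal(y_secondary_transform(10), 10L)
  expect_equal(y_secondary_transform(8, hook = function(y) y + 100), 15L)
  expect_equal(y_secondary_transform(8, hook = function(y) -3), 5L)
  # a plug-in with a declared inverse round-trips inside the valid range
  up <- function(y) y + 2; down <- function(y) y - 2
  for (y in 5:13) expect_equal(y_secondary_transform(up(y), down), y)
})

test_that("frames encode as '#X$Y\\r\\n' and decode back", {
  expect_equal(rawToChar(encode_frame(control_frame(12, 8))), "#12$8\r\n")
  expect_equal(rawToChar(encode_frame(control_frame(5, 5))), "#5$5\r\n")
  d <- decode_bytes(decoder_init(), encode_frame(control_frame(12, 8)))
  expect_equal(nrow(d$frames), 1)
  expect_equal(d$frames$x, 12L)
  expect_equal(d$frames$y, 8L)
})

test_that("encode/decode is the identity on all 231 valid control pairs", {
  st <- decoder_init()
  for (x in 5:25) for (y in 5:15) {
    out <- decode_bytes(st, encode_frame(control_frame(x, y)))
    st <- out$state
    expect_equal(out$frames$x, x)
    expect_equal(out$frames$y, y)
  }
  expect_equal(st$rejected, 0L)
})

test_that("a non-LF byte after CR discards the partial frame", {
  st <- decoder_init()
  out <- decode_bytes(st, c(charToRaw("#12$8\r"), charToRaw("X")))
  expect_equal(nrow(out$frames), 0)
  expect_equal(length(out$state$buffer), 0)
  expect_equal(out$state$rejected, 1L)
  # the stream recovers afterwards
  out2 <- decode_bytes(out$state, encode_frame(control_frame(7, 9)))
  expect_equal(out2$frames$x, 7L)
})

test_that("buffer overflow past capacity resets without emitting", {
  st <- decoder_init(capacity = 200L)
  out <- decode_bytes(st, as.raw(rep(0x41, 250)))
  expect_equal(nrow(out$frames), 0)
  expect_gte(out$state$rejected, 1L)
  expect_lte(length(out$state$buffer), 200L)
})

test_that("the decoder is prefix-robust across arbitrary stream splits", {
  stream <- do.call(c, lapply(list(c(6, 7), c(25, 15), c(13, 11)), function(p) {
    encode_frame(control_frame(p[1], p[2]))
  }))
  whole <- decode_bytes(decoder_init(), stream)$frames
  set.seed(40)
  for (k in 1:10) {
    cuts <- sort(sample(seq_len(length(stream) - 1), sample(1:5, 1)))
    pieces <- split(stream, cumsum(seq_along(stream) %in% (cuts + 1)))
    st <- decoder_init(); acc <- NULL
    for (p in pieces) {
      out <- decode_bytes(st, p)
      st <- out$state
      acc <- rbind(acc, out$frames)
    }
    expect_equal(acc, whole)
  }
})

test_that("malformed digit fields are rejected and counted, never raised", {
  st <- decoder_init()
  out <- decode_bytes(st, charToRaw("#ab$8\r\n"))
  expect_equal(nrow(out$frames), 0)
  expect_equal(out$state$rejected, 1L)
  # axis-separate packets pair up across frames
  out2 <- decode_bytes(out$state, charToRaw("#12\r\n$9\r\n"))
  expect_equal(nrow(out2$frames), 1)
  expect_equal(out2$frames$x, 12L)
  expect_equal(out2$frames$y, 9L)
})

test_that("tracker output streams as a continuous instruction sequence", {
  res <- tibble::tibble(frame = 1:3, id = 1, x = c(304, 336, 10000),
                        y = c(225, 225, 225), w = 32, h = 30, conf = 1)
  bytes <- gimbal_stream(res, target_id = 1)
  dec <- decode_bytes(decoder_init(), bytes)$frames
  expect_equal(nrow(dec), 3)
  expect_equal(dec$x, c(15L, 16L, 25L))
  expect_true(all(dec$y == 10L))
  expect_equal(gimbal_stream(res, target_id = 99), raw(0))
})
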