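gaze_stream <- function(t, v) {
  sensor_stream(tibble::tibble(time_s = t, value = v), "gisi", 30, "mm")
}

test_that("GISI is a non-negative symmetric x-distance", {
  expect_equal(gisi(10, 10), 0)
  expect_equal(gisi(10, -5), 15)
  expect_equal(gisi(10, -5, signed = TRUE), 15)
  expect_equal(gisi(-5, 10, signed = TRUE), -15)
  expect_true(is.na(gisi(NA, 3)))
  set.seed(1)
  a <- rnorm(100); b <- rnorm(100)
  expect_equal(gisi(a, b), gisi(b, a))
  expect_true(all(gisi(a, b) >= 0))
})

test_that("GISI at peak force samples the nearest gaze point at the force maximum", {
  tf <- seq(0, 1, by = 1 / 400)
  pulse <- sensor_stream(tibble::tibble(
    time_s = tf, value = 2 * sin(pi * tf)^2), "force_tray", 400, "N")
  seg <- tibble::tibble(onset_s = 0, offset_s = 1)
  tg <- seq(0, 1, by = 1 / 30)

  # constant GISI: result is the constant
  r <- gisi_at_peak_force(seg, pulse, gaze_stream(tg, rep(42, length(tg))))
  expect_equal(r$gisi_mm, 42)
  expect_equal(r$peak_force_time_s, 0.5, tolerance = 1 / 400)

  # linear GISI ramp 0 -> 100 with the peak at the midpoint: ~50
  r2 <- gisi_at_peak_force(seg, pulse, gaze_stream(tg, 100 * tg))
  expect_equal(r2$gisi_mm, 50, tolerance = 100 / 30 / 2)

  # flat force: tied maximum everywhere resolves to the segment onset
  flat <- sensor_stream(tibble::tibble(time_s = tf, value = rep(1, length(tf))),
                        "force_tray", 400, "N")
  r3 <- gisi_at_peak_force(seg, flat, gaze_stream(tg, 100 * tg))
  expect_equal(r3$peak_force_time_s, 0)
  expect_equal(r3$gisi_mm, 0)
})

test_that("progress profiles snapshot the quartiles", {
  tg <- seq(0, 2, by = 1 / 30)
  seg <- tibble::tibble(onset_s = 0, offset_s = 2)
  half_sample <- 100 / 60 / 2  # value change per half gaze period on the ramp

  p1 <- progress_profile(seg, gaze_stream(tg, rep(30, length(tg))))
  expect_equal(unlist(p1[1, 1:5], use.names = FALSE), rep(30, 5))

  p2 <- progress_profile(seg, gaze_stream(tg, 50 * tg))
  expect_equal(unlist(p2[1, 1:5], use.names = FALSE), c(0, 25, 50, 75, 100),
               tolerance = half_sample + 1e-9)

  v <- 100 - 100 * abs(tg - 1)
  p3 <- progress_profile(seg, gaze_stream(tg, v))
  expect_equal(unlist(p3[1, 1:5], use.names = FALSE), c(0, 50, 100, 50, 0),
               tolerance = 2 * half_sample + 1e-9)

  short <- tibble::tibble(onset_s = 0, offset_s = 0.1)
  p4 <- progress_profile(short, gaze_stream(tg, 50 * tg))
  expect_true(p4$too_short)
  expect_true(all(is.na(unlist(p4[1, 1:5]))))
})

test_that("temporal offset recovers pure shifts with the right sign", {
  set.seed(3)
  t <- (0:299) / 30
  base <- sin(2 * pi * 0.4 * t) + 0.3 * sin(2 * pi * 0.11 * t)
  gaze <- gaze_stream(t, c(base[5:300], base[1:4]))  # gaze sees the future
  hand <- sensor_stream(tibble::tibble(time_s = t, value = base), "hand_x", 30)
  o <- temporal_offset(gaze, hand)
  expect_equal(o$lag_samples, 4)
  expect_equal(o$offset_ms, 4 / 30 * 1000)

  same <- temporal_offset(hand, hand)
  expect_equal(same$lag_samples, 0)
  expect_equal(same$peak_correlation, 1)

  # antisymmetry and affine invariance
  o_rev <- temporal_offset(hand, gaze)
  expect_equal(o_rev$lag_samples, -o$lag_samples)
  hand2 <- sensor_stream(tibble::tibble(time_s = t, value = 3 * base + 100),
                         "hand_x", 30)
  o2 <- temporal_offset(gaze, hand2)
  expect_equal(o2$lag_samples, o$lag_samples)
  expect_equal(o2$peak_correlation, o$peak_correlation, tolerance = 1e-9)

  flat <- sensor_stream(tibble::tibble(time_s = t, value = rep(1, 300)),
                        "hand_x", 30)
  expect_error(temporal_offset(gaze, flat), "near-constant")
  expect_error(temporal_offset(gaze, hand, max_lag_ms = 10), "sample period")
})

test_that("force summaries compute durations, peaks, and torque integrals", {
  tf <- seq(0, 1, by = 1 / 400)
  streams <- list(
    force_tray = sensor_stream(tibble::tibble(
      time_s = tf, value = 2 * sin(pi * tf)^2), "force_tray", 400, "N"),
    torque_tray = sensor_stream(tibble::tibble(
      time_s = tf, value = rep(0.1, length(tf))), "torque_tray", 400, "N.m")
  )
  segs <- tibble::tibble(kind = "coarse_collection", peg = 1L,
                         onset_s = 0.25, offset_s = 0.75, transducer = "tray")
  out <- force_summaries(segs, streams)
  expect_equal(out$duration_ms, 500)
  expect_equal(out$peak_normal_force_N, 2, tolerance = 1e-4)
  expect_equal(out$total_torque, 0.05, tolerance = 1e-6)

  out_sum <- force_summaries(segs, streams, torque_mode = "sum")
  expect_equal(out_sum$total_torque, 0.1 * sum(tf >= 0.25 & tf <= 0.75))

  zero <- streams
  zero$force_tray$value <- 0 * zero$force_tray$value
  zero$torque_tray$value <- 0 * zero$torque_tray$value
  out0 <- force_summaries(segs, zero)
  expect_equal(out0$peak_normal_force_N, 0)
  expect_equal(out0$total_torque, 0)

  far <- dplyr::mutate(segs, onset_s = 5, offset_s = 6)
  expect_error(force_summaries(far, streams), "outside stream range")
})
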