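cfg_desk <- cpt_config(min_segment_samples = 8)

test_that("a pure staircase detrends to an identically zero residual", {
  steps <- data.frame(time = c(1, 2, 3), height = rep(-0.0745, 3))
  s <- build_force_stream(4, rate = 400, steps = steps)
  out <- detrend_load(s, cfg_desk, decimate = 1)
  expect_true(all(abs(out$value) < 1e-12))
})

test_that("an already-flat zero series is returned unchanged", {
  s <- build_force_stream(2, rate = 400)
  out <- detrend_load(s, cfg_desk, decimate = 1)
  expect_equal(out$value, s$value)
})

test_that("staircase plus disjoint pulses recenters per-trial baselines to zero", {
  # 8 downward steps of one peg weight, each inside a contact pulse
  t0s <- seq(0.5, by = 1.5, length.out = 8)
  pulses <- data.frame(t0 = t0s, t1 = t0s + 0.3, amp = 1.2)
  steps <- data.frame(time = t0s + 0.15, height = rep(-0.0745, 8))
  s <- build_force_stream(13, rate = 400, steps = steps, pulses = pulses)
  out <- detrend_load(s, cfg_desk, decimate = 1)
  for (i in seq_len(8)) {
    on <- out$value[which.min(abs(out$time_s - pulses$t0[i]))]
    off <- out$value[which.min(abs(out$time_s - pulses$t1[i]))]
    expect_lt(abs((on + off) / 2), 1e-6)
  }
  # residual carries the pulse; the step time inside a pulse is
  # unidentifiable, so the peak may be off by up to one peg weight
  peak <- max(out$value[out$time_s > pulses$t0[1] & out$time_s < pulses$t1[1]])
  expect_equal(peak, 1.2, tolerance = 0.0745 / 1.2)
})

test_that("series without quiescent intervals fail loudly", {
  t <- (0:799) / 400
  s <- sensor_stream(tibble::tibble(time_s = t, value = sin(2 * pi * 3 * t)),
                     "force_tray", 400)
  expect_error(detrend_load(s, cfg_desk, decimate = 1), "quiescent")
  expect_error(detrend_load(sensor_stream(
    tibble::tibble(time_s = numeric(0), value = numeric(0)),
    "force_tray", 400), cfg_desk), "empty")
})

test_that("detrending tolerates measurement noise", {
  set.seed(14)
  t0s <- seq(0.5, by = 1.5, length.out = 4)
  pulses <- data.frame(t0 = t0s, t1 = t0s + 0.3, amp = 1.2)
  steps <- data.frame(time = t0s + 0.15, height = rep(-0.0745, 4))
  s <- build_force_stream(7, rate = 400, steps = steps, pulses = pulses,
                          noise_sd = 0.01)
  out <- detrend_load(s, cfg_desk, decimate = 1)
  stair <- attr(out, "staircase")
  truth <- -0.0745 * rowSums(outer(out$time_s, steps$time, ">="))
  # compare away from the pulses: inside a pulse the step time (hence the
  # staircase) is unidentifiable to within the contact interval
  quiet <- rowSums(outer(out$time_s, pulses$t0, ">") &
                     outer(out$time_s, pulses$t1 + 0.1, "<")) == 0
  expect_lt(max(abs(stair[quiet] - truth[quiet])), 0.02)
  expect_equal(nrow(attr(out, "active")), 4)
})
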