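test_that("peg load force follows mass times gravity", {
  p <- sim_params()
  expect_equal(peg_load_force(0, p), 0)
  expect_equal(peg_load_force(1, p), 0.0076 * 9.80665)  # ~0.0745 N
  expect_equal(peg_load_force(8, p), 8 * 0.0076 * 9.80665)  # ~0.5962 N
  expect_error(peg_load_force(-1, p), ">= 0")
})

test_that("identical seed and config give bit-identical sessions", {
  sch <- phase_schedule()
  a <- simulate_session(sch, sim_params(), seed = 7)
  b <- simulate_session(sch, sim_params(), seed = 7)
  expect_identical(a$streams, b$streams)
  expect_identical(a$truth, b$truth)
  c <- simulate_session(sch, sim_params(), seed = 8)
  expect_false(identical(a$streams$gaze_x$value, c$streams$gaze_x$value))
})

test_that("identity coupling with zero lead pins gaze to the hand", {
  p <- noise_free_params(kappa = c(baseline = 1, sham = 1, anesthesia = 1),
                         gaze_lead_ms = c(baseline = 0, sham = 0, anesthesia = 0))
  ses <- simulate_session(phase_schedule(), p, seed = 1,
                          channels = c("hand", "gaze"))
  g <- ses$streams$gaze_x
  h <- ses$streams$hand_x
  common <- intersect(g$time_s, h$time_s)
  expect_gt(length(common), 100)
  expect_equal(g$value[match(common, g$time_s)],
               h$value[match(common, h$time_s)], tolerance = 1e-12)
})

test_that("ground truth holds one collection and one delivery pulse per peg", {
  ses <- simulate_session(phase_schedule(), noise_free_params(), seed = 2)
  tr <- ses$truth$segments
  expect_equal(sum(tr$kind == "coarse_collection"), 8)
  expect_equal(sum(tr$kind == "precise_delivery"), 8)
  expect_equal(sum(tr$kind == "transport"), 8)
  expect_equal(sum(tr$kind == "peg_free"), 8)
  # segments tile the phase: each offset is the next onset
  ord <- tr[order(tr$onset_s), ]
  expect_true(all(abs(utils::head(ord$offset_s, -1) -
                        utils::tail(ord$onset_s, -1)) < 1e-9))
})

test_that("tray load is a monotone staircase with the peg-weight step", {
  p <- noise_free_params()
  ses <- simulate_session(phase_schedule(phase = "placement"), p, seed = 3)
  tr <- ses$truth$segments
  f <- ses$streams$force_tray
  # sample the tray mid-transport (quiescent, pulse-free moments)
  mid <- (tr$onset_s[tr$kind == "transport"] +
            tr$offset_s[tr$kind == "transport"]) / 2
  loads <- vapply(mid, function(tt) f$value[which.min(abs(f$time_s - tt))],
                  numeric(1))
  expect_true(all(diff(loads) < 0))  # placement: tray loses pegs
  expect_equal(diff(loads), rep(-peg_load_force(1, p), 7), tolerance = 1e-9)

  ses_r <- simulate_session(phase_schedule(phase = "retrieval"), p, seed = 3)
  tr_r <- ses_r$truth$segments
  f_r <- ses_r$streams$force_tray
  mid_r <- (tr_r$onset_s[tr_r$kind == "transport"] +
              tr_r$offset_s[tr_r$kind == "transport"]) / 2
  loads_r <- vapply(mid_r, function(tt) f_r$value[which.min(abs(f_r$time_s - tt))],
                    numeric(1))
  expect_true(all(diff(loads_r) > 0))  # retrieval: tray gains pegs
})

test_that("gaze-hand separation shrinks as coupling rises", {
  sep <- vapply(c(0, 0.3, 0.6, 0.9, 1), function(k) {
    p <- noise_free_params(kappa = c(baseline = k, sham = k, anesthesia = k),
                           gaze_lead_ms = c(baseline = 0, sham = 0,
                                            anesthesia = 0))
    ses <- simulate_session(phase_schedule(), p, seed = 5,
                            channels = c("hand", "gaze"))
    g <- ses$streams$gaze_x
    h <- ses$streams$hand_x
    common <- intersect(g$time_s, h$time_s)
    mean(abs(g$value[match(common, g$time_s)] -
               h$value[match(common, h$time_s)]))
  }, numeric(1))
  expect_true(all(diff(sep) <= 1e-9))
})

test_that("a gaze lead longer than the shortest action is rejected", {
  expect_error(sim_params(gaze_lead_ms = c(baseline = 400, sham = 150,
                                           anesthesia = 75)),
               "gaze_lead_ms")
  expect_error(sim_params(kappa = c(baseline = 1.2, sham = 0.5,
                                    anesthesia = 0.5)), "kappa")
  expect_error(simulate_session(phase_schedule()[0, ], sim_params()),
               "empty schedule")
})
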