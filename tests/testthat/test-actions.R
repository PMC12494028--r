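test_that("a noise-free placement phase yields the full action inventory", {
  ses <- simulate_session(phase_schedule(), noise_free_params(), seed = 4)
  segs <- extract_actions(ses$streams, ses$manifest)
  expect_equal(sum(segs$kind == "coarse_collection"), 8)
  expect_equal(sum(segs$kind == "precise_delivery"), 8)
  expect_equal(sum(segs$kind == "transport"), 8)
  expect_equal(sum(segs$kind == "peg_free"), 8)  # initial reach + 7 interior

  # within the phase, actions tile without overlap in the canonical order
  ord <- segs[order(segs$onset_s), ]
  expect_equal(ord$kind,
               rep(c("peg_free", "coarse_collection", "transport",
                     "precise_delivery"), 8))
  expect_true(all(ord$offset_s > ord$onset_s))
  expect_true(all(utils::head(ord$offset_s, -1) <=
                    utils::tail(ord$onset_s, -1) + 1e-9))
  # transport onset is the preceding collection offset; peg-free onset is
  # the preceding delivery offset
  expect_equal(ord$onset_s[ord$kind == "transport"],
               ord$offset_s[ord$kind == "coarse_collection"])
  expect_equal(ord$onset_s[ord$kind == "peg_free"][-1],
               utils::head(ord$offset_s[ord$kind == "precise_delivery"], -1))
})

test_that("retrieval swaps transducer roles (precise collection, coarse delivery)", {
  ses <- simulate_session(phase_schedule(phase = "retrieval"),
                          noise_free_params(), seed = 5)
  segs <- extract_actions(ses$streams, ses$manifest)
  expect_equal(sum(segs$kind == "precise_collection"), 8)
  expect_equal(sum(segs$kind == "coarse_delivery"), 8)
  expect_equal(unique(segs$transducer[segs$kind == "precise_collection"]), "board")
  expect_equal(unique(segs$transducer[segs$kind == "coarse_delivery"]), "tray")
})

test_that("detected contact boundaries track ground truth at default noise", {
  errs <- c()
  for (seed in 1:3) {
    ses <- simulate_session(
      phase_schedule(block = 1 + seed %% 2, hand = "nondominant",
                     phase = c("placement", "retrieval")[1 + seed %% 2]),
      sim_params(), seed = seed)
    segs <- extract_actions(ses$streams, ses$manifest)
    errs <- c(errs, boundary_errors_ms(ses, segs))
  }
  expect_gte(mean(abs(errs) <= 10), 0.95)
})

test_that("count mismatches fail loudly with diagnostics", {
  ses <- simulate_session(phase_schedule(), noise_free_params(), seed = 6)
  expect_error(extract_actions(ses$streams, ses$manifest, pegs_per_phase = 9L),
               "expected 9")
  expect_error(extract_actions(list(), ses$manifest), "force_tray")
})
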