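test_that("descriptive delta-delta is plain cell-mean arithmetic", {
  d <- tidyr::expand_grid(subject = c("S1", "S2"), block = 1:2,
                          hand = c("T", "U"), rep = 1:3)
  d$treated <- d$hand == "T"
  base <- c(T1 = 100, T2 = 50, U1 = 90, U2 = 110)
  d$value <- base[paste0(d$hand, d$block)]
  spec <- contrast_spec("value")
  dc <- delta_contrasts(d, spec)
  expect_equal(unname(dc$delta["treated"]), -50)
  expect_equal(unname(dc$delta["untreated"]), 20)
  expect_equal(dc$ddelta, -70)

  # swapping the treated labels flips the sign
  d2 <- dplyr::mutate(d, treated = !treated)
  expect_equal(delta_contrasts(d2, spec)$ddelta, 70)

  # empty cell errors name the cell
  d3 <- d[!(d$block == 2 & d$hand == "T"), ]
  expect_error(delta_contrasts(d3, spec), "block 2, hand T")
})

test_that("model-based delta-delta equals the descriptive one on balanced data", {
  d <- simulate_gisi_data(n_subjects = 8, effect = -40, seed = 21)
  spec <- contrast_spec("value")
  dc <- delta_contrasts(d, spec)
  fm <- fit_mixed_model(d, spec)
  expect_equal(fm$ddelta$estimate, dc$ddelta, tolerance = 1e-6)

  # near-zero-variance data: contrast collapses to the arithmetic value
  d0 <- simulate_gisi_data(n_subjects = 3, effect = -40, sd_subject = 0,
                           sd_round = 0, sd_resid = 1e-6, seed = 2)
  fm0 <- fit_mixed_model(d0, spec)
  expect_equal(fm0$ddelta$estimate, delta_contrasts(d0, spec)$ddelta,
               tolerance = 1e-4)
})

test_that("injected treatment effects are recovered by both routes", {
  d <- simulate_gisi_data(n_subjects = 12, effect = -50, seed = 31)
  spec <- contrast_spec("value")
  expect_equal(delta_contrasts(d, spec)$ddelta, -50, tolerance = 0.1 * 50)
  fm <- fit_mixed_model(d, spec)
  expect_equal(fm$ddelta$estimate, -50, tolerance = 0.1 * 50)
  expect_lt(fm$wald$p_value[fm$wald$term == "block:hand"], 1e-6)
})

test_that("null data keep the delta-delta contrast near zero (coverage)", {
  # scaled-down null-calibration study: the contrast estimate should sit
  # within 2 SE of zero in about 95% of replicates
  hits <- 0
  n_rep <- 40
  for (i in seq_len(n_rep)) {
    d <- simulate_gisi_data(n_subjects = 6, n_rounds = 2, n_series = 3,
                            effect = 0, seed = 1000 + i)
    fm <- fit_mixed_model(d, contrast_spec("value"))
    if (abs(fm$ddelta$estimate) <= 2 * fm$ddelta$se) hits <- hits + 1
  }
  expect_gte(hits / n_rep, 0.85)
})

test_that("fixed-effect estimates ignore subject labels (exchangeability)", {
  d <- simulate_gisi_data(n_subjects = 6, seed = 41)
  spec <- contrast_spec("value")
  f1 <- fit_mixed_model(d, spec)
  set.seed(99)
  perm <- sample(unique(d$subject))
  names(perm) <- unique(d$subject)
  d2 <- dplyr::mutate(d, subject = unname(perm[subject]))
  f2 <- fit_mixed_model(d2, spec)
  expect_equal(lme4::fixef(f1$fit), lme4::fixef(f2$fit), tolerance = 1e-6)
})

test_that("learning trends recover slopes over within-block series", {
  spec <- contrast_spec("value", fixed = c("block", "hand", "series_block"))

  d <- simulate_gisi_data(n_subjects = 4, sd_subject = 0, sd_round = 0,
                          sd_resid = 0, seed = 2)
  d$value <- 42
  flat <- learning_trends(d, spec)
  expect_equal(flat$slope, rep(0, 4), tolerance = 1e-10)

  d$value <- 10 + 2 * d$series_block
  line <- learning_trends(d, spec)
  expect_equal(line$slope, rep(2, 4), tolerance = 1e-8)

  set.seed(3)
  d$value <- 100 - 1.5 * d$series_block + rnorm(nrow(d), 0, 2) +
    rep(rnorm(4, 0, 5), each = nrow(d) / 4)
  noisy <- learning_trends(d, spec)
  expect_equal(noisy$slope, rep(-1.5, 4), tolerance = 0.2)

  short <- d[d$series_block <= 2, ]
  expect_error(learning_trends(short, spec), "3 series")
  expect_error(learning_trends(d, contrast_spec("value")), "series_block")
})

test_that("degenerate inputs are rejected", {
  d <- simulate_gisi_data(n_subjects = 1, seed = 5)
  expect_error(fit_mixed_model(d, contrast_spec("value")), "2 subjects")
  d2 <- simulate_gisi_data(n_subjects = 4, seed = 6)
  d2$treated <- TRUE
  expect_error(fit_mixed_model(d2, contrast_spec("value")), "treated")
  expect_error(contrast_spec("value", fixed = c("block", "hand", "banana")),
               "unknown fixed effect")
})
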