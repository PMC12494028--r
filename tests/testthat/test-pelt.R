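test_that("single and double mean shifts are recovered exactly", {
  cfg <- cpt_config(penalty = 1, min_segment_samples = 2)
  expect_equal(pelt_changepoints(rep(3, 50), cfg), integer(0))

  x <- c(rep(0, 100), rep(5, 100))
  expect_equal(pelt_changepoints(x, cfg), 100L)

  y <- c(rep(0, 60), rep(5, 60), rep(0, 60))
  expect_equal(pelt_changepoints(y, cfg), c(60L, 120L))

  expect_error(pelt_changepoints(c(1, 2, 3), cpt_config(min_segment_samples = 2)),
               "shorter")
})

test_that("pruned search matches the exhaustive optimum on random series", {
  set.seed(101)
  for (i in 1:60) {
    n <- sample(12:60, 1)
    m <- sample(2:5, 1)
    k <- sample(0:3, 1)
    sites <- seq(m, n - m)
    k <- min(k, length(sites))
    cp_true <- sort(sample(sites, k))
    mu <- cumsum(c(0, sample(c(-5, -2, 2, 5), k, replace = TRUE)))
    x <- mu[findInterval(seq_len(n), cp_true + 1) + 1] +
      rnorm(n, 0, sample(c(0.1, 0.5, 1), 1))
    beta <- sample(c(0.5, 2, 5), 1)
    got <- pelt_changepoints(x, cpt_config(penalty = beta, min_segment_samples = m))
    want <- dp_segmentation_oracle(x, beta, m)
    expect_identical(got, as.integer(want))
  }
})

test_that("pruned search matches full enumeration at tiny n", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(8:14, 1)
    x <- rnorm(n) + rep(c(0, 4), length.out = n, each = ceiling(n / 2))[1:n]
    beta <- sample(c(1, 3), 1)
    got <- pelt_changepoints(x, cpt_config(penalty = beta, min_segment_samples = 2))
    want <- enumeration_oracle(x, beta, 2, max_k = 3)
    expect_equal(segmentation_objective(x, got, beta),
                 segmentation_objective(x, want, beta), tolerance = 1e-9)
  }
})

test_that("segmentation is invariant to constant offsets", {
  set.seed(33)
  x <- c(rnorm(80), rnorm(80, 4), rnorm(40, -2))
  cfg <- cpt_config(penalty = 10, min_segment_samples = 5)
  expect_identical(pelt_changepoints(x, cfg),
                   pelt_changepoints(x + 123.4, cfg))
})

test_that("ties break toward the earlier index", {
  # perfectly symmetric two-level series: split position is ambiguous within
  # the flat middle, the earlier admissible index must win deterministically
  x <- c(rep(0, 10), rep(1, 10))
  cfg <- cpt_config(penalty = 0.01, min_segment_samples = 2)
  a <- pelt_changepoints(x, cfg)
  b <- pelt_changepoints(x, cfg)
  expect_identical(a, b)
  expect_equal(a, 10L)
})
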