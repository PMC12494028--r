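test_that("Type-2 Wald statistics match classic Type-II sums of squares", {
  set.seed(11)
  n <- 120
  d <- data.frame(A = factor(sample(letters[1:3], n, TRUE)),
                  B = factor(sample(LETTERS[1:2], n, TRUE)))
  d$y <- rnorm(n) + as.numeric(d$A) + 0.5 * (d$A == "b") * (d$B == "B")
  fit <- lm(y ~ A * B, d)
  w <- type2_wald(fit)

  # independent oracle: residual-sum-of-squares model comparisons that
  # exclude each term's higher-order relatives
  s2 <- summary(fit)$sigma^2
  rss <- function(f) sum(resid(lm(f, d))^2)
  oracle <- c(A = rss(y ~ B) - rss(y ~ A + B),
              B = rss(y ~ A) - rss(y ~ A + B),
              `A:B` = rss(y ~ A + B) - rss(y ~ A * B)) / s2
  expect_equal(w$chisq, unname(oracle[w$term]), tolerance = 1e-8)
  expect_equal(w$df, c(2, 1, 2))
})

test_that("marginal cell means reproduce closed-form means on balanced data", {
  set.seed(12)
  d <- tidyr::expand_grid(A = factor(c("a", "b")), B = factor(c("x", "y", "z")),
                          rep = 1:10)
  d$y <- rnorm(nrow(d), mean = as.numeric(d$A) * 2 + as.numeric(d$B))
  fit <- lm(y ~ A * B, d)
  em <- emm_cells(fit, "A")
  # saturated balanced model: EMM over B equals the raw mean per A level
  raw <- tapply(d$y, d$A, mean)
  expect_equal(em$cells$emmean, as.numeric(raw[as.character(em$cells$A)]),
               tolerance = 1e-10)
})

test_that("Tukey adjustment never reports smaller p than the unadjusted test", {
  d <- simulate_gisi_data(n_subjects = 6, seed = 9)
  fit <- fit_mixed_model(d, contrast_spec("value"))
  expect_true(all(fit$posthoc$p_adjusted >= fit$posthoc$p_value - 1e-12))
  expect_equal(nrow(fit$posthoc), choose(4, 2))  # 2 blocks x 2 hands
})
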