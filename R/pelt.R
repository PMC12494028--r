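# Pruned Exact Linear Time change-point detection for a piecewise-constant
# mean with quadratic (L2) cost. The pruned dynamic program returns the same
# segmentation as exhaustive search (the quadratic cost satisfies the
# pruning condition with K = 0), at close to linear cost in practice.

#' Change-point detection configuration
#'
#' @param penalty Per-change-point penalty; `NULL` picks a BIC-like default
#'   `2 * sigma^2 * log(n)` with `sigma` estimated from the median absolute
#'   deviation of the differenced series.
#' @param min_segment_samples Minimum samples per segment (>= 2). The default
#'   of 40 suppresses contact chatter at 1,600 Hz (25 ms).
#' @return A `cpt_config` list.
#' @export
cpt_config <- function(penalty = NULL, min_segment_samples = 40L) {
  if (!is.null(penalty) && penalty < 0) {
    stop("cpt_config: penalty must be >= 0", call. = FALSE)
  }
  if (min_segment_samples < 2) {
    stop("cpt_config: min_segment_samples must be >= 2", call. = FALSE)
  }
  structure(list(penalty = penalty,
                 min_segment_samples = as.integer(min_segment_samples)),
            class = "cpt_config")
}

# Robust noise scale of a series with piecewise-smooth mean.
noise_scale <- function(x) {
  s <- stats::mad(diff(x)) / sqrt(2)
  # noise-free floor: keep the implied penalty well above the floating-point
  # cancellation error of the cumulative-sum cost, or exact plateaus shatter
  if (!is.finite(s) || s <= 0) s <- 1e-4 * max(1e-8, diff(range(x)))
  s
}

default_penalty <- function(x) 2 * noise_scale(x)^2 * log(length(x))

#' PELT change-point detection
#'
#' Minimizes `sum of segment costs + penalty * (number of change points)`
#' over all segmentations, where the cost of a segment is its within-segment
#' sum of squares about the mean. Returns the last index of every segment
#' but the final one, so a mean shift between indices `k` and `k + 1` is
#' reported as `k`. Ties are broken toward the earlier index.
#'
#' @param x Numeric series.
#' @param config A [cpt_config()].
#' @return Integer vector of change-point indices (possibly empty).
#' @examples
#' pelt_changepoints(c(rep(0, 20), rep(5, 20)), cpt_config(min_segment_samples = 2))
#' @export
pelt_changepoints <- function(x, config = cpt_config()) {
  n <- length(x)
  m <- config$min_segment_samples
  if (n < 2L * m) {
    stop("pelt_changepoints: series shorter than 2 * min_segment_samples",
         call. = FALSE)
  }
  beta <- config$penalty %||% default_penalty(x)

  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  segcost <- function(s, t) {
    # cost of x[(s+1):t], vectorized over s
    len <- t - s
    sm <- S[t + 1L] - S[s + 1L]
    (S2[t + 1L] - S2[s + 1L]) - sm^2 / len
  }

  F <- rep(Inf, n + 1L)
  F[1L] <- -beta
  prev <- integer(n + 1L)
  cand <- integer(0)
  expiry <- numeric(0)  # candidate s is dropped once t >= expiry

  for (t in seq_len(n)) {
    if (t - m >= 0L) {                        # s becomes eligible when t-s >= m
      cand <- c(cand, t - m)
      expiry <- c(expiry, Inf)
    }
    live <- expiry > t
    cand <- cand[live]
    expiry <- expiry[live]
    if (!length(cand)) next
    vals <- F[cand + 1L] + segcost(cand, t)
    i <- which.min(vals)                      # earliest minimizer
    F[t + 1L] <- vals[i] + beta
    prev[t + 1L] <- cand[i]
    # A candidate dominated now stays usable while the dominating split is
    # itself too recent to be eligible (minimum segment length), so removal
    # is scheduled m steps ahead rather than applied immediately.
    newly <- vals > F[t + 1L] & !is.finite(expiry)
    expiry[newly] <- t + m
  }

  if (!is.finite(F[n + 1L])) {
    stop("pelt_changepoints: no admissible segmentation", call. = FALSE)
  }
  cps <- integer(0)
  t <- n
  while (t > 0L) {
    s <- prev[t + 1L]
    if (s > 0L) cps <- c(s, cps)
    t <- s
  }
  cps
}
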