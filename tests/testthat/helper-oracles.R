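# Independent oracles and small fixture builders used across the suite.

# Unpruned O(n^2) optimal-partition dynamic program: exhaustive-search
# optimum for the penalized piecewise-constant-mean segmentation. Written
# independently of the pruned path it checks.
dp_segmentation_oracle <- function(x, penalty, min_seg) {
  n <- length(x)
  S <- c(0, cumsum(x))
  S2 <- c(0, cumsum(x^2))
  segcost <- function(s, t) (S2[t + 1] - S2[s + 1]) - (S[t + 1] - S[s + 1])^2 / (t - s)
  F <- rep(Inf, n + 1)
  F[1] <- -penalty
  prev <- integer(n + 1)
  for (t in min_seg:n) {
    for (s in 0:(t - min_seg)) {
      if (s > 0 && !is.finite(F[s + 1])) next
      v <- F[s + 1] + segcost(s, t) + penalty
      if (v < F[t + 1] - 1e-12) {
        F[t + 1] <- v
        prev[t + 1] <- s
      }
    }
  }
  cps <- integer(0)
  t <- n
  while (t > 0) {
    s <- prev[t + 1]
    if (s > 0) cps <- c(s, cps)
    t <- s
  }
  cps
}

# Total objective of a given segmentation (for enumeration cross-checks).
segmentation_objective <- function(x, cps, penalty) {
  bounds <- c(0, cps, length(x))
  cost <- 0
  for (j in seq_len(length(bounds) - 1)) {
    seg <- x[(bounds[j] + 1):bounds[j + 1]]
    cost <- cost + sum((seg - mean(seg))^2)
  }
  cost + penalty * length(cps)
}

# Full enumeration over all admissible change-point sets (tiny n only).
enumeration_oracle <- function(x, penalty, min_seg, max_k = 3) {
  n <- length(x)
  best <- list(cps = integer(0), obj = segmentation_objective(x, integer(0), penalty))
  sites <- seq_len(n - 1)
  for (k in seq_len(max_k)) {
    for (cps in utils::combn(sites, k, simplify = FALSE)) {
      lens <- diff(c(0, cps, n))
      if (any(lens < min_seg)) next
      obj <- segmentation_objective(x, cps, penalty)
      if (obj < best$obj - 1e-12) best <- list(cps = cps, obj = obj)
    }
  }
  as.integer(best$cps)
}

# One-phase schedule from the first experiment design.
phase_schedule <- function(block = 1, hand = "dominant", round = 1, series = 1,
                           phase = "placement") {
  sch <- build_schedule(exp1_design())
  sch[sch$block == block & sch$hand == hand & sch$round == round &
        sch$series == series & sch$phase == phase, ]
}

noise_free_params <- function(...) {
  sim_params(noise_sd = c(force = 0, torque = 0, hand = 0, gaze = 0), ...)
}

# Boundary errors (ms) between detected and ground-truth contact events
# (collections and deliveries: the force-defined boundaries).
boundary_errors_ms <- function(session, segs) {
  truth <- session$truth$segments
  contact <- c("coarse_collection", "precise_collection",
               "coarse_delivery", "precise_delivery")
  d <- segs[segs$kind %in% contact, ]
  t <- truth[truth$kind %in% contact, ]
  m <- merge(d, t, by = c("block", "hand", "round", "series", "phase",
                          "kind", "peg"), suffixes = c(".det", ".tru"))
  c((m$onset_s.det - m$onset_s.tru) * 1000,
    (m$offset_s.det - m$offset_s.tru) * 1000)
}

# A constructed force stream: piecewise-constant staircase plus
# raised-cosine pulses, on a uniform grid.
build_force_stream <- function(duration_s, rate = 400,
                               steps = NULL, pulses = NULL, noise_sd = 0,
                               channel = "force_tray") {
  t <- (0:floor(duration_s * rate)) / rate
  v <- numeric(length(t))
  if (!is.null(steps)) {
    for (i in seq_len(nrow(steps))) {
      v <- v + steps$height[i] * (t >= steps$time[i])
    }
  }
  if (!is.null(pulses)) {
    for (i in seq_len(nrow(pulses))) {
      inside <- t >= pulses$t0[i] & t <= pulses$t1[i]
      v[inside] <- v[inside] + pulses$amp[i] / 2 *
        (1 - cos(2 * pi * (t[inside] - pulses$t0[i]) / (pulses$t1[i] - pulses$t0[i])))
    }
  }
  if (noise_sd > 0) v <- v + rnorm(length(v), 0, noise_sd)
  sensor_stream(tibble::tibble(time_s = t, value = v),
                channel = channel, nominal_rate = rate, unit = "N")
}
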