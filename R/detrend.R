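# Remove the accumulating peg-weight load from a force series so that every
# trial's contact baseline is re-centered to zero.

# Partition one force series into quiescent runs (long, flat plateaus) and
# the active (contact) intervals between them, from a PELT segmentation.
# Fringe segments of a contact pulse are short and sloped, so they fail the
# plateau test and are absorbed into the active interval — this is what
# keeps the recovered staircase exact at pulse onset/offset points.
classify_runs <- function(x, cps, sigma, rate, min_quiet_s = 0.15,
                          merge_tol = NULL) {
  merge_tol <- merge_tol %||% max(0.02, 3 * sigma)
  min_quiet <- max(2L, round(min_quiet_s * rate))
  bounds <- c(0L, cps, length(x))
  k <- length(bounds) - 1L
  seg <- tibble::tibble(
    from = bounds[-(k + 1L)] + 1L,
    to = bounds[-1L]
  )
  seg$len <- seg$to - seg$from + 1L
  seg$mean <- vapply(seq_len(k), function(j) mean(x[seg$from[j]:seg$to[j]]),
                     numeric(1))
  seg$sd <- vapply(seq_len(k), function(j) stats::sd(x[seg$from[j]:seg$to[j]]),
                   numeric(1))
  seg$sd[is.na(seg$sd)] <- 0
  seg$plateau <- seg$len >= min_quiet & seg$sd <= 3 * sigma + 1e-12

  if (!any(seg$plateau)) {
    stop("detrend_load: no quiescent intervals found in series", call. = FALSE)
  }

  # merge consecutive plateau segments at the same level into quiescent runs
  runs <- list()
  j <- 1L
  while (j <= k) {
    if (!seg$plateau[j]) {
      j <- j + 1L
      next
    }
    from <- seg$from[j]
    to <- seg$to[j]
    while (j < k && seg$plateau[j + 1L] &&
           abs(seg$mean[j + 1L] - seg$mean[j]) <= merge_tol) {
      j <- j + 1L
      to <- seg$to[j]
    }
    runs[[length(runs) + 1L]] <- list(from = from, to = to,
                                      level = stats::median(x[from:to]))
    j <- j + 1L
  }
  dplyr::bind_rows(runs)
}

#' Detrend the accumulating peg-load staircase from a force series
#'
#' Delivered pegs add (and collected pegs remove) a persistent ~0.0745 N
#' offset on the transducers over a series. The staircase component is
#' estimated as the median force over each quiescent inter-action interval,
#' held piecewise-constant between detected steps, and subtracted so that
#' the per-trial baseline (average of the action onset and offset points
#' after detrending) is zero.
#'
#' @param force A [sensor_stream()] holding one series of one transducer.
#' @param config A [cpt_config()] for the underlying change-point detection.
#' @param decimate Decimation factor for the change-point pass only
#'   (`"auto"` targets ~200 Hz). Plateau levels, the staircase, and all
#'   downstream boundary refinement still use every sample; decimation only
#'   coarsens where the change-point search looks, which the sample-level
#'   refinement absorbs.
#' @return The detrended [sensor_stream()], with attributes `staircase`
#'   (numeric, same length), `runs` (quiescent runs: sample ranges and
#'   levels), and `active` (contact intervals between runs: `from`, `to`
#'   sample indices, pre/post levels).
#' @export
detrend_load <- function(force, config = cpt_config(), decimate = "auto") {
  x <- force$value
  n <- length(x)
  if (!n) stop("detrend_load: empty force stream", call. = FALSE)
  sigma <- noise_scale(x)
  rate <- stream_rate(force)
  dec <- if (identical(decimate, "auto")) max(1L, floor(rate / 200)) else
    as.integer(decimate)
  if (dec > 1L) {
    keep <- seq(1L, n, by = dec)
    cfg_dec <- cpt_config(config$penalty,
                          max(2L, round(config$min_segment_samples / dec)))
    cps <- keep[pelt_changepoints(x[keep], cfg_dec)]
  } else {
    cps <- pelt_changepoints(x, config)
  }
  runs <- classify_runs(x, cps, sigma, rate)

  stair <- numeric(n)
  nr <- nrow(runs)
  active <- list()
  stair[seq_len(runs$to[1])] <- runs$level[1]
  for (r in seq_len(nr - 1L)[nr > 1L]) {
    gap_from <- runs$to[r] + 1L
    gap_to <- runs$from[r + 1L] - 1L
    if (gap_from > gap_to) {
      # adjacent runs: a bare step with no contact interval
      step_at <- gap_from
    } else {
      step_at <- (gap_from + gap_to) %/% 2L
      active[[length(active) + 1L]] <-
        list(from = gap_from, to = gap_to,
             pre_level = runs$level[r], post_level = runs$level[r + 1L])
    }
    idx <- gap_from:runs$to[r + 1L]
    stair[idx] <- ifelse(idx < step_at, runs$level[r], runs$level[r + 1L])
  }
  if (runs$to[nr] < n) stair[(runs$to[nr] + 1L):n] <- runs$level[nr]
  # leading samples before the first run (e.g. a pulse right at the start)
  if (runs$from[1] > 1L) stair[seq_len(runs$from[1] - 1L)] <- runs$level[1]

  out <- sensor_stream(tibble::tibble(time_s = force$time_s, value = x - stair),
                       channel = stream_channel(force),
                       nominal_rate = stream_rate(force),
                       unit = attr(force, "unit"))
  attr(out, "staircase") <- stair
  attr(out, "runs") <- runs
  attr(out, "active") <- dplyr::bind_rows(active)
  attr(out, "sigma") <- sigma
  out
}
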