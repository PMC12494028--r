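# Dependent variables: GISI, GISI at peak force, action-progress profiles,
# durations, peak normal force, total torque, and gaze-hand temporal
# offsets.

#' Gaze-index separation index
#'
#' Horizontal distance between the gaze point and the index-finger position
#' at a common timestamp. Distance is a magnitude, so the absolute value is
#' taken; a signed variant is available for diagnostics.
#'
#' @param gaze_x,index_x Positions in mm on the screen-plane x axis.
#' @param signed Keep the sign (gaze minus index)?
#' @return Separation in mm; `NA` inputs propagate.
#' @export
gisi <- function(gaze_x, index_x, signed = FALSE) {
  d <- gaze_x - index_x
  if (signed) d else abs(d)
}

#' GISI time series on the gaze timebase
#'
#' Resamples the hand x-position onto the gaze timestamps (linear
#' interpolation, no extrapolation) and computes [gisi()] per sample.
#'
#' @param gaze_x,hand_x [sensor_stream()]s.
#' @return A [sensor_stream()] of GISI values at gaze timestamps that fall
#'   inside the hand stream's range.
#' @export
gisi_series <- function(gaze_x, hand_x) {
  rng <- range(hand_x$time_s)
  keep <- gaze_x$time_s >= rng[1] & gaze_x$time_s <= rng[2]
  g <- gaze_x[keep, , drop = FALSE]
  h <- resample_stream(hand_x, g$time_s)
  sensor_stream(tibble::tibble(time_s = g$time_s,
                               value = gisi(g$value, h$value)),
                channel = "gisi", nominal_rate = stream_rate(gaze_x),
                unit = "mm")
}

nearest_value <- function(stream, at) {
  i <- findInterval(at, stream$time_s)
  i <- pmin(pmax(i, 1L), nrow(stream))
  j <- pmin(i + 1L, nrow(stream))
  use_j <- (at - stream$time_s[i]) > (stream$time_s[j] - at)
  stream$value[ifelse(use_j, j, i)]
}

#' GISI at the time of peak normal force
#'
#' Finds the earliest maximum of the absolute detrended normal force within
#' the action and reads the GISI series at the nearest gaze sample.
#'
#' @param segment One-row segment (needs `onset_s`, `offset_s`).
#' @param force Detrended normal-force [sensor_stream()] covering the
#'   segment.
#' @param gisi A GISI [sensor_stream()] on the gaze timebase.
#' @return List with `gisi_mm` and `peak_force_time_s`.
#' @export
gisi_at_peak_force <- function(segment, force, gisi) {
  idx <- which(force$time_s >= segment$onset_s & force$time_s <= segment$offset_s)
  if (!length(idx)) stop("gisi_at_peak_force: force does not cover segment",
                         call. = FALSE)
  peak <- idx[which.max(abs(force$value[idx]))]  # which.max: earliest tie
  t_peak <- force$time_s[peak]
  in_seg <- gisi[gisi$time_s >= segment$onset_s & gisi$time_s <= segment$offset_s, ]
  val <- if (nrow(in_seg) && any(!is.na(in_seg$value))) {
    nearest_value(gisi, t_peak)
  } else NA_real_
  list(gisi_mm = val, peak_force_time_s = t_peak)
}

#' GISI snapshots at action-progress quartiles
#'
#' Progress runs from 0% at action onset to 100% at offset; the profile is
#' the GISI value at the gaze sample nearest each of
#' `{0, 25, 50, 75, 100}%`. Segments shorter than five gaze samples are
#' flagged (`too_short = TRUE`, values `NA`) and should be excluded.
#'
#' @param segment One-row segment.
#' @param gisi A GISI [sensor_stream()].
#' @return Tibble row with `ap0, ap25, ap50, ap75, ap100` (mm) and
#'   `too_short`.
#' @export
progress_profile <- function(segment, gisi) {
  dur <- segment$offset_s - segment$onset_s
  period <- 1 / stream_rate(gisi)
  qt <- segment$onset_s + c(0, 0.25, 0.5, 0.75, 1) * dur
  if (dur < 5 * period) {
    return(tibble::tibble(ap0 = NA_real_, ap25 = NA_real_, ap50 = NA_real_,
                          ap75 = NA_real_, ap100 = NA_real_, too_short = TRUE))
  }
  v <- nearest_value(gisi, qt)
  tibble::tibble(ap0 = v[1], ap25 = v[2], ap50 = v[3], ap75 = v[4], ap100 = v[5],
                 too_short = FALSE)
}

#' Gaze-hand temporal offset by cross-correlation
#'
#' The hand series is brought onto the gaze timebase and the Pearson
#' correlation between the mean-centered series is maximized over integer
#' sample lags. A positive offset means gaze leads the hand.
#'
#' @param gaze_x Gaze position [sensor_stream()] spanning the phase.
#' @param hand_x Hand position [sensor_stream()] (any rate; resampled).
#' @param max_lag_ms Search window, milliseconds (default ±1,000 ms).
#' @return List with `offset_ms`, `lag_samples`, `peak_correlation`.
#' @export
temporal_offset <- function(gaze_x, hand_x, max_lag_ms = 1000) {
  rng <- range(hand_x$time_s)
  keep <- gaze_x$time_s >= rng[1] & gaze_x$time_s <= rng[2]
  g <- gaze_x$value[keep]
  tg <- gaze_x$time_s[keep]
  h <- resample_stream(hand_x, tg)$value
  ok <- !is.na(g) & !is.na(h)
  g <- g[ok]; h <- h[ok]
  period <- 1 / stream_rate(gaze_x)
  L <- floor(max_lag_ms / 1000 / period)
  if (L < 1) stop("temporal_offset: max_lag_ms below one sample period",
                  call. = FALSE)
  n <- length(g)
  if (n < 2L * L + 10L) stop("temporal_offset: series too short for lag window",
                             call. = FALSE)
  if (stats::sd(g) < 1e-9 || stats::sd(h) < 1e-9) {
    stop("temporal_offset: near-constant series, offset undefined", call. = FALSE)
  }
  lags <- -L:L
  r <- vapply(lags, function(k) {
    if (k >= 0) stats::cor(g[seq_len(n - k)], h[seq_len(n - k) + k])
    else stats::cor(g[seq_len(n + k) - k], h[seq_len(n + k)])
  }, numeric(1))
  i <- which.max(r)
  list(offset_ms = lags[i] * period * 1000,
       lag_samples = lags[i],
       peak_correlation = r[i])
}

#' Duration, peak normal force, and total torque per segment
#'
#' Contact segments (collection/delivery) get peak absolute normal force and
#' total torque on their transducer; movement segments (transport, peg-free)
#' get durations only. Total torque is the time-integral of the absolute
#' torque (trapezoidal, N·m·s); a per-sample sum is available via
#' `torque_mode = "sum"`.
#'
#' @param segments Segment tibble from [extract_actions()] (or ground truth).
#' @param streams Named list holding detrended `force_tray`/`force_board`
#'   and raw `torque_tray`/`torque_board` streams.
#' @param torque_mode `"integral"` (default) or `"sum"`.
#' @return `segments` with `duration_ms`, `peak_normal_force_N`,
#'   `total_torque` columns appended.
#' @export
force_summaries <- function(segments, streams, torque_mode = c("integral", "sum")) {
  torque_mode <- match.arg(torque_mode)
  n <- nrow(segments)
  peak <- rep(NA_real_, n)
  torq <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tr <- segments$transducer[i]
    if (is.na(tr)) next
    f <- streams[[paste0("force_", tr)]]
    idx <- which(f$time_s >= segments$onset_s[i] & f$time_s <= segments$offset_s[i])
    if (!length(idx)) stop("force_summaries: segment outside stream range",
                           call. = FALSE)
    peak[i] <- max(abs(f$value[idx]))
    tq <- streams[[paste0("torque_", tr)]]
    if (!is.null(tq)) {
      jdx <- which(tq$time_s >= segments$onset_s[i] & tq$time_s <= segments$offset_s[i])
      v <- abs(tq$value[jdx])
      tt <- tq$time_s[jdx]
      torq[i] <- if (torque_mode == "integral" && length(jdx) > 1) {
        sum(diff(tt) * (utils::head(v, -1) + utils::tail(v, -1)) / 2)
      } else {
        sum(v)
      }
    }
  }
  dplyr::mutate(segments,
                duration_ms = (.data$offset_s - .data$onset_s) * 1000,
                peak_normal_force_N = peak,
                total_torque = torq)
}
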