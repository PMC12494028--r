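# Stream containers, delimited-text IO, the screen-plane coordinate frame,
# and multi-rate resampling.

#' Construct and validate a sensor stream
#'
#' A stream is a tibble of `(time_s, value)` with a channel id, unit, and
#' declared nominal rate. Timestamps must be strictly increasing; values may
#' be `NA` (explicit missing markers) but never infinite.
#'
#' @param data Data frame with columns `time_s` and `value`.
#' @param channel Channel label.
#' @param nominal_rate Nominal sampling rate, Hz.
#' @param unit Unit string (`"mm"`, `"N"`, `"N.m"`).
#' @return A tibble of class `sensor_stream`.
#' @export
sensor_stream <- function(data, channel, nominal_rate, unit = NA_character_) {
  if (!all(c("time_s", "value") %in% names(data))) {
    stop("sensor_stream: data needs columns time_s, value", call. = FALSE)
  }
  if (!is.numeric(nominal_rate) || nominal_rate <= 0) {
    stop("sensor_stream: nominal_rate must be > 0", call. = FALSE)
  }
  bad <- which(diff(data$time_s) <= 0)
  if (length(bad)) {
    stop(sprintf("sensor_stream: non-increasing timestamp at row %d (channel %s)",
                 bad[1] + 1L, channel), call. = FALSE)
  }
  if (any(is.infinite(data$value))) {
    stop("sensor_stream: infinite values; use NA for missing samples", call. = FALSE)
  }
  out <- tibble::as_tibble(data[c("time_s", "value")])
  structure(out, channel = channel, nominal_rate = nominal_rate, unit = unit,
            class = c("sensor_stream", class(out)))
}

stream_channel <- function(x) attr(x, "channel")
stream_rate <- function(x) attr(x, "nominal_rate")

#' Read sensor streams from delimited text
#'
#' Expects comma-separated files with a header row and columns
#' `time_s,value,channel` (a file may hold several channels). Streams are
#' validated: non-monotone timestamps are a parse error naming the offending
#' row, and channels absent from `schema` are a schema error.
#'
#' @param paths Character vector of CSV paths.
#' @param schema Named list mapping channel id to
#'   `list(nominal_rate =, unit =)`.
#' @return Named list of [sensor_stream()]s.
#' @export
load_streams <- function(paths, schema) {
  tabs <- lapply(paths, function(p) {
    readr::read_csv(p, col_types = readr::cols(
      time_s = readr::col_double(), value = readr::col_double(),
      channel = readr::col_character()))
  })
  tab <- dplyr::bind_rows(tabs)
  unknown <- setdiff(unique(tab$channel), names(schema))
  if (length(unknown)) {
    stop("load_streams: unknown channel(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- lapply(split(tab, tab$channel), function(d) {
    ch <- d$channel[1]
    sensor_stream(d[order(d$time_s), c("time_s", "value")], channel = ch,
                  nominal_rate = schema[[ch]]$nominal_rate,
                  unit = schema[[ch]]$unit %||% NA_character_)
  })
  out[intersect(names(schema), names(out))]
}

#' Write a simulated or loaded session to a directory of delimited text
#'
#' One CSV per stream plus `manifest.csv`, `truth_segments.csv` (when ground
#' truth is present), and a `run_log.txt` recording the seed.
#'
#' @param session A `session_recording`.
#' @param dir Output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (ch in names(session$streams)) {
    s <- session$streams[[ch]]
    readr::write_csv(tibble::tibble(time_s = s$time_s, value = s$value,
                                    channel = ch),
                     file.path(dir, paste0("stream_", ch, ".csv")))
  }
  readr::write_csv(session$manifest, file.path(dir, "manifest.csv"))
  if (!is.null(session$truth$segments)) {
    readr::write_csv(session$truth$segments, file.path(dir, "truth_segments.csv"))
  }
  writeLines(c(paste("seed:", session$seed %||% "NULL"),
               paste("written:", "gazehand", as.character(utils::packageVersion("gazehand")))),
             file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Read a session written by [write_session()]
#'
#' @param dir Directory containing `stream_*.csv` and `manifest.csv`.
#' @param rates Named rates per channel group, as in [sim_params()].
#' @return A `session_recording` (without ground truth unless
#'   `truth_segments.csv` is present).
#' @export
read_session <- function(dir, rates = sim_params()$sample_rates_hz) {
  files <- list.files(dir, pattern = "^stream_.*\\.csv$", full.names = TRUE)
  if (!file.exists(file.path(dir, "manifest.csv"))) {
    stop("read_session: no manifest.csv in ", dir, call. = FALSE)
  }
  chans <- sub("^stream_(.*)\\.csv$", "\\1", basename(files))
  rate_of <- function(ch) {
    if (grepl("^(force|torque)_", ch)) rates[["force"]]
    else if (grepl("^hand_", ch)) rates[["hand"]]
    else rates[["gaze"]]
  }
  schema <- stats::setNames(
    lapply(chans, function(ch) list(nominal_rate = rate_of(ch))), chans)
  streams <- load_streams(files, schema)
  truth <- NULL
  seg_path <- file.path(dir, "truth_segments.csv")
  if (file.exists(seg_path)) {
    truth <- list(segments = readr::read_csv(seg_path, show_col_types = FALSE))
  }
  structure(
    list(streams = streams,
         manifest = readr::read_csv(file.path(dir, "manifest.csv"),
                                    show_col_types = FALSE),
         truth = truth, params = NULL, seed = NA),
    class = "session_recording"
  )
}

#' Define a rigid planar frame in the screen plane
#'
#' @param origin Length-2 numeric, mm: where the new frame's origin sits in
#'   the reference frame.
#' @param angle_rad Rotation of the new frame's axes, radians
#'   (counterclockwise).
#' @return A `planar_frame`.
#' @export
planar_frame <- function(origin = c(0, 0), angle_rad = 0) {
  stopifnot(length(origin) == 2, is.finite(origin), is.finite(angle_rad))
  R <- matrix(c(cos(angle_rad), sin(angle_rad),
                -sin(angle_rad), cos(angle_rad)), 2, 2)
  structure(list(origin = as.numeric(origin), rotation = R),
            class = "planar_frame")
}

#' Map points into the common screen-plane frame
#'
#' Rigid (rotation + translation) mapping; pairwise distances are preserved.
#'
#' @param points Two-column matrix or data frame of (x, y) in mm.
#' @param frame A [planar_frame()].
#' @return Matrix of mapped (x, y).
#' @export
to_screen_frame <- function(points, frame) {
  if (!inherits(frame, "planar_frame")) stop("to_screen_frame: invalid frame",
                                             call. = FALSE)
  R <- frame$rotation
  if (max(abs(crossprod(R) - diag(2))) > 1e-12) {
    stop("to_screen_frame: frame axes are not orthonormal", call. = FALSE)
  }
  p <- as.matrix(points)
  stopifnot(ncol(p) == 2)
  sweep(p %*% t(R), 2, -frame$origin)
}

#' Resample a stream by linear interpolation
#'
#' Used to bring the 120 Hz hand signal onto the 30 Hz gaze timebase before
#' cross-correlation. Extrapolation is refused; `NA` runs in the source
#' propagate to targets that fall inside them.
#'
#' @param stream A [sensor_stream()].
#' @param target_timestamps Times (s) at which to interpolate; must lie
#'   within the source range.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return A [sensor_stream()] on the target timestamps.
#' @export
resample_stream <- function(stream, target_timestamps, method = c("linear", "nearest")) {
  method <- match.arg(method)
  rng <- range(stream$time_s)
  if (any(target_timestamps < rng[1] - 1e-12 | target_timestamps > rng[2] + 1e-12)) {
    stop("resample_stream: target timestamps outside source range (no extrapolation)",
         call. = FALSE)
  }
  ok <- !is.na(stream$value)
  if (sum(ok) < 2) stop("resample_stream: fewer than 2 non-missing samples",
                        call. = FALSE)
  v <- stats::approx(stream$time_s[ok], stream$value[ok], xout = target_timestamps,
                     method = if (method == "linear") "linear" else "constant",
                     ties = "ordered", rule = 2)$y
  if (method == "nearest") {
    # approx's "constant" is left-hold; snap to the nearer neighbor instead
    idx <- findInterval(target_timestamps, stream$time_s[ok])
    idx <- pmin(pmax(idx, 1L), sum(ok) - 1L)
    tt <- stream$time_s[ok]
    vv <- stream$value[ok]
    right <- (target_timestamps - tt[idx]) > (tt[idx + 1L] - target_timestamps)
    v <- ifelse(right, vv[idx + 1L], vv[idx])
  }
  # targets falling inside an NA gap stay missing
  if (any(!ok)) {
    na_t <- stream$time_s[!ok]
    gapped <- vapply(target_timestamps, function(tt) {
      i <- findInterval(tt, stream$time_s)
      i <- pmin(pmax(i, 1L), nrow(stream))
      j <- min(i + 1L, nrow(stream))
      is.na(stream$value[i]) || (tt > stream$time_s[i] && is.na(stream$value[j]))
    }, logical(1))
    v[gapped] <- NA_real_
  }
  sensor_stream(tibble::tibble(time_s = target_timestamps, value = v),
                channel = stream_channel(stream),
                nominal_rate = stream_rate(stream),
                unit = attr(stream, "unit"))
}

#' Bridge short tracker dropouts
#'
#' Missing samples are linearly interpolated when the surrounding gap is at
#' most `max_gap_ms`; longer gaps stay missing and are excluded from
#' downstream metrics.
#'
#' @param stream A [sensor_stream()].
#' @param max_gap_ms Longest gap to bridge, milliseconds.
#' @return A [sensor_stream()].
#' @export
bridge_gaps <- function(stream, max_gap_ms = 100) {
  v <- stream$value
  t <- stream$time_s
  if (!anyNA(v)) return(stream)
  r <- rle(is.na(v))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    a <- starts[i] - 1L
    b <- ends[i] + 1L
    if (a < 1L || b > length(v)) next  # edge gap: cannot bridge
    if ((t[b] - t[a]) * 1000 <= max_gap_ms) {
      idx <- starts[i]:ends[i]
      v[idx] <- v[a] + (v[b] - v[a]) * (t[idx] - t[a]) / (t[b] - t[a])
    }
  }
  sensor_stream(tibble::tibble(time_s = t, value = v),
                channel = stream_channel(stream),
                nominal_rate = stream_rate(stream),
                unit = attr(stream, "unit"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
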