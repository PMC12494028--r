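# End-to-end orchestration: segmentation -> metrics for a whole session.

#' Run segmentation and metrics over a session
#'
#' For every phase: detrends both force channels, extracts (or takes
#' ground-truth) action segments, computes the GISI series, GISI at peak
#' force and progress profiles per contact action, force summaries per
#' segment, and one gaze-hand temporal offset per series and phase. Stage
#' failures propagate as errors naming the phase; there is no silent repair.
#'
#' @param session A `session_recording`.
#' @param config A [cpt_config()].
#' @param use_truth_segments Analyze the simulator's ground-truth segments
#'   instead of detected ones (for calibration and recovery studies).
#' @param pegs_per_phase Expected contacts per transducer per phase.
#' @param max_lag_ms Lag window for [temporal_offset()].
#' @return List with `segments`, `metrics` (per-segment durations, forces,
#'   GISI profile and GISI at peak force), `offsets` (per series and
#'   phase), and a `report` of per-stage counts.
#' @export
analyze_session <- function(session, config = cpt_config(),
                            use_truth_segments = FALSE,
                            pegs_per_phase = 8L, max_lag_ms = 1000) {
  manifest <- session$manifest
  streams <- session$streams
  segments <- if (use_truth_segments) {
    session$truth$segments
  } else {
    extract_actions(streams, manifest, config, pegs_per_phase)
  }

  metrics <- vector("list", nrow(manifest))
  offsets <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i, ]
    win <- c(mrow$t_start_s, mrow$t_stop_s)
    gz <- slice_stream(streams$gaze_x, win[1], win[2])
    hd <- slice_stream(streams$hand_x, win[1], win[2])
    gs <- gisi_series(gz, hd)
    det <- lapply(c(tray = "force_tray", board = "force_board"), function(ch) {
      detrend_load(slice_stream(streams[[ch]], win[1], win[2]), config)
    })
    local_streams <- list(force_tray = det$tray, force_board = det$board,
                          torque_tray = streams$torque_tray,
                          torque_board = streams$torque_board)

    segs <- segments[
      segments$block == mrow$block & segments$hand == mrow$hand &
        segments$round == mrow$round & segments$series == mrow$series &
        segments$phase == mrow$phase, ]
    segs <- force_summaries(segs, local_streams)

    prof <- purrr::map_dfr(seq_len(nrow(segs)), function(j) {
      progress_profile(segs[j, ], gs)
    })
    peak <- purrr::map_dfr(seq_len(nrow(segs)), function(j) {
      tr <- segs$transducer[j]
      if (is.na(tr)) {
        return(tibble::tibble(gisi_at_peak_mm = NA_real_,
                              peak_force_time_s = NA_real_))
      }
      gp <- gisi_at_peak_force(segs[j, ], det[[tr]], gs)
      tibble::tibble(gisi_at_peak_mm = gp$gisi_mm,
                     peak_force_time_s = gp$peak_force_time_s)
    })
    metrics[[i]] <- dplyr::bind_cols(segs, prof, peak)

    off <- temporal_offset(gz, hd, max_lag_ms)
    keycols <- intersect(c("participant", "block", "condition", "hand",
                           "treated", "round", "series", "phase"), names(mrow))
    offsets[[i]] <- dplyr::bind_cols(
      mrow[keycols],
      tibble::tibble(offset_ms = off$offset_ms,
                     peak_correlation = off$peak_correlation))
  }

  metrics <- dplyr::bind_rows(metrics)
  offsets <- dplyr::bind_rows(offsets)
  list(segments = segments,
       metrics = metrics,
       offsets = offsets,
       report = list(n_phases = nrow(manifest),
                     n_segments = nrow(segments),
                     n_metric_rows = nrow(metrics),
                     n_offsets = nrow(offsets)))
}
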