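# Turn detrended force series into labeled task actions. Collection and
# delivery are force-defined contact events; transport and peg-free
# movements are the gaps between them.

slice_stream <- function(stream, t_start, t_stop) {
  keep <- stream$time_s >= t_start & stream$time_s <= t_stop
  if (!any(keep)) stop("slice_stream: no samples in window", call. = FALSE)
  sensor_stream(stream[keep, , drop = FALSE],
                channel = stream_channel(stream),
                nominal_rate = stream_rate(stream),
                unit = attr(stream, "unit"))
}

# Contact pulses of any smooth profile start with zero slope, so near onset
# the force grows quadratically and sqrt(force) grows linearly. Fitting a
# line to sqrt(force) on the rising edge and extrapolating to zero localizes
# the onset far better than the first threshold crossing, whose bias grows
# with pulse width. Falls back to a noise-floor walk if the edge is too
# short to fit.
refine_edge <- function(x, t, from, peak_idx, sigma, rising = TRUE) {
  idx <- if (rising) from:peak_idx else peak_idx:from
  xv <- x[idx]
  A <- x[peak_idx]
  lo <- max(2 * sigma, 0.02 * A)
  hi <- 0.25 * A
  edge <- which(xv >= lo & xv <= hi)
  if (length(edge) >= 3L) {
    tt <- t[idx[edge]]
    yy <- sqrt(pmax(xv[edge], 0))
    fit <- stats::lm.fit(cbind(1, tt), yy)
    b <- fit$coefficients
    if (is.finite(b[2]) && abs(b[2]) > 1e-12) {
      t0 <- -b[1] / b[2]
      span <- diff(range(t[idx])) + 1e-9
      ok <- if (rising) {
        t0 <= min(tt) && t0 >= min(tt) - 0.5 * span
      } else {
        t0 >= max(tt) && t0 <= max(tt) + 0.5 * span
      }
      if (ok) return(unname(t0))
    }
  }
  # fallback: outermost sample still above the noise floor
  floor_lvl <- max(0.005, sigma)
  above <- which(xv > floor_lvl)
  if (!length(above)) return(t[idx[1]])
  if (rising) t[idx[above[1]]] else t[idx[above[length(above)]]]
}

refine_event <- function(det, iv, sigma) {
  x <- det$value
  t <- det$time_s
  idx <- iv$from:iv$to
  peak <- idx[which.max(x[idx])]
  onset <- refine_edge(x, t, iv$from, peak, sigma, rising = TRUE)
  offset <- refine_edge(x, t, iv$to, peak, sigma, rising = FALSE)
  list(onset_s = onset, offset_s = offset, peak_idx = peak)
}

detect_contacts <- function(force, config) {
  det <- detrend_load(force, config)
  sigma <- attr(det, "sigma")
  ivs <- attr(det, "active")
  if (is.null(ivs) || !nrow(ivs)) {
    return(tibble::tibble(onset_s = numeric(0), offset_s = numeric(0)))
  }
  ev <- lapply(seq_len(nrow(ivs)), function(i) refine_event(det, ivs[i, ], sigma))
  tibble::tibble(onset_s = vapply(ev, `[[`, numeric(1), "onset_s"),
                 offset_s = vapply(ev, `[[`, numeric(1), "offset_s"))
}

#' Extract labeled action segments from force streams
#'
#' For every phase in the manifest, contact events are detected on both
#' transducers after detrending. In the placement phase the tray is the
#' source (coarse collection) and the pegboard the destination (precise
#' delivery); roles swap in retrieval. Transport spans collection offset to
#' the next delivery onset; peg-free movement spans delivery offset to the
#' next collection onset, with the initial reach anchored at the phase
#' start (its onset is not force-defined). A mismatch between detected
#' contact counts and `pegs_per_phase` raises a segmentation-mismatch error
#' carrying diagnostics — there is no silent repair.
#'
#' @param streams Named list of [sensor_stream()]s with `force_tray` and
#'   `force_board`.
#' @param manifest Tibble with one row per phase (see [simulate_session()]).
#' @param config A [cpt_config()].
#' @param pegs_per_phase Expected contacts per transducer per phase.
#' @return Tibble of detected segments keyed by the manifest columns, with
#'   `kind`, `peg`, `onset_s`, `offset_s`, `transducer`, `provenance`.
#' @export
extract_actions <- function(streams, manifest, config = cpt_config(),
                            pegs_per_phase = 8L) {
  if (is.null(streams$force_tray) || is.null(streams$force_board)) {
    stop("extract_actions: need force_tray and force_board streams", call. = FALSE)
  }
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    mrow <- manifest[i, ]
    ev <- lapply(c(tray = "force_tray", board = "force_board"), function(ch) {
      f <- slice_stream(streams[[ch]], mrow$t_start_s, mrow$t_stop_s)
      detect_contacts(f, config)
    })
    placement <- identical(mrow$phase, "placement")
    coll <- if (placement) ev$tray else ev$board
    deli <- if (placement) ev$board else ev$tray
    coll_tr <- if (placement) "tray" else "board"
    deli_tr <- if (placement) "board" else "tray"
    if (nrow(coll) != pegs_per_phase || nrow(deli) != pegs_per_phase) {
      stop(sprintf(paste0(
        "segmentation mismatch in %s phase (block %s, hand %s, round %s, ",
        "series %s): %d collections and %d deliveries detected, expected %d each"),
        mrow$phase, mrow$block, mrow$hand, mrow$round, mrow$series,
        nrow(coll), nrow(deli), pegs_per_phase), call. = FALSE)
    }
    ok_order <- all(coll$onset_s < coll$offset_s) &&
      all(deli$onset_s < deli$offset_s) &&
      all(coll$offset_s < deli$onset_s) &&
      all(utils::head(deli$offset_s, -1) < utils::tail(coll$onset_s, -1))
    if (!ok_order) {
      stop(sprintf(
        "segmentation mismatch in %s phase: contact events do not interleave as collection < delivery per peg",
        mrow$phase), call. = FALSE)
    }

    k <- pegs_per_phase
    segs <- tibble::tibble(
      kind = c(rep(c("peg_free",
                     if (placement) "coarse_collection" else "precise_collection",
                     "transport",
                     if (placement) "precise_delivery" else "coarse_delivery"),
                   k)),
      peg = rep(seq_len(k), each = 4L),
      onset_s = as.numeric(rbind(
        c(mrow$t_start_s, utils::head(deli$offset_s, -1)),
        coll$onset_s, coll$offset_s, deli$onset_s)),
      offset_s = as.numeric(rbind(
        coll$onset_s, coll$offset_s, deli$onset_s, deli$offset_s)),
      transducer = rep(c(NA_character_, coll_tr, NA_character_, deli_tr), k),
      provenance = "detected"
    )
    keycols <- intersect(c("participant", "block", "condition", "hand",
                           "treated", "round", "series", "phase"), names(mrow))
    out[[i]] <- dplyr::bind_cols(mrow[rep(1, nrow(segs)), keycols], segs)
  }
  dplyr::bind_rows(out)
}
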