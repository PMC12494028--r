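# Pegboard session simulator: minimum-jerk hand kinematics, a gaze signal
# blended between the upcoming target and the (lead-shifted) hand, and
# force-transducer channels carrying raised-cosine contact pulses on top of
# the accumulating peg-weight staircase.

# Workspace geometry, mm in the screen plane (x rightward from screen
# center). One collection tray and one handrest per side; the pegboard sits
# centrally with eight holes in two rows (13 mm within-row, 23 mm between
# rows).
.geom <- list(
  tray_x = 150, tray_y = 0,
  rest_x = 100, rest_y = -80,
  hole_x = rep(c(-19.5, -6.5, 6.5, 19.5), 2),
  hole_y = rep(c(-11.5, 11.5), each = 4),
  pad_s = 0.5,        # quiescent padding at phase start/end
  phase_gap_s = 4,    # pause between placement and retrieval
  series_gap_s = 2    # pause between recordings
)

# Minimum-jerk position profile on normalized time u in [0, 1].
min_jerk <- function(u) {
  u <- pmin(pmax(u, 0), 1)
  u^3 * (10 - 15 * u + 6 * u^2)
}

# Raised-cosine bell with support [t0, t1] and peak `amp` at the midpoint.
raised_cosine <- function(t, t0, t1, amp) {
  y <- numeric(length(t))
  inside <- t >= t0 & t <= t1
  y[inside] <- amp / 2 * (1 - cos(2 * pi * (t[inside] - t0) / (t1 - t0)))
  y
}

# Piecewise hand-position evaluator built from motion rows
# (t0, t1, x0, y0, x1, y1); dwells have x0 == x1. Clamps outside the plan.
make_hand_fun <- function(motions) {
  force(motions)
  function(t) {
    i <- findInterval(t, motions$t0)
    i <- pmin(pmax(i, 1L), nrow(motions))
    u <- (t - motions$t0[i]) / (motions$t1[i] - motions$t0[i])
    s <- min_jerk(u)
    list(x = motions$x0[i] + s * (motions$x1[i] - motions$x0[i]),
         y = motions$y0[i] + s * (motions$y1[i] - motions$y0[i]))
  }
}

make_target_fun <- function(targets) {
  force(targets)
  function(t) {
    i <- findInterval(t, targets$t0)
    i <- pmin(pmax(i, 1L), nrow(targets))
    list(x = targets$x[i], y = targets$y[i])
  }
}

# Lay out one phase: motion rows, ground-truth action segments, contact
# pulses, staircase steps, and the gaze-target timeline. Times are relative
# to phase start.
build_phase_plan <- function(phase, eff, params, side, pegs_per_phase) {
  g <- .geom
  tray <- c(x = side * g$tray_x, y = g$tray_y)
  rest <- c(x = side * g$rest_x, y = g$rest_y)
  holes <- cbind(x = g$hole_x, y = g$hole_y)[seq_len(pegs_per_phase), , drop = FALSE]

  d <- eff$durations_ms / 1000
  placement <- identical(phase, "placement")

  motions <- list(); segs <- list(); pulses <- list(); steps <- list()
  targets <- list()
  cur <- rest
  t <- g$pad_s
  targets[[length(targets) + 1]] <-
    list(t0 = 0, x = NA_real_, y = NA_real_)  # filled with first source below

  for (k in seq_len(pegs_per_phase)) {
    hole <- c(x = unname(holes[k, "x"]), y = unname(holes[k, "y"]))
    src <- if (placement) tray else hole
    dst <- if (placement) hole else tray
    src_tr <- if (placement) "tray" else "board"
    dst_tr <- if (placement) "board" else "tray"

    if (k == 1L) {
      targets[[1]] <- list(t0 = 0, x = src[["x"]], y = src[["y"]])
    }

    # peg-free approach to the collection site
    motions[[length(motions) + 1]] <-
      list(t0 = t, t1 = t + d[["peg_free"]],
           x0 = cur[["x"]], y0 = cur[["y"]], x1 = src[["x"]], y1 = src[["y"]])
    segs[[length(segs) + 1]] <-
      list(kind = "peg_free", onset_s = t, offset_s = t + d[["peg_free"]],
           transducer = NA_character_, peg = k)
    t <- t + d[["peg_free"]]

    # collection: dwell + contact pulse at the source transducer; the peg
    # leaves that transducer mid-contact
    motions[[length(motions) + 1]] <-
      list(t0 = t, t1 = t + d[["collection"]],
           x0 = src[["x"]], y0 = src[["y"]], x1 = src[["x"]], y1 = src[["y"]])
    segs[[length(segs) + 1]] <-
      list(kind = if (placement) "coarse_collection" else "precise_collection",
           onset_s = t, offset_s = t + d[["collection"]],
           transducer = src_tr, peg = k)
    pulses[[length(pulses) + 1]] <-
      list(transducer = src_tr, t0 = t, t1 = t + d[["collection"]],
           amp = eff$peaks_N[["collection"]])
    steps[[length(steps) + 1]] <-
      list(transducer = src_tr, time = t + d[["collection"]] / 2, delta = -1)
    targets[[length(targets) + 1]] <-
      list(t0 = t, x = dst[["x"]], y = dst[["y"]])  # gaze looks ahead
    t <- t + d[["collection"]]

    # transport to the delivery site
    motions[[length(motions) + 1]] <-
      list(t0 = t, t1 = t + d[["transport"]],
           x0 = src[["x"]], y0 = src[["y"]], x1 = dst[["x"]], y1 = dst[["y"]])
    segs[[length(segs) + 1]] <-
      list(kind = "transport", onset_s = t, offset_s = t + d[["transport"]],
           transducer = NA_character_, peg = k)
    t <- t + d[["transport"]]

    # delivery: dwell + pulse at the destination; peg lands mid-contact
    motions[[length(motions) + 1]] <-
      list(t0 = t, t1 = t + d[["delivery"]],
           x0 = dst[["x"]], y0 = dst[["y"]], x1 = dst[["x"]], y1 = dst[["y"]])
    segs[[length(segs) + 1]] <-
      list(kind = if (placement) "precise_delivery" else "coarse_delivery",
           onset_s = t, offset_s = t + d[["delivery"]],
           transducer = dst_tr, peg = k)
    pulses[[length(pulses) + 1]] <-
      list(transducer = dst_tr, t0 = t, t1 = t + d[["delivery"]],
           amp = eff$peaks_N[["delivery"]])
    steps[[length(steps) + 1]] <-
      list(transducer = dst_tr, time = t + d[["delivery"]] / 2, delta = +1)
    nxt <- if (k < pegs_per_phase) {
      if (placement) tray else c(x = unname(holes[k + 1, "x"]),
                                 y = unname(holes[k + 1, "y"]))
    } else rest
    targets[[length(targets) + 1]] <- list(t0 = t, x = nxt[["x"]], y = nxt[["y"]])
    t <- t + d[["delivery"]]
    cur <- dst
  }

  # return to the handrest (not an analyzed action)
  motions[[length(motions) + 1]] <-
    list(t0 = t, t1 = t + d[["peg_free"]],
         x0 = cur[["x"]], y0 = cur[["y"]], x1 = rest[["x"]], y1 = rest[["y"]])
  t <- t + d[["peg_free"]]

  list(
    motions = dplyr::bind_rows(motions),
    segments = dplyr::bind_rows(segs),
    pulses = dplyr::bind_rows(pulses),
    steps = dplyr::bind_rows(steps),
    targets = dplyr::bind_rows(targets),
    duration = t + .geom$pad_s
  )
}

# Sample all requested channels for one phase plan. `t_off` shifts times into
# the session clock.
sample_phase <- function(plan, eff, params, t_off, channels) {
  rates <- params$sample_rates_hz
  nz <- params$noise_sd
  lead <- eff$gaze_lead_ms / 1000
  kappa <- eff$kappa
  hand_at <- make_hand_fun(plan$motions)
  target_at <- make_target_fun(plan$targets)
  out <- list()

  grid <- function(rate) (0:floor(plan$duration * rate)) / rate

  if ("hand" %in% channels) {
    th <- grid(rates[["hand"]])
    h <- hand_at(th)
    n <- length(th)
    out$hand_x <- tibble::tibble(time_s = t_off + th,
                                 value = h$x + stats::rnorm(n, 0, nz[["hand"]]))
    out$hand_y <- tibble::tibble(time_s = t_off + th,
                                 value = h$y + stats::rnorm(n, 0, nz[["hand"]]))
  }
  if ("gaze" %in% channels) {
    tg <- grid(rates[["gaze"]])
    hl <- hand_at(tg + lead)
    tl <- target_at(tg + lead)
    n <- length(tg)
    gx <- (1 - kappa) * tl$x + kappa * hl$x
    gy <- (1 - kappa) * tl$y + kappa * hl$y
    out$gaze_x <- tibble::tibble(time_s = t_off + tg,
                                 value = gx + stats::rnorm(n, 0, nz[["gaze"]]))
    out$gaze_y <- tibble::tibble(time_s = t_off + tg,
                                 value = gy + stats::rnorm(n, 0, nz[["gaze"]]))
    out$target_xy <- tibble::tibble(time_s = t_off + tg,
                                    x = target_at(tg)$x, y = target_at(tg)$y)
  }
  if ("force" %in% channels) {
    tf <- grid(rates[["force"]])
    n <- length(tf)
    w <- peg_load_force(1, params)
    for (tr in c("tray", "board")) {
      stair <- numeric(n)
      st <- plan$steps[plan$steps$transducer == tr, ]
      for (i in seq_len(nrow(st))) {
        stair <- stair + w * st$delta[i] * (tf >= st$time[i])
      }
      normal <- stair
      torque <- numeric(n)
      pl <- plan$pulses[plan$pulses$transducer == tr, ]
      for (i in seq_len(nrow(pl))) {
        normal <- normal + raised_cosine(tf, pl$t0[i], pl$t1[i], pl$amp[i])
        torque <- torque + raised_cosine(tf, pl$t0[i], pl$t1[i], params$torque_scale_Nm)
      }
      out[[paste0("force_", tr)]] <-
        tibble::tibble(time_s = t_off + tf,
                       value = normal + stats::rnorm(n, 0, nz[["force"]]))
      out[[paste0("torque_", tr)]] <-
        tibble::tibble(time_s = t_off + tf,
                       value = torque + stats::rnorm(n, 0, nz[["torque"]]))
    }
  }
  out
}

#' Simulate a complete session of the pegboard task
#'
#' Realizes a trial schedule as multi-rate sensor streams with full ground
#' truth. The hand follows minimum-jerk point-to-point trajectories between
#' handrest, tray, and pegboard holes; gaze is a convex combination of the
#' upcoming target position and the hand position, both evaluated
#' `gaze_lead_ms` ahead of the current time; force channels carry one
#' raised-cosine pulse per contact superposed on the peg-weight staircase.
#' Identical `(schedule, params, seed)` gives bit-identical output.
#'
#' @param schedule A trial schedule from [build_schedule()], or any subset of
#'   its rows (whole phases are simulated for every distinct
#'   block/hand/round/series/phase combination present).
#' @param params A [sim_params()].
#' @param seed Integer seed; every source of randomness derives from it.
#' @param participant Participant label written into the manifest.
#' @param channels Channel groups to generate, subset of
#'   `c("force", "hand", "gaze")`. Restricting them speeds tests that only
#'   need kinematics.
#' @return A `session_recording`: list with `streams` (named list of
#'   `sensor_stream` tibbles), `manifest` (one row per phase), `truth`
#'   (ground-truth `segments`, gaze `targets`, per-cell injected parameters),
#'   `params`, and `seed`.
#' @export
simulate_session <- function(schedule, params = sim_params(), seed = 1L,
                             participant = "P01",
                             channels = c("force", "hand", "gaze")) {
  if (!nrow(schedule)) stop("simulate_session: empty schedule", call. = FALSE)
  channels <- match.arg(channels, several.ok = TRUE)
  cells <- dplyr::distinct(schedule, .data$block, .data$condition, .data$hand,
                           .data$treated, .data$round, .data$series, .data$phase)
  # canonical order = session chronology
  phase_rank <- match(cells$phase, c("placement", "retrieval"))
  cells <- cells[order(cells$block, match(cells$hand, unique(schedule$hand)),
                       cells$round, cells$series, phase_rank), ]

  hands <- unique(schedule$hand)
  sides <- stats::setNames(rep(c(1, -1), length.out = length(hands)), hands)

  run <- function() {
    streams <- list()
    manifest <- list()
    segments <- list()
    targets <- list()
    cellpar <- list()
    t_off <- 0

    for (i in seq_len(nrow(cells))) {
      cell <- cells[i, ]
      pegs <- sort(unique(schedule$peg[
        schedule$block == cell$block & schedule$hand == cell$hand &
          schedule$round == cell$round & schedule$series == cell$series &
          schedule$phase == cell$phase]))
      eff <- effective_params(params, cell$condition, cell$treated)
      plan <- build_phase_plan(cell$phase, eff, params, sides[[cell$hand]],
                               length(pegs))
      smp <- sample_phase(plan, eff, params, t_off, channels)

      key <- tibble::tibble(participant = participant, block = cell$block,
                            condition = cell$condition, hand = cell$hand,
                            treated = cell$treated, round = cell$round,
                            series = cell$series, phase = cell$phase)
      manifest[[i]] <- dplyr::mutate(key, t_start_s = t_off,
                                     t_stop_s = t_off + plan$duration)
      seg <- plan$segments
      seg$onset_s <- seg$onset_s + t_off
      seg$offset_s <- seg$offset_s + t_off
      seg$provenance <- "ground_truth"
      segments[[i]] <- dplyr::bind_cols(key[rep(1, nrow(seg)), ], seg)
      if (!is.null(smp$target_xy)) {
        targets[[i]] <- dplyr::bind_cols(key[rep(1, nrow(smp$target_xy)), ],
                                         smp$target_xy)
        smp$target_xy <- NULL
      }
      cellpar[[i]] <- dplyr::mutate(key, gaze_lead_ms = eff$gaze_lead_ms,
                                    kappa = eff$kappa)
      for (ch in names(smp)) {
        streams[[ch]] <- c(streams[[ch]], list(smp[[ch]]))
      }
      gap <- if (cell$phase == "placement") .geom$phase_gap_s else .geom$series_gap_s
      t_off <- t_off + plan$duration + gap
    }

    rate_of <- c(hand_x = "hand", hand_y = "hand", gaze_x = "gaze", gaze_y = "gaze",
                 force_tray = "force", force_board = "force",
                 torque_tray = "force", torque_board = "force")
    unit_of <- c(hand_x = "mm", hand_y = "mm", gaze_x = "mm", gaze_y = "mm",
                 force_tray = "N", force_board = "N",
                 torque_tray = "N.m", torque_board = "N.m")
    streams <- purrr::imap(streams, function(parts, ch) {
      sensor_stream(dplyr::bind_rows(parts), channel = ch,
                    nominal_rate = params$sample_rates_hz[[rate_of[[ch]]]],
                    unit = unit_of[[ch]])
    })

    structure(
      list(streams = streams,
           manifest = dplyr::bind_rows(manifest),
           truth = list(segments = dplyr::bind_rows(segments),
                        targets = if (length(targets)) dplyr::bind_rows(targets),
                        cell_params = dplyr::bind_rows(cellpar)),
           params = params,
           seed = seed),
      class = "session_recording"
    )
  }

  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' @export
print.session_recording <- function(x, ...) {
  cat("<session_recording> ", nrow(x$manifest), " phases, ",
      length(x$streams), " streams, ",
      nrow(x$truth$segments), " ground-truth segments\n", sep = "")
  invisible(x)
}
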