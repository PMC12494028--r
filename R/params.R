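#' Simulation parameters for the pegboard task
#'
#' Defaults state a plausible session: gaze leads the hand by ~150 ms under
#' intact sensation and couples tightly to it (shorter lead, high kappa) under
#' anesthesia of the treated hand; anesthesia also slows actions and raises
#' peak forces. Sham behaves like baseline. Only the treated hand is affected
#' in non-baseline blocks.
#'
#' @param gaze_lead_ms Named numeric (baseline/sham/anesthesia): how far the
#'   gaze signal runs ahead of the hand, milliseconds.
#' @param kappa Named numeric in `[0, 1]`: fraction of the gaze position
#'   anchored to the current hand position rather than the upcoming target.
#' @param duration_scale Named numeric: multiplies all action durations.
#' @param force_scale Named numeric: multiplies peak forces.
#' @param action_duration_ms Named numeric with entries `collection`,
#'   `delivery`, `transport`, `peg_free` (baseline durations).
#' @param peak_force_N Named numeric with entries `collection`, `delivery`:
#'   peak normal force of the contact pulse.
#' @param torque_scale_Nm Amplitude of torque pulses during contact, N·m.
#' @param peg_mass_g Mass of one peg, grams.
#' @param gravity_m_s2 Gravitational acceleration.
#' @param noise_sd Named numeric with entries `force` (N), `torque` (N·m),
#'   `hand` (mm), `gaze` (mm): additive Gaussian noise per sample.
#' @param sample_rates_hz Named numeric with entries `force`, `hand`, `gaze`.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(gaze_lead_ms = c(baseline = 150, sham = 150, anesthesia = 75),
                       kappa = c(baseline = 0.7, sham = 0.7, anesthesia = 0.92),
                       duration_scale = c(baseline = 1, sham = 1, anesthesia = 1.5),
                       force_scale = c(baseline = 1, sham = 1, anesthesia = 1.4),
                       action_duration_ms = c(collection = 300, delivery = 300,
                                              transport = 450, peg_free = 450),
                       peak_force_N = c(collection = 1.2, delivery = 1.5),
                       torque_scale_Nm = 0.01,
                       peg_mass_g = 7.6,
                       gravity_m_s2 = 9.80665,
                       noise_sd = c(force = 0.01, torque = 0.001, hand = 1, gaze = 3),
                       sample_rates_hz = c(force = 1600, hand = 120, gaze = 30)) {
  conds <- c("baseline", "sham", "anesthesia")
  need <- function(x, nms, what) {
    if (!all(nms %in% names(x))) {
      stop("sim_params: ", what, " needs entries ", paste(nms, collapse = ", "),
           call. = FALSE)
    }
    x[nms]
  }
  gaze_lead_ms <- need(gaze_lead_ms, conds, "gaze_lead_ms")
  kappa <- need(kappa, conds, "kappa")
  duration_scale <- need(duration_scale, conds, "duration_scale")
  force_scale <- need(force_scale, conds, "force_scale")
  action_duration_ms <- need(action_duration_ms,
                             c("collection", "delivery", "transport", "peg_free"),
                             "action_duration_ms")
  peak_force_N <- need(peak_force_N, c("collection", "delivery"), "peak_force_N")
  noise_sd <- need(noise_sd, c("force", "torque", "hand", "gaze"), "noise_sd")
  sample_rates_hz <- need(sample_rates_hz, c("force", "hand", "gaze"),
                          "sample_rates_hz")

  if (any(kappa < 0 | kappa > 1)) {
    stop("sim_params: kappa must lie in [0, 1]", call. = FALSE)
  }
  if (any(sample_rates_hz <= 0)) stop("sim_params: rates must be > 0", call. = FALSE)
  if (any(action_duration_ms <= 0) || any(duration_scale <= 0)) {
    stop("sim_params: durations must be > 0", call. = FALSE)
  }
  if (peg_mass_g <= 0) stop("sim_params: peg_mass_g must be > 0", call. = FALSE)
  if (any(noise_sd < 0)) stop("sim_params: noise_sd must be >= 0", call. = FALSE)
  # A lead longer than the shortest action would point the gaze past the
  # action it is supposed to anticipate.
  min_dur <- min(action_duration_ms) * min(duration_scale)
  if (any(gaze_lead_ms < 0) || any(gaze_lead_ms >= min_dur)) {
    stop("sim_params: gaze_lead_ms must be in [0, shortest action duration)",
         call. = FALSE)
  }

  structure(
    list(gaze_lead_ms = gaze_lead_ms, kappa = kappa,
         duration_scale = duration_scale, force_scale = force_scale,
         action_duration_ms = action_duration_ms, peak_force_N = peak_force_N,
         torque_scale_Nm = torque_scale_Nm, peg_mass_g = peg_mass_g,
         gravity_m_s2 = gravity_m_s2, noise_sd = noise_sd,
         sample_rates_hz = sample_rates_hz),
    class = "sim_params"
  )
}

#' Static load exerted by a stack of pegs
#'
#' The weight of delivered pegs accumulates on the receiving transducer; each
#' 7.6 g peg adds about 0.0745 N.
#'
#' @param n_pegs Number of pegs resting on the transducer.
#' @param params A [sim_params()].
#' @return Force in newtons.
#' @examples
#' peg_load_force(1, sim_params())  # 0.0745 N
#' @export
peg_load_force <- function(n_pegs, params = sim_params()) {
  if (any(n_pegs < 0)) stop("peg_load_force: n_pegs must be >= 0", call. = FALSE)
  n_pegs * (params$peg_mass_g / 1000) * params$gravity_m_s2
}

# Effective per-cell parameters: condition effects only touch the treated
# hand; the untreated hand behaves as at baseline in every block.
effective_params <- function(params, condition, treated) {
  key <- if (isTRUE(treated)) condition else "baseline"
  list(
    gaze_lead_ms = unname(params$gaze_lead_ms[key]),
    kappa = unname(params$kappa[key]),
    durations_ms = params$action_duration_ms * unname(params$duration_scale[key]),
    peaks_N = params$peak_force_N * unname(params$force_scale[key])
  )
}
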