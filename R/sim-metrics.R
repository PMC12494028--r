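# Metrics-level generator: draws a trial-level dependent-variable table with
# the random-effects structure the contrast models assume (subject and
# round-within-subject effects plus residual noise) and an injectable
# treated-hand-by-treatment-block shift. Used for recovery studies of the
# contrast machinery, where simulating full sensor streams for tens of
# subjects would be wasteful.

#' Simulate a trial-level metrics table with a known treatment effect
#'
#' Every subject contributes balanced cells over blocks, hands, rounds, and
#' series. The injected `effect` is added only to the (treated hand,
#' treatment block) cell, so the ground-truth delta-delta equals `effect`
#' and every other contrast is zero in expectation.
#'
#' @param n_subjects Number of subjects.
#' @param n_blocks Number of blocks (block 1 is baseline; the effect lands
#'   in `treatment_block`).
#' @param n_rounds,n_series Rounds per block-hand, series per round.
#' @param baseline Grand mean of the DV (e.g. GISI in mm).
#' @param effect Shift applied to the treated hand in `treatment_block`.
#' @param treatment_block Block receiving the effect.
#' @param sd_subject,sd_round,sd_resid Random-effect and residual SDs.
#' @param seed Integer seed.
#' @return Tibble with `subject`, `block`, `hand`, `treated`, `round`,
#'   `series`, `series_block`, `value`.
#' @export
simulate_gisi_data <- function(n_subjects = 20, n_blocks = 2,
                               n_rounds = 4, n_series = 5,
                               baseline = 80, effect = -50,
                               treatment_block = 2,
                               sd_subject = 15, sd_round = 5, sd_resid = 10,
                               seed = 1L) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      subject = sprintf("S%02d", seq_len(n_subjects)),
      block = seq_len(n_blocks),
      hand = c("treated_hand", "untreated_hand"),
      round = seq_len(n_rounds),
      series = seq_len(n_series)
    )
    grid$treated <- grid$hand == "treated_hand"
    u_subj <- stats::rnorm(n_subjects, 0, sd_subject)
    names(u_subj) <- unique(grid$subject)
    round_key <- paste(grid$subject, grid$block, grid$hand, grid$round)
    u_round_tab <- stats::rnorm(length(unique(round_key)), 0, sd_round)
    names(u_round_tab) <- unique(round_key)
    grid$series_block <- (grid$round - 1) * n_series + grid$series
    grid$value <- baseline +
      u_subj[grid$subject] +
      u_round_tab[round_key] +
      ifelse(grid$treated & grid$block == treatment_block, effect, 0) +
      stats::rnorm(nrow(grid), 0, sd_resid)
    grid
  })
}
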