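#' Describe a pegboard experiment design
#'
#' An experiment comprises condition blocks; within each block both hands are
#' tested over consecutive rounds, each round holds several series, and each
#' series has a placement phase followed by a retrieval phase, each engaging
#' every peg once.
#'
#' @param n_blocks Number of condition blocks.
#' @param hands Ordered hand labels; the first label is taken as the dominant
#'   hand unless stated otherwise by the labels themselves.
#' @param rounds_per_block_per_hand Rounds each hand performs in each block.
#' @param series_per_round Series within a round.
#' @param pegs_per_phase Pegs engaged once per phase.
#' @param phases Ordered phase labels.
#' @param treated_hand Which hand receives the injections.
#' @param block_conditions Condition label per block, one of
#'   `"baseline"`, `"sham"`, `"anesthesia"`.
#' @return An object of class `experiment_design`.
#' @seealso [exp1_design()], [exp2_design()], [build_schedule()]
#' @export
experiment_design <- function(n_blocks,
                              hands = c("dominant", "nondominant"),
                              rounds_per_block_per_hand = 4,
                              series_per_round = 5,
                              pegs_per_phase = 8,
                              phases = c("placement", "retrieval"),
                              treated_hand = "nondominant",
                              block_conditions = NULL) {
  counts <- c(n_blocks = n_blocks,
              rounds = rounds_per_block_per_hand,
              series = series_per_round,
              pegs = pegs_per_phase)
  if (any(!is.finite(counts)) || any(counts < 1) || any(counts != round(counts))) {
    stop("invalid design: all counts must be positive integers", call. = FALSE)
  }
  if (length(hands) < 1 || anyDuplicated(hands)) {
    stop("invalid design: hands must be distinct labels", call. = FALSE)
  }
  if (!treated_hand %in% hands) {
    stop("invalid design: treated_hand must be one of the hand labels", call. = FALSE)
  }
  if (is.null(block_conditions)) {
    block_conditions <- c("baseline", rep("anesthesia", n_blocks - 1))
  }
  if (length(block_conditions) != n_blocks) {
    stop("invalid design: need exactly one condition per block", call. = FALSE)
  }
  block_conditions <- match.arg(block_conditions,
                                c("baseline", "sham", "anesthesia"),
                                several.ok = TRUE)
  structure(
    list(n_blocks = as.integer(n_blocks),
         hands = as.character(hands),
         rounds_per_block_per_hand = as.integer(rounds_per_block_per_hand),
         series_per_round = as.integer(series_per_round),
         pegs_per_phase = as.integer(pegs_per_phase),
         phases = as.character(phases),
         treated_hand = treated_hand,
         block_conditions = block_conditions),
    class = "experiment_design"
  )
}

#' @export
print.experiment_design <- function(x, ...) {
  cat("<experiment_design>\n")
  cat("  blocks:    ", x$n_blocks, " (", paste(x$block_conditions, collapse = ", "), ")\n", sep = "")
  cat("  hands:     ", paste(x$hands, collapse = ", "),
      " (treated: ", x$treated_hand, ")\n", sep = "")
  cat("  structure: ", x$rounds_per_block_per_hand, " rounds x ",
      x$series_per_round, " series x ", length(x$phases), " phases x ",
      x$pegs_per_phase, " pegs\n", sep = "")
  invisible(x)
}

#' First experiment design: baseline and anesthesia of the nondominant hand
#'
#' Two blocks (baseline, anesthesia), both hands, four rounds per hand per
#' block, five series per round, two phases of eight pegs: 1,280 trials per
#' participant.
#' @return An `experiment_design`.
#' @export
exp1_design <- function() {
  experiment_design(n_blocks = 2,
                    treated_hand = "nondominant",
                    block_conditions = c("baseline", "anesthesia"))
}

#' Second experiment design: baseline, sham, and anesthesia of the dominant hand
#'
#' Three blocks (baseline, saline sham, anesthesia), otherwise identical to
#' the first design: 1,920 trials per participant.
#' @return An `experiment_design`.
#' @export
exp2_design <- function() {
  experiment_design(n_blocks = 3,
                    treated_hand = "dominant",
                    block_conditions = c("baseline", "sham", "anesthesia"))
}

#' Expand a design into its full trial schedule
#'
#' One row per (block, hand, round, series, phase, peg). The collection and
#' delivery of a single peg is one trial, so the total row count is the
#' product of the design counts.
#'
#' @param design An [experiment_design()].
#' @return A tibble with columns `block`, `condition`, `hand`, `treated`,
#'   `round`, `series`, `phase`, `peg`.
#' @examples
#' nrow(build_schedule(exp1_design()))  # 1280
#' @export
build_schedule <- function(design) {
  stopifnot(inherits(design, "experiment_design"))
  grid <- tidyr::expand_grid(
    block = seq_len(design$n_blocks),
    hand = design$hands,
    round = seq_len(design$rounds_per_block_per_hand),
    series = seq_len(design$series_per_round),
    phase = design$phases,
    peg = seq_len(design$pegs_per_phase)
  )
  tibble::tibble(
    block = grid$block,
    condition = design$block_conditions[grid$block],
    hand = grid$hand,
    treated = grid$hand == design$treated_hand,
    round = grid$round,
    series = grid$series,
    phase = grid$phase,
    peg = grid$peg
  )
}
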