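# Delta / delta-delta contrasts and the mixed-model analyses: within-hand
# change between condition blocks (delta), its difference between treated
# and untreated hands (delta-delta), Type-2 Wald tests, Tukey post hocs,
# and learning-trend slopes.

#' Specify a contrast analysis
#'
#' @param dv Column of the metrics table holding the dependent variable.
#' @param fixed Fixed effects: always `block` and `hand`; optionally one of
#'   `"progress"`, `"phase"`, `"series_block"` as a third crossed factor.
#' @param random Random structure: `"intercept_nested"` is
#'   `(1 | subject/round)`; `"maximal"` adds by-subject random slopes for
#'   the full fixed interaction plus `(0 + round | subject)`.
#' @param blocks Length-2: the blocks compared (baseline first, treatment
#'   second), as block numbers.
#' @return A `contrast_spec`.
#' @export
contrast_spec <- function(dv, fixed = c("block", "hand"),
                          random = c("intercept_nested", "maximal"),
                          blocks = c(1, 2)) {
  random <- match.arg(random)
  extra <- setdiff(fixed, c("block", "hand"))
  if (length(extra) > 1) {
    stop("contrast_spec: at most one factor beyond block and hand", call. = FALSE)
  }
  if (length(extra) && !extra %in% c("progress", "phase", "series_block")) {
    stop("contrast_spec: unknown fixed effect ", extra, call. = FALSE)
  }
  if (length(blocks) != 2) stop("contrast_spec: blocks must be a pair", call. = FALSE)
  structure(list(dv = dv, fixed = fixed, random = random,
                 extra = if (length(extra)) extra else NULL,
                 blocks = blocks),
            class = "contrast_spec")
}

check_contrast_data <- function(data, spec) {
  need <- c("subject", "block", "hand", "treated", spec$dv)
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    stop("contrast data lacks columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!all(spec$blocks %in% data$block)) {
    stop("compared blocks absent from data", call. = FALSE)
  }
  th <- unique(data$hand[data$treated])
  uh <- unique(data$hand[!data$treated])
  if (length(th) != 1 || length(uh) != 1) {
    stop("data must mark exactly one treated and one untreated hand", call. = FALSE)
  }
  list(treated = th, untreated = uh)
}

#' Descriptive delta and delta-delta contrasts
#'
#' `delta = mean(DV | treatment block, hand) - mean(DV | baseline block,
#' hand)` per hand; `ddelta = delta_treated - delta_untreated`. Purely
#' arithmetic — the model-based version lives in [fit_mixed_model()].
#'
#' @param data Metrics table (one row per observation) with columns
#'   `subject`, `block`, `hand`, `treated`, and the DV.
#' @param spec A [contrast_spec()].
#' @return List with `delta` (per hand) and `ddelta`.
#' @export
delta_contrasts <- function(data, spec) {
  hands <- check_contrast_data(data, spec)
  dv <- data[[spec$dv]]
  cell_mean <- function(b, h) {
    v <- dv[data$block == b & data$hand == h]
    v <- v[!is.na(v)]
    if (!length(v)) {
      stop(sprintf("empty cell: block %s, hand %s", b, h), call. = FALSE)
    }
    mean(v)
  }
  delta <- vapply(c(hands$treated, hands$untreated), function(h) {
    cell_mean(spec$blocks[2], h) - cell_mean(spec$blocks[1], h)
  }, numeric(1))
  names(delta) <- c("treated", "untreated")
  list(delta = delta, ddelta = unname(delta["treated"] - delta["untreated"]))
}

build_formula <- function(spec, stage) {
  extra_f <- switch(spec$extra %||% "none",
                    progress = " * progress",
                    phase = " * phase",
                    series_block = " * series_block",
                    none = "")
  fixed <- paste0(spec$dv, " ~ block * hand", extra_f)
  random <- switch(stage,
    maximal = paste0("(1 + block * hand", extra_f, " | subject) + ",
                     "(0 + round | subject)"),
    intercept_nested = "(1 | subject / round)",
    intercept = "(1 | subject)")
  stats::as.formula(paste(fixed, "+", random))
}

fit_stage_ladder <- function(data, spec) {
  stages <- if (spec$random == "maximal") {
    c("maximal", "intercept_nested", "intercept")
  } else {
    c("intercept_nested", "intercept")
  }
  notes <- character(0)
  n_subj <- length(unique(data$subject))
  for (st in stages) {
    f <- build_formula(spec, st)
    if (st == "maximal") {
      # A by-subject covariance with q slope columns has q(q+1)/2 parameters;
      # estimating more parameters than subjects can support stalls or lands
      # on a singular fit, so such stages are skipped with a note (this is
      # the "most comprehensive model that converges" ladder).
      q <- ncol(stats::model.matrix(
        stats::as.formula(paste("~ block * hand",
                                switch(spec$extra %||% "none",
                                       progress = "* progress",
                                       phase = "* phase",
                                       series_block = "* series_block",
                                       none = ""))),
        data))
      if (q * (q + 1) / 2 > 2 * n_subj) {
        notes <- c(notes, paste0("maximal: skipped (", q * (q + 1) / 2,
                                 " covariance parameters for ", n_subj,
                                 " subjects)"))
        next
      }
    }
    fit <- tryCatch(
      withCallingHandlers(
        lme4::lmer(f, data = data, REML = TRUE,
                   control = lme4::lmerControl(calc.derivs = FALSE)),
        warning = function(w) invokeRestart("muffleWarning"),
        message = function(m) invokeRestart("muffleMessage")),
      error = function(e) e)
    if (inherits(fit, "error")) {
      notes <- c(notes, paste0(st, ": error (", conditionMessage(fit), ")"))
      next
    }
    conv_msgs <- unlist(fit@optinfo$conv$lme4$messages)
    bad <- lme4::isSingular(fit, tol = 1e-4) ||
      (length(conv_msgs) && any(grepl("failed to converge", conv_msgs)))
    if (!bad || st == utils::tail(stages, 1)) {
      if (bad) notes <- c(notes, paste0(st, ": kept despite convergence issues"))
      return(list(fit = fit, formula = f, stage = st, notes = notes))
    }
    notes <- c(notes, paste0(st, ": non-convergent or singular, simplified"))
  }
  stop("fit_mixed_model: no random-effects structure converged", call. = FALSE)
}

prep_model_data <- function(data, spec) {
  d <- dplyr::as_tibble(data)
  d$block <- factor(d$block)
  d$hand <- factor(d$hand)
  d$subject <- factor(d$subject)
  if ("round" %in% names(d)) d$round <- factor(d$round)
  if (!is.null(spec$extra)) {
    if (spec$extra == "progress") d$progress <- factor(d$progress)
    if (spec$extra == "phase") d$phase <- factor(d$phase)
    if (spec$extra == "series_block") d$series_block <- as.numeric(d$series_block)
  }
  d[!is.na(d[[spec$dv]]), ]
}

#' Fit the mixed-effect model for a contrast analysis
#'
#' REML fit of `DV ~ block * hand (* progress | phase | series_block)` with
#' the requested random structure, simplified down a fixed ladder
#' (maximal slopes, then nested intercepts, then subject intercept) on
#' non-convergence or singular fit — fixed effects are never dropped. The
#' result carries Type-2 Wald chi-square tests, Tukey-adjusted pairwise
#' block-by-hand comparisons, and the delta / delta-delta contrasts (per
#' level of the extra factor when one is present).
#'
#' @param data Metrics table with `subject`, `block`, `hand`, `treated`,
#'   optionally `round` and the extra factor, plus the DV column.
#' @param spec A [contrast_spec()].
#' @return A `gh_mixed_fit` list: `fit`, `formula`, `stage`,
#'   `simplification_notes`, `wald`, `posthoc`, `ddelta` (tibble),
#'   `emmeans`.
#' @export
fit_mixed_model <- function(data, spec) {
  hands <- check_contrast_data(data, spec)
  d <- prep_model_data(data, spec)
  if (length(unique(d$subject)) < 2) {
    stop("fit_mixed_model: need at least 2 subjects", call. = FALSE)
  }
  res <- fit_stage_ladder(d, spec)
  fit <- res$fit

  X <- lme4::getME(fit, "X")
  if (qr(X)$rank < ncol(X)) {
    stop("fit_mixed_model: rank-deficient fixed effects", call. = FALSE)
  }

  wald <- type2_wald(fit)
  by <- c("block", "hand", spec$extra)
  posthoc <- tukey_pairs(fit, c("block", "hand"))
  dd <- ddelta_model(fit, spec, hands)

  structure(list(fit = fit, formula = res$formula, stage = res$stage,
                 simplification_notes = res$notes,
                 wald = wald, posthoc = posthoc, ddelta = dd,
                 emmeans = emm_cells(fit, by)$cells,
                 hands = hands, spec = spec),
            class = "gh_mixed_fit")
}

#' @export
print.gh_mixed_fit <- function(x, ...) {
  cat("<gh_mixed_fit> ", deparse(x$formula), "\n", sep = "")
  cat("random-effects stage:", x$stage, "\n")
  if (length(x$simplification_notes)) {
    cat("simplifications:", paste(x$simplification_notes, collapse = "; "), "\n")
  }
  cat("\nType-2 Wald tests:\n")
  print(as.data.frame(x$wald), row.names = FALSE)
  cat("\nDelta-delta contrasts:\n")
  print(as.data.frame(x$ddelta), row.names = FALSE)
  invisible(x)
}

# Model-based delta-delta: ((b2,treated) - (b1,treated)) - ((b2,untreated)
# - (b1,untreated)) on the EMM scale, overall and per level of the extra
# factor when present.
ddelta_model <- function(fit, spec, hands) {
  extra <- spec$extra
  by <- c("block", "hand", if (!is.null(extra) && extra != "series_block") extra)
  em <- emm_cells(fit, by)
  cells <- em$cells
  b1 <- as.character(spec$blocks[1])
  b2 <- as.character(spec$blocks[2])
  row_of <- function(block, hand, lev = NULL) {
    i <- cells$block == block & cells$hand == hand
    if (!is.null(lev)) i <- i & cells[[extra]] == lev
    which(i)
  }
  one <- function(lev = NULL) {
    l <- (em$L[row_of(b2, hands$treated, lev), ] -
            em$L[row_of(b1, hands$treated, lev), ]) -
         (em$L[row_of(b2, hands$untreated, lev), ] -
            em$L[row_of(b1, hands$untreated, lev), ])
    lab <- paste0("ddelta B", b2, "-B", b1,
                  if (!is.null(lev)) paste0(" @", extra, "=", lev))
    linear_contrast(l, em$beta, em$vcov, lab)
  }
  levs <- if (!is.null(extra) && extra != "series_block") {
    unique(cells[[extra]])
  } else NULL
  if (is.null(levs)) {
    one()
  } else {
    dplyr::bind_rows(lapply(levs, one))
  }
}

#' Learning-trend slopes per block and hand
#'
#' Fits `DV ~ block * hand * series_block + (1 | subject/round)` with the
#' within-block series index as a numeric trend and reports the marginal
#' slope of the DV per block-by-hand cell, with standard errors and z
#' tests.
#'
#' @param data Metrics table with a numeric `series_block` column (series
#'   index within block).
#' @param spec A [contrast_spec()] whose `fixed` includes `"series_block"`.
#' @return Tibble with `block`, `hand`, `slope`, `se`, `statistic`,
#'   `p_value`.
#' @export
learning_trends <- function(data, spec) {
  if (is.null(spec$extra) || spec$extra != "series_block") {
    stop("learning_trends: spec must include series_block", call. = FALSE)
  }
  check_contrast_data(data, spec)
  n_series <- tapply(data$series_block, data$block, function(s) length(unique(s)))
  if (any(n_series < 3)) {
    stop("learning_trends: need at least 3 series per block", call. = FALSE)
  }
  d <- prep_model_data(data, spec)
  res <- fit_stage_ladder(d, spec)
  fit <- res$fit
  info <- fixed_model_info(fit)
  tt <- stats::delete.response(info$terms)
  grid <- tidyr::expand_grid(block = factor(levels(d$block), levels(d$block)),
                             hand = factor(levels(d$hand), levels(d$hand)))
  s0 <- mean(d$series_block)
  g0 <- dplyr::mutate(grid, series_block = s0)
  g1 <- dplyr::mutate(grid, series_block = s0 + 1)
  ctr <- attr(stats::model.matrix(fit), "contrasts")
  Ld <- stats::model.matrix(tt, g1, contrasts.arg = ctr) -
        stats::model.matrix(tt, g0, contrasts.arg = ctr)
  est <- unname(drop(Ld %*% info$beta))
  se <- unname(sqrt(diag(Ld %*% info$vcov %*% t(Ld))))
  tibble::tibble(block = as.character(grid$block), hand = as.character(grid$hand),
                 slope = est, se = se, statistic = est / se,
                 p_value = 2 * stats::pnorm(-abs(est / se)))
}
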