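# Type-2 Wald chi-square tests, reference-grid (marginal) cell means, and
# Tukey-adjusted pairwise comparisons for fitted mixed models. Implemented
# here because the analysis needs them as first-class, testable objects:
# hypothesis matrices are built explicitly and every contrast is an L %*%
# beta with its own covariance.

fixed_model_info <- function(fit) {
  if (inherits(fit, "merMod")) {
    list(beta = lme4::fixef(fit),
         vcov = as.matrix(stats::vcov(fit)),
         terms = stats::terms(fit, fixed.only = TRUE),
         assign = attr(lme4::getME(fit, "X"), "assign"),
         frame = stats::model.frame(fit))
  } else {
    list(beta = stats::coef(fit),
         vcov = as.matrix(stats::vcov(fit)),
         terms = stats::terms(fit),
         assign = attr(stats::model.matrix(fit), "assign"),
         frame = stats::model.frame(fit))
  }
}

# Basis for the subspace of span(Z) that is ip-orthogonal to span(X);
# columns of X and Z live in coefficient space.
conj_comp <- function(X, Z, ip) {
  xq <- qr(t(Z) %*% ip %*% X)
  if (xq$rank == 0) return(Z)
  Z %*% qr.Q(xq, complete = TRUE)[, -seq_len(xq$rank), drop = FALSE]
}

# Does term `b` contain term `a` (strictly)? Containment in the
# marginality sense: every factor of a appears in b.
term_contains <- function(fac, a, b) {
  if (a == b) return(FALSE)
  all(fac[, a] <= fac[, b]) && any(fac[, b] > fac[, a])
}

#' Type-2 Wald chi-square tests for fixed effects
#'
#' Each fixed term is tested after all terms that do not contain it,
#' ignoring its higher-order relatives, by a Wald chi-square on a
#' hypothesis matrix built in coefficient space (the marginality-respecting
#' "Type II" tests).
#'
#' @param fit A fitted `lmer` or `lm` model.
#' @return Tibble with `term`, `chisq`, `df`, `p_value`.
#' @export
type2_wald <- function(fit) {
  info <- fixed_model_info(fit)
  b <- info$beta
  V <- info$vcov
  p <- length(b)
  fac <- attr(info$terms, "factors")
  labels <- attr(info$terms, "term.labels")
  if (is.null(labels) || !length(labels)) {
    stop("type2_wald: model has no fixed terms to test", call. = FALSE)
  }
  fac <- fac[, labels, drop = FALSE]
  Ip <- diag(p)
  out <- lapply(seq_along(labels), function(k) {
    cols_term <- which(info$assign == k)
    rel <- which(vapply(seq_along(labels), function(j) {
      term_contains(fac, labels[k], labels[j])
    }, logical(1)))
    cols_rel <- which(info$assign %in% rel)
    if (!length(cols_rel)) {
      L <- Ip[cols_term, , drop = FALSE]
    } else {
      Z <- t(Ip[c(cols_rel, cols_term), , drop = FALSE])
      X <- t(Ip[cols_rel, , drop = FALSE])
      L <- t(conj_comp(X, Z, V))
    }
    L <- L[rowSums(abs(L)) > 1e-10, , drop = FALSE]
    df <- qr(L)$rank
    est <- L %*% b
    stat <- drop(t(est) %*% solve(L %*% V %*% t(L), est))
    tibble::tibble(term = labels[k], chisq = stat, df = df,
                   p_value = stats::pchisq(stat, df, lower.tail = FALSE))
  })
  dplyr::bind_rows(out)
}

# Reference grid: all combinations of the fixed-effect factors (numeric
# covariates held at their mean). Returns the grid plus the row of the
# fixed model matrix for each grid point.
reference_grid <- function(fit) {
  info <- fixed_model_info(fit)
  tt <- stats::delete.response(info$terms)
  vars <- all.vars(tt)
  frame <- info$frame
  levs <- lapply(vars, function(v) {
    x <- frame[[v]]
    if (is.factor(x)) factor(levels(x), levels = levels(x))
    else if (is.character(x)) sort(unique(x))
    else mean(x)
  })
  names(levs) <- vars
  grid <- do.call(tidyr::expand_grid, levs)
  X <- stats::model.matrix(tt, data = grid,
                           contrasts.arg = attr(stats::model.matrix(fit), "contrasts"))
  list(grid = grid, X = X, beta = info$beta, vcov = info$vcov)
}

#' Estimated marginal means over a factor combination
#'
#' Averages reference-grid predictions (equal weights over the levels of
#' all other factors) within each cell of `by`.
#'
#' @param fit A fitted `lmer` or `lm` model.
#' @param by Character vector of factor names defining the cells.
#' @return List with `cells` (tibble of cell labels, `emmean`, `se`) and
#'   `L` (one hypothesis row per cell).
#' @export
emm_cells <- function(fit, by) {
  rg <- reference_grid(fit)
  miss <- setdiff(by, names(rg$grid))
  if (length(miss)) {
    stop("emm_cells: not model factors: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  key <- do.call(paste, c(rg$grid[by], sep = "\r"))
  groups <- split(seq_len(nrow(rg$X)), key)
  # preserve grid order of first appearance
  groups <- groups[unique(key)]
  L <- t(vapply(groups, function(idx) colMeans(rg$X[idx, , drop = FALSE]),
                numeric(ncol(rg$X))))
  cells <- rg$grid[match(names(groups), key), by, drop = FALSE]
  est <- unname(drop(L %*% rg$beta))
  se <- unname(sqrt(diag(L %*% rg$vcov %*% t(L))))
  list(cells = dplyr::bind_cols(tibble::as_tibble(cells),
                                tibble::tibble(emmean = est, se = se)),
       L = L, beta = rg$beta, vcov = rg$vcov)
}

#' Tukey-adjusted pairwise comparisons of cell means
#'
#' All pairwise differences among the `by` cells, with z statistics
#' (asymptotic degrees of freedom) and studentized-range (Tukey)
#' adjustment.
#'
#' @param fit A fitted `lmer` or `lm` model.
#' @param by Character vector of factor names defining the cells.
#' @param df Degrees of freedom; `Inf` (default) is the asymptotic method.
#' @return Tibble with one row per pair: `contrast`, `estimate`, `se`,
#'   `statistic`, `p_value` (unadjusted), `p_adjusted` (Tukey).
#' @export
tukey_pairs <- function(fit, by, df = Inf) {
  em <- emm_cells(fit, by)
  k <- nrow(em$L)
  labels <- do.call(paste, c(em$cells[by], sep = " "))
  pairs <- utils::combn(k, 2)
  out <- lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    l <- em$L[a, ] - em$L[b, ]
    est <- drop(l %*% em$beta)
    se <- drop(sqrt(t(l) %*% em$vcov %*% l))
    z <- est / se
    p_un <- if (is.infinite(df)) 2 * stats::pnorm(-abs(z))
            else 2 * stats::pt(-abs(z), df)
    p_tk <- stats::ptukey(abs(z) * sqrt(2), k, ifelse(is.infinite(df), Inf, df),
                          lower.tail = FALSE)
    tibble::tibble(contrast = paste(labels[a], "-", labels[b]),
                   estimate = est, se = se, statistic = z,
                   df = df, p_value = p_un, p_adjusted = p_tk)
  })
  dplyr::bind_rows(out)
}

# General linear contrast l'beta with z test (asymptotic df).
linear_contrast <- function(l, beta, vcov, label = "") {
  est <- drop(l %*% beta)
  se <- drop(sqrt(t(l) %*% vcov %*% l))
  z <- est / se
  tibble::tibble(contrast = label, estimate = est, se = se, statistic = z,
                 p_value = 2 * stats::pnorm(-abs(z)))
}
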