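#' Survey design object
#'
#' Bundles the stratum label, primary sampling unit (PSU) label and
#' sampling weight of each record. PSUs are nested in strata: the PSU id
#' is interpreted within its stratum, so reusing PSU label "1" in two
#' strata denotes two different PSUs. Variance estimation is design-based:
#' between-PSU variability within strata, with the usual with-replacement
#' first-stage approximation.
#'
#' @param strata Vector of stratum labels.
#' @param psu Vector of PSU labels, nested in `strata`.
#' @param weights Positive sampling weights.
#' @return An object of class `svy_design`.
#' @export
survey_design <- function(strata, psu, weights) {
  n <- length(weights)
  if (length(strata) != n || length(psu) != n)
    stop("strata, psu and weights must have equal length", call. = FALSE)
  if (!is.numeric(weights) || any(!is.finite(weights)) || any(weights <= 0))
    stop("weights must be finite and strictly positive", call. = FALSE)
  if (anyNA(strata) || anyNA(psu))
    stop("strata and psu labels must not be missing", call. = FALSE)
  d <- structure(
    list(strata = factor(strata),
         psu = interaction(factor(strata), factor(psu), drop = TRUE),
         weights = as.numeric(weights)),
    class = "svy_design")
  d
}

#' @export
print.svy_design <- function(x, ...) {
  cat(sprintf(
    "Stratified cluster design: %d records, %d strata, %d PSUs (df = %d)\n",
    length(x$weights), nlevels(droplevels(x$strata)),
    nlevels(droplevels(x$psu)), design_df(x)))
  invisible(x)
}

#' Subset a survey design
#'
#' Row-subsets the design in step with a data subset (e.g. a stratified
#' analysis within one level of a modifier). Stratum and PSU labels are
#' kept as-is; strata reduced to a single PSU by the subset are handled at
#' variance-estimation time by the singleton rule.
#'
#' @param design A `svy_design`.
#' @param i Logical or integer row index.
#' @return A `svy_design` on the selected rows.
#' @export
subset_design <- function(design, i) {
  structure(list(strata = design$strata[i], psu = design$psu[i],
                 weights = design$weights[i]),
            class = "svy_design")
}

#' Design degrees of freedom
#'
#' The customary design-based degrees of freedom: number of distinct PSUs
#' minus number of distinct strata (among records present).
#'
#' @param design A `svy_design`.
#' @return Integer df; an error if it falls below 1.
#' @export
design_df <- function(design) {
  df <- nlevels(droplevels(design$psu)) - nlevels(droplevels(design$strata))
  if (df < 1)
    stop("design degrees of freedom (#PSUs - #strata) is ", df,
         "; at least 1 is required", call. = FALSE)
  df
}

#' Weighted least squares coefficients
#'
#' Solves the weighted normal equations `(X'WX) b = X'Wy` via the QR
#' decomposition of the row-scaled design matrix. Point estimates are
#' invariant to rescaling all weights by a positive constant.
#'
#' @param x Numeric design matrix (with intercept column if wanted).
#' @param y Numeric outcome vector.
#' @param w Positive weights.
#' @return Named coefficient vector.
#' @export
weighted_ls <- function(x, y, w) {
  x <- as.matrix(x)
  qr_ <- qr(x * sqrt(w))
  if (qr_$rank < ncol(x)) {
    drop_ <- colnames(x)[qr_$pivot[(qr_$rank + 1L):ncol(x)]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(drop_, collapse = ", "), call. = FALSE)
  }
  b <- qr.coef(qr_, y * sqrt(w))
  names(b) <- colnames(x)
  b
}

#' Taylor-linearized covariance of survey-weighted coefficients
#'
#' The design-based sandwich estimator for stratified cluster samples.
#' Weighted score contributions `u_j = w_j e_j x_j` are totalled per PSU;
#' within each stratum the between-PSU scatter of those totals (times
#' `n_h / (n_h - 1)` for `n_h` PSUs) estimates the stratum's score
#' variance, and the sum over strata is sandwiched between `(X'WX)^-1`.
#' This is the standard with-replacement first-stage approximation used
#' for public-release national survey design files.
#'
#' Strata reduced to a single PSU (possible after subgroup subsetting)
#' cannot contribute a within-stratum contrast; under the default
#' `singleton = "centre"` rule their PSU total is contrasted against the
#' grand mean of all PSU totals (with a warning); `singleton = "fail"`
#' raises an error instead.
#'
#' @param x Design matrix used in the fit.
#' @param y Outcome vector.
#' @param beta Fitted coefficients, from [weighted_ls()].
#' @param design A `svy_design` aligned with the rows of `x`.
#' @param singleton `"centre"` or `"fail"`: handling of single-PSU strata.
#' @return Symmetric covariance matrix of `beta`, invariant to global
#'   weight rescaling.
#' @export
taylor_covariance <- function(x, y, beta, design,
                              singleton = c("centre", "fail")) {
  singleton <- match.arg(singleton)
  x <- as.matrix(x)
  w <- design$weights
  e <- y - drop(x %*% beta)
  u <- x * (w * e)                       # record-level weighted scores
  psu <- droplevels(design$psu)
  strata <- droplevels(design$strata)
  z <- rowsum(u, psu, reorder = TRUE)    # PSU score totals
  psu_stratum <- strata[match(rownames(z), as.character(psu))]
  nh <- table(psu_stratum)
  if (any(nh == 1L)) {
    if (singleton == "fail")
      stop("stratum with a single PSU: ",
           paste(names(nh)[nh == 1L], collapse = ", "), call. = FALSE)
    warning("singleton-PSU stratum contrasted against the grand mean: ",
            paste(names(nh)[nh == 1L], collapse = ", "), call. = FALSE)
  }
  grand <- colMeans(z)
  mid <- matrix(0, ncol(x), ncol(x), dimnames = list(colnames(x), colnames(x)))
  for (h in names(nh)) {
    zh <- z[psu_stratum == h, , drop = FALSE]
    ctr <- if (nrow(zh) > 1L) colMeans(zh) else grand
    d <- sweep(zh, 2L, ctr)
    f <- if (nrow(zh) > 1L) nrow(zh) / (nrow(zh) - 1) else 1
    mid <- mid + f * crossprod(d)
  }
  xwx_inv <- chol2inv(chol(crossprod(x * sqrt(w))))
  v <- xwx_inv %*% mid %*% xwx_inv
  (v + t(v)) / 2
}

#' Fit a survey-weighted linear model
#'
#' Design-based weighted linear regression: coefficients from
#' [weighted_ls()], covariance from [taylor_covariance()], inference on
#' the t distribution with the design degrees of freedom (not the normal
#' — subgroup analyses can have few PSUs). Factors in the formula use
#' their first level as reference; relevel beforehand to change it.
#'
#' @param formula Model formula, e.g. `phenoage ~ diet_class + chron_age +
#'   sex`.
#' @param data A data.frame holding every formula variable, with no
#'   missing values in them (apply exclusions first).
#' @param design A `svy_design` aligned row-for-row with `data`.
#' @param level Confidence level for the reported intervals.
#' @param singleton Singleton-PSU stratum rule, see [taylor_covariance()].
#' @return An object of class `svy_fit`: list with `coefficients`,
#'   `vcov`, `df`, `n`, `sum_weights`, `level`, `table` (term, estimate,
#'   se, ci_low, ci_high, t, p), plus the formula and terms.
#' @export
fit_survey_model <- function(formula, data, design, level = 0.95,
                             singleton = c("centre", "fail")) {
  singleton <- match.arg(singleton)
  mf <- stats::model.frame(formula, data, na.action = stats::na.fail)
  trm <- attr(mf, "terms")
  x <- stats::model.matrix(trm, mf)
  y <- stats::model.response(mf)
  if (nrow(x) != length(design$weights))
    stop("data and design have different numbers of rows", call. = FALSE)
  beta <- weighted_ls(x, y, design$weights)
  v <- taylor_covariance(x, y, beta, design, singleton)
  df <- design_df(design)
  se <- sqrt(diag(v))
  tcrit <- stats::qt(1 - (1 - level) / 2, df)
  tval <- beta / se
  tab <- data.frame(
    term = names(beta), estimate = unname(beta), se = unname(se),
    ci_low = unname(beta - tcrit * se), ci_high = unname(beta + tcrit * se),
    t = unname(tval),
    p = unname(2 * stats::pt(-abs(tval), df)),
    row.names = NULL)
  structure(
    list(coefficients = beta, vcov = v, df = df, n = nrow(x),
         sum_weights = sum(design$weights), level = level, table = tab,
         formula = formula, terms = trm),
    class = "svy_fit")
}

#' @export
coef.svy_fit <- function(object, ...) object$coefficients

#' @export
vcov.svy_fit <- function(object, ...) object$vcov

#' @export
confint.svy_fit <- function(object, parm, level = NULL, ...) {
  level <- if (is.null(level)) object$level else level
  tcrit <- stats::qt(1 - (1 - level) / 2, object$df)
  se <- sqrt(diag(object$vcov))
  ci <- cbind(object$coefficients - tcrit * se,
              object$coefficients + tcrit * se)
  colnames(ci) <- paste0(100 * c((1 - level) / 2, 1 - (1 - level) / 2), " %")
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.svy_fit <- function(x, digits = 4, ...) {
  cat("Survey-weighted linear model (Taylor-linearized variance)\n")
  cat(sprintf("n = %d, design df = %d, sum of weights = %.1f\n",
              x$n, x$df, x$sum_weights))
  print(cbind(
    estimate = round(x$table$estimate, digits),
    se = round(x$table$se, digits),
    ci_low = round(x$table$ci_low, digits),
    ci_high = round(x$table$ci_high, digits),
    p = signif(x$table$p, 3)),
    ...)
  invisible(x)
}

#' Joint Wald test of a coefficient subset
#'
#' Tests that a subset of q coefficients is jointly zero:
#' `W = b' V^-1 b` on the subset, reported as `F = W / q` against
#' `F(q, df - q + 1)` where `df` is the design degrees of freedom. For
#' `q = 1` this reduces exactly to the squared-t test of the single
#' coefficient. Used for interaction (effect-modification) tests: a
#' 3-level modifier contributes two product terms, tested jointly (q = 2)
#' so a single p-value summarizes the modifier.
#'
#' @param fit An `svy_fit`.
#' @param terms Character vector of coefficient names, or an integer/
#'   logical index into the coefficient vector.
#' @return List with `statistic` (the F value), `q`, `df_denom`, `p`.
#' @export
wald_test <- function(fit, terms) {
  b <- fit$coefficients
  idx <- if (is.character(terms)) match(terms, names(b)) else
    seq_along(b)[terms]
  if (anyNA(idx) || !length(idx))
    stop("unknown coefficient(s): ",
         paste(terms[is.na(idx)], collapse = ", "), call. = FALSE)
  q <- length(idx)
  vsub <- fit$vcov[idx, idx, drop = FALSE]
  w <- tryCatch(drop(crossprod(b[idx], solve(vsub, b[idx]))),
                error = function(e)
                  stop("singular covariance submatrix in Wald test",
                       call. = FALSE))
  df2 <- fit$df - q + 1
  if (df2 < 1)
    stop("not enough design df for a joint test of ", q, " terms",
         call. = FALSE)
  f <- w / q
  list(statistic = f, q = q, df_denom = df2,
       p = stats::pf(f, q, df2, lower.tail = FALSE))
}
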