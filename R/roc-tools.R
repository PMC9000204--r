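# Empirical ROC curves, Youden cut-offs, dichotomization and the DeLong
# paired test for equality of two AUCs measured on the same subjects.

as_case_indicator <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    ok <- labels %in% c("case", "control")
    if (!all(ok)) {
      stop("labels must be 'case'/'control' (or logical)", call. = FALSE)
    }
    return(labels == "case")
  }
  as.logical(labels)
}

#' Empirical ROC curve and AUC
#'
#' Computes the empirical ROC over all unique score thresholds with strict
#' `>` positivity. The AUC is the Mann-Whitney probability that a random
#' case scores above a random control, ties counted one half - identical to
#' the trapezoidal area under the curve.
#'
#' @param scores Numeric marker values.
#' @param labels `"case"`/`"control"` labels (or a logical case indicator) of
#'   the same length.
#' @return Object of class `roc_curve` with `thresholds`, `fpr`, `tpr`
#'   (including the (0,0) and (1,1) endpoints), `auc`, `n_cases`,
#'   `n_controls`.
#' @export
empirical_roc <- function(scores, labels) {
  is_case <- as_case_indicator(labels)
  stopifnot(length(scores) == length(is_case))
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  cases <- scores[is_case]
  controls <- scores[!is_case]
  if (length(cases) == 0 || length(controls) == 0) {
    stop("both cases and controls are required", call. = FALSE)
  }
  thr <- sort(unique(scores))
  tpr <- vapply(thr, function(t) mean(cases > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(controls > t), numeric(1))
  ord <- order(fpr, tpr)
  fpr <- c(0, fpr[ord], 1)
  tpr <- c(0, tpr[ord], 1)
  structure(
    list(thresholds = thr, fpr = fpr, tpr = tpr,
         auc = mann_whitney_auc(cases, controls),
         n_cases = length(cases), n_controls = length(controls)),
    class = "roc_curve"
  )
}

mann_whitney_auc <- function(cases, controls) {
  r <- rank(c(cases, controls))
  m <- length(cases)
  (sum(r[seq_len(m)]) - m * (m + 1) / 2) / (m * length(controls))
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("Empirical ROC: %d cases vs %d controls, AUC = %.4f\n",
              x$n_cases, x$n_controls, x$auc))
  invisible(x)
}

#' Youden-index cut-off
#'
#' Evaluates J = sensitivity + specificity - 1 at every observed score used
#' as a strict `>` threshold and returns the maximizer. Ties in J are broken
#' toward the smallest threshold (which maximizes sensitivity at equal J).
#' With `rounding = "integer"` the winning threshold is rounded to the
#' nearest integer in the marker's unit after maximization, and sensitivity,
#' specificity and J are re-evaluated at the rounded cut-off.
#'
#' @inheritParams empirical_roc
#' @param rounding `"integer"` (default) or `"none"`.
#' @return Object of class `cutoff_result`: `cutoff`, `youden`,
#'   `sensitivity`, `specificity`, `rounded`.
#' @export
youden_cutoff <- function(scores, labels, rounding = c("integer", "none")) {
  rounding <- match.arg(rounding)
  is_case <- as_case_indicator(labels)
  cases <- scores[is_case]
  controls <- scores[!is_case]
  if (length(cases) == 0 || length(controls) == 0) {
    stop("both cases and controls are required", call. = FALSE)
  }
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    mean(cases > t) + mean(controls <= t) - 1
  }, numeric(1))
  best <- thr[which.max(j)]  # which.max takes the first, i.e. smallest, tie
  cutoff <- if (rounding == "integer") round(best) else best
  se <- mean(cases > cutoff)
  sp <- mean(controls <= cutoff)
  structure(
    list(cutoff = cutoff, youden = se + sp - 1,
         sensitivity = se, specificity = sp,
         rounded = rounding == "integer"),
    class = "cutoff_result"
  )
}

#' @export
print.cutoff_result <- function(x, ...) {
  cat(sprintf("Cut-off > %g%s: Se = %.3f, Sp = %.3f, J = %.3f\n",
              x$cutoff, if (x$rounded) " (rounded)" else "",
              x$sensitivity, x$specificity, x$youden))
  invisible(x)
}

#' Dichotomize marker values at a cut-off
#'
#' Positivity is strict: a value equal to the cut-off is negative, matching
#' the conventional Ca125 rule of "> 35 IU/mL".
#'
#' @param values Numeric vector.
#' @param cutoff Single threshold.
#' @return Integer vector of 0/1 indicators.
#' @export
dichotomize <- function(values, cutoff) {
  as.integer(values > cutoff)
}

#' DeLong's paired test for equality of two AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects.
#' Per-subject placement components (the structural components of the
#' Mann-Whitney statistic) give the covariance of the two AUC estimators;
#' the difference divided by its standard error is referred to the standard
#' normal distribution, two sided.
#'
#' @param scores_a,scores_b Two markers on the same subjects (same length
#'   and order as `labels`).
#' @inheritParams empirical_roc
#' @return Object of class `auc_comparison`: `auc_a`, `auc_b`, `difference`,
#'   `variance`, `z`, `p_value`.
#' @references DeLong ER, DeLong DM, Clarke-Pearson DL. Comparing the areas
#'   under two or more correlated receiver operating characteristic curves.
#'   Biometrics 1988;44:837-845.
#' @export
auc_equality_test <- function(scores_a, scores_b, labels) {
  is_case <- as_case_indicator(labels)
  stopifnot(length(scores_a) == length(is_case),
            length(scores_b) == length(is_case))
  if (!any(is_case) || all(is_case)) {
    stop("both cases and controls are required", call. = FALSE)
  }
  comp <- function(scores) {
    cases <- scores[is_case]
    controls <- scores[!is_case]
    psi <- outer(cases, controls,
                 function(a, b) (a > b) + 0.5 * (a == b))
    list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
  }
  a <- comp(scores_a)
  b <- comp(scores_b)
  m <- sum(is_case)
  n <- sum(!is_case)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- a$auc - b$auc
  if (v <= 0) {
    if (abs(d) < .Machine$double.eps^0.5) {
      warning("zero variance with zero AUC difference; p set to 1",
              call. = FALSE)
      z <- 0; p <- 1; v <- 0
    } else {
      stop("zero variance with a nonzero AUC difference; ",
           "the paired test is undefined", call. = FALSE)
    }
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(
    list(auc_a = a$auc, auc_b = b$auc, difference = d,
         variance = v, z = z, p_value = p),
    class = "auc_comparison"
  )
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("Paired AUC comparison: %.4f vs %.4f (diff %+.4f), p = %.4g\n",
              x$auc_a, x$auc_b, x$difference, x$p_value))
  invisible(x)
}
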