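# Two-stage covariate-adjusted parametric ROC regression.
#
# Stage 1 models the marker among disease-free controls (ordinary least
# squares) and retains the empirical residual distribution. Each case is
# then standardized to a placement value: the covariate-adjusted fraction of
# controls exceeding it. Stage 2 fits a probit-link GLM to the exceedance
# indicators 1{PV <= u} over a grid of false-positive rates u, giving the
# parametric ROC  ROC_X(u) = pnorm(g0 + g1 * qnorm(u) + b'X)  whose
# covariate coefficients describe shifts in discriminatory accuracy.
# Confidence intervals come from a cluster bootstrap over hospitals.

#' Fit the stage-1 control model
#'
#' Ordinary least-squares regression of the marker on covariates among the
#' disease-free stratum. The empirical distribution of its residuals is the
#' reference distribution against which cases are standardized.
#'
#' @param controls data.frame of control records.
#' @param marker Column name of the marker.
#' @param covariates Character vector of covariate column names (may be
#'   empty for an intercept-only model).
#' @return Object of class `control_model_fit`: `coefficients`, `residuals`,
#'   `covariate_names`, `n_controls`, and the underlying `lm` fit.
#' @export
fit_control_model <- function(controls, marker, covariates = character()) {
  controls <- as.data.frame(controls)
  if (nrow(controls) < 10) {
    stop("at least 10 controls are required (got ", nrow(controls), ")",
         call. = FALSE)
  }
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  fml <- stats::as.formula(paste(marker, "~", rhs))
  mm <- stats::model.matrix(fml, data = controls)
  if (ncol(mm) > 1) {
    kap <- kappa(mm, exact = TRUE)
    if (!is.finite(kap) || kap >= 1e8) {
      stop("collinear control-model design (condition number ",
           format(kap, digits = 3), ") among covariates: ",
           paste(covariates, collapse = ", "),
           "; drop one of the correlated covariates", call. = FALSE)
    }
  }
  fit <- stats::lm(fml, data = controls)
  structure(
    list(coefficients = stats::coef(fit),
         residuals = unname(stats::residuals(fit)),
         covariate_names = covariates,
         n_controls = nrow(controls),
         lm_fit = fit),
    class = "control_model_fit"
  )
}

#' Placement values of cases against the control distribution
#'
#' For each case, the placement value is `1 - F0(y - x'theta)`: the fraction
#' of control residuals strictly exceeding the case's residual from the
#' control model. A small placement value means the case sits high in the
#' covariate-matched control distribution.
#'
#' @param cases data.frame of case records (covariate columns must match the
#'   control model).
#' @param control_fit A [fit_control_model()] result.
#' @param marker Column name of the marker.
#' @return Numeric vector in \[0, 1\], one per case.
#' @export
placement_values <- function(cases, control_fit, marker) {
  stopifnot(inherits(control_fit, "control_model_fit"))
  if (length(control_fit$residuals) < 10) {
    stop("control model must retain at least 10 residuals", call. = FALSE)
  }
  cases <- as.data.frame(cases)
  pred <- stats::predict(control_fit$lm_fit, newdata = cases)
  case_resid <- cases[[marker]] - unname(pred)
  vapply(case_resid, function(e) mean(control_fit$residuals > e), numeric(1))
}

#' Fit the stage-2 probit ROC-GLM
#'
#' Builds binary exceedance indicators `U_iu = 1{PV_i <= u}` for every case
#' `i` and grid point `u`, and fits a probit-link GLM with linear predictor
#' `g0 + g1 * qnorm(u) + b'X_i` by maximum likelihood. The fitted
#' covariate-specific ROC is `ROC_X(u) = pnorm(g0 + g1*qnorm(u) + b'X)`.
#' Placement values of exactly 0 (or 1) are moved to `1/(2*n_controls)`
#' (resp. `1 - 1/(2*n_controls)`) inside the indicator construction only, so
#' that grid-end indicators stay informative.
#'
#' @param pv Placement values in \[0, 1\].
#' @param case_covariates Optional data.frame/matrix of case-level ROC
#'   covariates (one row per case), or `NULL`.
#' @param fpr_grid Strictly increasing false-positive-rate grid inside
#'   (0, 1); default 30 equally spaced interior points.
#' @param n_controls Number of controls behind the placement values (sets
#'   the floor/cap for degenerate placement values); default 'length(pv)'.
#' @return Object of class `roc_glm_fit`: `gamma0`, `gamma1`,
#'   `covariate_betas`, `coefficients` (full named vector), `fpr_grid`,
#'   `placement_values`, `n_cases`, `converged`.
#' @export
fit_roc_glm <- function(pv, case_covariates = NULL,
                        fpr_grid = default_fpr_grid(),
                        n_controls = length(pv)) {
  stopifnot(all(pv >= 0), all(pv <= 1))
  if (any(fpr_grid <= 0) || any(fpr_grid >= 1) || is.unsorted(fpr_grid, strictly = TRUE)) {
    stop("fpr_grid must be strictly increasing inside (0, 1)", call. = FALSE)
  }
  if (all(pv == 0) || all(pv == 1)) {
    stop("degenerate placement values (all 0 or all 1): cases and controls ",
         "are perfectly separated; jitter the marker or use more data",
         call. = FALSE)
  }
  eps <- 1 / (2 * max(n_controls, length(pv)))
  pv_adj <- pmin(pmax(pv, eps), 1 - eps)

  n_case <- length(pv)
  ng <- length(fpr_grid)
  u <- rep(fpr_grid, each = n_case)
  U <- as.integer(rep(pv_adj, times = ng) <= u)
  dat <- data.frame(U = U, qnorm_u = stats::qnorm(u))
  cov_names <- character()
  if (!is.null(case_covariates)) {
    X <- as.data.frame(case_covariates)
    if (nrow(X) != n_case) {
      stop("case_covariates must have one row per case", call. = FALSE)
    }
    cov_names <- names(X)
    dat <- cbind(dat, X[rep(seq_len(n_case), times = ng), , drop = FALSE])
  }
  fml <- stats::as.formula(paste(
    "U ~ qnorm_u",
    if (length(cov_names)) paste("+", paste(cov_names, collapse = " + ")) else ""
  ))
  fit <- suppressWarnings(
    stats::glm(fml, family = stats::binomial(link = "probit"), data = dat)
  )
  if (!fit$converged) {
    stop("probit ROC-GLM did not converge after ", fit$iter,
         " IWLS iterations (deviance ", format(fit$deviance, digits = 4),
         "); consider a coarser grid or more cases", call. = FALSE)
  }
  cf <- stats::coef(fit)
  structure(
    list(gamma0 = unname(cf["(Intercept)"]),
         gamma1 = unname(cf["qnorm_u"]),
         covariate_betas = cf[setdiff(names(cf), c("(Intercept)", "qnorm_u"))],
         coefficients = cf,
         fpr_grid = fpr_grid,
         placement_values = pv,
         n_cases = n_case,
         converged = fit$converged),
    class = "roc_glm_fit"
  )
}

#' Default false-positive-rate grid
#'
#' Thirty equally spaced interior points `k/31`, `k = 1, ..., 30`; the
#' endpoints 0 and 1 are excluded because the probit is undefined there.
#'
#' @param size Number of interior points.
#' @return Numeric vector in (0, 1).
#' @export
default_fpr_grid <- function(size = 30) {
  seq_len(size) / (size + 1)
}

#' Evaluate the fitted covariate-specific ROC on the grid
#'
#' @param fit A [fit_roc_glm()] result.
#' @param covariate_values Named covariate values (or `NULL` for none).
#' @return data.frame with columns `fpr` and `tpr`.
#' @export
predict_roc <- function(fit, covariate_values = NULL) {
  shift <- covariate_shift(fit, covariate_values)
  data.frame(
    fpr = fit$fpr_grid,
    tpr = stats::pnorm(fit$gamma0 + fit$gamma1 * stats::qnorm(fit$fpr_grid) +
                         shift)
  )
}

covariate_shift <- function(fit, covariate_values) {
  if (length(fit$covariate_betas) == 0) return(0)
  if (is.null(covariate_values)) {
    stop("fit has covariates (", paste(names(fit$covariate_betas),
                                       collapse = ", "),
         "); supply covariate_values", call. = FALSE)
  }
  x <- unlist(covariate_values)[names(fit$covariate_betas)]
  if (anyNA(x)) stop("covariate_values missing entries", call. = FALSE)
  sum(fit$covariate_betas * x)
}

#' Closed-form AUC of the fitted binormal ROC at given covariates
#'
#' For the probit ROC `pnorm(g0 + g1*qnorm(u) + b'X)` the area under the
#' curve is `pnorm((g0 + b'X) / sqrt(1 + g1^2))`.
#'
#' @inheritParams predict_roc
#' @return AUC in \[0, 1\].
#' @export
covariate_adjusted_auc <- function(fit, covariate_values = NULL) {
  if (fit$gamma1 <= 0) {
    stop("closed-form AUC requires gamma1 > 0", call. = FALSE)
  }
  shift <- covariate_shift(fit, covariate_values)
  stats::pnorm((fit$gamma0 + shift) / sqrt(1 + fit$gamma1^2))
}

#' @export
print.roc_glm_fit <- function(x, ...) {
  cat(sprintf("Probit ROC-GLM on %d cases, %d grid points\n",
              x$n_cases, length(x$fpr_grid)))
  cat(sprintf("  gamma0 = %.4f, gamma1 = %.4f\n", x$gamma0, x$gamma1))
  if (length(x$covariate_betas)) {
    for (nm in names(x$covariate_betas)) {
      cat(sprintf("  beta[%s] = %.4f\n", nm, x$covariate_betas[[nm]]))
    }
  }
  invisible(x)
}

#' Full two-stage ROC regression
#'
#' Runs stage 1 (control model) and stage 2 (probit ROC-GLM) on a cohort
#' table, and optionally wraps the whole procedure in a hospital-cluster
#' bootstrap for confidence intervals.
#'
#' @param data data.frame with one row per subject.
#' @param marker Marker column name (e.g. `"he4_adj"`).
#' @param is_case Logical vector (or name of a logical column) marking
#'   diseased subjects; the rest are controls.
#' @param control_covariates Covariates for the stage-1 level model.
#' @param roc_covariates Covariates entering the stage-2 accuracy model
#'   (default: same as `control_covariates`).
#' @param cluster Optional column name of the bootstrap cluster variable
#'   (e.g. `"hospital"`); when given, percentile CIs are computed.
#' @param n_boot Bootstrap replicates (default 50).
#' @param seed Integer seed governing the bootstrap.
#' @param ci_type Bootstrap interval type (see [cluster_bootstrap()]).
#' @param fpr_grid False-positive-rate grid for stage 2.
#' @return Object of class `roc_regression_fit`: `control_fit`, `roc_fit`,
#'   and (with `cluster`) `bootstrap_cis`, a data.frame of percentile
#'   intervals per coefficient, plus `n_bootstrap`.
#' @export
roc_regression <- function(data, marker, is_case,
                           control_covariates = c("creatinine", "menopausal"),
                           roc_covariates = control_covariates,
                           cluster = NULL, n_boot = 50, seed = 1L,
                           ci_type = c("normal", "percentile"),
                           fpr_grid = default_fpr_grid()) {
  data <- as.data.frame(data)
  if (is.character(is_case) && length(is_case) == 1) {
    is_case <- as.logical(data[[is_case]])
  }
  stopifnot(length(is_case) == nrow(data))

  point <- roc_two_stage(data, marker, is_case, control_covariates,
                         roc_covariates, fpr_grid)

  out <- list(control_fit = point$control_fit, roc_fit = point$roc_fit,
              coefficients = point$coefficients,
              marker = marker,
              control_covariates = control_covariates,
              roc_covariates = roc_covariates)
  if (!is.null(cluster)) {
    boot <- cluster_bootstrap(
      function(d) {
        roc_two_stage(d, marker, as.logical(d$.is_case), control_covariates,
                      roc_covariates, fpr_grid)$coefficients
      },
      data = transform(data, .is_case = is_case),
      cluster = cluster, n_reps = n_boot, seed = seed,
      ci_type = match.arg(ci_type)
    )
    out$bootstrap_cis <- boot$ci
    out$n_bootstrap <- boot$n_used
    out$bootstrap_replicates <- boot$replicates
  }
  class(out) <- "roc_regression_fit"
  out
}

# one point estimate of the full two-stage procedure; returns a flat named
# coefficient vector (control model prefixed "control.", ROC model "roc.")
roc_two_stage <- function(data, marker, is_case, control_covariates,
                          roc_covariates, fpr_grid) {
  controls <- data[!is_case, , drop = FALSE]
  cases <- data[is_case, , drop = FALSE]
  if (nrow(cases) == 0 || nrow(controls) == 0) {
    stop("need both cases and controls", call. = FALSE)
  }
  cfit <- fit_control_model(controls, marker, control_covariates)
  pv <- placement_values(cases, cfit, marker)
  cov_df <- if (length(roc_covariates)) {
    cases[, roc_covariates, drop = FALSE]
  } else {
    NULL
  }
  rfit <- fit_roc_glm(pv, cov_df, fpr_grid, n_controls = cfit$n_controls)
  cf <- c(stats::setNames(cfit$coefficients,
                          paste0("control.", names(cfit$coefficients))),
          stats::setNames(rfit$coefficients,
                          paste0("roc.", names(rfit$coefficients))))
  list(control_fit = cfit, roc_fit = rfit, coefficients = cf)
}

#' @export
print.roc_regression_fit <- function(x, ...) {
  cat("Two-stage ROC regression\n")
  cat(sprintf("  Control model (n = %d): %s\n", x$control_fit$n_controls,
              paste(sprintf("%s = %.3f", names(x$control_fit$coefficients),
                            x$control_fit$coefficients), collapse = ", ")))
  print(x$roc_fit)
  if (!is.null(x$bootstrap_cis)) {
    cat(sprintf("  Cluster-bootstrap percentile CIs (%d replicates):\n",
                x$n_bootstrap))
    print(x$bootstrap_cis, digits = 4)
  }
  invisible(x)
}

#' Cluster bootstrap confidence intervals
#'
#' Resamples whole clusters (e.g. hospitals) with replacement - the same
#' number of clusters per replicate - refits the supplied procedure on each
#' resampled data set, and returns confidence intervals for every
#' coefficient. The default `"normal"` interval is the point estimate plus
#' or minus the normal quantile times the bootstrap standard deviation;
#' with typical replicate counts of about 50 the percentile interval's tail
#' quantiles rest on roughly one order statistic and run short, so
#' `"percentile"` is provided as an option rather than the default.
#' Replicates on which the procedure fails (for instance a resample with no
#' cases) are discarded and counted; more than 20% discarded is an error.
#'
#' @param fit_fun Function taking a data.frame and returning a named numeric
#'   coefficient vector.
#' @param data data.frame with one row per subject.
#' @param cluster Column name of the cluster variable (at least 2 distinct
#'   clusters).
#' @param n_reps Number of bootstrap replicates (>= 2; default 50).
#' @param seed Integer seed; replicate `b` uses the deterministic substream
#'   `seed + b`, so results are reproducible and extendable.
#' @param confidence Interval level (default 0.95).
#' @param ci_type `"normal"` (default) or `"percentile"`.
#' @return List: `ci` (data.frame coefficient/lower/upper), `replicates`
#'   (matrix of per-replicate coefficients), `n_used`, `n_discarded`.
#' @export
cluster_bootstrap <- function(fit_fun, data, cluster, n_reps = 50,
                              seed = 1L, confidence = 0.95,
                              ci_type = c("normal", "percentile")) {
  ci_type <- match.arg(ci_type)
  data <- as.data.frame(data)
  ids <- unique(data[[cluster]])
  if (length(ids) < 2) {
    stop("cluster bootstrap needs at least 2 clusters (got ",
         length(ids), ")", call. = FALSE)
  }
  if (n_reps < 2) stop("n_reps must be >= 2", call. = FALSE)
  rows_by_cluster <- split(seq_len(nrow(data)), data[[cluster]])

  reps <- vector("list", n_reps)
  discarded <- 0L
  for (b in seq_len(n_reps)) {
    set.seed(seed + b)
    take <- sample(ids, length(ids), replace = TRUE)
    idx <- unlist(rows_by_cluster[as.character(take)], use.names = FALSE)
    res <- tryCatch(fit_fun(data[idx, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(res)) {
      discarded <- discarded + 1L
      message("cluster bootstrap: replicate ", b, " discarded")
    } else {
      reps[[b]] <- res
    }
  }
  if (discarded > 0.2 * n_reps) {
    stop("more than 20% of bootstrap replicates failed (",
         discarded, "/", n_reps, ")", call. = FALSE)
  }
  mat <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  if (ci_type == "percentile") {
    probs <- c((1 - confidence) / 2, 1 - (1 - confidence) / 2)
    qs <- apply(mat, 2, stats::quantile, probs = probs, names = FALSE)
    lower <- qs[1, ]; upper <- qs[2, ]
  } else {
    point <- fit_fun(data)[colnames(mat)]
    z <- stats::qnorm(1 - (1 - confidence) / 2)
    bsd <- apply(mat, 2, stats::sd)
    lower <- point - z * bsd; upper <- point + z * bsd
  }
  ci <- data.frame(coefficient = colnames(mat),
                   lower = unname(lower), upper = unname(upper),
                   stringsAsFactors = FALSE)
  rownames(ci) <- NULL
  list(ci = ci, replicates = mat,
       n_used = nrow(mat), n_discarded = discarded)
}
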