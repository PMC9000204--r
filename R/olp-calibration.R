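#' Construct a calibration series for one test laboratory
#'
#' Pairs the reference laboratory's readings of a shared dilution series with
#' one test laboratory's readings of the same samples. If per-sample replicate
#' readings are supplied (samples are typically run in duplicate), they are
#' averaged into the `test` vector.
#'
#' @param reference Numeric vector of reference-lab concentrations (pmol/L).
#' @param test Numeric vector of the test lab's concentrations (pmol/L), or
#'   `NULL` if `replicates` is given.
#' @param lab_id Label for the test laboratory.
#' @param sample_ids Optional sample labels (default `A`, `B`, ...).
#' @param replicates Optional list, one numeric vector of replicate readings
#'   per sample; per-sample means become `test`.
#' @return An object of class `calibration_series`.
#' @export
calibration_series <- function(reference, test = NULL, lab_id = "lab",
                               sample_ids = NULL, replicates = NULL) {
  if (!is.null(replicates)) {
    rep_means <- vapply(replicates, function(v) mean(as.numeric(v)), numeric(1))
    if (is.null(test)) {
      test <- rep_means
    } else if (!isTRUE(all.equal(as.numeric(test), rep_means))) {
      stop("'test' must equal the per-sample mean of 'replicates'",
           call. = FALSE)
    }
  }
  reference <- as.numeric(reference)
  test <- as.numeric(test)
  n <- length(reference)
  if (length(test) != n) {
    stop("'reference' and 'test' must have equal length", call. = FALSE)
  }
  if (n < 3) {
    stop("calibration series needs at least 3 samples ('reference' has ",
         n, ")", call. = FALSE)
  }
  if (!all(is.finite(reference)) || any(reference <= 0)) {
    stop("'reference' concentrations must be finite and strictly positive",
         call. = FALSE)
  }
  if (!all(is.finite(test)) || any(test <= 0)) {
    stop("'test' concentrations must be finite and strictly positive",
         call. = FALSE)
  }
  if (is.null(sample_ids)) {
    sample_ids <- make.unique(rep(LETTERS, length.out = n))
  }
  structure(
    list(sample_ids = sample_ids, reference = reference, test = test,
         lab_id = lab_id, replicate_values = replicates),
    class = "calibration_series"
  )
}

#' Ordinary least product (geometric-mean) regression of reference on test lab
#'
#' Fits the symmetric regression `reference = alpha + beta * test` that
#' minimizes the sum of products of vertical and horizontal deviations.
#' Unlike ordinary least squares it treats measurement error in both
#' laboratories symmetrically: the slope is
#' `beta = sign(Sxy) * sqrt(Syy / Sxx)` and the intercept
#' `alpha = mean(y) - beta * mean(x)`, with `x` the test-lab and `y` the
#' reference-lab readings. An intercept whose confidence interval excludes 0
#' flags a fixed bias; a slope whose interval excludes 1 flags a proportional
#' bias.
#'
#' Analytic confidence limits follow Ludbrook's construction:
#' `B = t^2 (1 - r^2) / (n - 2)` with `t` the two-sided critical value on
#' `n - 2` df, slope limits `beta * (sqrt(B + 1) -/+ sqrt(B))`, and intercept
#' limits obtained by pairing each slope limit with the means. The bootstrap
#' alternative resamples sample pairs and takes percentile intervals.
#'
#' @param series A [calibration_series()].
#' @param confidence Two-sided confidence level in (0, 1); default 0.95.
#' @param ci_method `"analytic"` (default) or `"bootstrap"`.
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @param seed Integer seed for the bootstrap resampling.
#' @return An object of class `bias_estimate`: fields `lab_id`, `alpha`,
#'   `beta`, `alpha_ci`, `beta_ci`, `r`, `n`, `fixed_bias_significant`,
#'   `proportional_bias_significant`, `ci_method`.
#' @references Ludbrook J. Comparing methods of measurement. Clin Exp
#'   Pharmacol Physiol 1997;24:193-203.
#' @export
#' @examples
#' calib <- he4_calibration_curve()
#' fit_olp(calibration_series(calib$lab1, calib$lab2, lab_id = "lab2"))
fit_olp <- function(series, confidence = 0.95,
                    ci_method = c("analytic", "bootstrap"),
                    n_boot = 2000, seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(is.numeric(confidence), length(confidence) == 1,
            confidence > 0, confidence < 1)
  if (!inherits(series, "calibration_series")) {
    series <- do.call(calibration_series, as.list(series))
  }
  x <- series$test
  y <- series$reference
  n <- length(x)
  if (stats::var(x) == 0) {
    stop("'test' values have zero variance; cannot fit a slope", call. = FALSE)
  }
  if (stats::var(y) == 0) {
    stop("'reference' values have zero variance; cannot fit a slope",
         call. = FALSE)
  }
  est <- olp_point(x, y)
  if (est$r <= 0) {
    warning("reference and test readings are not positively correlated ",
            "(r = ", signif(est$r, 3), "); the series is likely corrupted",
            call. = FALSE)
  }

  if (ci_method == "analytic") {
    ci <- olp_analytic_ci(x, y, est, confidence)
  } else {
    ci <- olp_bootstrap_ci(x, y, confidence, n_boot, seed)
  }

  structure(
    list(lab_id = series$lab_id,
         alpha = est$alpha, beta = est$beta,
         alpha_ci = ci$alpha_ci, beta_ci = ci$beta_ci,
         r = est$r, n = n,
         fixed_bias_significant = ci$alpha_ci[1] > 0 || ci$alpha_ci[2] < 0,
         proportional_bias_significant = ci$beta_ci[1] > 1 || ci$beta_ci[2] < 1,
         confidence = confidence, ci_method = ci_method),
    class = "bias_estimate"
  )
}

# OLP point estimate: slope = sign(Sxy) * sqrt(Syy/Sxx), intercept from means
olp_point <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  syy <- sum((y - mean(y))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  beta <- sign(sxy) * sqrt(syy / sxx)
  if (sxy == 0) beta <- sqrt(syy / sxx)
  list(beta = beta, alpha = mean(y) - beta * mean(x),
       r = stats::cor(x, y))
}

olp_analytic_ci <- function(x, y, est, confidence) {
  n <- length(x)
  tq <- stats::qt(1 - (1 - confidence) / 2, df = n - 2)
  B <- tq^2 * (1 - est$r^2) / (n - 2)
  beta_lo <- est$beta * (sqrt(B + 1) - sqrt(B))
  beta_hi <- est$beta * (sqrt(B + 1) + sqrt(B))
  # each slope limit is paired with the centroid; the steeper slope gives the
  # lower intercept when mean(x) > 0
  a1 <- mean(y) - beta_hi * mean(x)
  a2 <- mean(y) - beta_lo * mean(x)
  list(beta_ci = c(beta_lo, beta_hi),
       alpha_ci = c(min(a1, a2), max(a1, a2)))
}

olp_bootstrap_ci <- function(x, y, confidence, n_boot, seed) {
  n <- length(x)
  coefs <- matrix(NA_real_, n_boot, 2)
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    xb <- x[idx]; yb <- y[idx]
    if (stats::var(xb) == 0 || stats::var(yb) == 0) next
    e <- olp_point(xb, yb)
    coefs[b, ] <- c(e$alpha, e$beta)
  }
  coefs <- coefs[stats::complete.cases(coefs), , drop = FALSE]
  probs <- c((1 - confidence) / 2, 1 - (1 - confidence) / 2)
  list(alpha_ci = unname(stats::quantile(coefs[, 1], probs)),
       beta_ci = unname(stats::quantile(coefs[, 2], probs)))
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf(
    "OLP bias estimate for %s (n = %d, r = %.4f, %s %g%% CI)\n",
    x$lab_id, x$n, x$r, x$ci_method, 100 * x$confidence))
  cat(sprintf("  fixed bias        alpha = %8.3f pmol/L  (%.3f, %.3f)%s\n",
              x$alpha, x$alpha_ci[1], x$alpha_ci[2],
              if (x$fixed_bias_significant) "  *" else ""))
  cat(sprintf("  proportional bias beta  = %8.4f         (%.4f, %.4f)%s\n",
              x$beta, x$beta_ci[1], x$beta_ci[2],
              if (x$proportional_bias_significant) "  *" else ""))
  invisible(x)
}

#' Fit OLP bias estimates for every test laboratory in a calibration table
#'
#' @param calib Wide calibration data.frame (`sample_id` plus one column per
#'   lab), e.g. from [he4_calibration_curve()] or [read_calibration()].
#' @param reference_lab Name of the reference-lab column (default `"lab1"`).
#' @param ... Passed to [fit_olp()] (confidence, ci_method, ...).
#' @return Named list of `bias_estimate` objects, one per test lab, with the
#'   reference-lab name attached as attribute `reference_lab`.
#' @export
fit_all_labs <- function(calib, reference_lab = "lab1", ...) {
  if (!reference_lab %in% names(calib)) {
    stop("reference lab '", reference_lab, "' not found in calibration table",
         call. = FALSE)
  }
  lab_cols <- setdiff(names(calib), c("sample_id", reference_lab))
  fits <- lapply(lab_cols, function(lab) {
    fit_olp(calibration_series(calib[[reference_lab]], calib[[lab]],
                               lab_id = lab,
                               sample_ids = calib$sample_id), ...)
  })
  names(fits) <- lab_cols
  attr(fits, "reference_lab") <- reference_lab
  fits
}

#' Classify each laboratory's systematic bias pattern
#'
#' Applies the confidence-interval containment rule to a set of bias
#' estimates: a lab has a fixed bias when its intercept CI excludes 0 and a
#' proportional bias when its slope CI excludes 1. The reference laboratory,
#' if listed, is always `"none"`.
#'
#' @param estimates A list of [fit_olp()] results (or a single one).
#' @param reference_lab Optional reference-lab id to report as `"none"`.
#' @return data.frame with columns `lab_id`, `alpha`, `beta`, CI bounds, and
#'   `bias` in `none`, `fixed`, `proportional`, `both`.
#' @export
classify_biases <- function(estimates, reference_lab = NULL) {
  if (inherits(estimates, "bias_estimate")) estimates <- list(estimates)
  if (length(estimates) == 0) {
    stop("'estimates' must contain at least one bias estimate", call. = FALSE)
  }
  if (is.null(reference_lab)) {
    reference_lab <- attr(estimates, "reference_lab")
  }
  rows <- lapply(estimates, function(e) {
    flag <- if (e$fixed_bias_significant && e$proportional_bias_significant) {
      "both"
    } else if (e$fixed_bias_significant) {
      "fixed"
    } else if (e$proportional_bias_significant) {
      "proportional"
    } else {
      "none"
    }
    if (!is.null(reference_lab) && identical(e$lab_id, reference_lab)) {
      flag <- "none"
    }
    data.frame(lab_id = e$lab_id, alpha = e$alpha, beta = e$beta,
               alpha_lo = e$alpha_ci[1], alpha_hi = e$alpha_ci[2],
               beta_lo = e$beta_ci[1], beta_hi = e$beta_ci[2],
               bias = flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Harmonize measurements onto the reference-laboratory scale
#'
#' Applies the fitted bias-correction equation `adjusted = alpha + beta * raw`
#' to a vector of raw concentrations. Under the default policy
#' `"biased_only"` the transform is applied only when the estimate flags a
#' significant fixed or proportional bias; `"always"` applies it
#' unconditionally and `"never"` returns the input unchanged. Values from the
#' reference laboratory itself should never be transformed (pass
#' `policy = "never"` or simply skip them).
#'
#' @param values Numeric vector of raw concentrations (pmol/L), finite and
#'   non-negative.
#' @param estimate A `bias_estimate` from [fit_olp()].
#' @param policy `"biased_only"` (default), `"always"`, or `"never"`.
#' @return Numeric vector of adjusted concentrations on the reference scale.
#'   Adjusted values below zero (possible for small inputs with a negative
#'   intercept) are clamped to 0 with a warning.
#' @export
#' @examples
#' est <- fit_olp(calibration_series(
#'   he4_calibration_curve()$lab1, he4_calibration_curve()$lab2, "lab2"))
#' harmonize(100, est)
harmonize <- function(values, estimate,
                      policy = c("biased_only", "always", "never")) {
  policy <- match.arg(policy)
  values <- as.numeric(values)
  if (length(values) && (!all(is.finite(values)) || any(values < 0))) {
    stop("'values' must be finite and non-negative", call. = FALSE)
  }
  apply_transform <- switch(
    policy,
    never = FALSE,
    always = TRUE,
    biased_only = isTRUE(estimate$fixed_bias_significant) ||
      isTRUE(estimate$proportional_bias_significant)
  )
  if (!apply_transform) return(values)
  adj <- estimate$alpha + estimate$beta * values
  neg <- adj < 0
  if (any(neg)) {
    warning(sum(neg), " adjusted value(s) below 0 clamped to 0", call. = FALSE)
    adj[neg] <- 0
  }
  adj
}

#' Write a per-laboratory bias report
#'
#' @param estimates List of bias estimates from [fit_all_labs()].
#' @param json_path,csv_path Optional output paths; either may be `NULL`.
#' @return The report data.frame, invisibly.
#' @export
write_bias_report <- function(estimates, json_path = NULL, csv_path = NULL) {
  report <- classify_biases(estimates)
  report$ci_method <- vapply(estimates, `[[`, "", "ci_method")
  if (!is.null(json_path)) {
    jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  if (!is.null(csv_path)) {
    utils::write.csv(report, csv_path, row.names = FALSE)
  }
  invisible(report)
}
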