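test_that("control model recovers level effects and rejects collinearity", {
  const <- data.frame(y = rep(50, 20), z = rnorm(20))
  fit <- fit_control_model(const, "y", "z")
  expect_equal(unname(fit$coefficients[1]), 50)
  expect_equal(unname(fit$coefficients[2]), 0, tolerance = 1e-10)
  expect_equal(length(fit$residuals), 20)
  expect_lt(abs(mean(fit$residuals)), 1e-8 * max(sd(fit$residuals), 1e-12))

  set.seed(41)
  d <- data.frame(menopause = rbinom(500, 1, 0.5))
  d$y <- 40 + 10 * d$menopause + rnorm(500, 0, 2)
  fit2 <- fit_control_model(d, "y", "menopause")
  expect_equal(unname(fit2$coefficients["menopause"]), 10, tolerance = 0.1)

  d$menopause2 <- d$menopause * (1 + 1e-12)
  expect_error(fit_control_model(d, "y", c("menopause", "menopause2")),
               "collinear")
  expect_error(fit_control_model(d[1:5, ], "y", "menopause"), "at least 10")
})

test_that("placement values are the fraction of controls above the case", {
  ctr <- data.frame(y = c(1, 2, 3, 4))
  ctr <- ctr[rep(1:4, 3), , drop = FALSE]  # 12 controls, same empirical law
  fit <- fit_control_model(ctr, "y")
  # prediction is the control mean (2.5); PV = share of controls > value
  expect_equal(placement_values(data.frame(y = 2.5), fit, "y"), 0.5)
  expect_equal(placement_values(data.frame(y = -10), fit, "y"), 1)
  expect_equal(placement_values(data.frame(y = 10), fit, "y"), 0)
})

test_that("probit ROC-GLM recovers binormal truth", {
  set.seed(11)
  controls <- data.frame(y = rnorm(2000))
  cases <- data.frame(y = rnorm(2000, 1.2, 1))
  cf <- fit_control_model(controls, "y")
  pv <- placement_values(cases, cf, "y")
  fit <- fit_roc_glm(pv, NULL, n_controls = cf$n_controls)
  expect_equal(fit$gamma0, 1.2, tolerance = 0.1 / 1.2)
  expect_equal(fit$gamma1, 1.0, tolerance = 0.1)
  expect_true(all(pv >= 0 & pv <= 1))
})

test_that("identically distributed cases and controls give a diagonal ROC", {
  set.seed(12)
  cf <- fit_control_model(data.frame(y = rnorm(2000)), "y")
  pv <- placement_values(data.frame(y = rnorm(2000)), cf, "y")
  fit <- fit_roc_glm(pv, NULL, n_controls = 2000)
  expect_lt(abs(fit$gamma0), 0.1)
})

test_that("a binary covariate shifting case separation is recovered", {
  set.seed(13)
  ctr <- data.frame(y = rnorm(2000), z = rbinom(2000, 1, 0.5))
  cs <- data.frame(z = rbinom(2000, 1, 0.5))
  cs$y <- rnorm(2000, 1.0 + 0.5 * cs$z, 1)
  cf <- fit_control_model(ctr, "y")
  pv <- placement_values(cs, cf, "y")
  fit <- fit_roc_glm(pv, cs[, "z", drop = FALSE], n_controls = 2000)
  expect_equal(unname(fit$covariate_betas["z"]), 0.5, tolerance = 0.12 / 0.5)
})

test_that("degenerate placement values and bad grids are rejected", {
  expect_error(fit_roc_glm(rep(0, 20), NULL), "perfectly separated")
  expect_error(fit_roc_glm(rep(1, 20), NULL), "perfectly separated")
  expect_error(fit_roc_glm(runif(20), NULL, fpr_grid = c(0, 0.5)),
               "fpr_grid")
  expect_error(fit_roc_glm(runif(20), NULL, fpr_grid = c(0.5, 0.2)),
               "fpr_grid")
})

test_that("fitted ROC is nondecreasing and its closed-form AUC matches quadrature", {
  set.seed(14)
  cf <- fit_control_model(data.frame(y = rnorm(400)), "y")
  pv <- placement_values(data.frame(y = rnorm(300, 0.8)), cf, "y")
  fit <- fit_roc_glm(pv, NULL, n_controls = 400)
  curve <- predict_roc(fit)
  expect_true(all(diff(curve$tpr) >= 0))
  auc_closed <- covariate_adjusted_auc(fit)
  auc_quad <- integrate(function(u) {
    pnorm(fit$gamma0 + fit$gamma1 * qnorm(u))
  }, 0, 1, rel.tol = 1e-10)$value
  expect_equal(auc_closed, auc_quad, tolerance = 1e-4)
})

test_that("closed-form binormal AUC evaluates the standard-normal CDF", {
  null_fit <- structure(list(gamma0 = 0, gamma1 = 1,
                             covariate_betas = numeric(0)),
                        class = "roc_glm_fit")
  expect_equal(covariate_adjusted_auc(null_fit), 0.5)
  bin <- structure(list(gamma0 = 1.2, gamma1 = 1,
                        covariate_betas = numeric(0)),
                   class = "roc_glm_fit")
  expect_equal(covariate_adjusted_auc(bin), pnorm(1.2 / sqrt(2)))
  neg <- structure(list(gamma0 = 1, gamma1 = -0.2,
                        covariate_betas = numeric(0)),
                   class = "roc_glm_fit")
  expect_error(covariate_adjusted_auc(neg), "gamma1 > 0")
})

test_that("two-stage AUC agrees with the Mann-Whitney AUC without covariates", {
  set.seed(15)
  controls <- data.frame(y = rlnorm(1500, 3.8, 0.4))
  cases <- data.frame(y = rlnorm(1500, 4.3, 0.5))
  cf <- fit_control_model(controls, "y")
  pv <- placement_values(cases, cf, "y")
  fit <- fit_roc_glm(pv, NULL, n_controls = 1500)
  emp <- empirical_roc(c(cases$y, controls$y),
                       rep(c("case", "control"), each = 1500))$auc
  expect_equal(covariate_adjusted_auc(fit), emp, tolerance = 0.02 / emp)
})

test_that("cluster bootstrap is deterministic, brackets estimates, and needs 2+ clusters", {
  set.seed(16)
  n <- 400
  d <- data.frame(y = rnorm(n), z = rbinom(n, 1, 0.5),
                  hospital = sample(paste0("h", 1:6), n, replace = TRUE),
                  is_case = rep(c(TRUE, FALSE), each = n / 2))
  d$y[d$is_case] <- d$y[d$is_case] + 1

  fit1 <- roc_regression(d, "y", d$is_case, control_covariates = "z",
                         cluster = "hospital", n_boot = 50, seed = 5)
  fit2 <- roc_regression(d, "y", d$is_case, control_covariates = "z",
                         cluster = "hospital", n_boot = 50, seed = 5)
  expect_identical(fit1$bootstrap_cis, fit2$bootstrap_cis)
  expect_equal(nrow(fit1$bootstrap_replicates), 50)
  expect_equal(fit1$n_bootstrap, 50)

  cis <- fit1$bootstrap_cis
  point <- fit1$coefficients[cis$coefficient]
  expect_true(all(cis$lower <= point & point <= cis$upper))

  d1 <- transform(d, hospital = "h1")
  expect_error(
    cluster_bootstrap(function(x) c(m = mean(x$y)), d1, "hospital"),
    "at least 2 clusters")
  expect_error(
    cluster_bootstrap(function(x) c(m = mean(x$y)), d, "hospital",
                      n_reps = 1), "n_reps")
})

test_that("replicates where the refit fails are discarded, with a cap", {
  set.seed(17)
  d <- data.frame(y = rnorm(60),
                  hospital = rep(c("a", "b", "c"), each = 20))
  flaky <- function(x) {
    if (all(x$hospital == "a")) stop("degenerate resample")
    c(m = mean(x$y))
  }
  res <- suppressMessages(
    cluster_bootstrap(flaky, d, "hospital", n_reps = 50, seed = 2,
                      ci_type = "percentile"))
  expect_gt(res$n_discarded, 0)
  expect_equal(res$n_used + res$n_discarded, 50)
  always_fail <- function(x) stop("nope")
  expect_error(suppressMessages(
    cluster_bootstrap(always_fail, d, "hospital", n_reps = 10, seed = 2)),
    "20%")
})

test_that("larger case-control separation in one stratum yields a positive ROC coefficient", {
  set.seed(18)
  n <- 1200
  meno <- rbinom(n, 1, 0.5)
  is_case <- rep(c(TRUE, FALSE), each = n / 2)
  y <- rnorm(n)
  y[is_case] <- y[is_case] + 0.8 + 0.6 * meno[is_case]
  d <- data.frame(y = y, meno = meno)
  fit <- roc_regression(d, "y", is_case, control_covariates = "meno")
  expect_gt(unname(fit$roc_fit$covariate_betas["meno"]), 0)
})
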