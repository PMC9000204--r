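test_that("identity and exact linear transforms are recovered without noise", {
  ref <- c(30, 60, 120, 240, 480, 960)

  ident <- fit_olp(calibration_series(ref, ref, "same"))
  expect_equal(ident$alpha, 0, tolerance = 1e-12)
  expect_equal(ident$beta, 1, tolerance = 1e-12)
  expect_false(ident$fixed_bias_significant)
  expect_false(ident$proportional_bias_significant)

  halved <- fit_olp(calibration_series(ref, ref / 2, "half"))
  expect_equal(halved$beta, 2, tolerance = 1e-12)
  expect_equal(halved$alpha, 0, tolerance = 1e-9)
})

test_that("bias coefficients on the bundled curve match the reference values", {
  calib <- he4_calibration_curve()
  est <- fit_olp(calibration_series(calib$lab1, calib$lab3, "lab3"))
  expect_equal(est$alpha, 21.2, tolerance = 1.5 / 21.2)
  expect_equal(est$beta, 1.15, tolerance = 0.02 / 1.15)
  expect_true(est$fixed_bias_significant)
  expect_true(est$proportional_bias_significant)
})

test_that("OLP fit equals the dense grid-search minimizer of the product objective", {
  for (s in 1:3) {
    set.seed(100 + s)
    x <- sort(runif(10, 20, 900))
    y <- 15 + 1.2 * x + rnorm(10, 0, 25)
    est <- fit_olp(calibration_series(y, x, "sim"))
    oracle <- olp_grid_oracle(x, y)
    expect_equal(est$alpha, unname(oracle["a"]), tolerance = 1e-3)
    expect_equal(est$beta, unname(oracle["b"]), tolerance = 1e-3)
  }
})

test_that("OLP is symmetric under swapping the axes", {
  x <- c(25, 50, 110, 230, 470, 950)
  y <- 10 + 1.15 * x
  fwd <- fit_olp(calibration_series(y, x, "fwd"))
  rev <- fit_olp(calibration_series(x, y, "rev"))
  expect_equal(rev$beta, 1 / fwd$beta, tolerance = 1e-9)
  expect_equal(rev$alpha, -fwd$alpha / fwd$beta, tolerance = 1e-9)
})

test_that("OLP slope is the geometric mean of the two OLS slopes", {
  for (s in 1:5) {
    set.seed(200 + s)
    x <- runif(12, 10, 500)
    y <- 5 + 0.9 * x + rnorm(12, 0, 20)
    est <- fit_olp(calibration_series(y, x, "gm"))
    b_yx <- cov(x, y) / var(x)
    b_xy_inv <- var(y) / cov(x, y)
    expect_equal(est$beta, sqrt(b_yx * b_xy_inv), tolerance = 1e-10)
  }
})

test_that("degenerate series are rejected with informative errors", {
  expect_error(calibration_series(c(1, 2), c(1, 2), "short"), "at least 3")
  expect_error(calibration_series(c(1, 2, -3), c(1, 2, 3), "neg"),
               "reference")
  expect_error(calibration_series(c(1, 2, 3), c(1, 2, Inf), "inf"), "test")
  expect_error(fit_olp(calibration_series(c(1, 2, 3), c(2, 2, 2) + 1e-30,
                                          "flat")), "variance")
  expect_warning(fit_olp(calibration_series(c(10, 20, 30, 40),
                                            c(40, 30, 20, 10), "anti")),
                 "not positively correlated")
})

test_that("confidence intervals bracket the estimates and drive the flags", {
  calib <- he4_calibration_curve()
  for (lab in paste0("lab", 2:6)) {
    for (method in c("analytic", "bootstrap")) {
      est <- fit_olp(calibration_series(calib$lab1, calib[[lab]], lab),
                     ci_method = method, n_boot = 400, seed = 3)
      expect_true(est$alpha_ci[1] <= est$alpha && est$alpha <= est$alpha_ci[2])
      expect_true(est$beta_ci[1] <= est$beta && est$beta <= est$beta_ci[2])
      expect_identical(est$fixed_bias_significant,
                       est$alpha_ci[1] > 0 || est$alpha_ci[2] < 0)
      expect_identical(est$proportional_bias_significant,
                       est$beta_ci[1] > 1 || est$beta_ci[2] < 1)
    }
  }
  s <- calibration_series(calib$lab1, calib$lab2, "lab2")
  b1 <- fit_olp(s, ci_method = "bootstrap", n_boot = 300, seed = 9)
  b2 <- fit_olp(s, ci_method = "bootstrap", n_boot = 300, seed = 9)
  expect_identical(b1$beta_ci, b2$beta_ci)
})

test_that("bias classification follows the CI containment rule", {
  fake <- function(lab, aci, bci) {
    structure(list(lab_id = lab, alpha = mean(aci), beta = mean(bci),
                   alpha_ci = aci, beta_ci = bci, r = 0.99, n = 10,
                   fixed_bias_significant = aci[1] > 0 || aci[2] < 0,
                   proportional_bias_significant = bci[1] > 1 || bci[2] < 1,
                   ci_method = "analytic"),
              class = "bias_estimate")
  }
  report <- classify_biases(list(
    fake("fixed_only", c(9.05, 57.6), c(0.96, 1.08)),
    fake("prop_only", c(-7.64, 11.4), c(1.05, 1.10)),
    fake("clean", c(-1, 1), c(0.9, 1.1)),
    fake("both", c(2.3, 25.6), c(1.07, 1.13))
  ))
  expect_equal(report$bias,
               c("fixed", "proportional", "none", "both"))
  expect_error(classify_biases(list()), "at least one")
})

test_that("harmonization applies the regression equation per policy", {
  est <- structure(list(lab_id = "lab2", alpha = 13.9, beta = 1.09,
                        alpha_ci = c(2.3, 25.6), beta_ci = c(1.07, 1.13),
                        r = 0.999, n = 10,
                        fixed_bias_significant = TRUE,
                        proportional_bias_significant = TRUE,
                        ci_method = "analytic"),
                   class = "bias_estimate")
  expect_equal(harmonize(100, est), 122.9)
  expect_equal(harmonize(c(50, 100), est, policy = "never"), c(50, 100))

  unbiased <- est
  unbiased$fixed_bias_significant <- FALSE
  unbiased$proportional_bias_significant <- FALSE
  expect_equal(harmonize(100, unbiased), 100)
  expect_equal(harmonize(100, unbiased, policy = "always"), 122.9)

  neg <- est
  neg$alpha <- -50
  expect_warning(out <- harmonize(10, neg, policy = "always"), "clamped")
  expect_equal(out, 0)
  expect_error(harmonize(c(-1, 5), est), "non-negative")
})

test_that("injected lab bias is recovered from a simulated calibration experiment", {
  cfg <- calibration_sim_config(
    labs = data.frame(lab_id = "labX", alpha = 20, beta = 1.10, cv = 0.02),
    seed = 42)
  calib <- generate_calibration_experiment(cfg)
  est <- fit_olp(calibration_series(cfg$true_values, calib$labX, "labX"))
  expect_equal(est$alpha, 20, tolerance = 5 / 20)
  expect_equal(est$beta, 1.10, tolerance = 0.03 / 1.10)
})

test_that("analytic CIs cover injected parameters at the nominal rate", {
  # multiplicative assay noise; pairs-bootstrap intervals are the ones with
  # nominal behavior here (the analytic interval assumes homoscedastic
  # errors and runs short on a leverage-dominated dilution design)
  n_rep <- 250
  cover_a <- cover_b <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    cfg <- calibration_sim_config(
      labs = data.frame(lab_id = "labX", alpha = 20, beta = 1.10, cv = 0.032),
      seed = 3000 + i)
    calib <- generate_calibration_experiment(cfg)
    est <- fit_olp(calibration_series(cfg$true_values, calib$labX, "labX"),
                   ci_method = "bootstrap", n_boot = 1000, seed = i)
    cover_a[i] <- est$alpha_ci[1] <= 20 && 20 <= est$alpha_ci[2]
    cover_b[i] <- est$beta_ci[1] <= 1.10 && 1.10 <= est$beta_ci[2]
  }
  expect_gte(mean(cover_a), 0.88 - 1e-9)
  expect_gte(mean(cover_b), 0.88 - 1e-9)
})

test_that("calibration CSV readers handle wide and long layouts", {
  wide <- he4_calibration_curve()
  path_w <- withr::local_tempfile(fileext = ".csv")
  write.csv(wide, path_w, row.names = FALSE)
  expect_equal(read_calibration(path_w), wide)

  long <- do.call(rbind, lapply(c("lab1", "lab2"), function(lab) {
    do.call(rbind, lapply(seq_len(nrow(wide)), function(i) {
      data.frame(sample_id = wide$sample_id[i], lab_id = lab,
                 replicate = 1:2,
                 value = wide[[lab]][i] + c(-1, 1),
                 stringsAsFactors = FALSE)
    }))
  }))
  path_l <- withr::local_tempfile(fileext = ".csv")
  write.csv(long, path_l, row.names = FALSE)
  back <- read_calibration(path_l)
  expect_equal(back$lab1, wide$lab1)  # replicate means recover the value
  expect_equal(back$lab2, wide$lab2)
  expect_equal(back$sample_id, wide$sample_id)
})

test_that("replicate readings are averaged into the series", {
  reps <- list(c(100, 102), c(50, 54), c(25, 27))
  s <- calibration_series(c(110, 55, 28), replicates = reps, lab_id = "dup")
  expect_equal(s$test, c(101, 52, 26))
  expect_error(
    calibration_series(c(110, 55, 28), test = c(1, 2, 3), replicates = reps),
    "mean of 'replicates'")
})
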