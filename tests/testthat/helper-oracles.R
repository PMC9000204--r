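# Independent oracles used across the suite. Each is a brute-force or
# closed-form alternative to the implementation under test and must stay
# free of package internals.

# OLP objective: sum of products of vertical and horizontal deviations.
# |y - a - b x| * |x - (y - a)/b| = (y - a - b x)^2 / |b|
olp_objective <- function(a, b, x, y) {
  sum((y - a - b * x)^2) / abs(b)
}

# Dense two-stage grid search minimizing the OLP objective. Centered on the
# OLS fit, refined three times.
olp_grid_oracle <- function(x, y) {
  ols <- stats::coef(stats::lm(y ~ x))
  a0 <- ols[[1]]; b0 <- ols[[2]]
  a_span <- max(abs(a0), 1) * 2
  b_span <- max(abs(b0), 0.5)
  best <- c(a = a0, b = b0)
  # gentle shrink: the objective has a long diagonal (a, b) ridge, so each
  # refinement must keep a wide margin around the current best
  for (stage in 1:8) {
    a_grid <- seq(best["a"] - a_span, best["a"] + a_span, length.out = 81)
    b_grid <- seq(best["b"] - b_span, best["b"] + b_span, length.out = 81)
    b_grid <- b_grid[b_grid != 0]
    vals <- outer(a_grid, b_grid,
                  Vectorize(function(a, b) olp_objective(a, b, x, y)))
    idx <- arrayInd(which.min(vals), dim(vals))
    best <- c(a = a_grid[idx[1]], b = b_grid[idx[2]])
    a_span <- a_span / 3
    b_span <- b_span / 3
  }
  best
}

# Exhaustive Youden search: every observed score as a strict ">" threshold,
# smallest maximizer wins.
youden_oracle <- function(scores, is_case) {
  thr <- sort(unique(scores))
  j <- vapply(thr, function(t) {
    mean(scores[is_case] > t) + mean(scores[!is_case] <= t) - 1
  }, numeric(1))
  list(threshold = thr[which.max(j)], j = max(j))
}

# Leave-one-subject-out jackknife variance of the difference of two
# empirical AUCs measured on the same subjects.
jackknife_auc_diff_var <- function(scores_a, scores_b, is_case) {
  auc <- function(s, d) {
    r <- rank(s)
    m <- sum(d)
    (sum(r[d]) - m * (m + 1) / 2) / (m * sum(!d))
  }
  n <- length(is_case)
  d_i <- vapply(seq_len(n), function(i) {
    auc(scores_a[-i], is_case[-i]) - auc(scores_b[-i], is_case[-i])
  }, numeric(1))
  (n - 1) / n * sum((d_i - mean(d_i))^2)
}

# Small deterministic cohort for pipeline edge-case tests.
tiny_cohort <- function() {
  data.frame(
    subject_id = sprintf("T%02d", 1:8),
    group = c("malignant", "malignant", "benign", "benign", "benign",
              "healthy", "healthy", "healthy"),
    subtype = c("ovarian_cancer", "ovarian_cancer", "endometriosis",
                "fibroma", "ovarian_lesion", "", "", ""),
    age = c(62, 45, 38, 52, 61, 30, 48, 66),
    menopausal = c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, FALSE, TRUE),
    creatinine = c(0.8, 0.7, 0.6, 0.9, 0.8, 0.7, 0.75, 0.85),
    he4_raw = c(400, 150, 60, 55, 70, 40, 45, 50),
    ca125 = c(500, 80, 40, 20, 60, 12, 15, 18),
    hospital = rep(c("lab1", "lab2"), 4),
    stringsAsFactors = FALSE
  )
}
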