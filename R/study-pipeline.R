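# End-to-end study orchestration: eligibility filtering, menopause/age
# stratification, the two case/control contrasts, the sensitivity analysis,
# the sample-size calculation, and the full report.

#' Apply the cohort eligibility rules
#'
#' Excludes, in order (each record is logged under the first rule it
#' trips): missing age; age outside 18-70; creatinine <= 0.3 or > 3 mg/dL;
#' premenopausal status with age > 55 (physiologically inconsistent);
#' missing or unrecognized diagnosis group.
#'
#' @param records Cohort data.frame (see [read_cohort_csv()] for the
#'   schema).
#' @return List: `eligible` (data.frame) and `log`, a data.frame of
#'   per-reason exclusion counts plus the eligible and input totals.
#' @export
apply_eligibility <- function(records) {
  records <- as.data.frame(records)
  group_ok <- !is.na(records$group) &
    records$group %in% c("malignant", "benign", "healthy")
  reason <- rep(NA_character_, nrow(records))
  rule <- function(cond, label) {
    hit <- is.na(reason) & cond
    reason[hit] <<- label
  }
  rule(is.na(records$age), "missing_age")
  rule(records$age < 18 | records$age > 70, "age_out_of_range")
  rule(is.na(records$creatinine) | records$creatinine <= 0.3 |
         records$creatinine > 3, "creatinine_out_of_range")
  rule(!is.na(records$menopausal) & !records$menopausal &
         records$age > 55, "premenopausal_over_55")
  rule(!group_ok, "ambiguous_group")

  eligible <- records[is.na(reason), , drop = FALSE]
  rownames(eligible) <- NULL
  reasons <- c("missing_age", "age_out_of_range", "creatinine_out_of_range",
               "premenopausal_over_55", "ambiguous_group")
  log <- data.frame(
    reason = c(reasons, "eligible", "input"),
    n = c(vapply(reasons, function(r) sum(reason == r, na.rm = TRUE),
                 integer(1)),
          nrow(eligible), nrow(records)),
    stringsAsFactors = FALSE
  )
  rownames(log) <- NULL
  list(eligible = eligible, log = log)
}

#' Stratify the cohort by menopausal status and age
#'
#' Pre-menopausal women are split at 40 years and post-menopausal women at
#' 60 years, boundaries inclusive on the lower side, giving four disjoint
#' strata covering every eligible record.
#'
#' @param records Eligible cohort data.frame.
#' @return Named list of four data.frames: `pre_le40`, `pre_gt40`,
#'   `post_le60`, `post_gt60`.
#' @export
stratify <- function(records) {
  records <- as.data.frame(records)
  pre <- !records$menopausal
  list(
    pre_le40 = records[pre & records$age <= 40, , drop = FALSE],
    pre_gt40 = records[pre & records$age > 40, , drop = FALSE],
    post_le60 = records[!pre & records$age <= 60, , drop = FALSE],
    post_gt60 = records[!pre & records$age > 60, , drop = FALSE]
  )
}

#' Run one case/control contrast within a stratum
#'
#' Cases are the malignant subjects; controls are either everyone else
#' (`"malignant_vs_rest"`) or the benign group alone
#' (`"malignant_vs_benign"`, healthy women dropped). Derives the stratum's
#' HE4 cut-off by Youden maximization, dichotomizes HE4 at it and Ca125 at
#' the conventional 35 IU/mL, and compares the two dichotomous markers'
#' AUCs with the paired DeLong test.
#'
#' @param stratum data.frame of one stratum's records.
#' @param contrast `"malignant_vs_rest"` or `"malignant_vs_benign"`.
#' @param he4_col,ca125_col Marker column names.
#' @param ca125_cutoff Conventional Ca125 cut-off (default 35 IU/mL).
#' @param rounding Cut-off rounding rule passed to [youden_cutoff()].
#' @return List with `contrast`, `n_cases`, `n_controls`, `cutoff` (a
#'   [youden_cutoff()] result for HE4), `auc_he4`, `auc_ca125` and
#'   `comparison` (an [auc_equality_test()] result), or `NULL` with a
#'   message when a class is absent.
#' @export
run_contrast <- function(stratum,
                         contrast = c("malignant_vs_rest",
                                      "malignant_vs_benign"),
                         he4_col = "he4_adj", ca125_col = "ca125",
                         ca125_cutoff = 35,
                         rounding = c("integer", "none")) {
  contrast <- match.arg(contrast)
  rounding <- match.arg(rounding)
  stratum <- as.data.frame(stratum)
  if (contrast == "malignant_vs_benign") {
    stratum <- stratum[stratum$group != "healthy", , drop = FALSE]
  }
  is_case <- stratum$group == "malignant"
  if (!any(is_case) || all(is_case)) {
    message("contrast ", contrast, " skipped: a class is absent (",
            sum(is_case), " cases, ", sum(!is_case), " controls)")
    return(NULL)
  }
  labels <- ifelse(is_case, "case", "control")
  cut <- youden_cutoff(stratum[[he4_col]], labels, rounding = rounding)
  he4_bin <- dichotomize(stratum[[he4_col]], cut$cutoff)
  ca125_bin <- dichotomize(stratum[[ca125_col]], ca125_cutoff)
  cmp <- auc_equality_test(he4_bin, ca125_bin, labels)
  list(contrast = contrast, n_cases = sum(is_case),
       n_controls = sum(!is_case), cutoff = cut,
       auc_he4 = cmp$auc_a, auc_ca125 = cmp$auc_b, comparison = cmp)
}

#' Restrict benign diagnoses for the sensitivity analysis
#'
#' Keeps, among benign subjects, only ovarian, annexal and peritoneal
#' lesions and endometriosis; malignant and healthy records pass through
#' unchanged. Benign records with a missing subtype are dropped with a
#' warning.
#'
#' @param records Cohort data.frame with a `subtype` column on benign rows.
#' @param keep Subtype labels retained in the benign group.
#' @return Filtered data.frame.
#' @export
sensitivity_subset <- function(records,
                               keep = c("ovarian_lesion", "annexal_lesion",
                                        "peritoneal_lesion",
                                        "endometriosis")) {
  records <- as.data.frame(records)
  benign <- records$group == "benign"
  missing_sub <- benign & (is.na(records$subtype) | records$subtype == "")
  if (any(missing_sub)) {
    warning(sum(missing_sub),
            " benign record(s) without subtype dropped from the ",
            "sensitivity subset", call. = FALSE)
  }
  drop <- benign & (missing_sub | !(records$subtype %in% keep))
  out <- records[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Sample size for estimating a diagnostic sensitivity
#'
#' Number of subjects needed so that a two-sided confidence interval for
#' the test's sensitivity has at most the given half-width:
#' `n_cases = ceiling(z^2 * Se * (1 - Se) / d^2)` with `z` the two-sided
#' normal quantile, then `total = ceiling(n_cases / prevalence)` to account
#' for the disease prevalence among those enrolled.
#'
#' @param prevalence Expected prevalence of disease among enrolled
#'   subjects, in (0, 1].
#' @param sensitivity Anticipated sensitivity of the test, in (0, 1).
#' @param confidence Confidence level (default 0.95).
#' @param ci_halfwidth Maximum CI half-width (default 0.05).
#' @return Required total number of subjects (integer).
#' @export
#' @examples
#' sample_size(0.20, 0.85) # 980
sample_size <- function(prevalence, sensitivity, confidence = 0.95,
                        ci_halfwidth = 0.05) {
  stopifnot(prevalence > 0, prevalence <= 1,
            sensitivity > 0, sensitivity < 1,
            confidence > 0, confidence < 1,
            ci_halfwidth > 0, ci_halfwidth < 1)
  z <- stats::qnorm(1 - (1 - confidence) / 2)
  n_cases <- ceiling(z^2 * sensitivity * (1 - sensitivity) / ci_halfwidth^2)
  as.integer(ceiling(n_cases / prevalence))
}

#' Study configuration
#'
#' Collects every knob of [run_study()]. `calibration` and `cohort` may be
#' data.frames, CSV paths, or `NULL` to simulate them with the bundled
#' generators (seeded deterministically from `seed`).
#'
#' @param calibration Wide calibration table, CSV path, or `NULL`.
#' @param cohort Cohort data.frame, CSV path, or `NULL`.
#' @param reference_lab Reference laboratory column/id.
#' @param policy Harmonization policy (see [harmonize()]).
#' @param confidence Confidence level for bias CIs.
#' @param ci_method `"analytic"` or `"bootstrap"` OLP intervals.
#' @param fpr_grid_size Interior grid points for the ROC-GLM.
#' @param n_boot Cluster-bootstrap replicates (default 50).
#' @param rounding Cut-off rounding rule.
#' @param ca125_cutoff Conventional Ca125 cut-off (IU/mL).
#' @param control_covariates Stage-1/2 covariates (age is deliberately
#'   absent by default: it is nearly collinear with menopausal status).
#' @param seed Master integer seed.
#' @return List of class `study_config`.
#' @export
study_config <- function(calibration = NULL, cohort = NULL,
                         reference_lab = "lab1",
                         policy = "biased_only",
                         confidence = 0.95, ci_method = "analytic",
                         fpr_grid_size = 30, n_boot = 50,
                         rounding = "integer", ca125_cutoff = 35,
                         control_covariates = c("creatinine", "menopausal"),
                         seed = 1L) {
  structure(
    list(calibration = calibration, cohort = cohort,
         reference_lab = reference_lab, policy = policy,
         confidence = confidence, ci_method = ci_method,
         fpr_grid_size = fpr_grid_size, n_boot = n_boot,
         rounding = rounding, ca125_cutoff = ca125_cutoff,
         control_covariates = control_covariates,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

#' Load a study configuration from JSON or YAML
#'
#' @param path A `.json`, `.yaml` or `.yml` file whose keys match
#'   [study_config()] arguments.
#' @return A `study_config`.
#' @export
study_config_from_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext == "json") {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("the 'yaml' package is required for YAML configs", call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    stop("unsupported config format: .", ext, call. = FALSE)
  }
  do.call(study_config, raw[intersect(names(raw),
                                      names(formals(study_config)))])
}

load_table <- function(x, reader, generator) {
  if (is.null(x)) return(generator())
  if (is.character(x) && length(x) == 1) return(reader(x))
  as.data.frame(x)
}

#' Run the complete harmonization-and-accuracy study
#'
#' Executes the full pipeline: OLP bias estimation on the calibration
#' experiment, harmonization of each hospital's raw HE4 onto the reference
#' scale, eligibility filtering, the two-stage covariate-adjusted ROC
#' regression with hospital-cluster bootstrap on the whole eligible cohort,
#' the four menopause/age strata with both case/control contrasts
#' (dichotomous HE4 vs dichotomous Ca125, paired AUC test), and the same
#' contrasts on the restricted-benign sensitivity subset. Fully
#' deterministic for a fixed config seed.
#'
#' @param config A [study_config()].
#' @return Object of class `study_report`: `bias_report`, `eligibility`
#'   (log), `roc_regression`, `comparisons` and `sensitivity_comparisons`
#'   (data.frames, one row per stratum x contrast), `cutoffs`, `cohort`
#'   (the harmonized eligible records), `skipped` (log of strata/contrasts
#'   without both classes), `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  seed <- config$seed

  calib <- load_table(config$calibration, read_calibration, function() {
    generate_calibration_experiment(calibration_sim_config(seed = seed))
  })
  cohort <- load_table(config$cohort, read_cohort_csv, function() {
    generate_cohort(cohort_sim_config(seed = seed + 1L))
  })

  fits <- fit_all_labs(calib, reference_lab = config$reference_lab,
                       confidence = config$confidence,
                       ci_method = config$ci_method)
  bias_report <- classify_biases(fits, reference_lab = config$reference_lab)

  cohort$he4_adj <- cohort$he4_raw
  for (lab in names(fits)) {
    in_lab <- !is.na(cohort$hospital) & cohort$hospital == lab
    if (any(in_lab)) {
      cohort$he4_adj[in_lab] <- harmonize(cohort$he4_raw[in_lab], fits[[lab]],
                                          policy = config$policy)
    }
  }

  elig <- apply_eligibility(cohort)
  eligible <- elig$eligible

  roc_fit <- roc_regression(
    eligible, marker = "he4_adj",
    is_case = eligible$group == "malignant",
    control_covariates = config$control_covariates,
    cluster = "hospital", n_boot = config$n_boot, seed = seed + 2L,
    fpr_grid = default_fpr_grid(config$fpr_grid_size)
  )

  run_all <- function(records) {
    strata <- stratify(records)
    rows <- list(); cuts <- list(); skipped <- character()
    for (s in names(strata)) {
      for (ct in c("malignant_vs_rest", "malignant_vs_benign")) {
        res <- suppressMessages(run_contrast(
          strata[[s]], ct, he4_col = "he4_adj",
          ca125_cutoff = config$ca125_cutoff, rounding = config$rounding))
        if (is.null(res)) {
          skipped <- c(skipped, paste(s, ct, sep = ":"))
          next
        }
        rows[[paste(s, ct)]] <- data.frame(
          stratum = s, contrast = ct,
          n_cases = res$n_cases, n_controls = res$n_controls,
          he4_cutoff = res$cutoff$cutoff,
          auc_he4 = res$auc_he4, auc_ca125 = res$auc_ca125,
          auc_difference = res$comparison$difference,
          p_value = res$comparison$p_value,
          stringsAsFactors = FALSE)
        cuts[[paste(s, ct)]] <- res$cutoff
      }
    }
    cmp <- do.call(rbind, rows)
    if (!is.null(cmp)) rownames(cmp) <- NULL
    list(comparisons = cmp, cutoffs = cuts, skipped = skipped)
  }
  main <- run_all(eligible)
  sens <- run_all(suppressWarnings(sensitivity_subset(eligible)))

  structure(
    list(bias_report = bias_report, bias_fits = fits,
         eligibility = elig$log,
         roc_regression = roc_fit,
         comparisons = main$comparisons,
         cutoffs = main$cutoffs,
         sensitivity_comparisons = sens$comparisons,
         skipped = c(main$skipped, sens$skipped),
         cohort = eligible,
         config = config),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("Study report\n============\n")
  cat("Laboratory bias classification:\n")
  print(x$bias_report[, c("lab_id", "alpha", "beta", "bias")], digits = 4)
  cat("\nEligibility:\n")
  print(x$eligibility)
  cat("\nROC regression (full cohort):\n")
  print(x$roc_regression)
  cat("\nStratified dichotomous HE4 vs Ca125 comparisons:\n")
  print(x$comparisons, digits = 3)
  cat("\nSensitivity-analysis comparisons (restricted benign group):\n")
  print(x$sensitivity_comparisons, digits = 3)
  invisible(x)
}

#' Write a study report to disk
#'
#' Emits `report.json` (bias report, eligibility log, ROC-regression
#' coefficients and CIs, all comparisons) plus `bias_report.csv`,
#' `comparisons.csv` and `sensitivity_comparisons.csv`.
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rr <- report$roc_regression
  payload <- list(
    bias_report = report$bias_report,
    eligibility = report$eligibility,
    roc_regression = list(
      control_coefficients = as.list(rr$control_fit$coefficients),
      n_controls = rr$control_fit$n_controls,
      gamma0 = rr$roc_fit$gamma0, gamma1 = rr$roc_fit$gamma1,
      covariate_betas = as.list(rr$roc_fit$covariate_betas),
      n_cases = rr$roc_fit$n_cases,
      bootstrap_cis = rr$bootstrap_cis,
      n_bootstrap = rr$n_bootstrap),
    comparisons = report$comparisons,
    sensitivity_comparisons = report$sensitivity_comparisons,
    skipped = report$skipped
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(report$bias_report, file.path(dir, "bias_report.csv"),
                   row.names = FALSE)
  utils::write.csv(report$comparisons, file.path(dir, "comparisons.csv"),
                   row.names = FALSE)
  utils::write.csv(report$sensitivity_comparisons,
                   file.path(dir, "sensitivity_comparisons.csv"),
                   row.names = FALSE)
  invisible(dir)
}
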