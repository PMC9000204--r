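# Synthetic calibration experiments and patient cohorts.
#
# The generators emulate the structure the analysis assumes: a shared
# dilution series read by several laboratories whose platforms carry fixed
# and proportional biases plus multiplicative assay noise, and a three-group
# cohort (malignant / benign gynecological disease / healthy) with
# right-skewed marker distributions, age-coupled menopausal status, and
# hospital-specific raw HE4 readings produced by inverting the
# harmonization map - so the estimated correction is, by construction, the
# transform that recovers the latent truth.

#' Default laboratory bias and noise parameters
#'
#' Six laboratories mirroring a multicentre HE4 setting: lab1 is the
#' unbiased reference; the others carry the fixed/proportional biases
#' estimated from the shared calibration curve bundled with the package.
#' Assay coefficients of variation follow the manufacturers' declared
#' totals for each platform family (CLEIA 3.2%, ECLIA 10%, CMIA 10% and
#' 4.9%).
#'
#' @return data.frame with columns `lab_id`, `alpha`, `beta`, `cv`.
#' @export
default_lab_biases <- function() {
  data.frame(
    lab_id = paste0("lab", 1:6),
    alpha = c(0, 13.9, 21.2, 1.88, 33.3, 13.88),
    beta = c(1, 1.09, 1.15, 1.08, 1.02, 1.04),
    cv = c(0.032, 0.10, 0.10, 0.049, 0.032, 0.032),
    stringsAsFactors = FALSE
  )
}

#' Configuration for a simulated calibration experiment
#'
#' @param true_values True concentrations of the dilution series (pmol/L);
#'   default: the bundled reference-lab curve.
#' @param labs data.frame with columns `lab_id`, `alpha`, `beta`, `cv`
#'   (fixed bias pmol/L, proportional bias, assay coefficient of variation).
#' @param duplicates Replicate readings per sample (default 2, averaged).
#' @param seed Integer seed.
#' @return List of class `calibration_sim_config`.
#' @export
calibration_sim_config <- function(true_values = he4_calibration_curve()$lab1,
                                   labs = default_lab_biases(),
                                   duplicates = 2, seed = 1L) {
  stopifnot(all(true_values > 0), all(labs$beta > 0), all(labs$cv >= 0),
            duplicates >= 1)
  structure(list(true_values = true_values, labs = labs,
                 duplicates = duplicates, seed = as.integer(seed)),
            class = "calibration_sim_config")
}

#' Simulate a multi-laboratory calibration experiment
#'
#' Each lab's reading of each sample solves the harmonization identity
#' `true = alpha + beta * reading`, i.e. `reading = (true - alpha) / beta`,
#' perturbed by multiplicative noise with the lab's CV; replicate readings
#' are averaged per sample. Fitting [fit_olp()] on the result therefore
#' recovers `(alpha, beta)` up to noise.
#'
#' @param config A [calibration_sim_config()].
#' @return Wide data.frame (`sample_id` + one column per lab) with the
#'   per-sample replicate means; the replicate-level readings are attached
#'   as attribute `"replicates"` and the config as `"config"`.
#' @export
generate_calibration_experiment <- function(config = calibration_sim_config()) {
  stopifnot(inherits(config, "calibration_sim_config"))
  set.seed(config$seed)
  tv <- config$true_values
  n <- length(tv)
  out <- data.frame(sample_id = make.unique(rep(LETTERS, length.out = n)),
                    stringsAsFactors = FALSE)
  reps <- list()
  for (i in seq_len(nrow(config$labs))) {
    lab <- config$labs[i, ]
    center <- (tv - lab$alpha) / lab$beta
    mat <- vapply(seq_len(config$duplicates), function(d) {
      # instruments cannot report below their limit of quantitation
      pmax(center * (1 + lab$cv * stats::rnorm(n)), 3.5)
    }, numeric(n))
    mat <- matrix(mat, nrow = n)
    out[[lab$lab_id]] <- rowMeans(mat)
    reps[[lab$lab_id]] <- mat
  }
  attr(out, "replicates") <- reps
  attr(out, "config") <- config
  out
}

#' Lognormal parameters from arithmetic moments
#'
#' Returns the log-scale mean and SD of the lognormal distribution whose
#' arithmetic mean and SD equal the supplied values:
#' `mu = log(mean^2 / sqrt(mean^2 + sd^2))`,
#' `sigma = sqrt(log(1 + sd^2 / mean^2))`.
#'
#' @param mean,sd Arithmetic mean and standard deviation (both > 0).
#' @return Named vector `c(log_mean, log_sd)`.
#' @export
lognormal_params_from_moments <- function(mean, sd) {
  stopifnot(mean > 0, sd > 0)
  c(log_mean = log(mean^2 / sqrt(mean^2 + sd^2)),
    log_sd = sqrt(log(1 + sd^2 / mean^2)))
}

#' Configuration for a simulated patient cohort
#'
#' Defaults emulate a 1509-subject multicentre gynecological cohort: group
#' sizes 627 malignant / 583 benign / 299 healthy; group-specific age
#' distributions, post-menopausal proportions and creatinine; heavily
#' right-skewed HE4 and Ca125 modeled lognormal with moment-matched
#' parameters (malignant HE4 mean 474.1, SD 1207 pmol/L; benign 59.7/62.1;
#' healthy 45.7/14.7). Malignant Ca125 uses a large dispersion (SD twice
#' the mean) rather than a literal small-SD summary, keeping the marker
#' heavy-tailed. Menopausal status is coupled to age (never post-menopausal
#' under 40, always over 55) so generated cohorts respect the eligibility
#' rules by construction.
#'
#' @param group_sizes Named counts for `malignant`, `benign`, `healthy`.
#' @param menopause_props Per-group post-menopausal proportions.
#' @param age_params Per-group `c(mean, sd)` of age in years (truncated to
#'   18-70).
#' @param he4_moments,ca125_moments Per-group `c(mean, sd)` of the markers
#'   (arithmetic scale; converted via [lognormal_params_from_moments()]).
#' @param creatinine_params Per-group `c(mean, sd)` in mg/dL, truncated to
#'   (0.3, 3].
#' @param menopause_effect Probit-scale increase in case-control HE4
#'   separation for post-menopausal cases (multiplies the case marker by
#'   `exp(effect * log_sd_healthy)`); default 0.5.
#' @param hospitals Lab/hospital table as in [default_lab_biases()];
#'   subjects are assigned uniformly and their raw HE4 is the
#'   inverse-bias-transformed latent value plus assay noise.
#' @param benign_subtype_mix Named proportions over benign diagnosis
#'   subtypes.
#' @param smoker_props,ethnicity_props Per-group optional label
#'   proportions.
#' @param contaminate_n Number of extra records deliberately violating the
#'   eligibility rules (for testing the filter); default 0. Their
#'   `subject_id` is prefixed `"contam"`.
#' @param seed Integer seed.
#' @return List of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(
    group_sizes = c(malignant = 627, benign = 583, healthy = 299),
    menopause_props = c(malignant = 0.754, benign = 0.377, healthy = 0.482),
    age_params = list(malignant = c(59.4, 13.8), benign = c(47.3, 13.9),
                      healthy = c(46.6, 13.0)),
    he4_moments = list(malignant = c(474.1, 1207.0), benign = c(59.7, 62.1),
                       healthy = c(45.7, 14.7)),
    ca125_moments = list(malignant = c(610.4, 1220.8), benign = c(30.1, 65.9),
                         healthy = c(15.4, 11.9)),
    creatinine_params = list(malignant = c(0.8, 0.2), benign = c(0.7, 0.2),
                             healthy = c(0.7, 0.1)),
    menopause_effect = 0.5,
    hospitals = default_lab_biases(),
    benign_subtype_mix = c(ovarian_lesion = 0.25, annexal_lesion = 0.10,
                           peritoneal_lesion = 0.05, endometriosis = 0.20,
                           fibroma = 0.20, ovarian_cyst = 0.10,
                           endometrial_polyp = 0.10),
    smoker_props = c(malignant = 0.266, benign = 0.286, healthy = 0.171),
    ethnicity_props = c(malignant = 0.019, benign = 0.033, healthy = 0.017),
    contaminate_n = 0,
    seed = 1L) {
  stopifnot(all(group_sizes >= 0),
            all(menopause_props >= 0 & menopause_props <= 1),
            all(vapply(he4_moments, function(m) all(m > 0), logical(1))),
            contaminate_n >= 0)
  structure(
    list(group_sizes = group_sizes, menopause_props = menopause_props,
         age_params = age_params, he4_moments = he4_moments,
         ca125_moments = ca125_moments,
         creatinine_params = creatinine_params,
         menopause_effect = menopause_effect, hospitals = hospitals,
         benign_subtype_mix = benign_subtype_mix,
         smoker_props = smoker_props, ethnicity_props = ethnicity_props,
         contaminate_n = as.integer(contaminate_n),
         seed = as.integer(seed)),
    class = "cohort_sim_config"
  )
}

# inverse-CDF truncated normal: one uniform draw per value, so the RNG
# stream length is independent of the truncation bounds
rtruncnorm <- function(n, mean, sd, lo, hi) {
  p <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(p, mean, sd)
}

#' Simulate a patient cohort
#'
#' Draws subjects per group with age, menopausal status, creatinine, latent
#' (true, reference-scale) HE4 and Ca125, a hospital, and the hospital's
#' raw HE4 reading obtained by inverting the harmonization map and adding
#' the platform's assay noise. Deterministic for a fixed seed.
#'
#' @param config A [cohort_sim_config()].
#' @return data.frame with columns `subject_id`, `group`, `subtype`, `age`,
#'   `menopausal`, `creatinine`, `he4_raw`, `ca125`, `hospital`, `smoker`,
#'   `ethnicity`. The latent reference-scale HE4 is attached as column
#'   `he4_true` (dropped by [write_cohort_csv()] since a real cohort never
#'   carries it).
#' @export
generate_cohort <- function(config = cohort_sim_config()) {
  stopifnot(inherits(config, "cohort_sim_config"))
  set.seed(config$seed)
  sigma_ref <- lognormal_params_from_moments(
    config$he4_moments$healthy[1], config$he4_moments$healthy[2])[["log_sd"]]

  blocks <- lapply(names(config$group_sizes), function(g) {
    n <- config$group_sizes[[g]]
    if (n == 0) return(NULL)
    age <- rtruncnorm(n, config$age_params[[g]][1], config$age_params[[g]][2],
                      18, 70)
    meno <- stats::runif(n) < config$menopause_props[[g]]
    meno[age < 40] <- FALSE
    meno[age > 55] <- TRUE
    creat <- rtruncnorm(n, config$creatinine_params[[g]][1],
                        config$creatinine_params[[g]][2], 0.3 + 1e-9, 3)
    he4p <- lognormal_params_from_moments(config$he4_moments[[g]][1],
                                          config$he4_moments[[g]][2])
    he4 <- stats::rlnorm(n, he4p[["log_mean"]], he4p[["log_sd"]])
    if (g == "malignant" && config$menopause_effect != 0) {
      he4[meno] <- he4[meno] * exp(config$menopause_effect * sigma_ref)
    }
    cap <- lognormal_params_from_moments(config$ca125_moments[[g]][1],
                                         config$ca125_moments[[g]][2])
    ca125 <- stats::rlnorm(n, cap[["log_mean"]], cap[["log_sd"]])
    subtype <- if (g == "benign") {
      sample(names(config$benign_subtype_mix), n, replace = TRUE,
             prob = config$benign_subtype_mix)
    } else if (g == "malignant") {
      rep("ovarian_cancer", n)
    } else {
      rep("", n)
    }
    hosp_idx <- sample.int(nrow(config$hospitals), n, replace = TRUE)
    hosp <- config$hospitals$lab_id[hosp_idx]
    alpha <- config$hospitals$alpha[hosp_idx]
    beta <- config$hospitals$beta[hosp_idx]
    cv <- config$hospitals$cv[hosp_idx]
    he4_raw <- pmax((he4 - alpha) / beta * (1 + cv * stats::rnorm(n)), 3.5)
    smoker <- ifelse(stats::runif(n) < config$smoker_props[[g]], "yes", "no")
    ethnicity <- ifelse(stats::runif(n) < config$ethnicity_props[[g]],
                        "non_caucasian", "caucasian")
    data.frame(group = g, subtype = subtype, age = age, menopausal = meno,
               creatinine = creat, he4_raw = he4_raw, ca125 = ca125,
               hospital = hosp, smoker = smoker, ethnicity = ethnicity,
               he4_true = he4, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, blocks)

  if (config$contaminate_n > 0) {
    out <- rbind(out, contaminated_records(config$contaminate_n, out))
  }
  out <- cbind(subject_id = c(sprintf("S%04d", seq_len(nrow(out) - config$contaminate_n)),
                              if (config$contaminate_n > 0)
                                sprintf("contam%03d", seq_len(config$contaminate_n))),
               out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

# records that each violate one eligibility rule, cycling through the rules
contaminated_records <- function(n, template) {
  base <- template[rep(1, n), , drop = FALSE]
  base$group <- "benign"
  base$subtype <- "fibroma"
  base$age <- 50
  base$menopausal <- FALSE
  base$creatinine <- 0.9
  rule <- (seq_len(n) - 1L) %% 4L
  base$age[rule == 0] <- NA          # missing age
  base$age[rule == 1] <- 75          # out of 18-70
  base$creatinine[rule == 2] <- 0.2  # creatinine <= 0.3
  base$age[rule == 3] <- 60          # premenopausal over 55
  rownames(base) <- NULL
  base
}

#' Write a cohort to the pipeline's CSV schema
#'
#' Drops the latent `he4_true` column (a real cohort never carries it) and
#' writes booleans as `true`/`false`, missing values as empty fields.
#'
#' @param cohort data.frame from [generate_cohort()].
#' @param path Output CSV path.
#' @export
write_cohort_csv <- function(cohort, path) {
  cohort$he4_true <- NULL
  cohort$menopausal <- ifelse(cohort$menopausal, "true", "false")
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
}

#' Read a cohort CSV
#'
#' @param path CSV with columns `subject_id, group, subtype, age,
#'   menopausal, creatinine, he4_raw, ca125, hospital` (optionally
#'   `smoker`, `ethnicity`); booleans written `true`/`false`, missing
#'   values empty.
#' @return data.frame with `menopausal` as logical.
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  df$menopausal <- tolower(as.character(df$menopausal)) %in% c("true", "1", "t")
  df
}
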