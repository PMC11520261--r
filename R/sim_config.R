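#' Simulation configuration for the synthetic claims generator
#'
#' Bundles every knob of the synthetic data-generating process: cohort size,
#' demographics, baseline labs with missingness, sparse phecode comorbidity
#' counts, a logistic treatment-assignment model, arm-specific
#' Weibull-baseline proportional-hazards event times, and independent
#' censoring over an administrative study horizon. Defaults emulate a large
#' type 2 diabetes insulin vs GLP-1 receptor agonist claims cohort: mean age
#' in the mid 60s, roughly three quarters of patients on insulin, baseline
#' HbA1c around 8.5%, a ~5.4-year study window, and marginal 5-year
#' heart-failure rates near 29% (insulin) and 18% (comparator).
#'
#' Treatment and hazard linear predictors act on internally standardized
#' covariates (using the configured means/SDs, not sample moments, so the
#' truth is well defined). Recognised coefficient names are `intercept`
#' (treatment model only), `age`, `male`, `hba1c`, `cholesterol`, `hdl`,
#' `ldl` and `age_x_hba1c` (an age-varying HbA1c effect).
#'
#' @param n_patients number of patients to simulate.
#' @param age_mean,age_sd age distribution at treatment start, in years.
#' @param frac_male proportion male.
#' @param n_phecode_features number of sparse comorbidity count features.
#' @param phecode_prevalence_range length-2 vector; per-feature prevalence is
#'   drawn uniformly from this range (spanning the 5% rarity threshold by
#'   default so the prevalence filter is exercised).
#' @param lab_means,lab_sds,lab_missing_rates named numeric vectors over
#'   `hba1c`, `cholesterol`, `hdl`, `ldl`: lab value distribution and
#'   missing-completely-at-random observation rates.
#' @param ps_coefficients named vector of treatment-model coefficients on the
#'   standardized scale (log-odds of insulin).
#' @param hazard_shape Weibull shape shared by both arms.
#' @param hazard_scale_by_arm named vector `c(insulin=, comparator=)` of
#'   Weibull scales (years).
#' @param log_hazard_coefficients_by_arm named list `insulin`/`comparator`
#'   of named log-hazard-ratio vectors.
#' @param censor_rate exponential censoring rate per year (0 = none).
#' @param censor_coefficients optional named vector making censoring
#'   covariate-dependent (log-rate scale); default independent censoring.
#' @param admin_end administrative end of follow-up, years.
#' @param horizon_t analysis horizon, years.
#' @param comparator_class drug-class label of the comparator arm in
#'   claim-stream mode.
#' @param frac_nonsustained,frac_single_fill,frac_other_class,frac_two_class,
#'   frac_tied_first_fill scripted pharmacy fill patterns in claim-stream
#'   mode (fractions of patients).
#' @param frac_prior_hf,frac_no_hba1c,frac_short_coverage,frac_t1dm scripted
#'   exclusion conditions in claim-stream mode.
#' @param seed integer seed; every generator call is deterministic given the
#'   config.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_patients = 5000,
                       age_mean = 65.4, age_sd = 10.3,
                       frac_male = 0.47,
                       n_phecode_features = 40,
                       phecode_prevalence_range = c(0.01, 0.40),
                       lab_means = c(hba1c = 8.5, cholesterol = 170.9,
                                     hdl = 45.5, ldl = 90.0),
                       lab_sds = c(hba1c = 1.2, cholesterol = 23.3,
                                   hdl = 6.6, ldl = 18.3),
                       lab_missing_rates = c(hba1c = 0.05, cholesterol = 0.15,
                                             hdl = 0.15, ldl = 0.15),
                       ps_coefficients = c(intercept = 1.25, age = 0.55,
                                           male = -0.08, hba1c = 0.35,
                                           age_x_hba1c = 0.12),
                       hazard_shape = 1.1,
                       hazard_scale_by_arm = c(insulin = 15.1, comparator = 26.3),
                       log_hazard_coefficients_by_arm =
                         list(insulin = c(age = 0.45, male = 0.12, hba1c = 0.30),
                              comparator = c(age = 0.45, male = 0.12, hba1c = 0.30)),
                       censor_rate = 0.25,
                       censor_coefficients = NULL,
                       admin_end = 5.4,
                       horizon_t = 5,
                       comparator_class = "glp1ra",
                       frac_nonsustained = 0.08,
                       frac_single_fill = 0.05,
                       frac_other_class = 0.04,
                       frac_two_class = 0.06,
                       frac_tied_first_fill = 0.02,
                       frac_prior_hf = 0.05,
                       frac_no_hba1c = 0.05,
                       frac_short_coverage = 0.05,
                       frac_t1dm = 0.03,
                       seed = 1L) {
  cfg <- list(
    n_patients = n_patients, age_mean = age_mean, age_sd = age_sd,
    frac_male = frac_male, n_phecode_features = n_phecode_features,
    phecode_prevalence_range = phecode_prevalence_range,
    lab_means = lab_means, lab_sds = lab_sds,
    lab_missing_rates = lab_missing_rates,
    ps_coefficients = ps_coefficients,
    hazard_shape = hazard_shape,
    hazard_scale_by_arm = hazard_scale_by_arm,
    log_hazard_coefficients_by_arm = log_hazard_coefficients_by_arm,
    censor_rate = censor_rate, censor_coefficients = censor_coefficients,
    admin_end = admin_end, horizon_t = horizon_t,
    comparator_class = comparator_class,
    frac_nonsustained = frac_nonsustained,
    frac_single_fill = frac_single_fill,
    frac_other_class = frac_other_class,
    frac_two_class = frac_two_class,
    frac_tied_first_fill = frac_tied_first_fill,
    frac_prior_hf = frac_prior_hf, frac_no_hba1c = frac_no_hba1c,
    frac_short_coverage = frac_short_coverage, frac_t1dm = frac_t1dm,
    seed = as.integer(seed))
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

# Field-by-field validation; errors name the offending field.
validate_sim_config <- function(cfg) {
  stop_field <- function(field, msg) {
    stop(sprintf("invalid sim_config field '%s': %s", field, msg), call. = FALSE)
  }
  if (!is.numeric(cfg$n_patients) || length(cfg$n_patients) != 1 ||
      cfg$n_patients < 1) stop_field("n_patients", "must be >= 1")
  if (cfg$age_sd <= 0) stop_field("age_sd", "must be > 0")
  props <- c(frac_male = cfg$frac_male,
             frac_nonsustained = cfg$frac_nonsustained,
             frac_single_fill = cfg$frac_single_fill,
             frac_other_class = cfg$frac_other_class,
             frac_two_class = cfg$frac_two_class,
             frac_tied_first_fill = cfg$frac_tied_first_fill,
             frac_prior_hf = cfg$frac_prior_hf,
             frac_no_hba1c = cfg$frac_no_hba1c,
             frac_short_coverage = cfg$frac_short_coverage,
             frac_t1dm = cfg$frac_t1dm)
  for (nm in names(props)) {
    if (!is.numeric(props[[nm]]) || props[[nm]] < 0 || props[[nm]] > 1)
      stop_field(nm, "must be a proportion in [0, 1]")
  }
  if (any(cfg$phecode_prevalence_range < 0) ||
      any(cfg$phecode_prevalence_range > 1) ||
      diff(cfg$phecode_prevalence_range) < 0)
    stop_field("phecode_prevalence_range", "must be an increasing pair in [0, 1]")
  if (any(cfg$lab_missing_rates < 0) || any(cfg$lab_missing_rates > 1))
    stop_field("lab_missing_rates", "must lie in [0, 1]")
  if (cfg$hazard_shape <= 0) stop_field("hazard_shape", "must be > 0")
  if (any(cfg$hazard_scale_by_arm <= 0))
    stop_field("hazard_scale_by_arm", "scales must be > 0")
  if (!all(c("insulin", "comparator") %in% names(cfg$hazard_scale_by_arm)))
    stop_field("hazard_scale_by_arm", "needs named entries 'insulin' and 'comparator'")
  if (!all(c("insulin", "comparator") %in%
           names(cfg$log_hazard_coefficients_by_arm)))
    stop_field("log_hazard_coefficients_by_arm",
               "needs named entries 'insulin' and 'comparator'")
  if (cfg$censor_rate < 0) stop_field("censor_rate", "must be >= 0")
  if (cfg$admin_end < cfg$horizon_t)
    stop_field("admin_end", "must be >= horizon_t")
  allowed <- c("intercept", "age", "male", "hba1c", "cholesterol", "hdl",
               "ldl", "age_x_hba1c")
  bad <- setdiff(names(cfg$ps_coefficients), allowed)
  if (length(bad))
    stop_field("ps_coefficients", paste("unknown names:", paste(bad, collapse = ", ")))
  for (arm in c("insulin", "comparator")) {
    bad <- setdiff(names(cfg$log_hazard_coefficients_by_arm[[arm]]),
                   setdiff(allowed, "intercept"))
    if (length(bad))
      stop_field("log_hazard_coefficients_by_arm",
                 paste("unknown names:", paste(bad, collapse = ", ")))
  }
  if (!is.finite(cfg$seed)) stop_field("seed", "must be a finite integer")
  invisible(cfg)
}

# Standardized covariate frame used by the generative linear predictors.
# Uses the configured moments, not sample moments, so the truth does not
# drift with n.
sim_standardize <- function(cov, cfg) {
  z <- data.frame(
    age = (cov$age - cfg$age_mean) / cfg$age_sd,
    male = cov$male,
    hba1c = (cov$hba1c - cfg$lab_means[["hba1c"]]) / cfg$lab_sds[["hba1c"]],
    cholesterol = (cov$cholesterol - cfg$lab_means[["cholesterol"]]) /
      cfg$lab_sds[["cholesterol"]],
    hdl = (cov$hdl - cfg$lab_means[["hdl"]]) / cfg$lab_sds[["hdl"]],
    ldl = (cov$ldl - cfg$lab_means[["ldl"]]) / cfg$lab_sds[["ldl"]])
  z$age_x_hba1c <- z$age * z$hba1c
  z
}

sim_lp <- function(z, coefs) {
  eta <- rep(0, nrow(z))
  for (nm in names(coefs)) {
    if (nm == "intercept") eta <- eta + coefs[[nm]]
    else eta <- eta + coefs[[nm]] * z[[nm]]
  }
  eta
}

# Draw the raw (true, pre-missingness) covariates for n patients.
sim_draw_covariates <- function(cfg, n) {
  data.frame(
    age = stats::rnorm(n, cfg$age_mean, cfg$age_sd),
    male = stats::rbinom(n, 1, cfg$frac_male),
    hba1c = stats::rnorm(n, cfg$lab_means[["hba1c"]], cfg$lab_sds[["hba1c"]]),
    cholesterol = stats::rnorm(n, cfg$lab_means[["cholesterol"]],
                               cfg$lab_sds[["cholesterol"]]),
    hdl = stats::rnorm(n, cfg$lab_means[["hdl"]], cfg$lab_sds[["hdl"]]),
    ldl = stats::rnorm(n, cfg$lab_means[["ldl"]], cfg$lab_sds[["ldl"]]))
}
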