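#' Generate a ready-made analytic cohort (direct mode)
#'
#' Draws patient covariates, treatment assignment, and censored event times
#' directly, bypassing claim-stream construction. Treatment is Bernoulli on
#' the logistic treatment model; event times follow the arm-specific
#' Weibull-baseline proportional-hazards model; censoring is the minimum of
#' an exponential time (optionally covariate-dependent) and the
#' administrative end of follow-up.
#'
#' Lab columns carry missing-completely-at-random `NA`s at the configured
#' rates; the underlying true values (used by the hazard) are kept in
#' attribute `"true_labs"` for oracle checks. Disease duration, auxiliary
#' medication counts, and the sparse phecode counts are pure noise covariates
#' (no effect on treatment or outcome) that exercise variable selection.
#'
#' @param config a [sim_config()].
#' @return a `data.frame` (one row per patient) with columns `patient_id`,
#'   `arm` (1 = insulin), `time` (years, censored follow-up), `event`
#'   (1 = heart failure), `age`, `male`, the four labs, `disease_duration`
#'   (months), four medication fill counts, and `phe_*` count columns.
#'   Attributes: `config`, `true_labs`, `propensity` (true assignment
#'   probabilities).
#' @export
generate_cohort <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  n <- as.integer(config$n_patients)
  cov <- sim_draw_covariates(config, n)
  z <- sim_standardize(cov, config)

  pi_true <- stats::plogis(sim_lp(z, config$ps_coefficients))
  arm <- stats::rbinom(n, 1, pi_true)

  k <- config$hazard_shape
  lam <- ifelse(arm == 1, config$hazard_scale_by_arm[["insulin"]],
                config$hazard_scale_by_arm[["comparator"]])
  eta1 <- sim_lp(z, config$log_hazard_coefficients_by_arm$insulin)
  eta0 <- sim_lp(z, config$log_hazard_coefficients_by_arm$comparator)
  eta <- ifelse(arm == 1, eta1, eta0)
  # Inverse-CDF draw from S(t|x) = exp(-(t/lam)^k * exp(eta))
  u <- stats::runif(n)
  t_event <- lam * (-log(u) / exp(eta))^(1 / k)

  if (config$censor_rate > 0) {
    crate <- config$censor_rate
    if (!is.null(config$censor_coefficients))
      crate <- crate * exp(sim_lp(z, config$censor_coefficients))
    t_cens <- stats::rexp(n, rate = crate)
  } else {
    t_cens <- rep(Inf, n)
  }
  t_cens <- pmin(t_cens, config$admin_end)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  labs <- cov[c("hba1c", "cholesterol", "hdl", "ldl")]
  obs_labs <- labs
  for (nm in names(obs_labs)) {
    miss <- stats::runif(n) < config$lab_missing_rates[[nm]]
    obs_labs[[nm]][miss] <- NA_real_
  }

  med <- data.frame(
    metformin = stats::rpois(n, 0.7),
    statins = stats::rpois(n, 0.8),
    sulfonylureas = stats::rpois(n, 0.4),
    thiazolidinediones = stats::rpois(n, 0.1))

  phe <- sim_draw_phecodes(config, n)

  out <- data.frame(
    patient_id = sprintf("P%06d", seq_len(n)),
    arm = arm, time = time, event = event,
    age = cov$age, male = cov$male, obs_labs,
    disease_duration = round(stats::rgamma(n, shape = 0.5, scale = 8), 1),
    med, phe, stringsAsFactors = FALSE)
  attr(out, "config") <- config
  attr(out, "true_labs") <- labs
  attr(out, "propensity") <- pi_true
  out
}

# Sparse zero-inflated Poisson phecode counts; prevalence per feature drawn
# uniformly from the configured range.
sim_draw_phecodes <- function(cfg, n) {
  p <- cfg$n_phecode_features
  if (p == 0) return(data.frame(row.names = seq_len(n)))
  prev <- stats::runif(p, cfg$phecode_prevalence_range[1],
                       cfg$phecode_prevalence_range[2])
  phe <- matrix(0L, n, p)
  for (j in seq_len(p)) {
    has <- stats::rbinom(n, 1, prev[j]) == 1
    phe[has, j] <- 1L + stats::rpois(sum(has), 0.6)
  }
  phe <- as.data.frame(phe)
  names(phe) <- sprintf("phe_%03d", seq_len(p))
  phe
}

#' True marginal event-free probability under a simulation config
#'
#' Oracle for acceptance checks: the marginal probability of being free of
#' heart failure at `t` years if everyone were assigned to `arm`. With no
#' covariate effects on the hazard this is the closed-form Weibull survival
#' `exp(-(t/lambda)^shape)`; otherwise it is a Monte Carlo average of the
#' conditional survival over fresh covariate draws.
#'
#' @param config a [sim_config()].
#' @param arm 1 (insulin) or 0 (comparator).
#' @param t horizon in years; must be `>= 0`.
#' @param n_draws Monte Carlo draws when covariate effects are present.
#' @param seed seed for the Monte Carlo draws (defaults to `config$seed + 1`).
#' @return a list with `value` (probability) and `mc_se` (0 for closed form).
#' @export
true_survival <- function(config, arm, t, n_draws = 1e6,
                          seed = config$seed + 1L) {
  validate_sim_config(config)
  if (!arm %in% c(0, 1)) stop("arm must be 0 or 1")
  if (!is.numeric(t) || any(t < 0)) stop("t must be >= 0")
  arm_name <- if (arm == 1) "insulin" else "comparator"
  lam <- config$hazard_scale_by_arm[[arm_name]]
  k <- config$hazard_shape
  beta <- config$log_hazard_coefficients_by_arm[[arm_name]]
  if (length(beta) == 0 || all(beta == 0)) {
    return(list(value = exp(-(t / lam)^k), mc_se = 0))
  }
  set.seed(seed)
  cov <- sim_draw_covariates(config, n_draws)
  z <- sim_standardize(cov, config)
  s <- exp(-(t / lam)^k * exp(sim_lp(z, beta)))
  list(value = mean(s), mc_se = stats::sd(s) / sqrt(n_draws))
}

#' Ground-truth effect values for a simulation config
#'
#' Returns the true arm-specific event-free probabilities at the horizon, the
#' treatment effect on both scales, and a per-patient conditional-effect
#' function. Sign conventions: `ate_surv = S1 - S0` (survival-probability
#' difference, positive favors insulin); `ate_rate = (1 - S1) - (1 - S0)`
#' (heart-failure-rate difference, positive means insulin has the higher HF
#' rate) — the scale on which the pipeline reports its headline ATE.
#'
#' @param config a [sim_config()].
#' @param t horizon in years (default the config's `horizon_t`).
#' @param n_draws Monte Carlo draws for the marginal probabilities.
#' @return list with `S1_t`, `S0_t`, `ate_surv`, `ate_rate`, `mc_se`
#'   (combined MC standard error of either difference) and `cate_fn`, a
#'   function mapping a covariate data.frame (columns `age`, `male`, `hba1c`,
#'   `cholesterol`, `hdl`, `ldl`) to the true conditional
#'   HF-rate difference at `t`.
#' @export
ground_truth <- function(config, t = config$horizon_t, n_draws = 1e6) {
  s1 <- true_survival(config, 1, t, n_draws, seed = config$seed + 1L)
  s0 <- true_survival(config, 0, t, n_draws, seed = config$seed + 2L)
  k <- config$hazard_shape
  lam1 <- config$hazard_scale_by_arm[["insulin"]]
  lam0 <- config$hazard_scale_by_arm[["comparator"]]
  b1 <- config$log_hazard_coefficients_by_arm$insulin
  b0 <- config$log_hazard_coefficients_by_arm$comparator
  cfg <- config
  cate_fn <- function(cov) {
    z <- sim_standardize(cov, cfg)
    s1x <- exp(-(t / lam1)^k * exp(sim_lp(z, b1)))
    s0x <- exp(-(t / lam0)^k * exp(sim_lp(z, b0)))
    (1 - s1x) - (1 - s0x)
  }
  list(S1_t = s1$value, S0_t = s0$value,
       ate_surv = s1$value - s0$value,
       ate_rate = (1 - s1$value) - (1 - s0$value),
       mc_se = sqrt(s1$mc_se^2 + s0$mc_se^2),
       cate_fn = cate_fn)
}

#' Generative-truth design matrix for a simulated cohort
#'
#' Rebuilds the exact standardized covariate columns the generator's
#' treatment and hazard models act on (including the age-by-HbA1c
#' interaction), using the *observed* labs with the cohort's own mean
#' imputation. Fitting an unpenalized logistic or Cox model on these columns
#' is what "correctly specified nuisance model" means in the simulation
#' studies.
#'
#' @param cohort a cohort from [generate_cohort()].
#' @param config the generating [sim_config()]; defaults to the cohort's
#'   `config` attribute.
#' @return numeric matrix with columns `age`, `male`, `hba1c`,
#'   `age_x_hba1c`.
#' @export
sim_true_design <- function(cohort, config = attr(cohort, "config")) {
  if (is.null(config)) stop("cohort carries no config attribute; pass one")
  labs <- cohort[c("hba1c", "cholesterol", "hdl", "ldl")]
  for (nm in names(labs)) {
    m <- mean(labs[[nm]], na.rm = TRUE)
    labs[[nm]][is.na(labs[[nm]])] <- m
  }
  cov <- data.frame(age = cohort$age, male = cohort$male, labs)
  z <- sim_standardize(cov, config)
  as.matrix(z[c("age", "male", "hba1c", "age_x_hba1c")])
}
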