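# One-call orchestration of the full analysis and the replicate-level
# simulation harness.

# Tiny FNV-style hash of a deparsed object, for run manifests.
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 2166136261 %% 2147483647
  for (ch in utf8ToInt(s))
    h <- (bitwXor(as.integer(h), ch) * 16777619) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Run the full comparative-effectiveness analysis
#'
#' Executes every stage in order — simulate or read claims, cohort
#' construction (claims mode), feature/design building, adaptive-LASSO
#' propensity and arm-specific Cox fits, IPW balance diagnostics, weighted
#' Kaplan-Meier curves, the doubly robust t-year HF-rate difference, the
#' personalized score, the score-specific CATE curve, and the score-sign
#' subgroup effects. Reruns with an identical configuration produce an
#' identical bundle.
#'
#' @param input a [sim_config()] (synthetic mode: `mode = "synthetic"` uses
#'   [generate_cohort()]; `mode = "claims"` uses [generate_claim_stream()]
#'   then [build_cohort()]), or a `claim_stream`, or a directory of claims
#'   tables.
#' @param mode `"synthetic"` or `"claims"`.
#' @param comparator comparator drug-class label (claims mode); validated
#'   against the pharmacy table.
#' @param t analysis horizon in years.
#' @param trim_bounds propensity trimming bounds.
#' @param nfolds cross-validation folds for the nuisance fits.
#' @param seed seed controlling fold splits (generation seeds come from the
#'   config).
#' @param nuisance `"adaptive_lasso"` (default) or `"glm"` (unpenalized, on
#'   the same design).
#' @param output_dir optional directory; when given, all result tables and
#'   a JSON manifest are written there.
#' @return list with `cohort`, `attrition`, `features`, `psfit`,
#'   `coxfit1`, `coxfit0`, `weights`, `balance`, `km`, `ate`, `score`,
#'   `cate`, `subgroups`, `manifest`.
#' @export
run_comparison <- function(input, mode = c("synthetic", "claims"),
                           comparator = "glp1ra", t = 5,
                           trim_bounds = c(0.01, 0.99), nfolds = 10,
                           seed = 1, nuisance = c("adaptive_lasso", "glm"),
                           output_dir = NULL) {
  mode <- match.arg(mode)
  nuisance <- match.arg(nuisance)
  attrition <- NULL
  if (inherits(input, "sim_config")) {
    if (mode == "synthetic") {
      cohort <- generate_cohort(input)
    } else {
      stream <- generate_claim_stream(input)
      comparator <- input$comparator_class
      built <- build_cohort(stream, comparator = comparator)
      cohort <- built$cohort
      attrition <- built$attrition
    }
  } else {
    stream <- if (is.character(input)) read_claim_stream(input) else input
    if (!comparator %in% stream$rx_claims$drug_class)
      stop("comparator class '", comparator,
           "' absent from the pharmacy claims")
    built <- build_cohort(stream, comparator = comparator)
    cohort <- built$cohort
    attrition <- built$attrition
  }
  if (length(unique(cohort$arm)) < 2)
    stop("cohort stage produced a single arm (n = ", nrow(cohort), ")")

  feats <- build_features(cohort)
  X <- feats$X
  ids <- cohort$patient_id

  if (nuisance == "adaptive_lasso") {
    psfit <- fit_adaptive_lasso_logistic(X, cohort$arm, patient_id = ids,
                                         nfolds = nfolds, seed = seed)
    i1 <- cohort$arm == 1; i0 <- !i1
    coxfit1 <- fit_adaptive_lasso_cox(X[i1, , drop = FALSE],
                                      cohort$time[i1], cohort$event[i1],
                                      patient_id = ids[i1], nfolds = nfolds,
                                      seed = seed + 1, arm_label = "insulin")
    coxfit0 <- fit_adaptive_lasso_cox(X[i0, , drop = FALSE],
                                      cohort$time[i0], cohort$event[i0],
                                      patient_id = ids[i0], nfolds = nfolds,
                                      seed = seed + 2,
                                      arm_label = "comparator")
  } else {
    psfit <- fit_logistic(X, cohort$arm)
    i1 <- cohort$arm == 1; i0 <- !i1
    coxfit1 <- fit_cox_breslow(X[i1, , drop = FALSE], cohort$time[i1],
                               cohort$event[i1], arm_label = "insulin")
    coxfit0 <- fit_cox_breslow(X[i0, , drop = FALSE], cohort$time[i0],
                               cohort$event[i0], arm_label = "comparator")
  }

  pi_full <- predict_propensity(psfit, X)
  w <- ipw_weights(pi_full, cohort$arm, trim_bounds)
  bal_covs <- cbind(age = cohort$age, feats$covariates)
  balance <- balance_diagnostics(bal_covs, cohort$arm, w$weights)
  km_before <- weighted_km(cohort$time, cohort$event, arm = cohort$arm)
  km_after <- weighted_km(cohort$time, cohort$event, weights = w$weights,
                          arm = cohort$arm)
  ate <- aipw_ate(cohort$time, cohort$event, cohort$arm, X, pi_full,
                  coxfit1, coxfit0, t = t, trim_bounds = trim_bounds)
  S <- compute_score(coxfit1, coxfit0, X, t)
  if (stats::sd(S) >= 1e-8) {
    cate <- score_specific_ate(S[ate$keep], ate$psi0 - ate$psi1)
    # split at S = 0 when both sign subgroups are populated (>= 1% of
    # patients), else at the median score
    thr <- if (min(mean(S > 0), mean(S <= 0)) >= 0.01) 0 else
      stats::median(S)
    if (min(mean(S > thr), mean(S <= thr)) >= 0.01) {
      subgroups <- subgroup_ate(S, cohort$time, cohort$event, cohort$arm,
                                X, pi_full, coxfit1, coxfit0, t = t,
                                threshold = thr,
                                trim_bounds = trim_bounds)
      subgroups$threshold <- thr
    } else {
      subgroups <- NULL   # scores too concentrated to split
    }
  } else {
    # both Cox fits give every patient the same score: the model-based
    # effect is constant, so no score-specific analysis is possible
    cate <- NULL
    subgroups <- NULL
  }

  manifest <- list(
    mode = mode, comparator = comparator, t = t,
    trim_bounds = trim_bounds, nfolds = nfolds, seed = seed,
    nuisance = nuisance,
    config_hash = if (inherits(input, "sim_config"))
      config_hash(unclass(input)) else NA_character_,
    n_cohort = nrow(cohort), n_used = ate$n_used,
    n_trimmed = ate$n_trimmed,
    design_columns = ncol(X),
    package_version = as.character(utils::packageVersion("drclaims")))

  bundle <- list(cohort = cohort, attrition = attrition, features = feats,
                 psfit = psfit, coxfit1 = coxfit1, coxfit0 = coxfit0,
                 weights = w, balance = balance,
                 km = list(before = km_before, after = km_after),
                 ate = ate, score = S, cate = cate, subgroups = subgroups,
                 manifest = manifest)
  if (!is.null(output_dir)) write_bundle(bundle, output_dir)
  bundle
}

# Write the result bundle as delimited tables + JSON summaries.
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                          quote = FALSE, row.names = FALSE)
  if (!is.null(bundle$attrition))
    wt(data.frame(reason = names(bundle$attrition),
                  n = as.integer(bundle$attrition)), "attrition.tsv")
  wt(as.data.frame(bundle$balance), "balance.tsv")
  wt(bundle$km$before, "km_before_ipw.tsv")
  wt(bundle$km$after, "km_after_ipw.tsv")
  wt(as.data.frame(bundle$cate), "cate_curve.tsv")
  a <- bundle$ate
  jsonlite::write_json(
    list(t = a$t, rate_insulin = a$rate1, se_rate_insulin = a$se_rate1,
         rate_comparator = a$rate0, se_rate_comparator = a$se_rate0,
         ate = a$ate, se = a$se, ci = a$ci, n_used = a$n_used,
         n_trimmed = a$n_trimmed),
    file.path(dir, "ate.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(bundle$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Replicate-level simulation study of the doubly robust estimator
#'
#' Runs seeded replicates of cohort generation and AIPW estimation under
#' scenarios that switch each nuisance model between correct (fit on the
#' generator's own covariate design, [sim_true_design()]) and deliberately
#' misspecified (intercept-only propensity / covariate-free Cox), and
#' summarizes bias, empirical and mean estimated standard errors, and 95%
#' CI coverage against the [true_survival()] ground truth.
#'
#' @param config base [sim_config()]; each replicate gets a fresh seed.
#' @param n_replicates replicates per scenario.
#' @param scenarios named list; each element is
#'   `list(ps_correct = , or_correct = )`. Default: the four on/off
#'   combinations.
#' @param t horizon.
#' @param trim_bounds trimming bounds.
#' @param seed master seed for the replicate seeds.
#' @param n_truth_draws Monte Carlo draws for the ground truth.
#' @return data.frame, one row per scenario: `scenario`, `ps_correct`,
#'   `or_correct`, `true_ate`, `mean_est`, `bias`, `emp_se`,
#'   `mean_est_se`, `se_ratio`, `coverage`, `n_replicates`. Attribute
#'   `estimates` carries the per-replicate matrices.
#' @export
run_simulation_study <- function(config, n_replicates = 200,
                                 scenarios = NULL, t = config$horizon_t,
                                 trim_bounds = c(0.01, 0.99), seed = 1,
                                 n_truth_draws = 1e6) {
  if (is.null(scenarios)) {
    scenarios <- list(
      both_correct = list(ps_correct = TRUE, or_correct = TRUE),
      ps_only_correct = list(ps_correct = TRUE, or_correct = FALSE),
      or_only_correct = list(ps_correct = FALSE, or_correct = TRUE),
      both_wrong = list(ps_correct = FALSE, or_correct = FALSE))
  }
  truth <- ground_truth(config, t, n_draws = n_truth_draws)
  rep_seeds <- seed * 1000L + seq_len(n_replicates)
  est_store <- list()
  rows <- lapply(names(scenarios), function(snm) {
    sc <- scenarios[[snm]]
    est <- se <- numeric(n_replicates)
    for (r in seq_len(n_replicates)) {
      cfg <- config
      cfg$seed <- rep_seeds[r]
      cohort <- generate_cohort(cfg)
      res <- aipw_from_cohort(cohort, ps_correct = sc$ps_correct,
                              or_correct = sc$or_correct, t = t,
                              trim_bounds = trim_bounds)
      est[r] <- res$ate
      se[r] <- res$se
    }
    est_store[[snm]] <<- cbind(est = est, se = se)
    covered <- abs(est - truth$ate_rate) <= 1.96 * se
    data.frame(scenario = snm, ps_correct = sc$ps_correct,
               or_correct = sc$or_correct,
               true_ate = truth$ate_rate,
               mean_est = mean(est), bias = mean(est) - truth$ate_rate,
               emp_se = stats::sd(est), mean_est_se = mean(se),
               se_ratio = stats::sd(est) / mean(se),
               coverage = mean(covered),
               n_replicates = n_replicates, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "estimates") <- est_store
  attr(out, "truth") <- truth
  out
}

# One AIPW estimate from a simulated cohort with correct/misspecified
# nuisance models (unpenalized fits on the generator's true design).
aipw_from_cohort <- function(cohort, ps_correct = TRUE, or_correct = TRUE,
                             t = 5, trim_bounds = c(0.01, 0.99)) {
  Z <- sim_true_design(cohort)
  psfit <- if (ps_correct) fit_logistic(Z, cohort$arm)
           else fit_logistic(NULL, cohort$arm)
  i1 <- cohort$arm == 1; i0 <- !i1
  Zor <- if (or_correct) Z else NULL
  coxfit1 <- fit_cox_breslow(if (is.null(Zor)) NULL else Zor[i1, , drop = FALSE],
                             cohort$time[i1], cohort$event[i1], "insulin")
  coxfit0 <- fit_cox_breslow(if (is.null(Zor)) NULL else Zor[i0, , drop = FALSE],
                             cohort$time[i0], cohort$event[i0], "comparator")
  Xpred <- if (or_correct) Z else Z[, 0, drop = FALSE]
  aipw_ate(cohort$time, cohort$event, cohort$arm, Xpred,
           psfit$propensity, coxfit1, coxfit0, t = t,
           trim_bounds = trim_bounds)
}
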