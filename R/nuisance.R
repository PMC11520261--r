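# Nuisance models: adaptive-LASSO logistic propensity fit and
# adaptive-LASSO Cox outcome fits (one per arm), plus unpenalized reference
# fitters used in simulation studies and misspecification scenarios.
#
# Adaptive LASSO is two-stage: (1) a ridge fit supplies initial
# coefficients beta0; (2) an L1 fit with per-column penalty weight
# 1/(|beta0_j| + eps)^gamma. Lambda is chosen by minimum 10-fold
# cross-validated deviance, with fold membership keyed to patient id (not
# row position) so refits under row permutation are identical.

# Extended-BIC along a glmnet path: deviance + df * (log n + 2 g log p).
# Unpenalized columns contribute a constant df offset, which cancels in the
# comparison across lambda.
pick_lambda_ebic <- function(fit, n, p, ebic_gamma = 0.5) {
  dev <- (1 - fit$dev.ratio) * fit$nulldev
  ebic <- dev + fit$df * (log(n) + 2 * ebic_gamma * log(p))
  fit$lambda[which.min(ebic)]
}

# Deterministic, row-permutation-invariant fold assignment.
make_foldid <- function(ids, nfolds, seed) {
  ord <- order(as.character(ids))
  set.seed(seed)
  f <- sample(rep_len(seq_len(nfolds), length(ids)))
  foldid <- integer(length(ids))
  foldid[ord] <- f
  foldid
}

#' Fit the adaptive-LASSO logistic propensity model
#'
#' Two-stage penalized logistic regression of treatment arm on the design
#' matrix. The intercept and the age-basis columns (names `B1..Bk`) are
#' never penalized: age is a forced confounder. Non-selected coefficients
#' are exactly zero.
#'
#' @param X design matrix (ideally a `design_matrix`).
#' @param arm binary treatment vector (1 = insulin).
#' @param patient_id ids used to key the CV fold split (default: rownames
#'   of `X`, else row index).
#' @param nfolds CV folds (default 10).
#' @param seed seed for the fold split.
#' @param gamma,eps adaptive-weight parameters: weight = 1/(|b0|+eps)^gamma.
#' @param lambda optional fixed penalty overriding the selection rule (`0`
#'   gives the unpenalized fit; `Inf` gives the
#'   intercept-plus-forced-columns fit).
#' @param lambda_rule how the stage-two penalty is chosen: `"ebic"`
#'   (default; extended BIC along the path, selection-consistent),
#'   `"cv_min"` (minimum 10-fold CV deviance) or `"cv_1se"` (1-SE rule).
#' @param ebic_gamma extended-BIC dimensionality weight (default 0.5).
#' @param unpenalized column names never penalized (default the age-basis
#'   columns).
#' @return object of class `ps_fit`: list with `coef` (named, incl.
#'   `(Intercept)`), `propensity`, `lambda`, `lambda_path`, `cv_deviance`,
#'   `support`, `columns`.
#' @export
fit_adaptive_lasso_logistic <- function(X, arm, patient_id = NULL,
                                        nfolds = 10, seed = 1,
                                        gamma = 1, eps = 1e-6,
                                        lambda = NULL,
                                        lambda_rule = c("ebic", "cv_min",
                                                        "cv_1se"),
                                        ebic_gamma = 0.5,
                                        unpenalized = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  arm <- as.numeric(arm)
  if (length(unique(arm)) < 2) stop("single-arm input: both arms required")
  if (nrow(X) <= 10) stop("need n > 10 to fit the propensity model")
  if (is.null(patient_id)) patient_id <- rownames(X)
  if (is.null(patient_id)) patient_id <- as.character(seq_len(nrow(X)))
  if (is.null(unpenalized)) unpenalized <- grep("^B[0-9]+$", colnames(X),
                                                value = TRUE)
  pf_base <- ifelse(colnames(X) %in% unpenalized, 0, 1)

  if (!is.null(lambda) && is.infinite(lambda)) {
    keep <- colnames(X) %in% unpenalized
    fit0 <- stats::glm.fit(cbind(`(Intercept)` = 1, X[, keep, drop = FALSE]),
                           arm, family = stats::binomial())
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    beta[keep] <- fit0$coefficients[-1]
    pi_hat <- as.numeric(stats::plogis(fit0$coefficients[1] + X %*% beta))
    return(new_ps_fit(fit0$coefficients[1], beta, pi_hat, Inf, NULL, NULL,
                      colnames(X)))
  }

  foldid <- make_foldid(patient_id, nfolds, seed)
  ridge <- glmnet::cv.glmnet(X, arm, family = "binomial", alpha = 0,
                             foldid = foldid, penalty.factor = pf_base,
                             standardize = FALSE, nlambda = 50)
  b0 <- as.numeric(stats::coef(ridge, s = "lambda.min"))[-1]
  w <- pf_base / (abs(b0) + eps)^gamma
  w[pf_base == 0] <- 0
  if (!is.null(lambda)) {
    las <- glmnet::glmnet(X, arm, family = "binomial", alpha = 1,
                          penalty.factor = w, standardize = FALSE,
                          lambda = sort(c(lambda, lambda + c(0.1, 0.01)),
                                        decreasing = TRUE),
                          thresh = 1e-12)
    cf <- stats::coef(las, s = lambda)
    sel_lambda <- lambda
    path <- las$lambda
    cvm <- NULL
  } else if (lambda_rule == "ebic") {
    las <- glmnet::glmnet(X, arm, family = "binomial", alpha = 1,
                          penalty.factor = w, standardize = FALSE)
    sel_lambda <- pick_lambda_ebic(las, nrow(X), ncol(X), ebic_gamma)
    cf <- stats::coef(las, s = sel_lambda)
    path <- las$lambda
    cvm <- NULL
  } else {
    las <- glmnet::cv.glmnet(X, arm, family = "binomial", alpha = 1,
                             foldid = foldid, penalty.factor = w,
                             standardize = FALSE, type.measure = "deviance")
    cf <- stats::coef(las, s = if (lambda_rule == "cv_min") "lambda.min"
                               else "lambda.1se")
    sel_lambda <- if (lambda_rule == "cv_min") las$lambda.min
                  else las$lambda.1se
    path <- las$lambda
    cvm <- las$cvm
  }
  cf <- as.numeric(cf)
  beta <- stats::setNames(cf[-1], colnames(X))
  pi_hat <- as.numeric(stats::plogis(cf[1] + X %*% beta))
  new_ps_fit(cf[1], beta, pi_hat, sel_lambda, path, cvm, colnames(X))
}

new_ps_fit <- function(intercept, beta, propensity, lambda, path, cvm,
                       columns) {
  structure(list(coef = c(`(Intercept)` = unname(intercept), beta),
                 propensity = propensity, lambda = lambda,
                 lambda_path = path, cv_deviance = cvm,
                 support = names(beta)[beta != 0], columns = columns),
            class = "ps_fit")
}

#' Predict propensities on new rows
#'
#' @param fit a `ps_fit`.
#' @param Xnew matrix with the same columns the fit was trained on.
#' @return vector of probabilities in (0, 1).
#' @export
predict_propensity <- function(fit, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) > 0 || length(fit$columns) > 0) {
    if (!identical(colnames(Xnew), fit$columns))
      stop("design columns do not match the propensity fit")
  }
  as.numeric(stats::plogis(fit$coef[1] + Xnew %*% fit$coef[-1]))
}

#' Fit an adaptive-LASSO Cox model for one arm
#'
#' Same two-stage scheme as the propensity model, on the Cox partial
#' likelihood with Breslow handling of tied event times. The Breslow
#' cumulative baseline hazard is computed at the final coefficients, so
#' conditional survival predictions `exp(-Lambda0(t) * exp(x'beta))` are
#' available; with no covariates the baseline reduces to the Nelson-Aalen
#' estimator.
#'
#' @inheritParams fit_adaptive_lasso_logistic
#' @param time,event follow-up times (> 0) and event indicators for the
#'   arm's patients.
#' @param arm_label optional label stored on the fit.
#' @return object of class `cox_fit`: list with `coef`, `basehaz`
#'   (data.frame `time`, `cumhaz`), `lambda`, `lambda_path`, `support`,
#'   `columns`, `arm_label`, `max_time`.
#' @export
fit_adaptive_lasso_cox <- function(X, time, event, patient_id = NULL,
                                   nfolds = 10, seed = 1, gamma = 1,
                                   eps = 1e-6, lambda = NULL,
                                   lambda_rule = c("ebic", "cv_min",
                                                   "cv_1se"),
                                   ebic_gamma = 0.5,
                                   arm_label = NULL) {
  lambda_rule <- match.arg(lambda_rule)
  X <- as.matrix(X)
  if (any(time <= 0)) stop("all follow-up times must be > 0")
  if (sum(event) < 1) stop("no events in this arm; cannot fit a Cox model")
  if (is.null(patient_id)) patient_id <- rownames(X)
  if (is.null(patient_id)) patient_id <- as.character(seq_len(nrow(X)))
  if (all(time == time[1]))
    warning("all follow-up times tied; Breslow ties approximation applied")
  y <- survival::Surv(time, event)

  if (!is.null(lambda) && is.infinite(lambda)) {
    beta <- stats::setNames(rep(0, ncol(X)), colnames(X))
    bh <- breslow_basehaz(time, event, rep(0, length(time)))
    return(new_cox_fit(beta, bh, Inf, NULL, colnames(X), arm_label,
                       max(time)))
  }
  foldid <- make_foldid(patient_id, nfolds, seed)
  if (!is.null(lambda)) {
    las <- glmnet::glmnet(X, y, family = "cox", alpha = 1,
                          lambda = sort(c(lambda, lambda + c(0.1, 0.01)),
                                        decreasing = TRUE),
                          standardize = FALSE, thresh = 1e-14)
    cf <- stats::coef(las, s = lambda)
    sel_lambda <- lambda
    path <- las$lambda
  } else {
    ridge <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 0,
                               foldid = foldid, standardize = FALSE,
                               nlambda = 50)
    b0 <- as.numeric(stats::coef(ridge, s = "lambda.min"))
    w <- 1 / (abs(b0) + eps)^gamma
    if (lambda_rule == "ebic") {
      las <- glmnet::glmnet(X, y, family = "cox", alpha = 1,
                            penalty.factor = w, standardize = FALSE)
      sel_lambda <- pick_lambda_ebic(las, nrow(X), ncol(X), ebic_gamma)
      cf <- stats::coef(las, s = sel_lambda)
    } else {
      las <- glmnet::cv.glmnet(X, y, family = "cox", alpha = 1,
                               foldid = foldid, penalty.factor = w,
                               standardize = FALSE,
                               type.measure = "deviance")
      cf <- stats::coef(las, s = if (lambda_rule == "cv_min") "lambda.min"
                                 else "lambda.1se")
      sel_lambda <- if (lambda_rule == "cv_min") las$lambda.min
                    else las$lambda.1se
    }
    path <- las$lambda
  }
  beta <- stats::setNames(as.numeric(cf), colnames(X))
  lp <- as.numeric(X %*% beta)
  bh <- breslow_basehaz(time, event, lp)
  new_cox_fit(beta, bh, sel_lambda, path, colnames(X), arm_label, max(time))
}

new_cox_fit <- function(beta, basehaz, lambda, path, columns, arm_label,
                        max_time) {
  structure(list(coef = beta, basehaz = basehaz, lambda = lambda,
                 lambda_path = path, support = names(beta)[beta != 0],
                 columns = columns, arm_label = arm_label,
                 max_time = max_time),
            class = "cox_fit")
}

#' Breslow cumulative baseline hazard
#'
#' `Lambda0(t) = sum over event times tj <= t of d_j / sum_{i at risk} exp(lp_i)`
#' with ties pooled (Breslow). With `lp = 0` this is the Nelson-Aalen
#' estimator.
#'
#' @param time,event follow-up data.
#' @param lp linear predictor per subject.
#' @return data.frame `time` (distinct event times, increasing), `hazard`
#'   (increment), `cumhaz`.
#' @export
breslow_basehaz <- function(time, event, lp) {
  ord <- order(time)
  t_s <- time[ord]; e_s <- event[ord]; r_s <- exp(lp[ord])
  # risk-set denominator just before each sorted time
  denom_all <- rev(cumsum(rev(r_s)))
  ev_times <- unique(t_s[e_s == 1])
  d <- tapply(e_s, t_s, sum)[as.character(ev_times)]
  first_at <- match(ev_times, t_s)  # risk set = everyone with time >= tj
  denom <- denom_all[first_at]
  haz <- as.numeric(d) / denom
  data.frame(time = ev_times, hazard = haz, cumhaz = cumsum(haz))
}

# Evaluate a cumulative-hazard step function at t (right-continuous).
eval_cumhaz <- function(basehaz, t) {
  if (nrow(basehaz) == 0) return(rep(0, length(t)))
  idx <- findInterval(t, basehaz$time)
  c(0, basehaz$cumhaz)[idx + 1]
}

#' Predict conditional survival from a Cox fit
#'
#' `S(t|x) = exp(-Lambda0(t) exp(x'beta))`; equals 1 at `t = 0` and is
#' non-increasing in `t`. For `t` beyond the last observed follow-up time
#' the value at the last step is returned and the result carries attribute
#' `extrapolated = TRUE`.
#'
#' @param fit a `cox_fit`.
#' @param Xnew design rows matching the fit's columns.
#' @param t horizon (single value or one per row).
#' @return vector of survival probabilities in (0, 1].
#' @export
predict_survival <- function(fit, Xnew, t) {
  if (any(t < 0)) stop("t must be >= 0")
  Xnew <- as.matrix(Xnew)
  if (ncol(Xnew) > 0 || length(fit$columns) > 0) {
    if (!identical(colnames(Xnew), fit$columns))
      stop("design columns do not match the Cox fit")
  }
  lp <- if (ncol(Xnew) == 0) rep(0, nrow(Xnew))
        else as.numeric(Xnew %*% fit$coef)
  ch <- eval_cumhaz(fit$basehaz, t)
  s <- exp(-ch * exp(lp))
  if (any(t > fit$max_time)) attr(s, "extrapolated") <- TRUE
  s
}

#' Unpenalized logistic propensity fit (reference / simulation fitter)
#'
#' Plain maximum-likelihood logistic regression, returned in the same
#' `ps_fit` form as the adaptive-LASSO fitter. `X = NULL` fits the
#' intercept-only (marginal) model, the deliberately misspecified
#' propensity in simulation scenarios.
#'
#' @param X design matrix or `NULL`.
#' @param arm binary treatment vector.
#' @return a `ps_fit`.
#' @export
fit_logistic <- function(X, arm) {
  arm <- as.numeric(arm)
  if (is.null(X) || ncol(as.matrix(X)) == 0) {
    p <- mean(arm)
    return(new_ps_fit(stats::qlogis(p), stats::setNames(numeric(0),
                                                        character(0)),
                      rep(p, length(arm)), NA_real_, NULL, NULL,
                      character(0)))
  }
  X <- as.matrix(X)
  fit <- stats::glm.fit(cbind(`(Intercept)` = 1, X), arm,
                        family = stats::binomial())
  beta <- stats::setNames(fit$coefficients[-1], colnames(X))
  new_ps_fit(fit$coefficients[1], beta, as.numeric(fit$fitted.values),
             NA_real_, NULL, NULL, colnames(X))
}

#' Unpenalized Cox fit with Breslow baseline (reference / simulation fitter)
#'
#' Wraps `survival::coxph` (Breslow ties) and attaches the in-package
#' Breslow baseline hazard, returned in the same `cox_fit` form as the
#' adaptive-LASSO fitter. `X = NULL` fits the null model (Nelson-Aalen
#' baseline), the deliberately misspecified outcome model in simulation
#' scenarios.
#'
#' @param X design matrix or `NULL`.
#' @param time,event follow-up data.
#' @param arm_label optional label stored on the fit.
#' @return a `cox_fit`.
#' @export
fit_cox_breslow <- function(X, time, event, arm_label = NULL) {
  if (any(time <= 0)) stop("all follow-up times must be > 0")
  if (sum(event) < 1) stop("no events in this arm; cannot fit a Cox model")
  if (is.null(X) || ncol(as.matrix(X)) == 0) {
    beta <- stats::setNames(numeric(0), character(0))
    bh <- breslow_basehaz(time, event, rep(0, length(time)))
    return(new_cox_fit(beta, bh, NA_real_, NULL, character(0), arm_label,
                       max(time)))
  }
  X <- as.matrix(X)
  fit <- survival::coxph(survival::Surv(time, event) ~ X,
                         ties = "breslow")
  beta <- stats::setNames(as.numeric(fit$coefficients), colnames(X))
  bh <- breslow_basehaz(time, event, as.numeric(X %*% beta))
  new_cox_fit(beta, bh, NA_real_, NULL, colnames(X), arm_label, max(time))
}

#' Cox partial log-likelihood and gradient (Breslow ties)
#'
#' Used for small-sample verification against brute-force risk-set
#' enumeration and for convergence diagnostics.
#'
#' @param beta coefficient vector.
#' @param X design matrix.
#' @param time,event follow-up data.
#' @return list with `loglik` and `gradient`.
#' @export
cox_partial_loglik <- function(beta, X, time, event) {
  X <- as.matrix(X)
  lp <- as.numeric(X %*% beta)
  r <- exp(lp)
  ll <- 0
  grad <- numeric(length(beta))
  for (tj in unique(time[event == 1])) {
    dead <- which(time == tj & event == 1)
    risk <- which(time >= tj)
    s0 <- sum(r[risk])
    s1 <- colSums(X[risk, , drop = FALSE] * r[risk])
    ll <- ll + sum(lp[dead]) - length(dead) * log(s0)
    grad <- grad + colSums(X[dead, , drop = FALSE]) - length(dead) * s1 / s0
  }
  list(loglik = ll, gradient = grad)
}

#' Serialize nuisance fits to a JSON-ready list
#'
#' Coefficients by column name, baseline hazard as (time, value) pairs, and
#' the lambda path, suitable for `jsonlite::write_json`.
#'
#' @param fit a `ps_fit` or `cox_fit`.
#' @return a plain list.
#' @export
serialize_fit <- function(fit) {
  if (inherits(fit, "ps_fit")) {
    list(type = "propensity", coef = as.list(fit$coef),
         lambda = fit$lambda, lambda_path = fit$lambda_path)
  } else if (inherits(fit, "cox_fit")) {
    list(type = "cox", arm = fit$arm_label, coef = as.list(fit$coef),
         lambda = fit$lambda, lambda_path = fit$lambda_path,
         baseline_cumhaz = list(time = fit$basehaz$time,
                                cumhaz = fit$basehaz$cumhaz))
  } else stop("not a nuisance fit")
}
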