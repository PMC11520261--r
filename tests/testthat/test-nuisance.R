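test_that("Cox partial likelihood and gradient match brute-force enumeration", {
  # 5 subjects with a tie at t = 2 (Breslow handling)
  X <- cbind(x1 = c(0.5, -1, 2, 0, 1), x2 = c(1, 0, -0.5, 2, 0.3))
  time <- c(1, 2, 2, 3, 4)
  event <- c(1, 1, 1, 0, 1)
  for (beta in list(c(0, 0), c(0.3, -0.2), c(-1, 0.5))) {
    got <- cox_partial_loglik(beta, X, time, event)
    want <- brute_cox_loglik(beta, X, time, event)
    expect_lt(abs(got$loglik - want$loglik), 1e-8)
    expect_lt(max(abs(got$gradient - want$gradient)), 1e-8)
  }
})

test_that("Breslow baseline with zero linear predictor is Nelson-Aalen", {
  set.seed(3)
  time <- rexp(40, 0.3)
  event <- rbinom(40, 1, 0.6)
  bh <- breslow_basehaz(time, event, rep(0, 40))
  na <- brute_nelson_aalen(time, event)
  expect_equal(bh$time, na$time)
  expect_equal(bh$cumhaz, na$cumhaz, tolerance = 1e-12)
  # the lambda -> Inf adaptive-LASSO Cox fit reduces to Nelson-Aalen exactly
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  fit <- fit_adaptive_lasso_cox(X, time, event, lambda = Inf)
  expect_equal(fit$coef, c(a = 0, b = 0))
  expect_equal(fit$basehaz$cumhaz, na$cumhaz, tolerance = 1e-12)
})

test_that("unpenalized fits agree with the reference implementation", {
  set.seed(11)
  n <- 300
  X <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, c("a", "b", "c")))
  time <- rexp(n, 0.2 * exp(0.5 * X[, 1] - 0.3 * X[, 2]))
  event <- rbinom(n, 1, 0.8)
  time <- pmax(time, 1e-6)
  ref <- survival::coxph(survival::Surv(time, event) ~ X, ties = "breslow")
  fit0 <- fit_adaptive_lasso_cox(X, time, event, lambda = 0)
  expect_lt(max(abs(fit0$coef - as.numeric(ref$coefficients))), 1e-6)
  fitb <- fit_cox_breslow(X, time, event)
  expect_lt(max(abs(fitb$coef - as.numeric(ref$coefficients))), 1e-10)
})

test_that("propensity predictions are consistent, bounded, and monotone", {
  set.seed(21)
  n <- 500
  X <- matrix(rnorm(2 * n), n, 2, dimnames = list(NULL, c("a", "b")))
  arm <- rbinom(n, 1, plogis(0.8 * X[, 1]))
  fit <- fit_adaptive_lasso_logistic(X, arm, seed = 2)
  expect_true(all(fit$propensity > 0 & fit$propensity < 1))
  expect_lt(max(abs(predict_propensity(fit, X) - fit$propensity)), 1e-12)
  # intercept-only (lambda -> Inf without forced columns): pi = arm fraction
  fit_inf <- fit_adaptive_lasso_logistic(X, arm, lambda = Inf)
  expect_equal(unique(round(fit_inf$propensity, 12)), round(mean(arm), 12))
  # monotone in a positive-coefficient column
  strong <- fit_logistic(X, arm)
  x_lo <- cbind(a = -1, b = 0); x_hi <- cbind(a = 1, b = 0)
  expect_gt(predict_propensity(strong, x_hi),
            predict_propensity(strong, x_lo))
  expect_error(predict_propensity(fit, X[, c(2, 1)]), "columns")
  expect_error(fit_adaptive_lasso_logistic(X, rep(1, n)), "single-arm")
})

test_that("survival predictions follow the hand-computed Breslow toy", {
  # 3 subjects: events at t = 1, 2, censored at 3, beta = 0
  # Lambda0(2) = 1/3 + 1/2, S(2) = exp(-5/6)
  time <- c(1, 2, 3); event <- c(1, 1, 0)
  fit <- fit_cox_breslow(NULL, time, event)
  X0 <- matrix(nrow = 3, ncol = 0)
  expect_equal(as.numeric(predict_survival(fit, X0, 2)),
               rep(exp(-(1 / 3 + 1 / 2)), 3), tolerance = 1e-12)
  expect_equal(as.numeric(predict_survival(fit, X0, 0)), rep(1, 3))
  # beyond the last observed time: flagged, value held at the last step
  s <- predict_survival(fit, X0, 10)
  expect_true(isTRUE(attr(s, "extrapolated")))
  expect_equal(as.numeric(s), as.numeric(predict_survival(fit, X0, 3)))
  # with beta = 0 all rows share the same curve
  set.seed(5)
  X <- matrix(rnorm(30), 10, 3, dimnames = list(NULL, c("a", "b", "c")))
  time2 <- rexp(10, 0.5); event2 <- rep(1, 10)
  fit2 <- fit_adaptive_lasso_cox(X, time2, event2, lambda = Inf)
  expect_equal(length(unique(predict_survival(fit2, X, 1))), 1)
  expect_error(fit_cox_breslow(NULL, time, c(0, 0, 0)), "no events")
  expect_error(fit_cox_breslow(NULL, c(-1, 2, 3), event), "> 0")
})

test_that("refits under row permutation give identical coefficients", {
  set.seed(31)
  n <- 400
  X <- matrix(rnorm(5 * n), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  ids <- sprintf("pt%04d", sample(n))
  arm <- rbinom(n, 1, plogis(X[, 1]))
  time <- pmax(rexp(n, 0.3 * exp(0.4 * X[, 2])), 1e-6)
  event <- rbinom(n, 1, 0.7)
  perm <- sample(n)
  f1 <- fit_adaptive_lasso_logistic(X, arm, patient_id = ids, seed = 4)
  f2 <- fit_adaptive_lasso_logistic(X[perm, ], arm[perm],
                                    patient_id = ids[perm], seed = 4)
  expect_equal(f1$coef, f2$coef, tolerance = 1e-12)
  c1 <- fit_adaptive_lasso_cox(X, time, event, patient_id = ids, seed = 4)
  c2 <- fit_adaptive_lasso_cox(X[perm, ], time[perm], event[perm],
                               patient_id = ids[perm], seed = 4)
  expect_equal(c1$coef, c2$coef, tolerance = 1e-12)
})

test_that("nuisance fits serialize to a JSON-ready structure", {
  time <- c(1, 2, 3); event <- c(1, 1, 0)
  fit <- fit_cox_breslow(NULL, time, event, arm_label = "insulin")
  s <- serialize_fit(fit)
  expect_equal(s$type, "cox")
  expect_equal(s$baseline_cumhaz$time, c(1, 2))
  txt <- jsonlite::toJSON(s, auto_unbox = TRUE, null = "null")
  expect_true(jsonlite::validate(txt))
})
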