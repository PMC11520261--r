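# Score-based treatment-effect heterogeneity: the personalized score S
# (model-based survival-probability difference between arms) and the
# score-specific average treatment effect curve.
#
# Sign conventions (used consistently package-wide): S = S1hat - S0hat, so
# positive S favors insulin; the CATE curve, like the overall ATE, is on
# the heart-failure-rate-difference scale (positive = insulin has the
# higher HF rate). Under correctly specified models CATE(s) is therefore
# close to -s.

#' Personalized insulin score
#'
#' `S_i = S_insulin(t|X_i) - S_comparator(t|X_i)`, the difference in
#' model-based t-year survival probability between the two arm-specific Cox
#' fits. Positive scores favor insulin.
#'
#' @param coxfit1,coxfit0 arm-specific `cox_fit`s sharing design metadata.
#' @param X design matrix.
#' @param t horizon.
#' @return numeric score vector in \[-1, 1\].
#' @export
compute_score <- function(coxfit1, coxfit0, X, t) {
  if (!identical(coxfit1$columns, coxfit0$columns))
    stop("the two Cox fits do not share design metadata")
  as.numeric(predict_survival(coxfit1, X, t)) -
    as.numeric(predict_survival(coxfit0, X, t))
}

#' Score-specific average treatment effect curve
#'
#' Local-constant (Nadaraya-Watson) Gaussian-kernel smoothing of the
#' per-patient doubly robust rate-difference contributions against the
#' score, evaluated on an equally spaced grid covering the 1st-99th
#' percentile of S. Pointwise standard errors come from the kernel-weighted
#' influence-function variance. The S histogram is returned alongside, as
#' in the usual presentation of score-based CATE results.
#'
#' @param S score vector (from [compute_score()], restricted to the same
#'   kept patients as the contributions).
#' @param contributions per-patient doubly robust contrast contributions on
#'   the HF-rate-difference scale (`psi0 - psi1` from an [aipw_ate()]
#'   result).
#' @param grid_size number of grid points (>= 50 enforced).
#' @param bandwidth kernel bandwidth; default Silverman's rule on S.
#' @param hist_bins bins for the S histogram.
#' @return object of class `cate_curve`: data.frame `score`, `cate`, `se`,
#'   `lower`, `upper`; attributes `bandwidth` and `histogram` (bin edges +
#'   counts).
#' @export
score_specific_ate <- function(S, contributions, grid_size = 50,
                               bandwidth = NULL, hist_bins = 30) {
  if (length(S) != length(contributions))
    stop("S and contributions are not aligned")
  sdS <- stats::sd(S)
  if (!is.finite(sdS) || sdS < 1e-8)
    stop("score is (near-)degenerate; treatment effect is constant in S - ",
         "use the overall ATE")
  n <- length(S)
  if (is.null(bandwidth)) {
    sigma <- min(sdS, stats::IQR(S) / 1.34)
    bandwidth <- 0.9 * sigma * n^(-1 / 5)
  }
  grid_size <- max(grid_size, 50)
  qs <- stats::quantile(S, c(0.01, 0.99), names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = grid_size)
  est <- se <- numeric(grid_size)
  for (g in seq_len(grid_size)) {
    kw <- stats::dnorm((S - grid[g]) / bandwidth)
    sw <- sum(kw)
    est[g] <- sum(kw * contributions) / sw
    se[g] <- sqrt(sum(kw^2 * (contributions - est[g])^2)) / sw
  }
  h <- graphics::hist(S, breaks = hist_bins, plot = FALSE)
  out <- data.frame(score = grid, cate = est, se = se,
                    lower = est - 1.96 * se, upper = est + 1.96 * se)
  attr(out, "bandwidth") <- bandwidth
  attr(out, "histogram") <- list(breaks = h$breaks, counts = h$counts)
  class(out) <- c("cate_curve", class(out))
  out
}

#' Subgroup doubly robust effects by score sign
#'
#' Recomputes the AIPW estimate within the score-defined subgroups
#' (default: `S > 0` vs `S <= 0`), reusing the nuisance fits from the full
#' cohort.
#'
#' @param S score vector over the full cohort rows.
#' @param time,event,arm,X full-cohort follow-up data and design.
#' @param psfit,coxfit1,coxfit0 full-cohort nuisance fits.
#' @param t horizon.
#' @param threshold score cut point (default 0).
#' @param trim_bounds propensity trimming bounds.
#' @return list with `high` (S > threshold), `low` (S <= threshold), both
#'   `ate_result`s, and `n_high`, `n_low`.
#' @export
subgroup_ate <- function(S, time, event, arm, X, psfit, coxfit1, coxfit0,
                         t = 5, threshold = 0, trim_bounds = c(0.01, 0.99)) {
  hi <- S > threshold
  if (all(hi) || all(!hi)) stop("a score subgroup is empty")
  pi_hat <- if (inherits(psfit, "ps_fit")) {
    if (length(psfit$propensity) == length(arm)) psfit$propensity
    else predict_propensity(psfit, X)
  } else as.numeric(psfit)
  run <- function(mask) {
    aipw_ate(time[mask], event[mask], arm[mask], X[mask, , drop = FALSE],
             pi_hat[mask], coxfit1, coxfit0, t = t,
             trim_bounds = trim_bounds)
  }
  list(high = run(hi), low = run(!hi),
       n_high = sum(hi), n_low = sum(!hi))
}
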