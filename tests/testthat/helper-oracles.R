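# Independent brute-force oracles, implemented without reference to the
# package internals.

# Cox partial log-likelihood with Breslow ties, by explicit enumeration of
# risk sets (double loop over subjects).
brute_cox_loglik <- function(beta, X, time, event) {
  X <- as.matrix(X)
  ll <- 0
  grad <- numeric(length(beta))
  for (i in seq_along(time)) {
    if (event[i] != 1) next
    risk <- which(time >= time[i])
    num <- sum(X[i, ] * beta)
    denom <- 0
    s1 <- numeric(length(beta))
    for (j in risk) {
      rj <- exp(sum(X[j, ] * beta))
      denom <- denom + rj
      s1 <- s1 + X[j, ] * rj
    }
    ll <- ll + num - log(denom)
    grad <- grad + X[i, ] - s1 / denom
  }
  list(loglik = ll, gradient = grad)
}

# Nelson-Aalen cumulative hazard by direct counting.
brute_nelson_aalen <- function(time, event) {
  tj <- sort(unique(time[event == 1]))
  ch <- cumsum(vapply(tj, function(t0) {
    sum(time == t0 & event == 1) / sum(time >= t0)
  }, numeric(1)))
  data.frame(time = tj, cumhaz = ch)
}

# Cox-de Boor recursion for a single B-spline basis function B_{i,k} on an
# augmented knot vector (0-based index i, order k = degree + 1).
cox_de_boor <- function(x, i, k, knots) {
  if (k == 1) {
    # right-closed at the final interval handled by the caller's nudge
    return(as.numeric(knots[i + 1] <= x & x < knots[i + 2]))
  }
  d1 <- knots[i + k] - knots[i + 1]
  d2 <- knots[i + k + 1] - knots[i + 2]
  t1 <- if (d1 > 0) (x - knots[i + 1]) / d1 * cox_de_boor(x, i, k - 1, knots) else 0
  t2 <- if (d2 > 0) (knots[i + k + 1] - x) / d2 * cox_de_boor(x, i + 1, k - 1, knots) else 0
  t1 + t2
}

# Full degree-d B-spline basis at points x via the recursion.
brute_bspline_basis <- function(x, inner_knots, degree) {
  aug <- c(rep(inner_knots[1], degree), inner_knots,
           rep(inner_knots[length(inner_knots)], degree))
  nb <- length(inner_knots) + degree - 1
  sapply(seq_len(nb) - 1, function(i) {
    vapply(x, function(xx) cox_de_boor(xx, i, degree + 1, aug), numeric(1))
  })
}

# PCA scores via explicit eigendecomposition of the correlation matrix.
brute_pca_scores <- function(x, k) {
  xs <- scale(as.matrix(x))
  eg <- eigen(stats::cov(xs), symmetric = TRUE)
  sc <- xs %*% eg$vectors[, seq_len(k), drop = FALSE]
  list(scores = sc, values = eg$values)
}

# Hand Kaplan-Meier product over distinct event times.
hand_km <- function(time, event, weights = rep(1, length(time))) {
  tj <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(tj))
  for (i in seq_along(tj)) {
    d <- sum(weights[time == tj[i] & event == 1])
    r <- sum(weights[time >= tj[i]])
    s <- s * (1 - d / r)
    out[i] <- s
  }
  data.frame(time = tj, surv = out)
}

# Small deterministic cohort fixture for estimator plumbing tests.
toy_cohort <- function(n = 400, seed = 7) {
  cfg <- sim_config(n_patients = n, n_phecode_features = 10,
                    phecode_prevalence_range = c(0.2, 0.6), seed = seed)
  generate_cohort(cfg)
}
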