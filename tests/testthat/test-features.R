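test_that("rare-feature filter uses a strict prevalence cutoff", {
  x <- data.frame(a = c(rep(1, 4), rep(0, 96)),   # prevalence 0.04
                  b = c(rep(2, 5), rep(0, 95)),   # prevalence 0.05 exactly
                  c = rep(1, 100))                # prevalence 1
  f <- filter_rare_features(x, 0.05)
  expect_equal(f$dropped, "a")
  expect_setequal(names(f$counts), c("b", "c"))
  # all features prevalent -> identity
  f2 <- filter_rare_features(x[c("b", "c")], 0.05)
  expect_equal(as.matrix(f2$counts), as.matrix(x[c("b", "c")]),
               ignore_attr = TRUE)
  expect_length(f2$dropped, 0)
  expect_error(filter_rare_features(x[0, ]), "empty")
  expect_error(filter_rare_features(data.frame(a = -1)), "non-negative")
})

test_that("lab imputation fills with the observed mean and reports", {
  r <- impute_labs_mean(data.frame(x = c(8, NA, 10)))
  expect_equal(r$labs$x, c(8, 9, 10))
  expect_equal(r$report$missing_fraction, 1 / 3)
  r2 <- impute_labs_mean(data.frame(x = c(7.5, NA, NA, 8.5)))
  expect_equal(r2$labs$x, c(7.5, 8, 8, 8.5))
  r3 <- impute_labs_mean(data.frame(x = 1:3))
  expect_equal(r3$report$missing_fraction, 0)
  expect_equal(r3$labs$x, 1:3)
  expect_error(impute_labs_mean(data.frame(bad = c(NA_real_, NA_real_))),
               "bad")
})

test_that("comorbidity PCA matches a brute-force eigendecomposition", {
  set.seed(42)
  x <- matrix(rpois(50, 2), 10, 5, dimnames = list(NULL, paste0("f", 1:5)))
  p <- comorbidity_pca(x, 3)
  oracle <- brute_pca_scores(x, 3)
  for (k in 1:3) {
    # sign convention may differ from the raw eigenvector
    expect_lt(min(max(abs(p$scores[, k] - oracle$scores[, k])),
                  max(abs(p$scores[, k] + oracle$scores[, k]))), 1e-8)
  }
  # orthogonality of score columns
  g <- crossprod(scale(p$scores, scale = FALSE))
  expect_lt(max(abs(g[upper.tri(g)])), 1e-8)
  # deterministic sign: largest-magnitude loading positive
  for (k in 1:3) {
    v <- p$loadings[, k]
    expect_gt(v[which.max(abs(v))], 0)
  }
})

test_that("rank-deficient comorbidity matrices error by default, zero on request", {
  base <- c(1, 2, 3, 4, 5)
  x <- outer(base, c(1, 2, 3))   # rank 1
  colnames(x) <- paste0("f", 1:3)
  expect_error(comorbidity_pca(x, 3), "rank")
  p <- comorbidity_pca(x, 3, on_rank_deficiency = "zero")
  v <- p$sdev^2
  expect_equal(v[1] / sum(v), 1, tolerance = 1e-10)
  expect_lt(max(abs(p$scores[, 2:3])), 1e-8)
})

test_that("age basis: partition of unity, clamping, determinism, degeneracy", {
  set.seed(7)
  age <- rnorm(500, 65, 10)
  b <- age_spline_basis(age)
  expect_equal(ncol(b), 3)
  expect_lt(max(abs(rowSums(b) - 1)), 1e-10)
  # identical ages give identical rows
  b2 <- age_spline_basis(c(60, 60, 80), knots = attr(b, "knots"))
  expect_equal(b2[1, ], b2[2, ])
  # out-of-domain ages are clamped to the boundary basis values
  kn <- attr(b, "knots")
  b3 <- age_spline_basis(c(kn[1] - 20, kn[3] + 20), knots = kn)
  expect_lt(max(abs(rowSums(b3) - 1)), 1e-10)
  expect_equal(unname(b3[1, 1]), 1, tolerance = 1e-9)
  expect_error(age_spline_basis(rep(50, 10)), "degenerate")
  expect_error(age_spline_basis(c(50, NA, 60)), "finite")
})

test_that("age basis matches an independent Cox-de Boor recursion", {
  kn <- c(50, 65, 80)
  x <- c(51.3, 57.9, 64.99, 65.01, 72.5, 79.2)
  b <- age_spline_basis(x, knots = kn, degree = 1)
  oracle <- brute_bspline_basis(x, kn, degree = 1)
  expect_lt(max(abs(b - oracle)), 1e-10)
  # a higher-degree basis obeys the same recursion
  kn4 <- c(50, 60, 70, 80)
  x2 <- c(52.1, 63.7, 68.2, 77.9)
  b2 <- age_spline_basis(x2, knots = kn4, degree = 2)
  oracle2 <- brute_bspline_basis(x2, kn4, degree = 2)
  expect_equal(ncol(b2), 5)
  expect_lt(max(abs(b2 - oracle2)), 1e-10)
})

test_that("design matrix: column count, interaction identity, zero columns", {
  set.seed(9)
  n <- 200
  covs <- data.frame(u = rnorm(n), v = rnorm(n, 5, 2),
                     w = rbinom(n, 1, 0.4), z = rpois(n, 2))
  b <- age_spline_basis(rnorm(n, 65, 9))
  X <- build_design_matrix(covs, b)
  expect_equal(ncol(X), 3 * (1 + 4))
  # basis partition of unity => interactions of Xj sum rowwise to
  # standardized Xj
  meta <- attr(X, "metadata")
  for (nm in c("u", "v", "z")) {
    cols <- meta$column[meta$covariate == nm]
    xstd <- (covs[[nm]] - meta$center[meta$covariate == nm][1]) /
      meta$scale[meta$covariate == nm][1]
    expect_lt(max(abs(rowSums(X[, cols]) - xstd)), 1e-10)
  }
  # binary covariates are not standardized
  wc <- meta[meta$covariate == "w", ]
  expect_equal(wc$center[1], 0)
  expect_equal(wc$scale[1], 1)
  # constant-zero covariate -> its interaction columns dropped with warning
  covs0 <- cbind(covs, q = 0)
  expect_warning(X0 <- build_design_matrix(covs0, b), "q")
  expect_equal(ncol(X0), 15)
  expect_error(build_design_matrix(covs[1:100, ], b), "misalignment")
  covs_na <- covs; covs_na$u[1] <- NA
  expect_error(build_design_matrix(covs_na, b), "missing")
})

test_that("feature pipeline is deterministic and row-order equivariant", {
  co <- toy_cohort(300, seed = 12)
  f1 <- build_features(co)
  f2 <- build_features(co)
  expect_identical(f1$X, f2$X)
  set.seed(5)
  perm <- sample(nrow(co))
  f3 <- build_features(co[perm, ])
  expect_equal(unclass(f3$X), unclass(f1$X)[perm, ], ignore_attr = TRUE)
})
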