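# Model-ready design construction shared by the propensity and outcome
# models: prevalence filtering of sparse comorbidity counts, mean imputation
# of labs, comorbidity principal components, an age-spline basis, and the
# basis-by-covariate interaction expansion.

#' Drop rare phecode count features
#'
#' Feature prevalence is the fraction of patients with a nonzero count;
#' features with prevalence strictly below `threshold` are dropped (a
#' feature at exactly the threshold is retained).
#'
#' @param phecode_counts patient-by-feature count data.frame or matrix.
#' @param threshold prevalence cutoff (default 0.05).
#' @return list with `counts` (filtered table), `dropped` (feature names),
#'   and `prevalence` (named vector).
#' @export
filter_rare_features <- function(phecode_counts, threshold = 0.05) {
  x <- as.matrix(phecode_counts)
  if (nrow(x) == 0) stop("empty cohort: no rows in phecode_counts")
  if (any(x < 0)) stop("phecode counts must be non-negative")
  prev <- colMeans(x > 0)
  drop <- prev < threshold
  list(counts = as.data.frame(x[, !drop, drop = FALSE]),
       dropped = colnames(x)[drop],
       prevalence = prev)
}

#' Mean-impute missing laboratory values
#'
#' Each missing entry is replaced by the observed-value mean of its column,
#' computed on the analysis cohort.
#'
#' @param labs data.frame of lab columns, possibly with `NA`s.
#' @return list with `labs` (complete columns) and `report` (per-column
#'   missing fraction and imputed mean).
#' @export
impute_labs_mean <- function(labs) {
  out <- as.data.frame(labs)
  rep_ <- data.frame(column = names(out),
                     missing_fraction = NA_real_, imputed_mean = NA_real_)
  for (j in seq_along(out)) {
    v <- out[[j]]
    if (all(is.na(v)))
      stop("lab column fully missing: ", names(out)[j])
    m <- mean(v, na.rm = TRUE)
    rep_$missing_fraction[j] <- mean(is.na(v))
    rep_$imputed_mean[j] <- m
    v[is.na(v)] <- m
    out[[j]] <- v
  }
  list(labs = out, report = rep_)
}

#' First three principal components of the comorbidity counts
#'
#' Columns are centered and scaled to unit variance (correlation PCA; count
#' scales differ by orders of magnitude) before the eigendecomposition. Each
#' component's sign is fixed so its largest-magnitude loading is positive.
#'
#' @param counts filtered phecode count table (>= 3 features, >= 4
#'   patients).
#' @param n_components number of leading components (default 3).
#' @param on_rank_deficiency `"error"` (default) stops when the matrix rank
#'   is below `n_components`, suggesting fewer components; `"zero"` returns
#'   the requested components with (numerically) zero scores beyond the
#'   rank.
#' @return list with `scores` (n x k matrix, columns `PC1..PCk`),
#'   `loadings`, `sdev`, and `center`/`scale` for reuse.
#' @export
comorbidity_pca <- function(counts, n_components = 3,
                            on_rank_deficiency = c("error", "zero")) {
  on_rank_deficiency <- match.arg(on_rank_deficiency)
  x <- as.matrix(counts)
  if (ncol(x) < n_components)
    stop("need at least ", n_components, " features after filtering")
  if (nrow(x) < 4) stop("need at least 4 patients for the comorbidity PCA")
  pr <- stats::prcomp(x, center = TRUE, scale. = TRUE)
  if (sum(pr$sdev > 1e-10) < n_components && on_rank_deficiency == "error")
    stop("comorbidity matrix rank < ", n_components,
         "; request fewer components")
  k <- n_components
  load <- pr$rotation[, seq_len(k), drop = FALSE]
  flip <- apply(load, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  load <- sweep(load, 2, flip, `*`)
  scores <- sweep(pr$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  colnames(scores) <- colnames(load) <- paste0("PC", seq_len(k))
  list(scores = scores, loadings = load, sdev = pr$sdev,
       center = pr$center, scale = pr$scale)
}

#' Age spline basis with equally spaced knots
#'
#' B-spline basis on `n_knots` equally spaced knots between the 5th and 95th
#' percentile of age, covering most of the age domain. The default degree-1
#' basis on 3 knots yields exactly 3 basis columns that form a partition of
#' unity (each row sums to 1), so models carry 3 sets of coefficients: the
#' age-basis columns and their interactions with every other covariate. Ages
#' outside the knot span are clamped to the boundary.
#'
#' @param age numeric vector of ages (years).
#' @param n_knots number of equally spaced knots (default 3).
#' @param degree spline degree (default 1; basis size is
#'   `n_knots + degree - 1`).
#' @param knots optional explicit knot locations (overrides the percentile
#'   placement; used to re-evaluate a stored basis on new data).
#' @return matrix with `n_knots + degree - 1` columns `B1..Bk`; attribute
#'   `knots` records the knot locations.
#' @export
age_spline_basis <- function(age, n_knots = 3, degree = 1, knots = NULL) {
  if (any(!is.finite(age))) stop("ages must be finite")
  if (is.null(knots)) {
    qs <- stats::quantile(age, c(0.05, 0.95), names = FALSE)
    if (diff(qs) <= 0) stop("degenerate age vector: no spread between P5 and P95")
    knots <- seq(qs[1], qs[2], length.out = n_knots)
  }
  ord <- degree + 1
  aug <- c(rep(knots[1], degree), knots, rep(knots[length(knots)], degree))
  x <- pmin(pmax(age, knots[1]), knots[length(knots)])
  # splineDesign is open on the right boundary; nudge boundary values in
  x[x >= knots[length(knots)]] <- knots[length(knots)] - 1e-9 * diff(range(knots))
  b <- splines::splineDesign(aug, x, ord = ord)
  colnames(b) <- paste0("B", seq_len(ncol(b)))
  attr(b, "knots") <- knots
  attr(b, "degree") <- degree
  b
}

#' Build the shared age-interaction design matrix
#'
#' Columns are the `k` age-basis columns plus `k x p` interaction columns
#' `Bk:Xj` for each retained covariate. Because the basis sums to 1 per row,
#' the `k` interaction columns of a covariate sum rowwise to the covariate
#' itself, so constant-in-age effects stay representable. Continuous
#' covariates (more than two distinct values) are standardized to mean 0,
#' SD 1 before interaction; binary covariates are left as-is for
#' interpretability of balance diagnostics. Standardization statistics are
#' computed on the supplied (full-analysis) cohort and stored in the column
#' metadata for reuse.
#'
#' @param covariates data.frame of non-age baseline covariates (demographics,
#'   labs, medication counts, comorbidity PCs, ...), complete (no `NA`).
#' @param basis age basis from [age_spline_basis()], row-aligned.
#' @param standardize_stats optional list with `center`/`scale` named
#'   vectors from a previous call (prediction-time reuse).
#' @return object of class `design_matrix`: the numeric matrix, with
#'   attributes `metadata` (data.frame: column, basis index, covariate,
#'   center, scale) and `knots`.
#' @export
build_design_matrix <- function(covariates, basis, standardize_stats = NULL) {
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(basis))
    stop("row misalignment: covariates and basis differ in length")
  if (anyNA(covariates)) stop("covariates contain missing values; impute first")
  k <- ncol(basis)
  p <- ncol(covariates)
  ctr <- stats::setNames(numeric(p), names(covariates))
  scl <- stats::setNames(rep(1, p), names(covariates))
  xs <- as.matrix(covariates)
  for (j in seq_len(p)) {
    v <- xs[, j]
    is_binary <- length(unique(v)) <= 2
    if (!is.null(standardize_stats)) {
      ctr[j] <- standardize_stats$center[[colnames(xs)[j]]]
      scl[j] <- standardize_stats$scale[[colnames(xs)[j]]]
    } else if (!is_binary) {
      ctr[j] <- mean(v)
      scl[j] <- stats::sd(v)
      if (scl[j] < 1e-12) stop("covariate has zero variance: ", colnames(xs)[j])
    }
    xs[, j] <- (v - ctr[j]) / scl[j]
  }
  cols <- vector("list", 1 + p)
  cols[[1]] <- basis
  meta <- data.frame(column = colnames(basis),
                     basis_index = seq_len(k),
                     covariate = "(age basis)",
                     center = 0, scale = 1, stringsAsFactors = FALSE)
  for (j in seq_len(p)) {
    block <- basis * xs[, j]
    colnames(block) <- paste0(colnames(basis), ":", colnames(xs)[j])
    cols[[j + 1]] <- block
    meta <- rbind(meta, data.frame(
      column = colnames(block), basis_index = seq_len(k),
      covariate = colnames(xs)[j], center = unname(ctr[j]),
      scale = unname(scl[j]), stringsAsFactors = FALSE))
  }
  X <- do.call(cbind, cols)
  zero <- apply(X, 2, function(v) all(v == 0))
  if (any(zero)) {
    warning("dropping constant-zero design columns: ",
            paste(colnames(X)[zero], collapse = ", "))
    X <- X[, !zero, drop = FALSE]
    meta <- meta[!zero, , drop = FALSE]
  }
  if (any(!is.finite(X))) stop("non-finite entries in design matrix")
  structure(X, metadata = meta, knots = attr(basis, "knots"),
            class = c("design_matrix", class(X)))
}

#' Full feature pipeline from a cohort table
#'
#' Convenience wrapper: filters rare phecode features, mean-imputes labs,
#' computes the comorbidity PCs, evaluates the age basis, and assembles the
#' design matrix. By default the raw phecode counts enter the models only
#' through the three PCs (`include_phecodes_directly = TRUE` adds the
#' filtered counts as covariates too).
#'
#' @param cohort cohort table from [generate_cohort()] or [build_cohort()].
#' @param prevalence_threshold rare-feature cutoff (default 0.05).
#' @param n_pcs number of comorbidity PCs (default 3).
#' @param include_phecodes_directly include filtered counts as direct
#'   covariates (default `FALSE`).
#' @param n_knots,degree age-basis controls, see [age_spline_basis()].
#' @return list with `X` (the `design_matrix`), `covariates` (the processed
#'   covariate frame), `pca`, `imputation`, `filter`, `basis`.
#' @export
build_features <- function(cohort, prevalence_threshold = 0.05, n_pcs = 3,
                           include_phecodes_directly = FALSE,
                           n_knots = 3, degree = 1) {
  phe_cols <- grep("^phe", names(cohort), value = TRUE)
  lab_cols <- intersect(c("hba1c", "cholesterol", "hdl", "ldl"), names(cohort))
  med_cols <- intersect(c("metformin", "statins", "sulfonylureas",
                          "thiazolidinediones"), names(cohort))
  filt <- filter_rare_features(cohort[phe_cols], prevalence_threshold)
  imp <- impute_labs_mean(cohort[lab_cols])
  pca <- comorbidity_pca(filt$counts, n_pcs)
  covs <- data.frame(male = cohort$male, imp$labs,
                     disease_duration = cohort$disease_duration,
                     cohort[med_cols], pca$scores, check.names = FALSE)
  if (include_phecodes_directly) covs <- cbind(covs, filt$counts)
  basis <- age_spline_basis(cohort$age, n_knots = n_knots, degree = degree)
  X <- build_design_matrix(covs, basis)
  list(X = X, covariates = covs, pca = pca, imputation = imp,
       filter = filt, basis = basis)
}
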