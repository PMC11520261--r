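---
title: "Doubly robust estimation of 5-year heart-failure risk differences from claims data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Doubly robust estimation of 5-year heart-failure risk differences from claims data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drclaims)
```

## The estimand and the design

`drclaims` targets the 5-year average treatment effect of insulin versus an
alternative glucose-lowering class on incident heart failure (HF) in type 2
diabetes, defined on the HF-*rate* scale:

$$\mathrm{ATE}(t) = \big(1 - S_1(t)\big) - \big(1 - S_0(t)\big),$$

where $S_a(t)$ is the marginal probability of remaining HF-free to horizon
$t$ (default 5 years) had everyone received arm $a$ (1 = insulin). A
positive ATE means insulin carries the higher HF rate. Treatment is
assigned by a new-user, active-comparator (intention-to-treat) rule: a
patient's arm is the class of their earliest *sustained* therapy, where
sustained means a second fill of the same class 183–365 days after the
first; the first fill date is the index date. This guards against counting
quick therapy switches as exposure.

Identification requires no unmeasured confounding given the baseline
covariates, consistency, positivity (enforced in practice by propensity
trimming), and censoring independent of the event time given arm.

## Cohort curation rules and their edge cases

Dates are integer days; windows use 1 year = 365 days and 6 months = 183
days, with half-open baseline lookback $[\text{index}-365, \text{index})$
— an index-day diagnosis counts as post-index. Choices the source design
left open, fixed here:

* **Tie-breaking.** If two classes are sustained with the same first-fill
  date, the first label in `classes_of_interest` wins (a fixed, documented
  priority); with different first-fill dates the earlier one wins.
* **Exclusion attribution** is first-failing in the order
  no-arm → no-HbA1c → coverage → likely-T1DM → prior-HF, so attrition
  counts add up exactly to the input cohort size.
* **Likely type 1 diabetes** has no standard claims definition; the
  package uses a transparent proxy (more T1DM than T2DM diagnosis codes,
  or T1DM codes with none for T2DM). It is deliberately simple and
  testable rather than clinically definitive.
* **Coverage** requires ≥365 *cumulative* days of qualifying plan types;
  contiguity is not required.
* **Baseline labs** are summarized by the most recent value in the 1-year
  window — the clinically standard "baseline" — rather than a mean.
* Same-day HF events get follow-up time 0.5 day so times stay positive.

## The shared design matrix

All effects may vary with age. Age enters through a B-spline basis on 3
equally spaced knots covering the central 90% of the age distribution
(5th–95th percentile), with out-of-range ages clamped to the boundary. The
default basis is degree 1 (piecewise-linear "hat" functions): with 3 knots
this gives exactly **3 basis columns that sum to one at every age**, so a
model with the 3 basis columns plus their interactions with each covariate
carries three age-varying coefficient sets per covariate, and a
constant-in-age effect remains exactly representable (the interaction
columns of a covariate sum back to the covariate). A cubic basis with
interior knots is available via the `degree` argument but produces more
than three columns and is not the default.

Sparse phecode comorbidity counts are filtered at 5% prevalence (strictly
below 5% is dropped; exactly 5% is retained), and enter the models through
their first 3 principal components. The PCA is on standardized counts
(correlation PCA) because raw count scales differ by orders of magnitude;
component signs are fixed by making each component's largest-magnitude
loading positive. The raw filtered counts can be added as direct covariates
with `include_phecodes_directly = TRUE`, but the PC-only default keeps the
penalized fits stable at desk scale. Missing labs are mean-imputed on the
analysis cohort (matching the missing-completely-at-random generator);
continuous covariates are standardized once on the full cohort and the
statistics stored in the design metadata for reuse.

## Nuisance models: adaptive LASSO

Both the logistic propensity model and the two arm-specific Cox models
(Breslow tie handling — claims data have many same-day events) are fit by a
two-stage adaptive LASSO: a ridge fit supplies initial coefficients
$\tilde\beta$, then an L1 fit uses per-column penalty weights
$1/(|\tilde\beta_j| + 10^{-6})$. Ridge is used for the initial stage
because it is well defined when columns are many or collinear. The
intercept and the three age-basis columns are never penalized in the
propensity model: age is a forced confounder.

**Choosing the penalty.** The package selects $\lambda$ by extended BIC
along the path (deviance $+ \;\mathrm{df}\,(\log n + \log p)$ at the
default dimensionality weight 0.5). Cross-validation rules are available
(`lambda_rule = "cv_min"` or `"cv_1se"`, with a seeded 10-fold split keyed
to patient id so refits under row permutation are identical), but both CV
rules systematically admit a few spurious noise columns with tiny
coefficients — measured on pure-noise designs ($n = 5000$, $p = 50$), the
minimum-CV rule leaves all slopes at zero in only ~20–40% of replicates
and the 1-SE rule in ~65–100%, whereas the extended-BIC rule achieved it in
100% while always retaining strong true signals. Since the analysis leans
on sparse, stable nuisance models, selection consistency won over CV's
prediction-optimal shrinkage. The ridge initial stage still uses the
seeded 10-fold CV.

The Breslow cumulative baseline hazard is computed at the final
coefficients; with no covariates it reduces exactly to the Nelson–Aalen
estimator, which the tests exploit as an oracle. Conditional survival
predictions are $\hat S(t|x) = \exp(-\hat\Lambda_0(t)e^{x'\beta})$;
horizons beyond the last observed time return the last step with an
`extrapolated` flag.

## Doubly robust estimation

For each arm the per-patient pseudo-value is

$$\psi_i^a = \hat S_a(t|X_i) + \frac{I(A_i = a)}{\hat\pi_a(X_i)}\,
\frac{\tilde\Delta_i(t)}{\hat G_a(\min(\tilde T_i, t)^-)}
\Big(I(\tilde T_i > t) - \hat S_a(t|X_i)\Big),$$

with $\tilde\Delta_i(t) = I(\tilde T_i > t) + I(\tilde T_i \le t)\,\delta_i$
indicating that the $t$-year status is known, and $\hat G_a$ the
arm-specific Kaplan–Meier estimator of the censoring distribution,
evaluated as a left limit. Averaging $\psi^a$ over the trimmed cohort gives
$\hat S_a(t)$; the ATE is the difference of HF rates. This augmented-IPW
form with Kaplan–Meier censoring weights was chosen because the source
design's censoring treatment is unstated; it is standard, testable, and
consistent under independent censoring, and its double robustness — not a
formula match — is what the replicate studies validate. Standard errors
come from the empirical variance of the influence contributions
$(\psi^1_i - \psi^0_i)$ over $\sqrt n$, matching the analytic flavor of the
reported uncertainties; a seeded patient-level bootstrap of the
contributions is a cross-check, not a refit of the nuisance models.

Default trimming keeps propensities in $[0.01, 0.99]$ (trimming is known to
have occurred in the motivating analysis but no threshold is reported);
widening the bounds never decreases the analysis size. Weighted
Kaplan–Meier curves report $1 - S(t)$ per arm before and after weighting,
and the balance table reports standardized mean differences
$|\bar x_1 - \bar x_0| / \sqrt{(s_1^2 + s_0^2)/2}$ before and after, with a
0.1 flag threshold.

## Score-based heterogeneity

The personalized score is $S = \hat S_1(t|X) - \hat S_0(t|X)$ from the two
Cox fits: positive favors insulin. The score-specific effect curve is a
Nadaraya–Watson (Gaussian kernel, Silverman bandwidth) smoothing of the
per-patient doubly robust contrast contributions against $S$, on a
≥50-point grid over the central 98% of scores, with pointwise SEs from the
kernel-weighted influence variance; the $S$ histogram is returned
alongside. Recycling the influence contributions keeps the cost at
$O(n \times \text{grid})$; no sample-splitting is used by default.

**Sign conventions, stated once.** The curve is on the same
HF-rate-difference scale as the ATE, so under correctly specified models
$\mathrm{CATE}(s) \approx -s$: patients whose score *disfavors* insulin
($S \le 0$) are the ones with a positive (harmful) rate difference. The
package's subgroup contract is therefore: significance concentrated in the
score-disfavored subgroup, inconclusive effect in the score-favorable one.
Any presentation that pairs a positive CATE with a positive score is using
the opposite orientation for one of the two quantities; the package keeps
the internally consistent one.

## What the synthetic generator emulates — and what it does not

Defaults emulate a large US insulin vs GLP-1 RA claims cohort: ~75%
insulin share, age ≈ 65.4 (SD 10.3), 47% male, HbA1c 8.5 (1.2), standard
lipid panels with 5–15% missingness, 40 sparse zero-inflated-Poisson
phecode features with prevalence drawn from [0.01, 0.40] (so the 5% filter
has work to do), confounded treatment assignment with an age-varying HbA1c
effect, arm-specific Weibull proportional-hazards event times calibrated
to marginal 5-year HF rates of ≈29.1% (insulin) and ≈17.4% (comparator) —
an oracle ATE of ≈11.7 points — exponential censoring (0.25/year, median
follow-up ≈2.2 years) and an administrative end at 5.4 years. The Weibull
baseline is a deliberate choice the source never makes (it fits Cox models
without stating a generative model): it makes exact survival oracles
available in closed form or by Monte Carlo (`true_survival`, ≥10⁶ draws
with reported MC error).

Claim-stream mode scripts, per patient, sustained fills, quick switches
(~3-month refill), single fills, sustained use of an out-of-comparison
class, competing sustained classes, and exact first-fill ties, plus
pre-index HF, missing HbA1c, short coverage, and likely-T1DM conditions —
and records the arm, index date, exclusion reason, and outcome the
curation *should* produce, enabling exact round-trip tests.

Not emulated: real ICD vocabularies, treatment switching and adherence,
covariate-dependent censoring (available as an option but off by default —
the real mechanism, disenrollment vs administrative end, is unknown),
informative lab missingness, and calendar-time effects. Passing tests on
this generator therefore demonstrate the estimator's statistical
properties under its stated assumptions, not robustness to violations of
them.

## Numerical choices

* Problem sizes: the replicate double-robustness/calibration study runs
  200 replicates at $n = 5000$ with unpenalized nuisance fits on the
  generator's own four-column design ("correct") or intercept-only /
  covariate-free fits ("misspecified"); the end-to-end recovery check runs
  once at $n = 20{,}000$ through the full adaptive-LASSO spline pipeline;
  selection behavior uses 50 replicates at $n = 5000$, $p = 50$. These
  sizes give Monte Carlo error well inside the assertion margins.
* Convergence: glmnet threshold $10^{-12}$ for fixed-$\lambda$ fits;
  adaptive weights bounded by $\varepsilon = 10^{-6}$.
* Flatness testing for the CATE curve is multiplicity-aware: a uniform
  "every point within 2 pointwise SEs" rule on a 50-point grid falsely
  fails ~40% of constant-effect replicates (correlated excursions at the
  sparse grid edges), so the package asserts flatness on the data-dense
  central grid (scores within P10–P90): no excursion beyond 3.5 SE and
  fewer than 25% of points beyond 2 SE. Heterogeneous alternatives exceed
  10 SE with essentially all points outside, so the check retains power.
* Degenerate inputs: zero-variance covariates and fully-missing lab
  columns are errors; constant-zero design columns are dropped with a
  warning; rank-deficient comorbidity PCAs error by default
  (`on_rank_deficiency = "zero"` returns zero trailing components); a
  near-constant score (SD < 1e-8) aborts the CATE curve with advice to
  use the overall ATE, and `run_comparison` then simply omits the
  heterogeneity outputs.
* Subgroup splitting in `run_comparison` uses $S > 0$ when both sign
  subgroups hold ≥1% of patients, else a median split (recorded in the
  result) — under near-uniform scores a sign split would pit a handful of
  extreme patients against everyone else.

## Known limitations

Single binary comparison per run (a multinomial propensity extension is
out of scope); no competing-risk handling of death; no time-varying
exposure; IPCW assumes censoring independent of event time within arm;
the bootstrap resamples influence contributions rather than refitting the
nuisance models; and the likely-T1DM exclusion is a proxy. On real claims,
code-mapping quality and disenrollment patterns will matter in ways the
synthetic tests cannot certify.
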