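---
title: "Residual cognitive reserve and moderated sequential mediation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Residual cognitive reserve and moderated sequential mediation: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reservemed)
```

## The scientific problem

Cognitive reserve is the hypothesised property that lets some people perform
better than expected given the state of their brain.  The *residual
approach* operationalises it directly: regress a memory composite on
demographics and brain-integrity measures, and read the part of performance
the predictors cannot explain — the **residual reserve index (MEMR)** — as
the expression of reserve.  A subject with a large positive residual
performs better than their brain volumes and AD biomarkers predict.

`reservemed` implements the full two-stage analysis used to study how this
index interacts with the AT(N) biomarker cascade of Alzheimer's disease
(Amyloid: CSF A&beta;42/A&beta;40, lower = more pathology; Tau: plasma
p-tau181, higher = more pathology; Neurodegeneration: FDG metabolism in
AD-signature regions, lower = more neurodegeneration):

1. **Decomposition stage.** A structural model splits baseline memory into
   a linear predictor (age, sex, education, APOE &epsilon;4 count,
   TIV-corrected hippocampal and whole-brain volume, log WMH volume,
   baseline amyloid ratio, p-tau181 and FDG), a latent residual MEMR
   constrained to be uncorrelated with every predictor, and a *fixed*
   measurement-error variance &theta; = 0.161 taken from external
   reliability work.  Freeing &theta; would confound measurement noise with
   reserve; fixing it makes MEMR an error-purged residual.
2. **Moderated sequential mediation stage.**  Baseline amyloid (X) predicts
   executive-function growth both directly and through tau at the first
   follow-up (M1) and FDG metabolism at the second (M2):
   `X -> M1 -> M2 -> EF`.  EF over eight annual visits is a latent linear
   growth model (random intercept centred at the third follow-up, random
   slope per year).  MEMR (W) moderates every mediation path, following the
   PROCESS "Model 92" tradition in which products of the focal variables
   with the moderator enter each equation as fixed regressors.

The conditional indirect effects at moderator value `w` are products of
conditional paths,

- `B_AT(w)  = (a1 + a1w·w)(b1 + b1w·w)`
- `B_ATN(w) = (a1 + a1w·w)(d21 + d21w·w)(b2 + b2w·w)`
- `B_AN(w)  = (a2 + a2w·w)(b2 + b2w·w)`

and for a recursive linear system they satisfy, at every `w`,
`total = direct + B_AT + B_ATN + B_AN` exactly — the package treats this as
a tested invariant, not a numerical coincidence.  The **index of moderated
mediation (IMM)** is the derivative of a conditional indirect effect with
respect to `w`.  When only one path on a pathway is moderated it is the
familiar product (`IMM_AN = a2w·b2`); when several paths are moderated the
conditional effect is curved in `w`, a single number no longer summarises
it, and the package reports the derivative at a stated `w` (default: the
moderator mean) — the conditional-effect table over the grid is the more
complete summary in that case.

## Estimation machinery

**Full-information likelihood.**  All missing-data likelihoods go through
two primitives: the marginal multivariate-normal log-likelihood over each
row's observed cells, and EM estimation of the saturated mean/covariance
(ML divisor `n`).  The saturated model doubles as the H1 reference for
likelihood-ratio fit statistics (chi-square, RMSEA with its noncentral
chi-square 90% CI, CFI, TLI) and SRMR.  Conventions that differ across
software are explicit arguments: the RMSEA denominator defaults to `n - 1`
(the classic formula; `n` is available), and SRMR is computed over
covariance residuals only by default, with mean residuals available via a
flag.

**Zero-covariance constraints.**  The decomposition model is saturated when
unconstrained, so its fit statistics are driven entirely by the
covariances fixed to zero (mirroring the practice of zeroing
non-significant correlations to stabilise estimation;
`auto_zero_cov()` reproduces that selection rule).  Constrained saturated
models are estimated by EM whose M-step runs iterative conditional fitting
on the expected sufficient statistics, which is exact ML under the
constraints — each sweep solves the per-variable pseudo-regression exactly,
so the likelihood increases monotonically.

**Growth block.**  The EF likelihood is the marginal normal of each
subject's observed visits with covariance `Z Psi Z' + Theta`,
`Z = [1, t - 3]`.  Subjects are grouped by EF missingness pattern and the
mean parameters are profiled out by generalised least squares on
pattern-level cross products, leaving a four-dimensional optimisation
(log-Cholesky factor of `Psi`, log residual variance; per-visit residual
variances are available via `ef_variance = "by_time"`).  An analytic
gradient (envelope theorem) drives `nlminb`; bootstrap refits additionally
whiten the variance parameters with the full-data Hessian and restart from
the full-data optimum, which makes a refit a few milliseconds without
changing the estimator (point estimates agree with cold-started fits to
~1e-13).  The log-Cholesky parameterisation keeps `Psi` inside the positive
semi-definite cone by construction, so no constraint handling is needed.

**Standard errors.**  Mediator-block SEs are the usual ML regression form;
growth fixed-effect SEs are `(X' V-hat^{-1} X)^{-1}` at the ML variance
parameters, and variance-parameter SEs come from the numerical Hessian of
the profiled likelihood.  These model-based SEs condition on the estimated
variance parameters, the standard ML practice; small-sample refinements of
the Kenward–Roger type are deliberately out of scope.

**Bayesian plausible values.**  Using a single factor-score estimate of
MEMR ignores factor-score indeterminacy, so the decomposition is
re-estimated by a Gibbs sampler that draws the latent residual explicitly:
(i) per-subject MEMR from `N(r·(mem - x'beta), r·theta)` with
`r = psi/(psi+theta)`; (ii) coefficients from their conjugate normal;
(iii) `psi` from its conjugate inverse-gamma; (iv) `theta` by a
random-walk Metropolis step targeting the likelihood times the highly
informative `N(0.161, 0.00002)` prior truncated to the positives — a
normal prior on a variance is unusual, but it is honoured literally
because it is the stated prior; (v) missing predictor cells from their
exact full conditional: the ML saturated predictor model acts as the
prior and, for rows with observed memory, the memory likelihood enters as
a rank-one precision update.  Conditioning on the observed predictors
alone would not be a valid Gibbs kernel — it attenuates the coefficient
draws whenever predictors are missing at scale and drives the posterior
predictive p-value to zero on correctly specified data.  (Binary
predictors are treated as numeric in this step, a documented
approximation.)  Chains start at the ML solution.  Convergence is monitored with the
Gelman–Rubin potential scale reduction factor on the second half of each
chain (gate: below 1.1), model adequacy with a posterior predictive
p-value whose discrepancy is the likelihood-ratio distance between a
dataset's saturated moments and a draw's implied moments.  Replicated
datasets keep the predictors fixed and redraw memory conditionally;
replicating the predictor block too would add saturated-fit noise on only
one side of the comparison and push the PPP to 1 regardless of fit.  Note
that because `psi` is free, a too-small fixed `theta` is absorbed rather
than detected; the misfit this PPP can see is an error variance pinned
*above* the achievable residual.

`M = 30` plausible-value vectors are stored at equally spaced post-burn-in
iterations alternating across chains (spacing reduces autocorrelation
between saved sets).  Their reliability is summarised by ICC(2,k) — the
two-way random-effects, absolute-agreement, average-measures intraclass
correlation — with a McGraw–Wong F-based confidence interval.

**Inference across imputations.**  The mediation model is fitted once per
plausible-value set and pooled by Rubin's rules with Barnard–Rubin
degrees of freedom (correct small-M behaviour at M = 30).  Because
bootstrapping within each imputed dataset is not meaningful for the
product-of-paths effects, the bias-corrected bootstrap (case resampling of
subjects, B = 2000 by default, half-count tie convention in the bias
probit, interval endpoints by type-6 empirical quantiles) is run on a model
that uses each subject's average plausible value — the same two-track
design as the original analysis.  With bias `z0 = 0` the BC interval
equals the percentile interval on the same resamples, another tested
identity.

## The synthetic cohort generator

Access to the motivating cohort data is restricted, so the package ships a
generative model with known ground truth (`true_params()`,
`cohort_config()`): every downstream stage is validated by parameter
recovery rather than by reproducing published point estimates.

The generator emulates an ADNI-like ageing cohort: demographic and
biomarker marginals follow published descriptive statistics of such a
cohort (age 73.10 (7.27) years; 52.9% male; education 16.06 (2.75) years;
APOE &epsilon;4 allele distribution ~53/37/10%; TIV, hippocampal,
whole-brain and log-normal WMH volumes with realistic TIV and age
dependence; CSF amyloid ratio mean shifting down with &epsilon;4 dose;
plasma p-tau181 and FDG SUVR marginals at their respective visits).  The
recursive structure mirrors the analysis model: amyloid &rarr; latent
reserve &rarr; tau(T1) &rarr; FDG(T2) &rarr; memory and the EF growth
curve, with T0 companion biomarkers correlated 0.8 with their
analysis-time copies (only their cross-sectional association matters, as
they appear only in the decomposition).  Structural coefficients are
expressed per SD of z-scored biomarkers and a unit-variance standardized
reserve; the defaults (`a1 = -0.33`, total amyloid&rarr;FDG effect
&asymp; +0.34) reproduce the reported magnitude of "one third of an SD of
downstream pathology per SD of amyloid", and the single active interaction
`a2w = -0.15` with `b2_I = 0.40`, `b2_S = 0.05` gives
`IMM_AN(intercept) = -0.060` and `IMM_AN(slope) = -0.0075` — the same
signs and order of magnitude as the published ADNI estimates, chosen as a
plausible calibration, not as a claim about the restricted data.  This
calibration produces the qualitative crossover that motivates the model:
the reserve–metabolism association is positive under high amyloid
pathology and negative under low pathology, with predicted EF favouring
high reserve most strongly under high pathology.

Missingness emulates the study architecture: a configurable subsample
(default 332/2351) keeps complete mediation biomarkers;
decomposition-stage predictors are missing at Table-like per-variable
rates outside it; and the EF series drops out monotonically with a
per-visit logistic hazard in the previous observed EF value and age (MAR),
so FIML growth estimation remains consistent and recovery tests are
interpretable.  What the generator does *not* emulate: visit-window
jitter, non-monotone intermittent missingness, floor/ceiling effects and
non-normal biomarker tails (raw p-tau is generated as a location-scale
normal, which admits occasional non-physical negative values in the far
tail), practice effects on the composites, and any MNAR dropout.  Passing
recovery tests therefore certify the estimators under a clean MAR
Gaussian world, not robustness to those real-data features.

Exact model-implied moments of the mediators, EF series and growth factors
are available algebraically (`implied_growth_moments()`, an
Isserlis-moment expansion over the independent shocks, exact even with the
interaction products), and the generator's empirical covariance is tested
against them — a check against algebra rather than against a second
simulation.

## Numerical choices and degenerate inputs

- EM convergence: 1e-8 in log-likelihood units, 500 iterations maximum
  (non-convergence flags rather than fails); likelihood monotonicity is a
  tested property.
- `psi` below its boundary (memory residual smaller than the fixed error
  variance) is clipped to zero with a boundary warning, and its SE is
  reported missing; interpretability of the reserve index takes precedence
  over allowing a negative variance.
- Chi-square statistics are floored at zero when H0 and H1 numerically
  cross; CFI is clipped to [0, 1]; RMSEA is 0 whenever chi-square &le; df.
- Singular information matrices yield per-parameter missing SEs (flat
  directions identified from the null eigenvectors), never a failure.
- Collinear decomposition predictors (condition number above 1e10) are
  rejected by name; zero-variance variables raise degenerate-scale errors.
- The bias probit `z0` is clamped away from the ±&infin; that an extreme
  bootstrap count would produce; degenerate bootstrap distributions return
  a collapsed interval with a warning; more than 5% failed resamples is an
  error.
- All randomness is seed-derived: cohort generation, missingness, Gibbs
  chains (per-chain streams), bootstrap resampling and the pipeline's
  per-stage seeds are deterministic functions of one integer seed, and the
  end-to-end pipeline reproduces its outputs bit-for-bit.

## Design choices where the design was open

- **Estimating the decomposition by the saturated-joint route.**  FIML for
  this model class is exactly the saturated joint (predictors, memory)
  moments plus algebraic extraction of the regression; this is both exact
  ML and directly testable against OLS on complete data.
- **Which correlations to zero.**  The original selection of fixed-to-zero
  correlations is not enumerable from outside; the constraint list is
  user-supplied, with `auto_zero_cov()` implementing the "not significant,
  then fixed to zero" rule as a default procedure.
- **Moderator scale.**  Whether biomarkers and moderator were z-scored
  before entry is implied by SD-unit language in the source analyses;
  `mediation_spec(standardize = TRUE)` is the default, with raw-scale
  entry available.
- **EF residual structure.**  A single shared residual variance is the
  default (the original choice is not stated); per-visit variances are one
  flag away.
- **IMM with several moderated paths.**  Reported as the derivative at a
  stated `w` plus the conditional-effect grid, since a single constant no
  longer exists in that case.
- **Monte-Carlo problem sizes.**  Validation experiments use cohorts of
  n = 332 (the analysis-subset size) for recovery, type-I-error and
  sign-pattern studies — 100–500 replicates for recovery summaries, 400
  replicates with B = 500 for bootstrap calibration, 20 replicates for
  PPP calibration, and n = 10,000 single cohorts for moment checks; these
  sizes give Monte-Carlo standard errors comfortably inside the asserted
  tolerances.  The coverage study uses 500 replicates because per-
  coefficient coverage bands of a few percent require coverage estimates
  with ~1% Monte-Carlo error to be meaningful.

## Known limitations

- Product terms involving endogenous mediators are fixed regressors (the
  PROCESS estimation tradition); a full distributional treatment of latent
  interactions is out of scope.
- The Gibbs sampler's missing-predictor step conditions on observed
  predictors only (not on memory), and treats binary predictors as
  numeric; both are documented approximations of convenience with
  negligible effect at the missingness rates emulated here.
- Model-based SEs condition on estimated variance parameters; no sandwich
  or small-sample-corrected covariance is provided.
- Fit indices for the mediation model compare against an H1 multivariate
  regression with a common residual covariance; under strong moderation
  the H0 model is not strictly nested in this H1 (its implied conditional
  covariance varies with the moderator), which is the standard situation
  for product-term models and is handled by the conventional zero floor on
  the chi-square.
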