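---
title: "Estimating center-level effects among the treated: models, machinery, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating center-level effects among the treated}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ettmachine)
```

## The estimand

For a patient-level observational cohort with a binary center-level
exposure $S$ (1 = treated at a large-volume trauma center), outcome $Y$
and confounders $C$, the package targets the effect of treatment among
the treated (ETT, also written ATT):

$$\psi \;=\; E\!\left[\, E(Y \mid S = 1, C) - E(Y \mid S = 0, C)
  \;\middle|\; S = 1 \right].$$

This is the expected change in outcome for the patients actually treated
at large-volume centers had they, covariates held fixed, been treated at
small-volume centers instead.  Averaging over the treated (rather than
the whole cohort) keeps the parameter interpretable when the two
patient populations differ substantially, and makes it directly
comparable to a matching estimator that pairs each treated patient with
controls.

Identification requires the usual assumptions: no unmeasured confounding
given the observed basis (including the missingness indicators, see
below), positivity ($P(S = 1 \mid C)$ bounded away from 1 on the support
of the treated), and consistency of the counterfactuals.  None of these
are testable from the data; the synthetic-cohort module exists precisely
so the machinery can be exercised where they hold by construction.

## Missing covariates: the indicator basis

Rather than imputing, each sometimes-missing covariate $C_j$ is replaced
by the fully observed pair $(\Delta_j,\ \Delta_j C_j)$, where
$\Delta_j = 1$ when the value was recorded and $\Delta_j C_j$ carries the
value with 0 where masked.  Both columns enter **all** model fits —
outcome regression and propensity score — so informative missingness is
available to the learners as signal.  The propensity-score inclusion is
a documented choice (configurable in principle by passing a reduced
design): conditioning the exposure model on recordedness is the natural
counterpart of conditioning the outcome model on it.  Covariates with
zero observed missingness keep a single column; a constant
$\Delta \equiv 1$ column would be degenerate.  For a categorical
covariate the reference-coded dummies (modal category as reference)
share one $\Delta$ column, since their missingness pattern is common —
per-dummy indicators would be exact duplicates.

The identification cost is explicit: adjustment is for the *observed*
information $(\Delta, \Delta C)$, not for the latent complete $C$.  When
missingness depends on treatment and the masked covariate confounds, a
residual bias remains; it is small when per-covariate missingness or the
masked covariate's residual confounding is small, and the generator's
MNAR switch exists to probe the harder case.

## The ensemble learner

Both nuisance functions, $\bar Q(S, C) = E(Y \mid S, C)$ and
$g(C) = P(S = 1 \mid C)$, are fit by a from-scratch cross-validated
stacking ensemble.  $V = 10$ folds (sizes within one of each other;
stratified on the outcome when a binary outcome has prevalence below 5%,
so no training fold is empty of events — a deliberate deviation from
plain random splitting that only matters for rare outcomes at desk
scale).  Each learner is fit on every training fold and predicts its
held-out fold, giving an $n \times L$ honest prediction matrix; the
ensemble weight vector minimizes cross-validated risk over the simplex
(squared error for continuous outcomes, Bernoulli negative
log-likelihood with predictions pre-bounded at $[0.001, 0.999]$ for
binary ones); each learner is then refit on the full data for
prediction.

The solver is projected gradient on the simplex followed by a vertex
polish: if any single learner attains the interior solution's risk (to
$10^{-12}$), the earliest such learner takes all the weight.  This both
guarantees the defining inequality — ensemble CV risk never exceeds any
single learner's — and breaks degenerate ties toward the simpler model
(the library is ordered simple-to-complex).  A learner that errors on
any training fold receives infinite CV risk and weight zero, with a
warning; the fit proceeds with the survivors.

The default library is: grand mean; main-terms GLM (with a ridge
fallback under separation); a GLM adding site-by-covariate interaction
terms (so effect modification by the exposure is representable); lasso
GLM with the penalty chosen by inner 5-fold cross-validation; a shallow
random forest (300 trees, depth 4); and 20-nearest-neighbor averaging on
standardized columns.  The k-NN
learner is written in the package (a small exact-distance average) since
no installed dependency provides k-NN *regression*.  The library is an
explicit stand-in: ensemble results always depend on the library, and a
reduced, parametric-only library (mean, GLM, interaction GLM) is
provided for replication studies where thousands of refits are needed.

## The four estimators

**Unadjusted difference.** $\bar Y_{S=1} - \bar Y_{S=0}$ with an
unpooled two-sample variance.  Included as the naive benchmark.

**Substitution (plug-in).**
$\hat\psi = \tfrac{1}{n_1}\sum_{i: S_i = 1}\left[Y_i - \bar Q(0, C_i)\right]$,
with $\bar Q$ either the main-terms regression or the ensemble fit.  The
mean of the treated patients' counterfactual residuals
$Y - \bar Q(0, C)$ *is* this estimator — an identity the diagnostics
module asserts to $10^{-12}$.  Inference is by nonparametric bootstrap
(rows resampled with replacement, unstratified by default; all model
fitting repeated inside every replicate), with a Wald interval centered
at the full-data estimate.  The direction of the counterfactual switch
(treated patients moved to $S = 0$) follows the estimand's definition;
the converse direction would estimate a different (control-side)
parameter.

**TMLE.** The substitution estimator is targeted by an iterative dual
fluctuation.  Outcome step: the clever covariate
$H_Y(S, C) = \mathbb{1}\{S=1\} - \mathbb{1}\{S=0\}\, g(C)/(1 - g(C))$
enters an intercept-free logistic regression of $Y$ on $H_Y$ with
$\operatorname{logit} \bar Q(S, C)$ as offset; the coefficient
$\varepsilon_Q$ updates $\bar Q$ at both site values.  Propensity step:
with $\psi_{cur}$ the current plug-in value,
$H_S(C) = \bar Q(1, C) - \bar Q(0, C) - \psi_{cur}$ fluctuates $g$ the
same way (offset $\operatorname{logit} g$), and $g$ is re-truncated.
Cycles repeat until $\max(|\varepsilon_Q|, |\varepsilon_g|) < 10^{-5}$
(`tol`), with `max_iter = 50` and a warning on non-convergence.  The
constant $1/P(S=1)$ factor in the canonical ETT clever covariates is
absorbed into the $\varepsilon$'s — it rescales the fluctuation
coefficient without changing the submodel's span, so the solution is
identical.  Continuous outcomes are mapped to $[0,1]$ by the observed
range $(a, b)$ — no padding — fluctuated on the logistic scale, and
mapped back; this keeps updates inside the outcome's range and makes the
estimator equivariant under affine relabeling (tested).  The standard
error comes from the efficient influence curve at the solution,

$$D_i = \frac{S_i}{p_1}\left(\bar Q(1, C_i) - \bar Q(0, C_i) - \psi\right)
 + \left[\frac{S_i}{p_1} - \frac{(1 - S_i)\, g(C_i)}{(1 - g(C_i))\, p_1}\right]
   \left(Y_i - \bar Q(S_i, C_i)\right),$$

whose empirical mean vanishes at convergence (asserted below
$10 \times$ `tol`).  TMLE is doubly robust: it remains consistent when
either $\bar Q$ or $g$ (not necessarily both) is consistent, which the
test suite demonstrates under both misspecification directions.

**Matching.** $g$ is estimated by the ensemble and truncated to
$[\delta, 1 - \delta]$ with $\delta = 0.025$ (positivity protection; the
exact value is a design choice, not data-driven).  Each treated patient
is matched to the nearest control by $|g_i - g_j|$, with replacement;
controls at exactly tied distance (tolerance $10^{-12}$) are all used
and their outcomes averaged.  The caliper is $0.05 \times \sigma_g$ with
$\sigma_g$ the standard deviation of the *pooled* truncated scores —
"pooled" is a documented reading of an underspecified convention.
Treated patients with no control inside the caliper are discarded and
counted; the estimand silently narrows to the matchable treated, which
is reported rather than hidden.  The SE treats the paired differences as
the base variance and adds a reuse penalty: with $K_j$ the
(tie-fractional) multiplicity of control $j$,
$\widehat{\text{Var}} = s_d^2/n_1 + \hat\sigma_c^2 \max(0, \sum_j K_j^2 - n_1)/n_1^2$.
It reduces exactly to the ordinary paired SE with no reuse, and grows
strictly under reuse; it is a pragmatic stand-in for a formal
matching-variance estimator (conditional-on-match-structure, in the
spirit of Abadie–Imbens) since the convention this layout mirrors does
not state one.

## Diagnostics

Counterfactual residuals $r_i = Y_i - \bar Q(1 - S_i, C_i)$ are plotted
against a *common* risk axis: predicted overall mortality with the site
set to "large" for every patient.  The factual-site axis is available
(`risk_site = NULL`), but a single counterfactual scale makes the two
site groups' curves comparable at the same abscissa; the convention is
switchable because either reading is defensible.  Curves are local-linear
loess (tricube kernel, span 0.75 by default, exact "direct" surface) on
a 100-point grid per site group, with pointwise bands from the local
weighted residual variance.  The bands are exploratory only — these are
post-hoc plots, not inference.

The divergence cutoff is the smallest grid point from which the absolute
smoothed residual exceeds a threshold over a consecutive run covering at
least 10% of the remaining grid (so a one-point blip cannot trigger it).
The default threshold — half the median pointwise band half-width — makes
the "started to diverge from zero" judgment reproducible while remaining
configurable; it is a formalization of what is inherently a visual call,
and the flagged/unflagged subgroup comparison built on it (Welch t /
Pearson chi-square) is descriptive, not confirmatory.

Matched-set balance uses the scaled covariate matrix of the matched rows
(continuous columns z-scored; binary and indicator columns left raw so
distances and colors stay interpretable), agglomerative hierarchical
clustering with Euclidean distance and average linkage — chosen for
determinism; the convention being mirrored specifies only "hierarchical
clustering" — plus standardized mean differences before/after matching
and a chi-square association between 2-cluster membership and site.

## The synthetic-cohort generator

The generator is the package's ground-truth instrument, emulating the
statistical structure of a multi-center trauma-transfusion cohort:
1,242 patients with roughly 44% at large-volume centers; seven
covariates with trauma-plausible marginals (age truncated-normal 41/18.5
on [16, 90]; male 0.74; penetrating injury 0.35; injury severity score
truncated-gamma mean 26 sd 15 on [1, 75]; ED systolic pressure normal
108/31; hemoglobin 11.7/2.3; base deficit −7/5.6); a logistic site model
on standardized covariates whose coefficients are set to the published
standardized site differences (large centers younger, more penetrating
injury, higher hemoglobin); per-covariate logistic missingness on site
and severity, with rates in the published ranges (base deficit ~27%/17%
small/large, hemoglobin ~2.5%/5%); and three outcomes — overall
mortality (~21–22%, Bernoulli-logit with a negative site main effect
modified by severity and penetrating mechanism, so the ETT differs from
the ATE), rare multiple organ failure (~1%), and a right-skewed
gamma-loglinear plasma-volume outcome (site-wise means ~5/7.5 units).
Outcome intercepts were set once so these marginals land near the
published summary rates.

What the generator deliberately does **not** emulate: correlation among
covariates (draws are independent given the site model), the ten
individual centers and any within-center clustering, longitudinal
structure, and the volume-ranking procedure that produced the site
labels (labels are drawn directly).  Passing tests therefore demonstrate
that the machinery is correct under a known mechanism of realistic
*shape* — not that the defaults are calibrated to any real joint
distribution, which is not public.

Truth is computed by Monte Carlo: draw $10^6$ covariate/site vectors
from the mechanism, evaluate both counterfactual outcome means for the
treated rows, average the difference.  A quadrature oracle over the
covariate distribution cross-checks the Monte-Carlo truth in the tests.
Missingness is MAR given site and the other covariates by default; a
per-covariate MNAR coefficient (`self`) lets the missingness depend on
the masked value itself for robustness experiments.  One master seed is
split into sub-streams (covariates / site / missingness / outcomes), so
switching missingness on or off does not perturb the outcome draws.
The discrete toy (`make_discrete_toy`) is the exact-oracle fixture: one
binary covariate with a closed-form ETT, where saturated fits must
reproduce the plug-in formula to numerical precision and the TMLE
fluctuations must vanish at the first cycle.

## Numerical choices and problem sizes

Probability bounds 0.001/0.999 for all binary-loss predictions;
propensity truncation $\delta = 0.025$; TMLE tolerance $10^{-5}$ with at
most 50 cycles; bootstrap defaults 500 replicates for tests and 1,000
for reports, resampling unstratified (a site-stratified option exists).
Bootstrap replicates that error are skipped and counted; more than 10%
failures aborts.  The replication studies in the test suite use 200
cohorts of 1,250 (parameter recovery and null calibration), 100 of 2,000
(double robustness), and 20–50 replicates for weight-dominance and
balance checks, with the reduced learner library inside replications —
sizes chosen to make the Monte-Carlo error small relative to the effects
being checked while keeping a full run at desk scale.

## Known limitations

Under treatment-dependent covariate masking the indicator basis
identifies an observed-data functional that can differ slightly from the
complete-data ETT; on the default mechanism this gap is about 0.002 on
the mortality-risk scale (a few percent of the effect), measured by
fitting flexible models at very large n.  Estimator validation against
the complete-data truth inherits that offset — it is a property of the
missingness process, not of any estimator.
The ETT after caliper discarding is an effect among the *matchable*
treated.  Influence-curve SEs for TMLE assume the nuisance estimators
converge fast enough; with very small samples or aggressive libraries
the bootstrap fallback is safer.  The matching SE is a documented
approximation.  No multiplicity adjustment is applied across outcomes.
Within-center correlation is ignored throughout (a non-goal), so SEs
would be anti-conservative on strongly clustered real data.
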