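# ettmachine

Targeted machine learning for **center-level effects among the treated**,
built for comparative-effectiveness questions of the form *"did being
treated at a large-volume trauma center, rather than a small one, change
patient outcomes — for the patients who were actually treated there?"*
The intended users are biostatisticians and outcomes researchers working
with observational, patient-level multi-center cohorts where the patient
populations differ across centers and covariates are partly missing.

## The estimand and the machinery

With outcome $Y$, site exposure $S$ (1 = large-volume) and confounders
$C$, the target is the effect of treatment among the treated (ETT/ATT):

$$\psi = E\left[\,E(Y \mid S{=}1, C) - E(Y \mid S{=}0, C)\,\middle|\, S{=}1\right].$$

The package provides, end to end:

* **Indicator design basis** — each sometimes-missing covariate becomes
  the fully observed pair $(\Delta, \Delta C)$ ("recorded?" and
  "value-if-recorded"), used by *all* model fits instead of imputation.
* **A from-scratch super learner** — 10-fold cross-validated stacking
  over a library (mean, GLM, site-interaction GLM, lasso, shallow forest, k-NN) with convex
  weights minimizing CV risk; the ensemble provably never does worse in
  CV risk than any single library member.
* **Four ETT estimators** — unadjusted difference; substitution
  (plug-in) with regression or ensemble outcome fits; TMLE with an
  iterative dual "clever covariate" fluctuation and influence-curve SEs
  (doubly robust); propensity-score nearest-neighbor matching with
  replacement, tie-averaging and a 0.05-sd caliper.
* **Inference** — nonparametric bootstrap (models refit per replicate)
  for substitution, efficient-influence-curve SEs for TMLE, a
  reuse-corrected paired SE for matching, Wald intervals throughout.
* **Diagnostics** — counterfactual residuals $Y - \bar Q(1{-}S, C)$
  with loess smooths against predicted mortality risk, divergence-region
  subgrouping, risk histograms, and matched-set balance (SMDs +
  hierarchical clustering).
* **A synthetic trauma-cohort generator** with a known mechanism and
  Monte-Carlo ground truth, emulating a ~1,242-patient two-tier cohort
  (confounded site assignment, site/severity-dependent missingness,
  rare-to-common binary outcomes and skewed transfusion volumes), so
  every estimator can be validated against a target it cannot see.

## Worked example

```r
library(ettmachine)

cfg     <- default_emulator_config(1242)        # the shipped mechanism
cohort  <- generate_cohort(cfg, seed = 7)
truth   <- true_ett(cfg, "overall_mortality", n_mc = 1e6, seed = 7)
est     <- estimate_ett(cohort, "overall_mortality",
                        library = default_library(reduced = TRUE),
                        B = 200, seed = 7)
truth$psi0
est$tmle; est$matching; est$unadjusted
```

```
[1] -0.05973939
ETT [tmle]: -0.04282  (SE 0.0242, 95% CI -0.09018 to 0.004545)
ETT [matching]: -0.04356  (SE 0.0366, 95% CI -0.1153 to 0.02814)  [18 treated discarded]
ETT [unadjusted]: -0.02332  (SE 0.0235, 95% CI -0.0694 to 0.02276)
```

The true mortality ETT in this mechanism is about −0.06: treatment at a
large-volume site lowers the mortality of the treated by six percentage
points.  On a single cohort the adjusted TMLE estimate moves from the
attenuated unadjusted contrast toward the truth; across replications the
TMLE is nearly unbiased with ~95% CI coverage, while the unadjusted
difference carries the (mild, partially cancelling) confounding of this
mechanism (run `analysis/05_operating_characteristics.R`).
Matching reports how many treated patients had no control within the
caliper — its estimand is the effect among the *matchable* treated.

The `analysis/` directory holds the numbered pipeline
(`01_simulate` → `02_describe` → `03_estimate` → `04_diagnose` →
`05_operating_characteristics`); each script prints what it found and
writes its tables under `results/`.  `vignettes/ett-methods.Rmd`
documents the models, the design decisions and the generator's scope.

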