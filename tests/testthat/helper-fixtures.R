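## Shared fixtures: tiny mechanisms with analytically known structure.

## single continuous confounder, logit outcome with site-by-covariate
## interaction; simple enough for a quadrature oracle
one_confounder_config <- function(n = 1000, site_b = 0.8,
                                  y_site = -0.6, y_inter = -0.4) {
  generator_config(
    n_patients = n,
    covariates = list(cov_spec("w", "normal", mean = 0, sd = 1)),
    site_model = list(intercept = -0.2, coef = c(w = site_b)),
    outcomes = list(y = outcome_spec("bernoulli", intercept = -1,
                                     coef = c(w = 0.9), site = y_site,
                                     interaction = if (y_inter != 0) c(w = y_inter) else numeric()))
  )
}

## well-overlapped, correctly-specified mechanism: logit-linear outcome and
## site model, no interactions, no missingness — glm fits are correct here
linear_mechanism <- function(n, site_eff = -0.5, confounded = TRUE) {
  generator_config(
    n_patients = n,
    covariates = list(cov_spec("w1", "normal"), cov_spec("w2", "normal")),
    site_model = list(intercept = 0,
                      coef = if (confounded) c(w1 = 0.8, w2 = -0.5) else c(w1 = 0, w2 = 0)),
    outcomes = list(y = outcome_spec("bernoulli", intercept = -0.5,
                                     coef = c(w1 = 1.0, w2 = 0.7),
                                     site = site_eff))
  )
}

## cohort with a sometimes-missing covariate, for design-basis tests
masked_cohort <- function(n = 300, seed = 11) {
  cfg <- generator_config(
    n_patients = n,
    covariates = list(cov_spec("age", "normal", mean = 40, sd = 15),
                      cov_spec("bmi", "normal", mean = 28, sd = 7)),
    site_model = list(intercept = 0, coef = c(age = 0.3)),
    missingness = list(bmi = calibrate_missingness(0.136, 0.328)),
    outcomes = list(y = outcome_spec("bernoulli", intercept = -1,
                                     coef = c(age = 0.5), site = -0.3))
  )
  generate_cohort(cfg, seed)
}

quick_design <- function(cohort) expand_missingness(cohort)
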