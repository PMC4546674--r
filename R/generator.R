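## Synthetic trauma-cohort generator with a known data-generating
## mechanism, so every estimator downstream can be checked against a
## ground-truth effect among the treated computed from the mechanism
## itself.
##
## The mechanism: covariates are drawn independently from declared
## marginals; the site label S (1 = large-volume center) follows a
## logistic model on standardized covariates; covariate missingness
## follows per-covariate logistic models on S and the other covariates
## (MAR given observables, with an optional MNAR switch); outcomes are
## drawn from Bernoulli-logit, Gaussian-identity or Gamma-loglinear
## models on the *complete* (pre-masking) covariates, with a site main
## effect and optional site-by-covariate interactions (so the effect
## among the treated need not equal the average effect).

#' Declare a covariate for the cohort generator
#'
#' @param name column name.
#' @param dist distribution family: `"normal"` (optionally truncated),
#'   `"binary"`, or `"gamma"` (optionally truncated; parameterized by mean
#'   and sd).
#' @param mean,sd mean and standard deviation (normal / gamma).
#' @param p success probability (binary).
#' @param lower,upper truncation bounds (normal / gamma), via the inverse
#'   CDF so draws remain one-uniform-per-patient.
#' @param center,scale standardization constants used when this covariate
#'   enters a linear predictor; default to the nominal distribution
#'   moments.
#' @return a covariate spec (list).
#' @export
cov_spec <- function(name, dist = c("normal", "binary", "gamma"),
                     mean = 0, sd = 1, p = 0.5,
                     lower = -Inf, upper = Inf,
                     center = NULL, scale = NULL) {
  dist <- match.arg(dist)
  if (dist == "binary") {
    center <- center %||% p
    scale <- scale %||% sqrt(p * (1 - p))
  } else {
    center <- center %||% mean
    scale <- scale %||% sd
  }
  list(name = name, dist = dist, mean = mean, sd = sd, p = p,
       lower = lower, upper = upper, center = center, scale = scale)
}

#' Declare an outcome model for the cohort generator
#'
#' The linear predictor is
#' `intercept + sum(coef * z) + site * S + sum(interaction * z * S)`
#' where `z` are standardized covariate values (using each covariate's
#' `center`/`scale`).
#'
#' @param family `"bernoulli"` (logit link), `"gaussian"` (identity link,
#'   residual sd `sd`), or `"gamma"` (log link, shape `shape`).
#' @param intercept numeric.
#' @param coef named numeric vector of covariate coefficients.
#' @param site site (S = 1) main effect on the link scale.
#' @param interaction named numeric vector of site-by-covariate
#'   interaction coefficients.
#' @param sd residual sd (gaussian).
#' @param shape gamma shape parameter.
#' @return an outcome spec (list).
#' @export
outcome_spec <- function(family = c("bernoulli", "gaussian", "gamma"),
                         intercept = 0, coef = numeric(), site = 0,
                         interaction = numeric(), sd = 1, shape = 1) {
  family <- match.arg(family)
  list(family = family, intercept = intercept, coef = coef, site = site,
       interaction = interaction, sd = sd, shape = shape)
}

#' Assemble a generator configuration
#'
#' @param n_patients number of rows to draw (>= 2).
#' @param covariates list of [cov_spec()] objects.
#' @param site_model list with `intercept` and a named `coef` vector on
#'   standardized covariates, for logit P(S = 1 | C).
#' @param missingness named list (by covariate) of lists with `intercept`,
#'   `site` coefficient, named `coef` on the other standardized covariates,
#'   and optionally `self` (MNAR coefficient on the covariate's own
#'   standardized value; default 0, i.e. MAR).
#' @param outcomes named list of [outcome_spec()] objects.
#' @return object of class `ett_generator_config`.
#' @export
generator_config <- function(n_patients, covariates, site_model,
                             missingness = list(), outcomes) {
  stopifnot(n_patients >= 2, length(covariates) > 0, length(outcomes) > 0)
  cov_names <- vapply(covariates, `[[`, character(1), "name")
  if (anyDuplicated(cov_names)) stop("duplicate covariate names")
  check_refs <- function(v, what) {
    bad <- setdiff(names(v), cov_names)
    if (length(bad))
      stop(what, " references unknown covariate(s): ", paste(bad, collapse = ", "))
  }
  check_refs(site_model$coef, "site model")
  bad_mn <- setdiff(names(missingness), cov_names)
  if (length(bad_mn))
    stop("missingness model for unknown covariate(s): ", paste(bad_mn, collapse = ", "))
  for (nm in names(missingness)) check_refs(missingness[[nm]]$coef, paste0("missingness[", nm, "]"))
  for (nm in names(outcomes)) {
    check_refs(outcomes[[nm]]$coef, paste0("outcome[", nm, "]"))
    check_refs(outcomes[[nm]]$interaction, paste0("outcome[", nm, "] interaction"))
    if (!outcomes[[nm]]$family %in% c("bernoulli", "gaussian", "gamma"))
      stop("invalid outcome family for ", nm)
  }
  structure(list(n_patients = as.integer(n_patients),
                 covariates = covariates,
                 cov_names = cov_names,
                 site_model = site_model,
                 missingness = missingness,
                 outcomes = outcomes),
            class = "ett_generator_config")
}

## --- internal draws ------------------------------------------------------

draw_covariates <- function(config, n) {
  out <- lapply(config$covariates, function(sp) {
    switch(sp$dist,
      normal = {
        pl <- stats::pnorm(sp$lower, sp$mean, sp$sd)
        pu <- stats::pnorm(sp$upper, sp$mean, sp$sd)
        stats::qnorm(stats::runif(n, pl, pu), sp$mean, sp$sd)
      },
      binary = stats::rbinom(n, 1, sp$p),
      gamma = {
        shape <- (sp$mean / sp$sd)^2
        rate <- sp$mean / sp$sd^2
        pl <- stats::pgamma(max(sp$lower, 0), shape, rate)
        pu <- stats::pgamma(sp$upper, shape, rate)
        stats::qgamma(stats::runif(n, pl, pu), shape, rate)
      },
      stop("invalid distribution family: ", sp$dist))
  })
  names(out) <- config$cov_names
  as.data.frame(out)
}

## standardized covariate matrix using each covariate's center/scale constants
standardize_covariates <- function(config, C) {
  z <- mapply(function(sp, col) (col - sp$center) / sp$scale,
              config$covariates, C[config$cov_names], SIMPLIFY = FALSE)
  names(z) <- config$cov_names
  do.call(cbind, z)
}

linpred <- function(intercept, coef, Z) {
  lp <- rep(intercept, nrow(Z))
  if (length(coef)) lp <- lp + as.vector(Z[, names(coef), drop = FALSE] %*% coef)
  lp
}

## conditional mean of an outcome given (s, standardized covariates)
outcome_mean <- function(spec, s, Z) {
  lp <- linpred(spec$intercept, spec$coef, Z) + spec$site * s
  if (length(spec$interaction))
    lp <- lp + s * as.vector(Z[, names(spec$interaction), drop = FALSE] %*% spec$interaction)
  switch(spec$family,
         bernoulli = expit(lp),
         gaussian = lp,
         gamma = exp(lp))
}

draw_outcome <- function(spec, mu) {
  n <- length(mu)
  switch(spec$family,
         bernoulli = stats::rbinom(n, 1, mu),
         gaussian = stats::rnorm(n, mu, spec$sd),
         gamma = stats::rgamma(n, shape = spec$shape, rate = spec$shape / mu))
}

## --- public operations ---------------------------------------------------

#' Generate a synthetic cohort
#'
#' Draws covariates, site labels, covariate missingness and outcomes from
#' the configured mechanism.  Outcomes are generated from the complete
#' (pre-masking) covariates; missingness affects covariates only.  One
#' master seed is split into four sub-streams (covariates / site /
#' missingness / outcomes) so that, e.g., switching missingness off does
#' not change the drawn outcomes.
#'
#' @param config an [generator_config()].
#' @param seed integer master seed.
#' @return an [cohort_table()] with `NA` marking masked covariate values.
#' @export
generate_cohort <- function(config, seed) {
  stopifnot(inherits(config, "ett_generator_config"))
  n <- config$n_patients
  ss <- derive_subseeds(seed, 4)

  C <- with_seed(ss[1], draw_covariates(config, n))
  Z <- standardize_covariates(config, C)

  S <- with_seed(ss[2], stats::rbinom(n, 1, expit(linpred(
    config$site_model$intercept, config$site_model$coef, Z))))

  Cobs <- C
  if (length(config$missingness)) {
    miss <- with_seed(ss[3], {
      lapply(names(config$missingness), function(nm) {
        m <- config$missingness[[nm]]
        ## `self` (default 0) is the MNAR switch: missingness depending on
        ## the covariate's own, possibly unobserved, value
        lp <- linpred(m$intercept, m$coef, Z) + (m$site %||% 0) * S +
          (m$self %||% 0) * Z[, nm]
        stats::rbinom(n, 1, expit(lp))
      })
    })
    names(miss) <- names(config$missingness)
    for (nm in names(miss)) Cobs[[nm]][miss[[nm]] == 1] <- NA
  }

  Y <- with_seed(ss[4], {
    lapply(config$outcomes, function(spec) draw_outcome(spec, outcome_mean(spec, S, Z)))
  })

  types <- vapply(config$outcomes, function(o)
    if (o$family == "bernoulli") "binary" else "continuous", character(1))
  cov_types <- vapply(config$covariates, function(sp)
    if (sp$dist == "binary") "binary" else "continuous", character(1))
  names(cov_types) <- config$cov_names

  d <- data.frame(id = seq_len(n), site_large = S)
  for (nm in names(Y)) d[[nm]] <- Y[[nm]]
  for (nm in config$cov_names) d[[nm]] <- Cobs[[nm]]
  cohort_table(d, outcomes = types, covariates = cov_types)
}

#' Monte-Carlo ground truth for the effect among the treated
#'
#' Draws `n_mc` covariate vectors and site labels from the mechanism and
#' evaluates, for rows with S = 1, both counterfactual outcome means
#' (site set to 1 and to 0, covariates fixed).  The ETT is the mean
#' difference over those rows; the ATE averages over all rows.
#'
#' @inheritParams generate_cohort
#' @param outcome name of a configured outcome.
#' @param n_mc Monte-Carlo sample size (>= 1e4).
#' @return list of class `ett_truth` with `psi0` (ETT), `ate`, their
#'   Monte-Carlo standard errors and `n_mc`.
#' @export
true_ett <- function(config, outcome, n_mc = 1e6, seed = 1) {
  stopifnot(inherits(config, "ett_generator_config"), n_mc >= 1e4)
  if (!outcome %in% names(config$outcomes))
    stop("outcome not in config: ", outcome)
  spec <- config$outcomes[[outcome]]
  ss <- derive_subseeds(seed, 2)
  C <- with_seed(ss[1], draw_covariates(config, n_mc))
  Z <- standardize_covariates(config, C)
  S <- with_seed(ss[2], stats::rbinom(n_mc, 1, expit(linpred(
    config$site_model$intercept, config$site_model$coef, Z))))
  diff <- outcome_mean(spec, 1, Z) - outcome_mean(spec, 0, Z)
  d1 <- diff[S == 1]
  structure(list(outcome = outcome,
                 psi0 = mean(d1),
                 psi0_se = stats::sd(d1) / sqrt(length(d1)),
                 ate = mean(diff),
                 ate_se = stats::sd(diff) / sqrt(n_mc),
                 n_mc = n_mc),
            class = "ett_truth")
}

#' Discrete toy cohort with closed-form truth
#'
#' One binary covariate W, binary site S and outcome Y, with all
#' configured probabilities strictly inside (0.1, 0.9).  The closed-form
#' effect among the treated,
#' `psi0 = sum_w [P(Y=1|S=1,w) - P(Y=1|S=0,w)] P(w|S=1)`,
#' is returned alongside so saturated-model estimators can be checked
#' against an exact target.
#'
#' @param n rows (>= 50).
#' @param seed integer seed.
#' @param p_w P(W = 1).
#' @param p_s length-2 vector, P(S = 1 | W = 0) and P(S = 1 | W = 1).
#' @param p_y 2x2 matrix, `p_y[s + 1, w + 1]` = P(Y = 1 | S = s, W = w).
#' @return list with `cohort` (an `ett_cohort`), `psi0`, and the
#'   probability table `probs`.
#' @export
make_discrete_toy <- function(n = 1000, seed = 1, p_w = 0.4,
                              p_s = c(0.35, 0.65),
                              p_y = matrix(c(0.30, 0.60, 0.45, 0.80), 2, 2)) {
  stopifnot(n >= 50, all(c(p_w, p_s, p_y) > 0.1), all(c(p_w, p_s, p_y) < 0.9))
  ss <- derive_subseeds(seed, 3)
  W <- with_seed(ss[1], stats::rbinom(n, 1, p_w))
  S <- with_seed(ss[2], stats::rbinom(n, 1, p_s[W + 1]))
  Y <- with_seed(ss[3], stats::rbinom(n, 1, p_y[cbind(S + 1, W + 1)]))
  ## P(w | S = 1) by Bayes over the two W strata
  pw1 <- c(p_s[1] * (1 - p_w), p_s[2] * p_w)
  pw1 <- pw1 / sum(pw1)
  psi0 <- sum((p_y[2, ] - p_y[1, ]) * pw1)
  cohort <- cohort_table(data.frame(id = seq_len(n), site_large = S, y = Y, w = W),
                         outcomes = c(y = "binary"),
                         covariates = c(w = "binary"))
  list(cohort = cohort, psi0 = psi0,
       probs = list(p_w = p_w, p_s = p_s, p_y = p_y, p_w_given_s1 = pw1))
}
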