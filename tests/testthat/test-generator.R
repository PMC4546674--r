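test_that("same config and seed reproduce the cohort exactly", {
  cfg <- default_emulator_config(500)
  a <- generate_cohort(cfg, seed = 42)
  b <- generate_cohort(cfg, seed = 42)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c <- generate_cohort(cfg, seed = 43)
  expect_false(identical(as.data.frame(a), as.data.frame(c)))
})

test_that("default cohort matches the emulated study's shape", {
  ch <- generate_cohort(default_emulator_config(1242), seed = 7)
  expect_equal(nrow(ch), 1242)
  p_target <- 551 / 1242
  expect_lt(abs(mean(ch$site_large) - p_target),
            3 * sqrt(p_target * (1 - p_target) / 1242))
  expect_true(all(ch$age >= 16 & ch$age <= 90, na.rm = TRUE))
  expect_true(all(ch$iss >= 1 & ch$iss <= 75, na.rm = TRUE))
  expect_true(all(ch$plasma_24h >= 0))
})

test_that("a null site model yields a balanced split and balanced covariates", {
  cfg <- default_emulator_config(4000)
  cfg$site_model <- list(intercept = 0,
                         coef = setNames(rep(0, 7), cfg$cov_names))
  ch <- generate_cohort(cfg, seed = 3)
  expect_lt(abs(mean(ch$site_large) - 0.5), 3 * sqrt(0.25 / 4000))
  z_age <- (mean(ch$age[ch$site_large == 1], na.rm = TRUE) -
            mean(ch$age[ch$site_large == 0], na.rm = TRUE)) /
    (sd(ch$age, na.rm = TRUE) * sqrt(4 / 4000))
  expect_lt(abs(z_age), 4)
})

test_that("site-calibrated missingness hits its per-site target rates", {
  cfg <- generator_config(
    n_patients = 1242,
    covariates = list(cov_spec("bmi", "normal", mean = 28, sd = 7)),
    site_model = list(intercept = -0.227, coef = c(bmi = 0)),
    missingness = list(bmi = calibrate_missingness(0.136, 0.328)),
    outcomes = list(y = outcome_spec("bernoulli", intercept = -1))
  )
  rates <- t(vapply(1:200, function(r) {
    ch <- generate_cohort(cfg, seed = r)
    c(mean(is.na(ch$bmi[ch$site_large == 0])),
      mean(is.na(ch$bmi[ch$site_large == 1])))
  }, numeric(2)))
  ## mean realized rate over 200 replicates vs target, within 3 MC SE
  for (j in 1:2) {
    target <- c(0.136, 0.328)[j]
    mc_se <- sd(rates[, j]) / sqrt(200)
    expect_lt(abs(mean(rates[, j]) - target), 3 * mc_se + 1e-4)
  }
})

test_that("sub-streams isolate missingness from outcomes", {
  cfg <- default_emulator_config(400)
  a <- generate_cohort(cfg, seed = 5)
  cfg$missingness <- list()
  b <- generate_cohort(cfg, seed = 5)
  expect_identical(a$overall_mortality, b$overall_mortality)
  expect_identical(a$site_large, b$site_large)
})

test_that("configuration errors are caught", {
  expect_error(generator_config(
    10, list(cov_spec("w", "normal")),
    site_model = list(intercept = 0, coef = c(zz = 1)),
    outcomes = list(y = outcome_spec("bernoulli"))), "unknown covariate")
  expect_error(generator_config(
    10, list(cov_spec("w", "normal")),
    site_model = list(intercept = 0, coef = c(w = 1)),
    outcomes = list(y = outcome_spec("bernoulli", coef = c(nope = 2)))),
    "unknown covariate")
  expect_error(cov_spec("w", "weibull"))
})

test_that("true ETT is zero under a null outcome mechanism", {
  cfg <- one_confounder_config(y_site = 0, y_inter = 0)
  tr <- true_ett(cfg, "y", n_mc = 5e4, seed = 2)
  expect_lt(abs(tr$psi0), 3 * tr$psi0_se + 1e-12)
  expect_equal(tr$psi0, 0)  # identical counterfactual means, exactly
})

test_that("additive site effect on the identity scale is recovered exactly", {
  cfg <- generator_config(
    n_patients = 100,
    covariates = list(cov_spec("w", "normal")),
    site_model = list(intercept = 0, coef = c(w = 0.6)),
    outcomes = list(y = outcome_spec("gaussian", intercept = 1,
                                     coef = c(w = 2), site = 0.7, sd = 1)))
  tr <- true_ett(cfg, "y", n_mc = 1e4, seed = 3)
  expect_equal(tr$psi0, 0.7, tolerance = 1e-12)
  expect_equal(tr$ate, 0.7, tolerance = 1e-12)
})

test_that("MC truth matches a quadrature oracle under effect modification", {
  cfg <- one_confounder_config()
  ## oracle: psi0 = Int (mu1 - mu0) g(w) phi(w) dw / Int g(w) phi(w) dw
  g <- function(w) plogis(-0.2 + 0.8 * w)
  mu <- function(s, w) plogis(-1 + 0.9 * w + s * (-0.6) + s * (-0.4) * w)
  num <- integrate(function(w) (mu(1, w) - mu(0, w)) * g(w) * dnorm(w),
                   -Inf, Inf, rel.tol = 1e-10)$value
  den <- integrate(function(w) g(w) * dnorm(w), -Inf, Inf, rel.tol = 1e-10)$value
  oracle <- num / den
  tr <- true_ett(cfg, "y", n_mc = 2e5, seed = 4)
  expect_lt(abs(tr$psi0 - oracle), 3 * tr$psi0_se)
})

test_that("MC SE shrinks like 1/sqrt(n_mc)", {
  cfg <- one_confounder_config()
  a <- true_ett(cfg, "y", n_mc = 1e4, seed = 5)
  b <- true_ett(cfg, "y", n_mc = 9e4, seed = 5)
  expect_equal(a$psi0_se / b$psi0_se, 3, tolerance = 0.35)
})

test_that("ETT differs from ATE under the default confounded mechanism", {
  tr <- true_ett(default_emulator_config(), "overall_mortality",
                 n_mc = 2e5, seed = 6)
  expect_gt(abs(tr$psi0 - tr$ate), 3 * sqrt(tr$psi0_se^2 + tr$ate_se^2))
})

test_that("discrete toy closed form agrees with enumeration and edge cases", {
  ## identical outcome probabilities across sites -> zero effect
  t0 <- make_discrete_toy(100, seed = 1,
                          p_y = matrix(c(0.3, 0.3, 0.7, 0.7), 2, 2))
  expect_equal(t0$psi0, 0)
  ## constant 0.1 uplift in every stratum -> exactly 0.1
  t1 <- make_discrete_toy(100, seed = 1,
                          p_y = matrix(c(0.3, 0.4, 0.6, 0.7), 2, 2))
  expect_equal(t1$psi0, 0.1, tolerance = 1e-12)
  ## arbitrary table vs brute-force enumeration over the joint distribution
  p_w <- 0.45; p_s <- c(0.3, 0.7)
  p_y <- matrix(c(0.25, 0.55, 0.40, 0.85), 2, 2)
  tt <- make_discrete_toy(100, seed = 1, p_w = p_w, p_s = p_s, p_y = p_y)
  joint_s1 <- c(p_s[1] * (1 - p_w), p_s[2] * p_w)  # P(S=1, W=w)
  oracle <- sum(vapply(0:1, function(w)
    (p_y[2, w + 1] - p_y[1, w + 1]) * joint_s1[w + 1], numeric(1))) / sum(joint_s1)
  expect_equal(tt$psi0, oracle, tolerance = 1e-14)
  ## generated frequencies are consistent with the table
  ch <- make_discrete_toy(20000, seed = 9, p_w = p_w, p_s = p_s, p_y = p_y)$cohort
  expect_lt(abs(mean(ch$w) - p_w), 4 * sqrt(p_w * (1 - p_w) / 20000))
})
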