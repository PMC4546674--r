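## helpers building residual sets directly (diagnostics are pure
## functions of residuals + risk scores)
mk_residuals <- function(risk, residual, site) {
  structure(data.frame(id = seq_along(risk), site_large = site,
                       residual = residual, risk = risk),
            class = c("ett_residuals", "data.frame"))
}

test_that("residuals: bounds, identity with substitution, perfect predictor", {
  toy <- make_discrete_toy(600, seed = 41)
  d <- expand_missingness(toy$cohort)
  qf <- fit_outcome_model(d, toy$cohort$site_large, toy$cohort$y,
                          method = "regression", interactions = TRUE)
  res <- counterfactual_residuals(toy$cohort, qf, qf, "y")
  expect_true(all(res$residual >= -1 & res$residual <= 1))
  e <- substitution_ett(toy$cohort, qf, "y")
  expect_lt(abs(mean(res$residual[res$site_large == 1]) - e$psi), 1e-12)

  ## a model that reproduces Y at both site values gives zero residuals
  ch0 <- as.data.frame(toy$cohort)
  ch0$y <- as.numeric(toy$cohort$w)  # outcome = covariate, no site effect
  ch0 <- cohort_table(ch0, c(y = "continuous"), c(w = "binary"))
  qfp <- fit_outcome_model(d, ch0$site_large, ch0$y, method = "regression",
                           interactions = TRUE, binary = FALSE)
  resp <- counterfactual_residuals(ch0, qfp, qfp, "y")
  expect_lt(max(abs(resp$residual)), 1e-8)
})

test_that("loess reproduces constants and straight lines", {
  set.seed(42)
  x <- runif(300)
  site <- rep(c(0, 1), 150)
  rc <- mk_residuals(x, rep(0.3, 300), site)
  cc <- loess_curves(rc, span = 0.75)
  expect_lt(max(abs(cc$fit - 0.3)), 1e-8)

  rl <- mk_residuals(x, 2 * x - 0.5, site)
  cl <- loess_curves(rl, span = 0.5)
  interior <- cl$risk > quantile(x, 0.05) & cl$risk < quantile(x, 0.95)
  expect_lt(max(abs(cl$fit[interior] - (2 * cl$risk[interior] - 0.5))), 1e-6)
  expect_true(all(cl$band >= 0))
  expect_error(loess_curves(rl, span = 1.5), "span")
})

test_that("loess tracks a smooth signal in noise", {
  ## one residual set of n = 2000 (smoothing bias ~0.05-0.08 at the peaks
  ## of sin(6x) with this span, plus noise)
  devs <- vapply(1:5, function(s) {
    set.seed(s)
    n <- 2000
    x <- runif(n)
    r <- sin(6 * x) + rnorm(n, 0, 0.3)
    rs <- mk_residuals(x, r, rep(1, n))
    cv <- loess_curves(rs, span = 0.3)
    interior <- cv$risk > 0.1 & cv$risk < 0.9
    max(abs(cv$fit[interior] - sin(6 * cv$risk[interior])))
  }, numeric(1))
  expect_lt(median(devs), 0.1)
})

test_that("divergence partition finds step locations and honors the null", {
  grid <- seq(0, 1, length.out = 100)
  mkcurve <- function(fit) data.frame(site_large = 1, risk = grid, fit = fit,
                                      band = rep(0.02, 100))
  res <- mk_residuals(runif(200), rnorm(200, 0, 0.1), rep(1, 200))

  p0 <- partition_by_divergence(mkcurve(rep(0, 100)), res, threshold = 0.05)
  expect_equal(p0$cutoff, Inf)
  expect_length(p0$flagged_ids, 0)

  step <- ifelse(grid >= 0.5, 0.2, 0)
  p1 <- partition_by_divergence(mkcurve(step), res, threshold = 0.05)
  expect_equal(p1$cutoff, grid[min(which(grid >= 0.5))])
  expect_setequal(p1$flagged_ids, res$id[res$risk >= p1$cutoff])
  expect_setequal(c(p1$positive_ids, p1$negative_ids), p1$flagged_ids)

  ## a one-point blip does not trigger a cutoff
  blip <- rep(0, 100); blip[50] <- 0.2
  p2 <- partition_by_divergence(mkcurve(blip), res, threshold = 0.05)
  expect_equal(p2$cutoff, Inf)
})

test_that("step location is recovered within one grid cell from noisy data", {
  errs <- vapply(1:20, function(s) {
    set.seed(300 + s)
    n <- 2000
    x <- runif(n)
    r <- ifelse(x >= 0.6, 0.25, 0) + rnorm(n, 0, 0.15)
    rs <- mk_residuals(x, r, rep(1, n))
    cv <- loess_curves(rs, span = 0.2)
    p <- partition_by_divergence(cv[cv$site_large == 1, ], rs, threshold = 0.125)
    p$cutoff - 0.6
  }, numeric(1))
  grid_cell <- 1 / 99
  expect_lt(abs(median(errs)), 2 * grid_cell)
})

test_that("subgroup comparisons match closed-form test oracles", {
  ## chi-square oracle: table (30,70 / 70,30) -> X2 = 32, p ~ 1.5e-8
  ch <- cohort_table(
    data.frame(id = 1:200, site_large = rep(0:1, 100),
               y = rbinom(200, 1, 0.5),
               flag = c(rep(1, 30), rep(0, 70), rep(1, 70), rep(0, 30))),
    c(y = "binary"), c(flag = "binary"))
  part <- structure(list(flagged_ids = 1:100, unflagged_ids = 101:200),
                    class = "ett_partition")
  tab <- compare_subgroups(ch, part)
  row <- tab[tab$variable == "flag", ]
  p_oracle <- pchisq(32, df = 1, lower.tail = FALSE)
  expect_equal(row$p_value, p_oracle, tolerance = 1e-10)

  ## t-test power oracle: 3-sd mean separation at n=100 per arm
  set.seed(44)
  ch2 <- cohort_table(
    data.frame(id = 1:200, site_large = rep(0:1, 100),
               y = rbinom(200, 1, 0.5),
               v = c(rnorm(100, 0, 1), rnorm(100, 3, 1))),
    c(y = "binary"), c(v = "continuous"))
  tab2 <- compare_subgroups(ch2, part)
  expect_lt(tab2[tab2$variable == "v", "p_value"], 1e-6)

  ## identical subgroups: chi-square statistic 0, p = 1
  ch3 <- cohort_table(
    data.frame(id = 1:200, site_large = rep(0:1, 100),
               y = rbinom(200, 1, 0.5),
               b = rep(c(0, 1), 100)),
    c(y = "binary"), c(b = "binary"))
  part3 <- structure(list(flagged_ids = 1:100, unflagged_ids = 101:200),
                     class = "ett_partition")
  tab3 <- compare_subgroups(ch3, part3)
  expect_equal(tab3[tab3$variable == "b", "p_value"], 1, tolerance = 1e-10)
})

test_that("matched balance: perfect matches give zero SMD and clusters ignore site", {
  ## treated and controls with identical covariates pairwise
  n <- 40
  set.seed(45)
  xv <- rnorm(n / 2)
  x <- c(xv, xv)
  S <- rep(c(1, 0), each = n / 2)
  d <- structure(list(x = cbind(v = x), continuous = "v", id = 1:n),
                 class = "ett_design")
  matched <- structure(list(treated_rows = 1:(n / 2),
                            control_rows = as.list((n / 2 + 1):n)),
                       class = "ett_matched")
  bal <- matched_balance(matched, d, S)
  expect_equal(unname(bal$smd_post["v"]), 0, tolerance = 1e-12)
  ## two separated covariate clusters, each mixing both sites
  x2 <- c(rnorm(20, -5), rnorm(20, 5))
  S2 <- rep(c(1, 0), 20)
  d2 <- structure(list(x = cbind(v = x2), continuous = "v", id = 1:40),
                  class = "ett_design")
  m2 <- structure(list(treated_rows = which(S2 == 1),
                       control_rows = as.list(which(S2 == 0))),
                  class = "ett_matched")
  b2 <- matched_balance(m2, d2, S2)
  expect_gt(b2$cluster_site_p, 0.05)
  expect_length(b2$cluster, 40)
})

test_that("matching improves covariate balance on confounded data", {
  improved <- vapply(1:25, function(s) {
    cfg <- linear_mechanism(600)
    ch <- generate_cohort(cfg, seed = 500 + s)
    d <- expand_missingness(ch)
    gf <- fit_propensity(d, ch$site_large, method = "regression")
    e <- matching_ett(ch, gf, "y", caliper_sd = 0.05)
    bal <- matched_balance(e$matched, d, ch$site_large)
    mean(abs(bal$smd_post)) < mean(abs(bal$smd_pre))
  }, logical(1))
  expect_gte(mean(improved), 0.9)
})

test_that("risk histogram conserves counts with shared edges", {
  rs <- mk_residuals(rep(0.5, 37), rnorm(37), rep(c(0, 1), length.out = 37))
  h <- risk_histogram(rs, bins = 10)
  expect_equal(sum(h$count_small) + sum(h$count_large), 37)
  expect_equal(sum(h$count_small > 0) + sum(h$count_large > 0), 2)

  set.seed(46)
  ru <- mk_residuals(runif(10000), rnorm(10000), rep(c(0, 1), 5000))
  hu <- risk_histogram(ru, bins = 10)
  tot <- hu$count_small + hu$count_large
  expect_equal(sum(tot), 10000)
  ## multinomial oracle: per-bin count within 4 sd of n/bins
  expect_true(all(abs(tot - 1000) < 4 * sqrt(10000 * 0.1 * 0.9)))
})

test_that("diagnostics are deterministic given fixed fits", {
  toy <- make_discrete_toy(300, seed = 47)
  d <- expand_missingness(toy$cohort)
  qf <- fit_outcome_model(d, toy$cohort$site_large, toy$cohort$y,
                          method = "regression")
  r1 <- counterfactual_residuals(toy$cohort, qf, qf, "y")
  r2 <- counterfactual_residuals(toy$cohort, qf, qf, "y")
  expect_identical(r1, r2)
  set.seed(48)
  rs <- mk_residuals(runif(200), rnorm(200), rep(c(0, 1), 100))
  expect_identical(loess_curves(rs, 0.75), loess_curves(rs, 0.75))
})
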