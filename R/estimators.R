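## The four estimators of the effect among the treated (ETT):
## unadjusted difference, outcome-regression substitution (main-terms or
## super-learner fit), targeted maximum likelihood with an iterative dual
## fluctuation of the outcome and propensity fits, and propensity-score
## nearest-neighbor caliper matching with replacement.
##
## The estimand is psi = E[ E(Y | S=1, C) - E(Y | S=0, C) | S=1 ]: the
## change in mean outcome for patients treated at large-volume centers
## had they, covariates fixed, been treated at small-volume centers.

ett_estimate <- function(estimator, psi, se = NA_real_, level = 0.95,
                         n_treated = NA_integer_, n_discarded = 0L,
                         extra = list()) {
  ci <- if (is.na(se)) c(NA_real_, NA_real_) else wald_ci(psi, se, level)
  structure(c(list(estimator = estimator, psi = psi, se = se,
                   ci_lower = ci[1], ci_upper = ci[2],
                   n_treated = n_treated, n_discarded = n_discarded),
              extra),
            class = "ett_estimate")
}

#' @export
print.ett_estimate <- function(x, ...) {
  cat(sprintf("ETT [%s]: %.4g", x$estimator, x$psi))
  if (!is.na(x$se))
    cat(sprintf("  (SE %.3g, 95%% CI %.4g to %.4g)", x$se, x$ci_lower, x$ci_upper))
  if (x$n_discarded > 0) cat(sprintf("  [%d treated discarded]", x$n_discarded))
  cat("\n")
  invisible(x)
}

#' Unadjusted difference in means
#'
#' `mean(Y | S = 1) - mean(Y | S = 0)` with a two-sample (Welch-type,
#' unpooled) standard error and Wald confidence interval.
#'
#' @param cohort an [cohort_table()].
#' @param outcome outcome column name.
#' @param level confidence level.
#' @return an `ett_estimate`.
#' @export
unadjusted_difference <- function(cohort, outcome, level = 0.95) {
  y <- cohort[[outcome]]
  keep <- !is.na(y)
  y <- y[keep]; S <- cohort$site_large[keep]
  n1 <- sum(S == 1); n0 <- sum(S == 0)
  if (n1 == 0 || n0 == 0) stop("both site levels must be present with observed outcomes")
  y1 <- y[S == 1]; y0 <- y[S == 0]
  psi <- mean(y1) - mean(y0)
  v1 <- if (n1 > 1) stats::var(y1) else 0
  v0 <- if (n0 > 1) stats::var(y0) else 0
  se <- sqrt(v1 / n1 + v0 / n0)
  ett_estimate("unadjusted", psi, se, level, n_treated = n1)
}

## --- nuisance fits --------------------------------------------------------

design_frame <- function(design, S) {
  x <- cbind(design$x, site_large = S)
  x
}

#' Fit the outcome regression Q(s, C)
#'
#' Fits `E[Y | S, C]` on the indicator design basis plus the site column,
#' either by main-terms regression (logistic for binary outcomes, linear
#' for continuous; with an optional full set of site-by-covariate
#' interactions for saturated fits on discrete problems) or by the super
#' learner.  The fit is evaluable at both counterfactual site values by
#' swapping the site column.
#'
#' @param design an [expand_missingness()] design.
#' @param S site indicator vector.
#' @param y outcome vector (rows with missing `y` must be excluded by the
#'   caller).
#' @param method `"regression"` or `"superlearner"`.
#' @param binary whether the outcome is binary.
#' @param interactions include site-by-covariate interaction terms in the
#'   main-terms regression (ignored for the super learner).
#' @param library,folds passed to [fit_superlearner()].
#' @param bound probability bound for binary predictions.
#' @return object of class `ett_qfit`.
#' @export
fit_outcome_model <- function(design, S, y, method = c("regression", "superlearner"),
                              binary = all(y %in% c(0, 1)),
                              interactions = FALSE,
                              library = default_library(), folds = NULL,
                              bound = 0.001) {
  method <- match.arg(method)
  stopifnot(!anyNA(y), length(y) == nrow(design$x), length(S) == length(y))
  x <- design_frame(design, S)
  a <- min(y); b <- max(y)
  if (method == "regression") {
    d <- data.frame(y = y, x, check.names = FALSE)
    fam <- if (binary) stats::binomial() else stats::gaussian()
    form <- if (interactions) y ~ . + site_large * . else y ~ .
    fit <- suppressWarnings(stats::glm(form, data = d, family = fam))
    if (binary && glm_is_suspect(fit)) {
      warning("outcome regression unstable (possible separation); ridge fallback used")
      fit <- list(kind = "ridge",
                  fit = ridge_backup(x, y, if (binary) "binomial" else "gaussian"))
    } else fit <- list(kind = "glm", fit = fit)
    model <- fit
  } else {
    model <- fit_superlearner(x, y, library = library, folds = folds,
                              loss = if (binary) "bernoulli" else "squared",
                              bound = bound)
  }
  structure(list(method = method, model = model, design = design, S = S,
                 binary = binary, a = a, b = b, bound = bound,
                 cols = colnames(x)),
            class = "ett_qfit")
}

#' Evaluate a fitted outcome regression at a counterfactual site value
#'
#' @param qfit an `ett_qfit`.
#' @param s scalar 0/1, or a vector (e.g. the observed site labels).
#' @param design optional new design (defaults to the training design).
#' @return predicted conditional means; bounded into `(bound, 1 - bound)`
#'   for binary outcomes.
#' @export
predict_qbar <- function(qfit, s, design = NULL) {
  design <- design %||% qfit$design
  n <- nrow(design$x)
  x <- design_frame(design, rep(s, length.out = n))
  p <- if (qfit$method == "regression") {
    if (qfit$model$kind == "glm")
      unname(stats::predict(qfit$model$fit, newdata = as.data.frame(x),
                            type = "response"))
    else
      as.vector(stats::predict(qfit$model$fit,
                               newx = cbind(as.matrix(x), `..pad` = 0),
                               type = "response"))
  } else {
    sl_predict(qfit$model, x)
  }
  if (qfit$binary) p <- bound(p, qfit$bound, 1 - qfit$bound)
  p
}

#' Fit the propensity score g(C) = P(S = 1 | C)
#'
#' @param design an [expand_missingness()] design (indicator columns are
#'   candidate predictors here too).
#' @param S site indicator vector.
#' @param method `"regression"` (main-terms logistic) or `"superlearner"`.
#' @param delta truncation bound: scores are forced into
#'   `[delta, 1 - delta]` (positivity protection).
#' @param library,folds passed to [fit_superlearner()].
#' @return object of class `ett_gfit` with `g` (truncated scores),
#'   `sigma_g` (sd of the truncated scores over all rows), and `delta`.
#' @export
fit_propensity <- function(design, S, method = c("regression", "superlearner"),
                           delta = 0.025, library = default_library(),
                           folds = NULL) {
  method <- match.arg(method)
  stopifnot(delta >= 0, delta < 0.5)
  if (length(unique(S)) < 2) stop("site indicator is constant")
  x <- design$x
  if (method == "regression") {
    d <- data.frame(S = S, x, check.names = FALSE)
    fit <- suppressWarnings(stats::glm(S ~ ., data = d, family = stats::binomial()))
    if (glm_is_suspect(fit)) {
      warning("propensity regression unstable; ridge fallback used")
      fit <- list(kind = "ridge", fit = ridge_backup(x, S, "binomial"))
      g <- as.vector(stats::predict(fit$fit, newx = cbind(as.matrix(x), `..pad` = 0),
                                    type = "response"))
    } else {
      g <- unname(stats::fitted(fit))
      fit <- list(kind = "glm", fit = fit)
    }
    model <- fit
  } else {
    model <- fit_superlearner(x, S, library = library, folds = folds,
                              loss = "bernoulli")
    g <- sl_predict(model, x)
  }
  g <- bound(g, delta, 1 - delta)
  structure(list(method = method, model = model, g = g,
                 sigma_g = stats::sd(g), delta = delta),
            class = "ett_gfit")
}

## --- substitution ---------------------------------------------------------

#' Substitution (plug-in) estimator of the ETT
#'
#' Among treated rows, the average of the observed outcome minus the
#' predicted outcome had the patient been treated at a small-volume site:
#' `psi = mean_{S=1}[ Y - Q(0, C) ]`.  Standard errors are attached via
#' the nonparametric bootstrap ([bootstrap_ci()]), not here.
#'
#' @param cohort an [cohort_table()].
#' @param qfit an [fit_outcome_model()] fit on this cohort's design.
#' @param outcome outcome column name.
#' @return an `ett_estimate` (no SE).
#' @export
substitution_ett <- function(cohort, qfit, outcome) {
  S <- qfit$S
  y <- cohort[[outcome]][cohort$id %in% qfit$design$id]
  stopifnot(length(y) == length(S))
  treated <- S == 1
  if (!any(treated)) stop("no treated rows")
  q0 <- predict_qbar(qfit, 0)
  psi <- mean(y[treated] - q0[treated])
  label <- if (qfit$method == "regression") "substitution-regression" else "substitution-SL"
  ett_estimate(label, psi, n_treated = sum(treated))
}

## --- TMLE -----------------------------------------------------------------

#' Targeted maximum-likelihood estimator of the ETT
#'
#' Iteratively updates the outcome fit and the propensity fit with
#' "clever covariate" logistic fluctuations, each fit as an
#' intercept-free logistic regression with the log-odds of the current
#' prediction as offset:
#'
#' * outcome step: `H_Y(S, C) = 1{S=1} - 1{S=0} g(C) / (1 - g(C))`;
#'   regress Y on `H_Y` with offset `logit Q(S, C)`, giving `eps_Q`, and
#'   update `Q(s, C)` at both site values;
#' * propensity step: with `psi` the current plug-in estimate,
#'   `H_S(C) = Q(1, C) - Q(0, C) - psi`; regress S on `H_S` with offset
#'   `logit g(C)`, giving `eps_g`, update and re-truncate g.
#'
#' Iteration stops when `max(|eps_Q|, |eps_g|) < tol`.  Continuous
#' outcomes are mapped onto `[0, 1]` by the observed range before
#' fluctuation and the final estimate is mapped back.  The constant
#' `1/P(S=1)` factor of the canonical clever covariates is absorbed into
#' the fluctuation coefficients (it does not change the submodel's span).
#'
#' @param cohort an [cohort_table()].
#' @param qfit an [fit_outcome_model()] fit.
#' @param gfit an [fit_propensity()] fit.
#' @param outcome outcome column name.
#' @param tol convergence tolerance on the fluctuation coefficients.
#' @param max_iter maximum fluctuation cycles.
#' @param level confidence level for the influence-curve Wald interval.
#' @return an `ett_estimate` with influence-curve SE and a `state` field
#'   (class `ett_tmle_state`) holding the targeted fits, the per-patient
#'   efficient influence curve, iteration count and convergence flag.
#' @export
tmle_ett <- function(cohort, qfit, gfit, outcome, tol = 1e-5, max_iter = 50,
                     level = 0.95) {
  S <- qfit$S
  y_raw <- cohort[[outcome]][cohort$id %in% qfit$design$id]
  stopifnot(length(y_raw) == length(S))
  a <- qfit$a; b <- qfit$b
  if (qfit$binary) {
    y <- y_raw
    q1 <- predict_qbar(qfit, 1)
    q0 <- predict_qbar(qfit, 0)
  } else {
    if (b <= a) stop("degenerate continuous outcome (no spread)")
    y <- (y_raw - a) / (b - a)
    q1 <- bound((predict_qbar(qfit, 1) - a) / (b - a), qfit$bound, 1 - qfit$bound)
    q0 <- bound((predict_qbar(qfit, 0) - a) / (b - a), qfit$bound, 1 - qfit$bound)
  }
  g <- gfit$g
  delta <- gfit$delta
  p1 <- mean(S)
  stopifnot(p1 > 0, p1 < 1)

  eps_q <- eps_g <- Inf
  converged <- FALSE
  iter <- 0
  qb <- qfit$bound
  while (iter < max_iter) {
    iter <- iter + 1
    ## (i) outcome fluctuation
    hy <- ifelse(S == 1, 1, -g / (1 - g))
    off <- logit(ifelse(S == 1, q1, q0))
    fq <- suppressWarnings(stats::glm(y ~ -1 + hy, offset = off,
                                      family = stats::binomial()))
    eps_q <- unname(stats::coef(fq))
    if (!is.finite(eps_q)) eps_q <- 0
    q1 <- bound(expit(logit(q1) + eps_q * 1), qb, 1 - qb)
    q0 <- bound(expit(logit(q0) + eps_q * (-g / (1 - g))), qb, 1 - qb)
    ## (ii) propensity fluctuation
    psi_cur <- mean(q1[S == 1] - q0[S == 1])
    hs <- q1 - q0 - psi_cur
    fg <- suppressWarnings(stats::glm(S ~ -1 + hs, offset = logit(g),
                                      family = stats::binomial()))
    eps_g <- unname(stats::coef(fg))
    if (!is.finite(eps_g)) eps_g <- 0
    g <- bound(expit(logit(g) + eps_g * hs), delta, 1 - delta)
    if (max(abs(eps_q), abs(eps_g)) < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("TMLE did not converge in ", max_iter, " iterations; ",
            "max |eps| = ", signif(max(abs(eps_q), abs(eps_g)), 3))
  if (mean(g <= delta | g >= 1 - delta) > 0.2)
    warning("positivity: propensity score at truncation bounds for >20% of rows")

  psi <- mean(q1[S == 1] - q0[S == 1])
  qS <- ifelse(S == 1, q1, q0)
  ## efficient influence curve for the ETT (transformed scale)
  eif <- (S / p1) * (q1 - q0 - psi) +
    (S / p1 - (1 - S) * g / ((1 - g) * p1)) * (y - qS)
  scale_back <- if (qfit$binary) 1 else (b - a)
  se <- stats::sd(eif) / sqrt(length(y)) * scale_back
  state <- structure(list(q1 = q1, q0 = q0, g = g, p1 = p1, S = S, y = y,
                          eps_q = eps_q, eps_g = eps_g, iterations = iter,
                          converged = converged, eif = eif,
                          binary = qfit$binary, a = a, b = b),
                     class = "ett_tmle_state")
  ett_estimate("tmle", psi * scale_back, se, level,
               n_treated = sum(S == 1), extra = list(state = state))
}

## --- matching -------------------------------------------------------------

#' Propensity-score caliper matching estimator of the ETT
#'
#' Each treated (large-site) patient is matched to the nearest control
#' (small-site) patient by propensity score, with replacement; controls at
#' exactly tied distance are all used and their outcomes averaged.
#' Treated patients with no control within the caliper
#' (`caliper_sd * sd(g)`, with sd over the pooled truncated scores) are
#' discarded and counted.  `psi` is the mean over matched treated rows of
#' the observed outcome minus the mean matched-control outcome.
#'
#' @param cohort an [cohort_table()].
#' @param gfit an [fit_propensity()] fit on this cohort's design.
#' @param outcome outcome column name.
#' @param caliper_sd caliper width in propensity-score standard
#'   deviations (default 0.05).
#' @param level confidence level.
#' @return an `ett_estimate` with a reuse-weighted SE (see
#'   [matching_se()]) and a `matched` field (class `ett_matched`) holding
#'   the per-treated match lists, caliper, and discarded ids.
#' @export
matching_ett <- function(cohort, gfit, outcome, caliper_sd = 0.05, level = 0.95) {
  S <- cohort$site_large
  y <- cohort[[outcome]]
  keep <- !is.na(y)
  g <- gfit$g
  stopifnot(length(g) == nrow(cohort))
  caliper <- caliper_sd * gfit$sigma_g

  t_idx <- which(S == 1 & keep)
  c_idx <- which(S == 0 & keep)
  if (!length(t_idx) || !length(c_idx)) stop("both site levels must be present")

  gc <- g[c_idx]
  ord <- order(gc)
  gc_sorted <- gc[ord]
  c_sorted <- c_idx[ord]

  match_one <- function(gt) {
    pos <- findInterval(gt, gc_sorted)
    cand <- unique(pmin(pmax(c(pos, pos + 1L), 1L), length(gc_sorted)))
    dmin <- min(abs(gc_sorted[cand] - gt))
    if (dmin > caliper) return(integer(0))
    ## all controls at exactly the minimal distance (either side)
    tol <- 1e-12
    lo <- gt - dmin - tol
    hi <- gt + dmin + tol
    sel <- which(gc_sorted >= lo & gc_sorted <= hi)
    sel <- sel[abs(gc_sorted[sel] - gt) <= dmin + tol]
    c_sorted[sel]
  }

  matches <- lapply(g[t_idx], match_one)
  matched <- lengths(matches) > 0
  if (!any(matched)) stop("all treated rows discarded by the caliper")
  discarded_ids <- cohort$id[t_idx[!matched]]

  diffs <- vapply(which(matched), function(i) {
    y[t_idx[i]] - mean(y[matches[[i]]])
  }, numeric(1))
  psi <- mean(diffs)

  mset <- structure(list(treated_ids = cohort$id[t_idx[matched]],
                         control_ids = lapply(matches[matched], function(m) cohort$id[m]),
                         control_rows = matches[matched],
                         treated_rows = t_idx[matched],
                         diffs = diffs, caliper = caliper,
                         discarded_ids = discarded_ids),
                    class = "ett_matched")
  se <- if (sum(matched) >= 2) matching_se(mset, cohort, outcome) else NA_real_
  ett_estimate("matching", psi, se, level,
               n_treated = sum(matched), n_discarded = sum(!matched),
               extra = list(matched = mset))
}
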