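## Standard errors and 95% Wald-style confidence intervals: nonparametric
## bootstrap for the substitution estimators, influence-curve variance for
## TMLE, a reuse-weighted two-sample variance for matching, closed form
## for the unadjusted difference.

#' Wald confidence interval
#' @param psi point estimate.
#' @param se standard error (>= 0).
#' @param level confidence level in (0, 1).
#' @return numeric `c(lower, upper)`.
#' @export
wald_ci <- function(psi, se, level = 0.95) {
  stopifnot(se >= 0, level > 0, level < 1)
  z <- stats::qnorm((1 + level) / 2)
  c(psi - z * se, psi + z * se)
}

#' Nonparametric bootstrap standard error and Wald interval
#'
#' Resamples rows with replacement `B` times, re-running the full
#' estimation procedure (including any model refits) on each resample.
#' The interval is Wald-style, centered at the full-data estimate with
#' the bootstrap standard deviation as SE.
#'
#' @param cohort an [cohort_table()] (or any data.frame).
#' @param statistic function taking a resampled cohort and returning a
#'   single numeric estimate.
#' @param B number of bootstrap replicates (>= 2; >= 200 for reported
#'   intervals).
#' @param seed integer seed (replicate resamples are reproducible).
#' @param level confidence level.
#' @param stratify_by_site resample within site groups instead of
#'   unconditionally (default `FALSE`).
#' @return list of class `ett_bootstrap`: `psi` (full-data estimate),
#'   `se`, `ci`, `replicates`, `n_failed`.
#' @export
bootstrap_ci <- function(cohort, statistic, B = 1000, seed = 1, level = 0.95,
                         stratify_by_site = FALSE) {
  stopifnot(B >= 2)
  psi <- statistic(cohort)
  n <- nrow(cohort)
  idx_sets <- with_seed(seed, {
    lapply(seq_len(B), function(b) {
      if (stratify_by_site) {
        s1 <- which(cohort$site_large == 1)
        s0 <- which(cohort$site_large == 0)
        c(sample(s1, replace = TRUE), sample(s0, replace = TRUE))
      } else sample.int(n, replace = TRUE)
    })
  })
  reps <- vapply(idx_sets, function(idx) {
    tryCatch(statistic(cohort_subset(cohort, idx)),
             error = function(e) NA_real_)
  }, numeric(1))
  n_failed <- sum(is.na(reps))
  if (n_failed > 0.1 * B)
    stop("bootstrap: ", n_failed, " of ", B, " replicates failed")
  if (n_failed > 0)
    warning("bootstrap: ", n_failed, " replicate(s) failed and were skipped")
  se <- stats::sd(reps, na.rm = TRUE)
  structure(list(psi = psi, se = se, ci = wald_ci(psi, se, level),
                 replicates = reps, B = B, n_failed = n_failed,
                 level = level),
            class = "ett_bootstrap")
}

#' Influence-curve standard error of the TMLE
#'
#' The per-patient efficient influence curve at the targeted solution,
#' with `p1 = P(S = 1)` estimated empirically:
#' `D = (S/p1) (Q(1,C) - Q(0,C) - psi) +
#'      [S/p1 - (1-S) g(C) / ((1 - g(C)) p1)] (Y - Q(S,C))`,
#' and `SE = sd(D) / sqrt(n)`; for continuous outcomes the EIF lives on
#' the [0, 1]-transformed scale and the SE is scaled back by the observed
#' range.
#'
#' @param state an `ett_tmle_state` (from [tmle_ett()]).
#' @return standard error (numeric scalar).
#' @export
tmle_eif_se <- function(state) {
  stopifnot(inherits(state, "ett_tmle_state"))
  if (!state$converged)
    stop("TMLE did not converge; use the bootstrap fallback for inference")
  scale_back <- if (state$binary) 1 else (state$b - state$a)
  stats::sd(state$eif) / sqrt(length(state$eif)) * scale_back
}

#' Reuse-weighted matching standard error
#'
#' Base term: the variance of the paired differences divided by the
#' number of matched treated rows.  Because controls are reused across
#' pairs (matching with replacement), paired differences are positively
#' correlated; a control matched into several pairs contributes its
#' outcome variance once per squared multiplicity.  With `K_j` the
#' (tie-fractional) number of times control `j` is used, the correction
#' adds `sigma_c^2 (sum K_j^2 - n1) / n1^2`, which is zero when no
#' control is reused and strictly positive under reuse.  The correction
#' is floored at zero so the SE is never below the naive paired SE.
#'
#' @param matched an `ett_matched` (from [matching_ett()]).
#' @param cohort the cohort the matching was run on.
#' @param outcome outcome column name.
#' @return standard error (numeric scalar).
#' @export
matching_se <- function(matched, cohort, outcome) {
  stopifnot(inherits(matched, "ett_matched"))
  d <- matched$diffs
  n1 <- length(d)
  if (n1 < 2) stop("need at least two matched treated rows")
  base <- stats::var(d) / n1
  ## tie-fractional multiplicity of each control row
  K <- numeric(nrow(cohort))
  for (m in matched$control_rows) K[m] <- K[m] + 1 / length(m)
  ## control-outcome variance from the full control pool (stable even
  ## when few distinct controls are reused)
  yc <- cohort[[outcome]][cohort$site_large == 0]
  yc <- yc[!is.na(yc)]
  sigma_c2 <- if (length(yc) > 1) stats::var(yc) else 0
  correction <- sigma_c2 * max(0, sum(K^2) - n1) / n1^2
  sqrt(base + correction)
}
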