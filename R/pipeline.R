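## Orchestration: one call running simulate -> preprocess -> fit ->
## estimate -> diagnose -> report, with a declarative run configuration,
## reproducible seeds, and CSV/JSON outputs.  The numbered scripts under
## analysis/ are thin drivers over these functions.

run_config_defaults <- list(
  input = NULL,            # path to a cohort CSV (alternative to `generator`)
  outcome_types = NULL,    # named list for CSV input: outcome -> binary/continuous
  covariate_types = NULL,  # named list for CSV input
  generator = "default",   # "default" or "null" built-in mechanism
  n_patients = 1242L,
  outcomes = NULL,         # default: all declared outcomes
  estimators = c("unadjusted", "substitution-regression", "substitution-SL",
                 "tmle", "matching"),
  library = "full",        # learner library: "full" or "reduced"
  K = 10L,                 # cross-validation folds
  delta = 0.025,           # propensity truncation
  caliper_sd = 0.05,       # matching caliper in propensity-score sds
  B = 1000L,               # bootstrap replicates
  tol = 1e-5,              # TMLE convergence tolerance
  max_iter = 50L,
  seed = 1L,
  n_mc_truth = 1e6,        # Monte-Carlo size for the ground-truth report
  output_dir = NULL
)

known_estimators <- c("unadjusted", "substitution-regression",
                      "substitution-SL", "tmle", "matching")

#' Load and validate a run configuration
#'
#' YAML or JSON; unknown keys are an error; defaults (10 folds, truncation
#' 0.025, caliper 0.05 sd, 1000 bootstrap replicates, tolerance 1e-5) fill
#' any omitted field.
#'
#' @param path file path, or a named list of overrides.
#' @return list of class `ett_run_config`.
#' @export
load_run_config <- function(path) {
  raw <- if (is.list(path)) path
  else if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), names(run_config_defaults))
  if (length(unknown)) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(run_config_defaults, raw)
  bad <- setdiff(cfg$estimators, known_estimators)
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  if (is.null(cfg$input) && !cfg$generator %in% c("default", "null"))
    stop("generator must be \"default\" or \"null\" when no input file is given")
  structure(cfg, class = c("ett_run_config", "list"))
}

#' Estimate the ETT for one outcome with the requested estimators
#'
#' Builds the indicator design once (rows with a missing value of this
#' outcome are dropped), fits the outcome regression(s) and propensity
#' score, and runs each requested estimator.  Substitution estimators get
#' their standard error from the nonparametric bootstrap, refitting all
#' models on every resample.
#'
#' @param cohort an [cohort_table()].
#' @param outcome outcome column name.
#' @param estimators subset of
#'   `c("unadjusted", "substitution-regression", "substitution-SL",
#'   "tmle", "matching")`.
#' @param library learner list for super-learner fits
#'   (default [default_library()]).
#' @param K cross-validation folds.
#' @param delta propensity truncation bound.
#' @param caliper_sd matching caliper in propensity-score sds.
#' @param B bootstrap replicates for substitution estimators (0 skips the
#'   bootstrap).
#' @param tol,max_iter TMLE fluctuation controls.
#' @param seed integer seed governing folds and bootstrap.
#' @return list of `ett_estimate` objects, named by estimator.
#' @export
estimate_ett <- function(cohort, outcome,
                         estimators = known_estimators,
                         library = default_library(),
                         K = 10, delta = 0.025, caliper_sd = 0.05,
                         B = 1000, tol = 1e-5, max_iter = 50, seed = 1) {
  bad <- setdiff(estimators, known_estimators)
  if (length(bad)) stop("unknown estimator(s): ", paste(bad, collapse = ", "))
  if (!outcome %in% names(cohort_outcomes(cohort)))
    stop("unknown outcome: ", outcome)
  binary <- cohort_outcomes(cohort)[[outcome]] == "binary"
  sub <- cohort[!is.na(cohort[[outcome]]), , drop = FALSE]
  sub <- cohort_table(as.data.frame(sub), cohort_outcomes(cohort),
                      cohort_covariates(cohort))
  design <- expand_missingness(sub)
  S <- sub$site_large
  y <- sub[[outcome]]
  seeds <- derive_subseeds(seed, 4)
  folds_y <- make_folds(nrow(sub), K = min(K, nrow(sub)), seed = seeds[1],
                        stratify_on = if (binary && min(mean(y), 1 - mean(y)) < 0.05) y)
  folds_g <- make_folds(nrow(sub), K = min(K, nrow(sub)), seed = seeds[2])

  needs_sl <- any(c("substitution-SL", "tmle", "matching") %in% estimators)
  qfit_sl <- gfit <- NULL
  if (needs_sl) {
    if (any(c("substitution-SL", "tmle") %in% estimators))
      qfit_sl <- fit_outcome_model(design, S, y, method = "superlearner",
                                   binary = binary, library = library,
                                   folds = folds_y)
    if (any(c("tmle", "matching") %in% estimators))
      gfit <- fit_propensity(design, S, method = "superlearner", delta = delta,
                             library = library, folds = folds_g)
  }

  out <- list()
  for (est in estimators) {
    out[[est]] <- switch(est,
      "unadjusted" = unadjusted_difference(sub, outcome),
      "substitution-regression" = {
        qf <- fit_outcome_model(design, S, y, method = "regression", binary = binary)
        e <- substitution_ett(sub, qf, outcome)
        if (B >= 2) {
          bs <- bootstrap_ci(sub, function(ch) {
            dgn <- expand_missingness(ch)
            qfb <- fit_outcome_model(dgn, ch$site_large, ch[[outcome]],
                                     method = "regression", binary = binary)
            substitution_ett(ch, qfb, outcome)$psi
          }, B = B, seed = seeds[3])
          e <- ett_estimate(e$estimator, e$psi, bs$se, n_treated = e$n_treated,
                            extra = list(bootstrap = bs))
        }
        e
      },
      "substitution-SL" = {
        e <- substitution_ett(sub, qfit_sl, outcome)
        if (B >= 2) {
          bs <- bootstrap_ci(sub, function(ch) {
            dgn <- expand_missingness(ch)
            fb <- make_folds(nrow(ch), K = min(K, nrow(ch)), seed = seeds[1])
            qfb <- fit_outcome_model(dgn, ch$site_large, ch[[outcome]],
                                     method = "superlearner", binary = binary,
                                     library = library, folds = fb)
            substitution_ett(ch, qfb, outcome)$psi
          }, B = B, seed = seeds[4])
          e <- ett_estimate(e$estimator, e$psi, bs$se, n_treated = e$n_treated,
                            extra = list(bootstrap = bs))
        }
        e
      },
      "tmle" = tmle_ett(sub, qfit_sl, gfit, outcome, tol = tol,
                        max_iter = max_iter),
      "matching" = matching_ett(sub, gfit, outcome, caliper_sd = caliper_sd))
  }
  out
}

#' Collect ETT estimates into a results table
#' @param estimates nested list: outcome -> estimator -> `ett_estimate`.
#' @return data.frame with one row per (outcome, estimator).
#' @export
estimates_table <- function(estimates) {
  rows <- list()
  for (oc in names(estimates)) {
    for (est in names(estimates[[oc]])) {
      e <- estimates[[oc]][[est]]
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, estimator = e$estimator, psi = e$psi, se = e$se,
        ci_lower = e$ci_lower, ci_upper = e$ci_upper,
        n_treated = e$n_treated, n_discarded = e$n_discarded)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full pipeline
#'
#' simulate (or read) -> summarize -> estimate -> diagnose -> report.
#' Writes, into `config$output_dir` (if set): the resolved configuration,
#' a bivariate summary CSV, an estimates CSV (one row per
#' outcome-estimator pair), a residual-diagnostics CSV per outcome, the
#' ground-truth JSON when the cohort is synthetic, and a plain-text log.
#'
#' @param config an [load_run_config()] object (or a named list of
#'   overrides).
#' @return list: `cohort`, `summary`, `estimates` (nested list),
#'   `estimates_table`, `diagnostics`, `truth` (synthetic input only).
#' @export
run_pipeline <- function(config = list()) {
  if (!inherits(config, "ett_run_config")) config <- load_run_config(config)
  t0 <- Sys.time()

  gen_cfg <- NULL
  if (!is.null(config$input)) {
    cohort <- read_cohort_csv(config$input,
                              outcomes = unlist(config$outcome_types),
                              covariates = unlist(config$covariate_types))
  } else {
    gen_cfg <- switch(config$generator,
                      default = default_emulator_config(config$n_patients),
                      null = null_emulator_config(config$n_patients))
    cohort <- generate_cohort(gen_cfg, seed = config$seed)
  }
  outcomes <- config$outcomes %||% names(cohort_outcomes(cohort))
  bad <- setdiff(outcomes, names(cohort_outcomes(cohort)))
  if (length(bad)) stop("unknown outcome(s): ", paste(bad, collapse = ", "))

  summary_tab <- bivariate_summary(cohort)
  lib <- default_library(reduced = identical(config$library, "reduced"))

  estimates <- list()
  diagnostics <- list()
  for (oc in outcomes) {
    estimates[[oc]] <- estimate_ett(
      cohort, oc, estimators = config$estimators, library = lib,
      K = config$K, delta = config$delta, caliper_sd = config$caliper_sd,
      B = config$B, tol = config$tol, max_iter = config$max_iter,
      seed = config$seed)
  }

  ## diagnostics on the first binary outcome (mortality-style risk axis)
  bin_out <- outcomes[cohort_outcomes(cohort)[outcomes] == "binary"]
  if (length(bin_out)) {
    oc <- bin_out[1]
    sub <- cohort[!is.na(cohort[[oc]]), , drop = FALSE]
    sub <- cohort_table(as.data.frame(sub), cohort_outcomes(cohort),
                        cohort_covariates(cohort))
    design <- expand_missingness(sub)
    qf <- fit_outcome_model(design, sub$site_large, sub[[oc]],
                            method = "regression", binary = TRUE)
    res <- counterfactual_residuals(sub, qf, qf, oc)
    diagnostics$residuals <- res
    diagnostics$curves <- loess_curves(res)
    diagnostics$histogram <- risk_histogram(res)
  }

  truth <- NULL
  if (!is.null(gen_cfg)) {
    truth <- lapply(outcomes, function(oc)
      true_ett(gen_cfg, oc, n_mc = config$n_mc_truth, seed = config$seed))
    names(truth) <- outcomes
  }

  tab <- estimates_table(estimates)

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    out <- function(f) file.path(config$output_dir, f)
    yaml::write_yaml(unclass(config), out("config_resolved.yaml"))
    utils::write.csv(summary_tab, out("cohort_summary.csv"), row.names = FALSE)
    utils::write.csv(tab, out("estimates.csv"), row.names = FALSE)
    if (!is.null(diagnostics$residuals))
      utils::write.csv(diagnostics$residuals, out("residuals.csv"), row.names = FALSE)
    if (!is.null(truth))
      jsonlite::write_json(lapply(truth, unclass), out("truth.json"),
                           auto_unbox = TRUE, digits = NA)
    writeLines(c(
      sprintf("ettmachine %s", as.character(utils::packageVersion("ettmachine"))),
      sprintf("seed: %d", config$seed),
      sprintf("outcomes: %s", paste(outcomes, collapse = ", ")),
      sprintf("estimators: %s", paste(config$estimators, collapse = ", ")),
      sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs")))
    ), out("run.log"))
  }

  list(cohort = cohort, summary = summary_tab, estimates = estimates,
       estimates_table = tab, diagnostics = diagnostics, truth = truth)
}
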