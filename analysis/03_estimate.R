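#!/usr/bin/env Rscript

## Step 3 — estimate the effect among the treated.
##
## For each outcome: unadjusted difference, substitution estimators
## (main-terms regression and super-learner outcome fits, bootstrap SEs),
## TMLE with influence-curve SEs, and propensity-score caliper matching.
## The results table mirrors the outcomes-by-estimators layout of a
## comparative-effectiveness report.

suppressPackageStartupMessages(library(ettmachine))

cohort <- read_cohort_csv(
  "results/cohort.csv",
  outcomes = c(overall_mortality = "binary", mof = "binary",
               plasma_24h = "continuous"),
  covariates = c(age = "continuous", male = "binary", penetrating = "binary",
                 iss = "continuous", ed_sbp = "continuous",
                 hemoglobin = "continuous", base_deficit = "continuous"))

estimates <- list()
for (oc in c("overall_mortality", "mof", "plasma_24h")) {
  cat("estimating", oc, "...\n")
  estimates[[oc]] <- suppressWarnings(estimate_ett(
    cohort, oc,
    library = default_library(reduced = TRUE),  # study size: keep refits honest but fast
    B = 200, seed = 7))
}

tab <- estimates_table(estimates)
write.csv(tab, "results/estimates.csv", row.names = FALSE)
print(tab, digits = 3)

truth <- jsonlite::read_json("results/truth.json", simplifyVector = TRUE)
cat("\nestimates vs mechanism truth:\n")
for (oc in names(estimates)) {
  cat(sprintf("  %-18s truth %8.4g | tmle %8.4g | matching %8.4g | unadjusted %8.4g\n",
              oc, truth[[oc]]$psi0,
              estimates[[oc]]$tmle$psi,
              estimates[[oc]]$matching$psi,
              estimates[[oc]]$unadjusted$psi))
}
cat("wrote results/estimates.csv\n")
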