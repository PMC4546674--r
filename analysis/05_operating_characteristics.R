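#!/usr/bin/env Rscript

## Step 5 — operating characteristics at desk scale.
##
## A compact replication study over the emulator mechanism: 50 cohorts of
## 1,250 patients, TMLE and unadjusted estimates per cohort, summarized
## as bias against the Monte-Carlo truth and 95% CI coverage.  The full
## 200-replicate versions of these checks (plus double robustness and
## null calibration) run in the package's test suite.

suppressPackageStartupMessages(library(ettmachine))

cfg <- default_emulator_config(1250)
truth <- true_ett(cfg, "overall_mortality", n_mc = 1e6, seed = 99)
lib <- default_library(reduced = TRUE)

r <- suppressWarnings(vapply(1:50, function(s) {
  ch <- generate_cohort(cfg, seed = 60000 + s)
  d <- expand_missingness(ch)
  S <- ch$site_large; y <- ch$overall_mortality
  qf <- fit_outcome_model(d, S, y, method = "superlearner", library = lib,
                          folds = make_folds(length(y), 10, seed = s))
  gf <- fit_propensity(d, S, method = "superlearner", library = lib,
                       folds = make_folds(length(y), 10, seed = s + 1))
  tm <- tmle_ett(ch, qf, gf, "overall_mortality")
  un <- unadjusted_difference(ch, "overall_mortality")
  c(tmle = tm$psi, tmle_cover = tm$ci_lower <= truth$psi0 & truth$psi0 <= tm$ci_upper,
    unadj = un$psi)
}, numeric(3)))

summary_tab <- data.frame(
  estimator = c("tmle", "unadjusted"),
  mean_estimate = c(mean(r["tmle", ]), mean(r["unadj", ])),
  bias = c(mean(r["tmle", ]) - truth$psi0, mean(r["unadj", ]) - truth$psi0),
  sd = c(sd(r["tmle", ]), sd(r["unadj", ])),
  coverage_95 = c(mean(r["tmle_cover", ]), NA))
dir.create("results", showWarnings = FALSE)
write.csv(summary_tab, "results/operating_characteristics.csv", row.names = FALSE)

cat(sprintf("truth: %.4f\n", truth$psi0))
print(summary_tab, digits = 3)
cat(sprintf("\n|unadjusted bias| / |tmle bias| = %.1f (net confounding of mortality is mild\nunder these defaults: the site differences partially cancel).\n",
            abs(summary_tab$bias[2]) / max(abs(summary_tab$bias[1]), 1e-6)))
cat("wrote results/operating_characteristics.csv\n")
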