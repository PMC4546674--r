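## Interpretability layer: counterfactual residuals against a common
## mortality-risk axis, loess smooths, divergence-region subgrouping,
## matched-set balance with hierarchical clustering, and risk histograms.

#' Counterfactual residuals
#'
#' For every patient, the observed outcome minus the model prediction at
#' the *opposite* site value: `r = Y - Q(1 - S, C)`.  For treated rows the
#' mean residual equals the substitution ETT exactly.  The accompanying
#' risk score is the overall-mortality model's prediction with the site
#' set to 1 for every patient (one common counterfactual scale).
#'
#' @param cohort an [cohort_table()].
#' @param qfit_outcome outcome-model fit for the outcome under study.
#' @param qfit_mortality outcome-model fit for overall mortality (risk
#'   axis); may be the same object as `qfit_outcome`.
#' @param outcome outcome column name.
#' @param risk_site site value at which the risk axis is evaluated
#'   (default 1; set `NULL` to use each patient's factual site).
#' @return data.frame of class `ett_residuals`: `id`, `site_large`,
#'   `residual`, `risk`.
#' @export
counterfactual_residuals <- function(cohort, qfit_outcome, qfit_mortality,
                                     outcome, risk_site = 1) {
  S <- qfit_outcome$S
  y <- cohort[[outcome]][cohort$id %in% qfit_outcome$design$id]
  n_dropped <- sum(is.na(y))
  if (n_dropped > 0) message(n_dropped, " row(s) with missing outcome excluded")
  q_cf <- ifelse(S == 1, predict_qbar(qfit_outcome, 0), predict_qbar(qfit_outcome, 1))
  risk <- if (is.null(risk_site)) {
    ifelse(S == 1, predict_qbar(qfit_mortality, 1), predict_qbar(qfit_mortality, 0))
  } else predict_qbar(qfit_mortality, risk_site)
  keep <- !is.na(y)
  out <- data.frame(id = qfit_outcome$design$id[keep],
                    site_large = S[keep],
                    residual = (y - q_cf)[keep],
                    risk = risk[keep])
  class(out) <- c("ett_residuals", "data.frame")
  out
}

#' Loess smooths of counterfactual residuals by site group
#'
#' Local-linear smooth (tricube kernel via [stats::loess()], exact
#' "direct" surface) of residuals against the risk score, per site group,
#' evaluated on a 100-point grid within each group's observed risk range,
#' with pointwise standard-error bands from the local weighted residual
#' variance.  The bands are exploratory only — they are not reliable
#' post-hoc inference.
#'
#' @param residuals an [counterfactual_residuals()] result.
#' @param span loess span in (0, 1].
#' @param n_grid grid size.
#' @return data.frame of class `ett_loess`: `site_large`, `risk`
#'   (grid), `fit`, `band` (pointwise SE half-width at 1 sd).
#' @export
loess_curves <- function(residuals, span = 0.75, n_grid = 100) {
  if (span <= 0 || span > 1) stop("span must lie in (0, 1]")
  one <- function(d, s) {
    if (nrow(d) < 10) stop("need >= 10 points per site group")
    fit <- stats::loess(residual ~ risk, data = d, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    grid <- seq(min(d$risk), max(d$risk), length.out = n_grid)
    pr <- stats::predict(fit, newdata = data.frame(risk = grid), se = TRUE)
    data.frame(site_large = s, risk = grid, fit = as.vector(pr$fit),
               band = as.vector(pr$se.fit))
  }
  groups <- intersect(c(1, 0), unique(residuals$site_large))
  out <- do.call(rbind, lapply(groups, function(s)
    one(residuals[residuals$site_large == s, , drop = FALSE], s)))
  structure(out, span = span, class = c("ett_loess", "data.frame"))
}

#' Partition patients at the point where the smoothed residuals diverge
#'
#' The cutoff is the smallest grid risk value from which the absolute
#' smoothed residual exceeds `threshold` persistently — over a
#' consecutive run covering at least 10% of the remaining grid.  Patients
#' (of the curve's site group) with risk at or beyond the cutoff are
#' flagged and split by residual sign.  A curve that never exceeds the
#' threshold yields an empty flagged region.
#'
#' @param curve one site group's rows of an [loess_curves()] result.
#' @param residuals the matching [counterfactual_residuals()] result.
#' @param threshold divergence threshold on the absolute smoothed
#'   residual; default half the median pointwise band half-width.
#' @return list of class `ett_partition`: `cutoff` (risk value or `Inf`),
#'   `flagged_ids`, `unflagged_ids`, `positive_ids`, `negative_ids`.
#' @export
partition_by_divergence <- function(curve, residuals, threshold = NULL) {
  stopifnot(length(unique(curve$site_large)) == 1)
  s <- curve$site_large[1]
  threshold <- threshold %||% (0.5 * stats::median(curve$band))
  exceed <- abs(curve$fit) > threshold
  m <- length(exceed)
  cutoff <- Inf
  for (i in seq_len(m)) {
    if (!exceed[i]) next
    need <- max(1L, ceiling(0.1 * (m - i + 1L)))
    if (i + need - 1L <= m && all(exceed[i:(i + need - 1L)])) {
      cutoff <- curve$risk[i]
      break
    }
  }
  r <- residuals[residuals$site_large == s, , drop = FALSE]
  flagged <- r$risk >= cutoff
  structure(list(cutoff = cutoff, threshold = threshold, site_large = s,
                 flagged_ids = r$id[flagged],
                 unflagged_ids = r$id[!flagged],
                 positive_ids = r$id[flagged & r$residual > 0],
                 negative_ids = r$id[flagged & r$residual <= 0]),
            class = "ett_partition")
}

#' Compare flagged versus unflagged patients
#'
#' Per covariate and outcome: mean (sd) in each subgroup and a two-sided
#' p-value — Welch t-test for ordered variables, Pearson chi-square
#' (without continuity correction) for binary ones.  Degenerate inputs
#' (zero margin, zero variance in both groups) report p = 1 with a
#' warning.
#'
#' @param cohort an [cohort_table()].
#' @param partition an [partition_by_divergence()] result.
#' @return data.frame: variable, subgroup means/sds, p-value, test label.
#' @export
compare_subgroups <- function(cohort, partition) {
  in_ids <- partition$flagged_ids
  out_ids <- partition$unflagged_ids
  if (!length(in_ids) || !length(out_ids)) stop("both subgroups must be nonempty")
  covs <- cohort_covariates(cohort)
  outs <- cohort_outcomes(cohort)
  vars <- c(covs, setNames(ifelse(outs == "binary", "binary", "continuous"),
                           names(outs)))
  vars <- vars[vars != "categorical"]
  rows <- lapply(names(vars), function(nm) {
    vin <- cohort[[nm]][cohort$id %in% in_ids]
    vout <- cohort[[nm]][cohort$id %in% out_ids]
    vin <- vin[!is.na(vin)]; vout <- vout[!is.na(vout)]
    if (vars[[nm]] == "binary") {
      tab <- rbind(c(sum(vin == 1), sum(vin == 0)),
                   c(sum(vout == 1), sum(vout == 0)))
      p <- if (any(colSums(tab) == 0) || any(rowSums(tab) == 0)) {
        warning("degenerate 2x2 margin for ", nm, "; p reported as 1")
        1
      } else if (stats::sd(c(vin, vout)) == 0) 1 else {
        unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value))
      }
      data.frame(variable = nm, mean_in = mean(vin), sd_in = NA_real_,
                 mean_out = mean(vout), sd_out = NA_real_,
                 p_value = p, test = "Pearson chi-square")
    } else {
      p <- if (stats::sd(vin) == 0 && stats::sd(vout) == 0) {
        if (mean(vin) == mean(vout)) 1 else 0
      } else unname(stats::t.test(vin, vout)$p.value)
      data.frame(variable = nm, mean_in = mean(vin), sd_in = stats::sd(vin),
                 mean_out = mean(vout), sd_out = stats::sd(vout),
                 p_value = p, test = "Welch t")
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Standardized mean differences between site groups
#' @param x numeric design matrix.
#' @param S site indicator.
#' @return named numeric vector of SMDs (difference in means over pooled sd).
#' @keywords internal
smd <- function(x, S) {
  apply(x, 2, function(col) {
    m1 <- mean(col[S == 1]); m0 <- mean(col[S == 0])
    s1 <- stats::var(col[S == 1]); s0 <- stats::var(col[S == 0])
    pooled <- sqrt((s1 + s0) / 2)
    if (!is.finite(pooled) || pooled == 0) return(0)
    (m1 - m0) / pooled
  })
}

#' Balance diagnostics for a matched set
#'
#' Builds the matched data set (matched treated rows plus their matched
#' controls, tie-weighted multiplicities rounded to inclusion), scales
#' the covariate columns, runs agglomerative hierarchical clustering of
#' patients (Euclidean distance, average linkage), and reports
#' per-covariate standardized mean differences before and after matching
#' together with a chi-square association test between 2-cluster
#' membership and site label.  Little cluster-site association indicates
#' covariate balance.
#'
#' @param matched an `ett_matched` (from [matching_ett()]).
#' @param design the [expand_missingness()] design of the full cohort.
#' @param S site indicator of the full cohort.
#' @return list of class `ett_balance`: `smd_pre`, `smd_post`,
#'   `hclust` (the dendrogram), `order`, `site`, `cluster`,
#'   `cluster_site_p` (chi-square p-value), `scaled` matrix.
#' @export
matched_balance <- function(matched, design, S) {
  t_rows <- matched$treated_rows
  c_rows <- unique(unlist(matched$control_rows))
  rows <- c(t_rows, c_rows)
  if (length(rows) < 3) stop("need at least 3 matched rows")
  sm <- standardize_design(design)
  xs <- sm$x[rows, , drop = FALSE]
  s_m <- S[rows]
  hc <- stats::hclust(stats::dist(xs, method = "euclidean"), method = "average")
  cl <- stats::cutree(hc, k = 2)
  tab <- table(cl, s_m)
  p <- if (any(dim(tab) < 2) || any(rowSums(tab) == 0) || any(colSums(tab) == 0)) 1
       else unname(suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value))
  structure(list(smd_pre = smd(design$x, S),
                 smd_post = smd(design$x[rows, , drop = FALSE], s_m),
                 hclust = hc, order = hc$order, site = s_m, cluster = cl,
                 cluster_site_p = p, scaled = xs),
            class = "ett_balance")
}

#' Histogram of risk scores by site group
#'
#' Shared bin edges over [0, 1].
#'
#' @param residuals an [counterfactual_residuals()] result.
#' @param bins number of bins (>= 2).
#' @return data.frame: `bin_lower`, `bin_upper`, `count_small`,
#'   `count_large`.
#' @export
risk_histogram <- function(residuals, bins = 20) {
  stopifnot(bins >= 2)
  edges <- seq(0, 1, length.out = bins + 1)
  cut_counts <- function(x) {
    idx <- pmin(pmax(findInterval(x, edges, rightmost.closed = TRUE), 1L), bins)
    tabulate(idx, nbins = bins)
  }
  data.frame(bin_lower = edges[-(bins + 1)], bin_upper = edges[-1],
             count_small = cut_counts(residuals$risk[residuals$site_large == 0]),
             count_large = cut_counts(residuals$risk[residuals$site_large == 1]))
}
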