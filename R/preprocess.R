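## Missingness-indicator design basis and cohort summaries.
##
## Rather than imputing, every sometimes-missing covariate C_j is replaced
## by the fully observed pair (Delta_j, Delta_j * C_j), where Delta_j = 1
## when the value was recorded.  Both columns enter all downstream model
## fits (outcome and propensity), so informative missingness can be used
## by the learners directly.

#' Expand a cohort into the fully observed indicator design basis
#'
#' Categorical covariates are first expanded to reference-coded indicators
#' (modal category as reference).  Covariates with zero observed
#' missingness keep a single value column; sometimes-missing covariates
#' contribute the pair `<name>_obs` (the Delta indicator) and `<name>`
#' (Delta * C, i.e. the value with 0 where masked).
#'
#' @param cohort an [cohort_table()].
#' @return object of class `ett_design`: list with `x` (numeric matrix,
#'   no missing entries), `continuous` (names of continuous value
#'   columns, used by [standardize_design()]), and `id`.
#' @export
expand_missingness <- function(cohort) {
  stopifnot(nrow(cohort) > 0)
  covs <- cohort_covariates(cohort)
  cols <- list()
  continuous <- character()
  for (nm in names(covs)) {
    v <- cohort[[nm]]
    if (all(is.na(v))) stop("covariate entirely missing: ", nm)
    if (covs[[nm]] == "categorical") {
      ## reference-code with the modal observed level as reference
      lev <- names(sort(table(v), decreasing = TRUE))
      for (l in lev[-1]) {
        ind <- as.numeric(v == l)
        cols[[paste0(nm, "_", make.names(l))]] <- ind  # NA propagates; handled below
      }
      ## each dummy shares the covariate's missingness
      dummy_names <- paste0(nm, "_", make.names(lev[-1]))
      if (anyNA(v)) {
        delta <- as.numeric(!is.na(v))
        cols[[paste0(nm, "_obs")]] <- delta
        for (dn in dummy_names) cols[[dn]][is.na(cols[[dn]])] <- 0
      }
    } else {
      if (anyNA(v)) {
        delta <- as.numeric(!is.na(v))
        val <- ifelse(is.na(v), 0, v)
        cols[[paste0(nm, "_obs")]] <- delta
        cols[[nm]] <- val
      } else {
        cols[[nm]] <- v
      }
      if (covs[[nm]] == "continuous") continuous <- c(continuous, nm)
    }
  }
  x <- do.call(cbind, cols)
  rownames(x) <- NULL
  stopifnot(!anyNA(x))
  structure(list(x = x, continuous = continuous, id = cohort$id),
            class = "ett_design")
}

#' Standardize the continuous columns of a design
#'
#' Continuous value columns are centered to mean 0 and scaled to sd 1;
#' binary and indicator columns are left untouched (keeps matching
#' distances and heatmap colors interpretable).  Zero-variance continuous
#' columns are left unscaled with a warning.
#'
#' @param design an `ett_design` (or plain numeric matrix, in which case
#'   all columns with more than two distinct values are treated as
#'   continuous).
#' @param params optional scaling parameters from a previous call, applied
#'   as-is to new rows.
#' @return list with `x` (scaled matrix) and `params` (named list of
#'   `center` and `scale` vectors).
#' @export
standardize_design <- function(design, params = NULL) {
  if (inherits(design, "ett_design")) {
    x <- design$x
    cont <- design$continuous
  } else {
    x <- as.matrix(design)
    cont <- colnames(x)[apply(x, 2, function(col) length(unique(col)) > 2)]
  }
  if (is.null(params)) {
    center <- vapply(cont, function(cn) mean(x[, cn]), numeric(1))
    scale <- vapply(cont, function(cn) stats::sd(x[, cn]), numeric(1))
    degenerate <- scale == 0 | is.na(scale)
    if (any(degenerate)) {
      warning("zero-variance continuous column(s) left unscaled: ",
              paste(cont[degenerate], collapse = ", "))
      center[degenerate] <- 0
      scale[degenerate] <- 1
    }
    params <- list(center = center, scale = scale)
  }
  for (cn in names(params$center)) {
    if (cn %in% colnames(x))
      x[, cn] <- (x[, cn] - params$center[[cn]]) / params$scale[[cn]]
  }
  list(x = x, params = params)
}

## pooled two-proportion z-test (no continuity correction)
two_prop_z <- function(x1, n1, x2, n2) {
  p1 <- x1 / n1; p2 <- x2 / n2
  p <- (x1 + x2) / (n1 + n2)
  se <- sqrt(p * (1 - p) * (1 / n1 + 1 / n2))
  if (se == 0) return(list(z = 0, p = 1))
  z <- (p1 - p2) / se
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Bivariate cohort summary by site
#'
#' One row per variable (covariates, their missingness indicators, and
#' outcomes): per-site mean (sd) for continuous variables or percentage
#' for binary ones, the missing percentage, and a two-sided p-value —
#' rank-sum (Mann-Whitney, normal approximation with tie correction and
#' no continuity correction) for continuous variables, pooled
#' two-proportion Z-test for binary ones.
#'
#' @param cohort an [cohort_table()].
#' @return data.frame of class `ett_bivariate`.
#' @export
bivariate_summary <- function(cohort) {
  S <- cohort$site_large
  if (length(unique(S)) < 2) stop("both site levels must be present")
  covs <- cohort_covariates(cohort)
  outs <- cohort_outcomes(cohort)
  vars <- c(covs, setNames(ifelse(outs == "binary", "binary", "continuous"), names(outs)))

  one <- function(nm, type) {
    v <- cohort[[nm]]
    v0 <- v[S == 0]; v1 <- v[S == 1]
    miss0 <- mean(is.na(v0)); miss1 <- mean(is.na(v1))
    rows <- list()
    if (type == "binary") {
      x0 <- sum(v0 == 1, na.rm = TRUE); n0 <- sum(!is.na(v0))
      x1 <- sum(v1 == 1, na.rm = TRUE); n1 <- sum(!is.na(v1))
      zt <- two_prop_z(x1, n1, x0, n0)
      rows[[1]] <- data.frame(
        variable = nm, type = "binary",
        small = 100 * x0 / n0, small_sd = NA_real_,
        large = 100 * x1 / n1, large_sd = NA_real_,
        p_value = zt$p, test = "two-proportion Z")
    } else if (type == "categorical") {
      for (l in sort(unique(stats::na.omit(v)))) {
        x0 <- sum(v0 == l, na.rm = TRUE); n0 <- sum(!is.na(v0))
        x1 <- sum(v1 == l, na.rm = TRUE); n1 <- sum(!is.na(v1))
        zt <- two_prop_z(x1, n1, x0, n0)
        rows[[length(rows) + 1]] <- data.frame(
          variable = paste0(nm, ": ", l), type = "binary",
          small = 100 * x0 / n0, small_sd = NA_real_,
          large = 100 * x1 / n1, large_sd = NA_real_,
          p_value = zt$p, test = "two-proportion Z")
      }
    } else {
      wt <- suppressWarnings(stats::wilcox.test(v1, v0, exact = FALSE, correct = FALSE))
      rows[[1]] <- data.frame(
        variable = nm, type = "continuous",
        small = mean(v0, na.rm = TRUE), small_sd = stats::sd(v0, na.rm = TRUE),
        large = mean(v1, na.rm = TRUE), large_sd = stats::sd(v1, na.rm = TRUE),
        p_value = unname(wt$p.value), test = "Mann-Whitney U")
    }
    if (miss0 > 0 || miss1 > 0) {
      zt <- two_prop_z(sum(is.na(v1)), length(v1), sum(is.na(v0)), length(v0))
      rows[[length(rows) + 1]] <- data.frame(
        variable = paste0(nm, ": missing"), type = "binary",
        small = 100 * miss0, small_sd = NA_real_,
        large = 100 * miss1, large_sd = NA_real_,
        p_value = zt$p, test = "two-proportion Z")
    }
    do.call(rbind, rows)
  }

  out <- do.call(rbind, lapply(names(vars), function(nm) one(nm, vars[[nm]])))
  rownames(out) <- NULL
  class(out) <- c("ett_bivariate", "data.frame")
  out
}

#' Render a bivariate summary as a monospaced text table
#' @param x an `ett_bivariate`.
#' @param ... unused.
#' @export
format.ett_bivariate <- function(x, ...) {
  fmt <- function(m, s, type) {
    ifelse(type == "binary", sprintf("%.1f%%", m), sprintf("%.1f (%.1f)", m, s))
  }
  d <- data.frame(Variable = x$variable,
                  Small = fmt(x$small, x$small_sd, x$type),
                  Large = fmt(x$large, x$large_sd, x$type),
                  p = sprintf("%.3f", x$p_value))
  paste(utils::capture.output(print(d, row.names = FALSE)), collapse = "\n")
}

#' @export
print.ett_bivariate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}
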