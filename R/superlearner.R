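## From-scratch cross-validated ensemble stacking ("super learner").
##
## Learners are fit on each of K training folds; their held-out
## predictions form an n-by-L matrix; the ensemble weight vector is the
## convex combination minimizing cross-validated risk (squared error or
## Bernoulli negative log-likelihood); each learner is then refit on the
## full data for prediction.

#' Assign V-fold cross-validation folds
#'
#' Fold sizes differ by at most one.  With `stratify_on` given (a binary
#' vector), each fold's positive count differs from exact proportionality
#' by at most one — used for rare binary outcomes so no fold is empty of
#' positives.
#'
#' @param n number of rows.
#' @param K number of folds (default 10).
#' @param seed integer seed.
#' @param stratify_on optional binary vector of length `n`.
#' @return object of class `ett_folds`: list with `K` and integer
#'   `assignment` of length `n`.
#' @export
make_folds <- function(n, K = 10, seed = 1, stratify_on = NULL) {
  if (K > n) stop("K must not exceed n")
  stopifnot(K >= 2)
  assignment <- integer(n)
  with_seed(seed, {
    if (is.null(stratify_on)) {
      ord <- sample.int(n)
      assignment[ord] <- rep_len(seq_len(K), n)
    } else {
      stopifnot(length(stratify_on) == n)
      ## deal strata into folds consecutively on one K-cycle so overall
      ## fold sizes also stay within one of each other
      pos <- 0L
      for (s in sort(unique(stratify_on), decreasing = TRUE)) {
        idx <- which(stratify_on == s)
        idx <- idx[sample.int(length(idx))]
        assignment[idx] <- ((pos + seq_along(idx) - 1L) %% K) + 1L
        pos <- pos + length(idx)
      }
    }
  })
  structure(list(K = K, assignment = assignment), class = "ett_folds")
}

## --- learner library -----------------------------------------------------
##
## A learner is a list(name, fit(x, y, family) -> model,
## predict(model, x) -> numeric).  `family` is "binomial" or "gaussian".

#' Built-in learners
#'
#' Constructors for the learner library: `lrn_mean` (grand mean),
#' `lrn_glm` (main-terms linear/logistic regression; falls back to a
#' ridge fit under separation or rank problems), `lrn_glmnet`
#' (L1-penalized, penalty by inner cross-validation), `lrn_forest`
#' (shallow random forest), `lrn_knn` (k-nearest-neighbor mean over
#' standardized columns).
#'
#' @param k neighbors for `lrn_knn`.
#' @param num.trees,max.depth forest size and depth for `lrn_forest`.
#' @return a learner spec (list with `name`, `fit`, `predict`).
#' @name learners
NULL

#' @rdname learners
#' @export
lrn_mean <- function() {
  list(name = "mean",
       fit = function(x, y, family) mean(y),
       predict = function(model, x) rep(model, nrow(x)))
}

glm_is_suspect <- function(fit) {
  cf <- stats::coef(fit)
  !fit$converged || any(abs(cf[!is.na(cf)]) > 15)
}

ridge_backup <- function(x, y, family) {
  x2 <- cbind(x, `..pad` = 0)  # glmnet needs >= 2 columns
  glmnet::glmnet(x2, y, family = family, alpha = 0, lambda = 1e-3)
}

#' @rdname learners
#' @export
lrn_glm <- function() {
  list(
    name = "glm",
    fit = function(x, y, family) {
      d <- data.frame(y = y, x, check.names = FALSE)
      fit <- suppressWarnings(stats::glm(y ~ ., data = d, family = family))
      if (family == "binomial" && glm_is_suspect(fit)) {
        warning("glm learner unstable (possible separation); ridge fallback used")
        return(list(kind = "ridge", fit = ridge_backup(as.matrix(x), y, family)))
      }
      list(kind = "glm", fit = fit)
    },
    predict = function(model, x) {
      if (model$kind == "glm") {
        unname(stats::predict(model$fit, newdata = as.data.frame(x), type = "response"))
      } else {
        as.vector(stats::predict(model$fit, newx = cbind(as.matrix(x), `..pad` = 0),
                                 type = "response"))
      }
    }
  )
}

#' @rdname learners
#' @export
lrn_glm_interactions <- function(with = "site_large") {
  ## main-terms GLM plus interactions of one focal column (by default the
  ## site exposure) with every other predictor; reduces to lrn_glm when
  ## the focal column is absent
  list(
    name = paste0("glm_x_", with),
    fit = function(x, y, family) {
      d <- data.frame(y = y, x, check.names = FALSE)
      form <- if (with %in% colnames(x))
        stats::as.formula(paste0("y ~ . + `", with, "` * .")) else y ~ .
      fit <- suppressWarnings(stats::glm(form, data = d, family = family))
      if (family == "binomial" && glm_is_suspect(fit)) {
        warning("interaction glm learner unstable; ridge fallback used")
        return(list(kind = "ridge", fit = ridge_backup(as.matrix(x), y, family)))
      }
      list(kind = "glm", fit = fit)
    },
    predict = function(model, x) {
      if (model$kind == "glm")
        unname(stats::predict(model$fit, newdata = as.data.frame(x), type = "response"))
      else
        as.vector(stats::predict(model$fit, newx = cbind(as.matrix(x), `..pad` = 0),
                                 type = "response"))
    }
  )
}

#' @rdname learners
#' @export
lrn_glmnet <- function() {
  list(
    name = "glmnet",
    fit = function(x, y, family) {
      x <- as.matrix(x)
      if (ncol(x) < 2) x <- cbind(x, `..pad` = 0)
      glmnet::cv.glmnet(x, y, family = family, alpha = 1, nfolds = 5)
    },
    predict = function(model, x) {
      x <- as.matrix(x)
      if (ncol(x) < 2) x <- cbind(x, `..pad` = 0)
      as.vector(stats::predict(model, newx = x, s = "lambda.min", type = "response"))
    }
  )
}

#' @rdname learners
#' @export
lrn_forest <- function(num.trees = 300, max.depth = 4) {
  list(
    name = "forest",
    fit = function(x, y, family) {
      d <- data.frame(y = y, x, check.names = FALSE)
      ranger::ranger(y ~ ., data = d, num.trees = num.trees,
                     max.depth = max.depth, min.node.size = 20,
                     seed = 1, num.threads = 1)
    },
    predict = function(model, x) {
      stats::predict(model, data = as.data.frame(x), num.threads = 1)$predictions
    }
  )
}

#' @rdname learners
#' @export
lrn_knn <- function(k = 20) {
  list(
    name = "knn",
    fit = function(x, y, family) {
      x <- as.matrix(x)
      ctr <- colMeans(x)
      scl <- apply(x, 2, stats::sd)
      scl[scl == 0] <- 1
      list(x = sweep(sweep(x, 2, ctr), 2, scl, "/"), y = y,
           ctr = ctr, scl = scl, k = min(k, length(y)))
    },
    predict = function(model, x) {
      xn <- sweep(sweep(as.matrix(x), 2, model$ctr), 2, model$scl, "/")
      ## squared Euclidean distances via the cross-product expansion
      d2 <- outer(rowSums(xn^2), rowSums(model$x^2), "+") - 2 * xn %*% t(model$x)
      apply(d2, 1, function(row) mean(model$y[order(row)[seq_len(model$k)]]))
    }
  )
}

#' Default learner library
#'
#' Ordered from simple to complex; degenerate weight ties are broken in
#' favor of earlier (simpler) learners.
#'
#' @param reduced if `TRUE`, return only the parametric learners (mean,
#'   main-terms GLM, site-interaction GLM) — used for large simulation
#'   studies where thousands of refits are needed.
#' @return list of learner specs.
#' @export
default_library <- function(reduced = FALSE) {
  if (reduced) list(lrn_mean(), lrn_glm(), lrn_glm_interactions())
  else list(lrn_mean(), lrn_glm(), lrn_glm_interactions(), lrn_glmnet(),
            lrn_forest(), lrn_knn())
}

## --- simplex weight solver ----------------------------------------------

## Euclidean projection onto the probability simplex (Duchi et al.)
project_simplex <- function(v) {
  u <- sort(v, decreasing = TRUE)
  css <- cumsum(u)
  rho <- max(which(u - (css - 1) / seq_along(u) > 0))
  theta <- (css[rho] - 1) / rho
  pmax(v - theta, 0)
}

cv_risk <- function(pred, y, loss, bound = 0.001) {
  if (loss == "bernoulli") {
    p <- bound(pred, bound, 1 - bound)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((y - pred)^2)
  }
}

## minimize CV risk of Z %*% alpha over the simplex by projected gradient
solve_simplex_weights <- function(Z, y, loss, bound = 0.001,
                                  max_iter = 1000, tol = 1e-12) {
  L <- ncol(Z)
  if (loss == "bernoulli") Z <- bound(Z, bound, 1 - bound)
  ok <- apply(Z, 2, function(col) all(is.finite(col)))
  Z[, !ok] <- 0  # failed learners: excluded from objective, forced to weight 0
  alpha <- ifelse(ok, 1, 0)
  alpha <- alpha / sum(alpha)
  obj <- function(a) {
    p <- as.vector(Z %*% a)
    cv_risk(p, y, loss, bound)
  }
  grad <- function(a) {
    p <- as.vector(Z %*% a)
    if (loss == "bernoulli") {
      p <- bound(p, bound, 1 - bound)
      as.vector(crossprod(Z, (p - y) / (p * (1 - p)))) / length(y)
    } else {
      -2 * as.vector(crossprod(Z, y - p)) / length(y)
    }
  }
  f <- obj(alpha)
  step <- 1
  for (it in seq_len(max_iter)) {
    g <- grad(alpha)
    g[!ok] <- max(g[ok]) + 1  # never step toward failed learners
    repeat {
      cand <- project_simplex(alpha - step * g)
      cand[!ok] <- 0
      if (sum(cand) == 0) cand <- alpha
      cand <- cand / sum(cand)
      fc <- obj(cand)
      if (fc <= f + 1e-15 || step < 1e-12) break
      step <- step / 2
    }
    moved <- sum(abs(cand - alpha))
    alpha <- cand
    if (f - fc < tol && it > 10) { f <- fc; break }
    f <- fc
    step <- min(step * 2, 1e3)
    if (moved < 1e-14) break
  }
  ## polish: a vertex (single learner) may still beat the interior point;
  ## taking the earliest such vertex also enforces the simple-first
  ## tie-break
  vrisk <- vapply(seq_len(L), function(l) {
    if (!ok[l]) return(Inf)
    e <- numeric(L); e[l] <- 1
    obj(e)
  }, numeric(1))
  best <- which.min(vrisk)
  if (vrisk[best] <= f + 1e-12) {
    alpha <- numeric(L); alpha[best] <- 1
    f <- vrisk[best]
  }
  alpha[alpha < 1e-8] <- 0
  alpha <- alpha / sum(alpha)
  list(alpha = alpha, risk = obj(alpha))
}

## --- super learner --------------------------------------------------------

#' Fit a cross-validated stacking ensemble
#'
#' @param x numeric matrix or data.frame of fully observed predictors
#'   (typically an indicator design basis, plus the site column when
#'   fitting an outcome model).
#' @param y outcome vector; must be 0/1 for `loss = "bernoulli"`.
#' @param library list of learner specs (see [default_library()]).
#' @param folds an [make_folds()] object (default: 10 folds, seed 1;
#'   stratified on `y` automatically when `y` is rare binary).
#' @param loss `"squared"` or `"bernoulli"`.
#' @param bound probability bound applied before Bernoulli loss and to
#'   ensemble predictions (default 0.001).
#' @return object of class `ett_sl`: cross-validated prediction matrix,
#'   convex weights, per-learner and ensemble CV risks, full-data refits.
#' @export
fit_superlearner <- function(x, y, library = default_library(),
                             folds = NULL, loss = c("squared", "bernoulli"),
                             bound = 0.001) {
  loss <- match.arg(loss)
  stopifnot(length(library) > 0, !anyNA(y))
  if (loss == "bernoulli" && !all(y %in% c(0, 1)))
    stop("bernoulli loss requires a 0/1 outcome")
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  n <- nrow(x)
  if (is.null(folds)) {
    strat <- if (loss == "bernoulli" && min(mean(y), 1 - mean(y)) < 0.05) y else NULL
    folds <- make_folds(n, K = min(10, n), seed = 1, stratify_on = strat)
  }
  family <- if (loss == "bernoulli") "binomial" else "gaussian"
  L <- length(library)
  lnames <- vapply(library, `[[`, character(1), "name")

  cvpred <- matrix(NA_real_, n, L, dimnames = list(NULL, lnames))
  for (k in seq_len(folds$K)) {
    hold <- folds$assignment == k
    for (l in seq_len(L)) {
      pred <- tryCatch({
        m <- library[[l]]$fit(x[!hold, , drop = FALSE], y[!hold], family)
        library[[l]]$predict(m, x[hold, , drop = FALSE])
      }, error = function(e) {
        warning("learner `", lnames[l], "` failed on fold ", k, ": ",
                conditionMessage(e))
        rep(NA_real_, sum(hold))
      })
      cvpred[hold, l] <- pred
    }
  }

  learner_risks <- vapply(seq_len(L), function(l) {
    p <- cvpred[, l]
    if (anyNA(p)) Inf else cv_risk(p, y, loss, bound)
  }, numeric(1))
  names(learner_risks) <- lnames

  sol <- solve_simplex_weights(cvpred, y, loss, bound)

  refits <- lapply(seq_len(L), function(l) {
    if (sol$alpha[l] == 0) return(NULL)
    library[[l]]$fit(x, y, family)
  })

  structure(list(library = library, learner_names = lnames,
                 cv_predictions = cvpred, weights = sol$alpha,
                 learner_cv_risks = learner_risks, ensemble_cv_risk = sol$risk,
                 refits = refits, loss = loss, bound = bound,
                 folds = folds, train_cols = colnames(x)),
            class = "ett_sl")
}

#' Predict from a fitted super learner
#'
#' @param fit an `ett_sl`.
#' @param x_new matrix/data.frame with the training columns.
#' @return numeric vector; bounded into `[bound, 1 - bound]` for
#'   Bernoulli-loss fits.
#' @export
sl_predict <- function(fit, x_new) {
  x_new <- as.matrix(x_new)
  if (!identical(colnames(x_new), fit$train_cols)) {
    extra <- setdiff(colnames(x_new), fit$train_cols)
    miss <- setdiff(fit$train_cols, colnames(x_new))
    if (length(extra) || length(miss))
      stop("column mismatch; missing: [", paste(miss, collapse = ", "),
           "] unexpected: [", paste(extra, collapse = ", "), "]")
    x_new <- x_new[, fit$train_cols, drop = FALSE]
  }
  pred <- numeric(nrow(x_new))
  for (l in which(fit$weights > 0)) {
    pred <- pred + fit$weights[l] *
      fit$library[[l]]$predict(fit$refits[[l]], x_new)
  }
  if (fit$loss == "bernoulli") pred <- bound(pred, fit$bound, 1 - fit$bound)
  pred
}
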