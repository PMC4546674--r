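## Small numerical helpers shared across the package.

#' Bound a numeric vector into [lo, hi]
#' @param x numeric vector.
#' @param lo,hi bounds.
#' @return bounded vector.
#' @keywords internal
bound <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## logit / expit with bounding so offsets stay finite
logit <- function(p) stats::qlogis(p)
expit <- function(x) stats::plogis(x)

#' Derive independent sub-stream seeds from a master seed
#'
#' One master seed is split into named sub-seeds (covariates, site,
#' missingness, outcomes, ...) so that toggling one stage of a simulation
#' does not perturb the draws of another.  All derived seeds are kept
#' below 2^31.
#'
#' @param seed master integer seed.
#' @param n number of sub-seeds.
#' @return integer vector of length `n`.
#' @keywords internal
derive_subseeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

## run code under a seed without clobbering the caller's RNG state
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
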