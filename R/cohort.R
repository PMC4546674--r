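## Cohort container: a data.frame of patient rows carrying declared
## outcome and covariate types as attributes.  The site indicator column
## is always named `site_large` (1 = large-volume center).

#' Construct a cohort table
#'
#' Wraps a patient-level data.frame into the container used throughout the
#' package.  The exposure column `site_large` must be binary 0/1 and fully
#' observed; at least one outcome must be fully observed; covariates may
#' contain `NA` (an explicit missingness marker handled downstream by the
#' indicator basis).
#'
#' @param data data.frame with columns `id`, `site_large`, the declared
#'   outcomes and covariates.
#' @param outcomes named character vector mapping outcome column names to
#'   their type, `"binary"` or `"continuous"`.
#' @param covariates named character vector mapping covariate column names
#'   to `"continuous"`, `"binary"` or `"categorical"`.
#' @return an object of class `ett_cohort` (a data.frame).
#' @export
cohort_table <- function(data, outcomes, covariates) {
  stopifnot(is.data.frame(data), nrow(data) >= 2)
  if (!"id" %in% names(data)) data$id <- seq_len(nrow(data))
  if (anyDuplicated(data$id)) stop("cohort ids must be unique")
  if (!"site_large" %in% names(data)) stop("cohort must contain a `site_large` column")
  s <- data$site_large
  if (anyNA(s) || !all(s %in% c(0, 1)))
    stop("`site_large` must be fully observed and coded 0/1; found values: ",
         paste(utils::head(unique(s[!s %in% c(0, 1)])), collapse = ", "))
  missing_cols <- setdiff(c(names(outcomes), names(covariates)), names(data))
  if (length(missing_cols))
    stop("declared columns absent from data: ", paste(missing_cols, collapse = ", "))
  if (!any(vapply(names(outcomes), function(o) !anyNA(data[[o]]), logical(1))))
    stop("at least one outcome must be fully observed")
  for (o in names(outcomes)) {
    if (outcomes[[o]] == "binary") {
      v <- data[[o]]
      if (!all(v[!is.na(v)] %in% c(0, 1)))
        stop("outcome `", o, "` declared binary but contains other values")
    }
  }
  structure(data,
            outcomes = outcomes,
            covariates = covariates,
            class = c("ett_cohort", "data.frame"))
}

cohort_outcomes <- function(cohort) attr(cohort, "outcomes")
cohort_covariates <- function(cohort) attr(cohort, "covariates")

#' Subset cohort rows, keeping type metadata
#' @param cohort an `ett_cohort`.
#' @param idx row indices (possibly with repeats, e.g. bootstrap resamples).
#' @return an `ett_cohort`.
#' @export
cohort_subset <- function(cohort, idx) {
  d <- as.data.frame(cohort)[idx, , drop = FALSE]
  d$id <- seq_len(nrow(d))  # re-key: resampled rows are new pseudo-patients
  rownames(d) <- NULL
  cohort_table(d, cohort_outcomes(cohort), cohort_covariates(cohort))
}

#' Write a cohort to CSV
#'
#' RFC-4180 CSV, header row, missing values written as empty fields.
#'
#' @param cohort an `ett_cohort`.
#' @param path output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Empty fields are parsed as missing.  Column types are validated against
#' the declarations: the site column must be binary 0/1 and binary outcomes
#' must contain only 0/1.
#'
#' @param path CSV file with a header row and a `site_large` column.
#' @inheritParams cohort_table
#' @return an `ett_cohort`.
#' @export
read_cohort_csv <- function(path, outcomes, covariates) {
  d <- utils::read.csv(path, na.strings = "", check.names = FALSE)
  cohort_table(d, outcomes, covariates)
}
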