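#' Incomplete dataset container
#'
#' Bundles a rectangular dataset with its missingness structure: a complete
#' outcome column, covariate columns that may contain `NA`, the
#' observed-data indicator matrix \eqn{R_c} (TRUE = observed) and the
#' per-covariate fraction missing \eqn{f_c}.
#'
#' @param data A data frame.
#' @param outcome Name of the (complete, numeric) outcome column.
#' @param covariates Character vector of covariate columns; defaults to all
#'   non-outcome columns.
#' @param binary Character vector naming which covariates are binary (0/1);
#'   these are imputed by logistic regression and exempt from positivity
#'   requirements.
#'
#' @details Continuous covariates must be strictly positive for FP
#'   transforms.  A covariate whose observed values include zero or
#'   negative numbers is shifted on construction by the standard FP origin
#'   rule ([shift_to_positive()]: the smallest shifted value equals the
#'   smallest increment between distinct observed values); the applied
#'   shifts are recorded in the `shifts` component, and all downstream
#'   selected powers refer to the shifted covariate.
#' @return An object of class `incomplete_data`.
#' @export
incomplete_data <- function(data, outcome,
                            covariates = setdiff(names(data), outcome),
                            binary = character(0)) {
  stopifnot(is.data.frame(data), outcome %in% names(data))
  missing_cols <- setdiff(covariates, names(data))
  if (length(missing_cols))
    stop("unknown covariate column(s): ", paste(missing_cols, collapse = ", "))
  y <- data[[outcome]]
  if (!is.numeric(y)) stop("outcome must be numeric")
  if (anyNA(y)) stop("outcome column must be complete")
  for (cv in covariates)
    if (!is.numeric(data[[cv]]))
      stop("covariate '", cv, "' must be numeric")
  bad_bin <- setdiff(binary, covariates)
  if (length(bad_bin)) stop("binary names must be covariates")
  mask <- vapply(covariates, function(cv) !is.na(data[[cv]]),
                 logical(nrow(data)))
  mask <- matrix(mask, nrow = nrow(data),
                 dimnames = list(NULL, covariates))
  f <- 1 - colMeans(mask)
  if (any(f >= 1)) stop("covariate with zero observed values")
  shifts <- stats::setNames(numeric(length(covariates)), covariates)
  for (cv in setdiff(covariates, binary)) {
    obs <- data[[cv]][mask[, cv]]
    if (min(obs) <= 0) {
      shifts[[cv]] <- shift_to_positive(obs)$shift
      data[[cv]] <- data[[cv]] + shifts[[cv]]
    }
  }
  structure(list(data = data[, c(outcome, covariates), drop = FALSE],
                 outcome = outcome, covariates = covariates,
                 binary = binary, mask = mask, f = f, shifts = shifts),
            class = "incomplete_data")
}

#' @export
print.incomplete_data <- function(x, ...) {
  cat("Incomplete dataset: ", nrow(x$data), " rows, outcome '",
      x$outcome, "', ", length(x$covariates), " covariate(s)\n",
      sep = "")
  cat("Fraction missing per covariate:\n")
  print(round(x$f, 3))
  invisible(x)
}
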