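# Resolve the "other covariates" argument into one matrix per imputation.
# `other` may be NULL, a character vector of column names (entered
# linearly), or a pre-built list of M matrices (used by the MFP cycler to
# condition on currently selected transforms).
mi_other_list <- function(mi, other) {
  if (is.null(other)) return(rep(list(NULL), mi$M))
  if (is.character(other)) {
    return(lapply(mi$datasets, function(d)
      as.matrix(d[, other, drop = FALSE])))
  }
  if (is.list(other) && length(other) == mi$M) return(other)
  stop("other must be NULL, column names, or a list of M matrices")
}

#' Stack multiply imputed datasets
#'
#' Treats the M imputed datasets as a single dataset of n x M rows, with
#' per-covariate test weights \eqn{w_c = (1 - f_c)/M}, where \eqn{f_c} is
#' the fraction of missing data for covariate c.  The weight equals 1/M for
#' a complete covariate, so with no missing data a weighted stacked
#' likelihood-ratio statistic reduces exactly to the complete-data one.
#'
#' @param mi An `mi_datasets` object.
#' @return An object of class `stacked_data`: the stacked data frame with
#'   an `.imp` imputation index column, and the weight vector `w`.
#' @export
stack_mi <- function(mi) {
  stopifnot(inherits(mi, "mi_datasets"))
  d <- do.call(rbind, mi$datasets)
  d$.imp <- rep(seq_len(mi$M), each = nrow(mi$datasets[[1L]]))
  structure(list(data = d, w = (1 - mi$f) / mi$M,
                 outcome = mi$outcome, covariates = mi$covariates,
                 M = mi$M, n = nrow(mi$datasets[[1L]])),
            class = "stacked_data")
}

#' @export
print.stacked_data <- function(x, ...) {
  cat("Stacked MI data:", nrow(x$data), "rows (n =", x$n, "x M =",
      x$M, ")\nWeights w_c = (1 - f_c)/M:\n")
  print(round(x$w, 4))
  invisible(x)
}

#' Estimate FP exponents from stacked MI data
#'
#' Fits every candidate FP model of dimension `D` to the stacked
#' (unweighted) data and returns the best fit by log-likelihood.  Because
#' candidate models of the same dimension are equally complex, their
#' log-likelihood ordering is invariant to any common positive weighting of
#' the stacked observations, so no weights are needed for estimation.
#'
#' @param mi An `mi_datasets` object.
#' @param covariate Name of the FP covariate.
#' @param D FP dimension (1 or 2).
#' @param grid Candidate power grid.
#' @param other Other covariates: column names or a list of M matrices.
#' @param family Model family.
#' @return The best stacked `fp_fit` (its `powers` are the estimate).
#' @export
estimate_p_stacked_ll <- function(mi, covariate, D = 1L,
                                  grid = fp_grid_default(), other = NULL,
                                  family = "gaussian") {
  oth <- mi_other_list(mi, other)
  y <- rep(mi$datasets[[1L]][[mi$outcome]], mi$M)
  x <- unlist(lapply(mi$datasets, `[[`, covariate), use.names = FALSE)
  o <- if (is.null(oth[[1L]])) NULL else do.call(rbind, oth)
  profile_best_powers(y, x, o, family, D, grid)
}

# Pool the FP-coefficient block of per-imputation fits; degenerates to the
# single fit when M = 1.
pool_fp_block <- function(fits) {
  idx <- fits[[1L]]$fp_idx
  if (length(fits) == 1L)
    return(list(qbar = fits[[1L]]$coefficients[idx],
                T = fits[[1L]]$vcov[idx, idx, drop = FALSE]))
  est <- lapply(fits, function(f) f$coefficients[idx])
  cov <- lapply(fits, function(f) f$vcov[idx, idx, drop = FALSE])
  rubin_pool(est, cov)
}

# Pooled Wald statistic (against the null model) of one model class fitted
# per imputation.  Returns NA on candidate failure.
mi_class_wald <- function(mi, covariate, powers, oth, family) {
  y <- mi$datasets[[1L]][[mi$outcome]]
  fits <- tryCatch(
    lapply(seq_len(mi$M), function(m)
      fp_fit(y, mi$datasets[[m]][[covariate]], powers, oth[[m]], family)),
    error = function(e) NULL)
  if (is.null(fits)) return(list(stat = NA_real_, fits = NULL))
  pooled <- pool_fp_block(fits)
  Ti <- tryCatch(solve(as.matrix(pooled$T)), error = function(e) NULL)
  if (is.null(Ti)) return(list(stat = NA_real_, fits = fits))
  list(stat = drop(crossprod(pooled$qbar, Ti %*% pooled$qbar)),
       fits = fits, pooled = pooled)
}

#' Estimate FP exponents by pooled Wald statistics
#'
#' For each candidate power multiset of dimension `D`, fits the FP model in
#' every imputed dataset, pools the FP coefficient block by Rubin's rules,
#' and computes the Wald statistic for the block being zero.  The estimate
#' is the candidate maximising this statistic.  Candidates with singular
#' pooled covariance (or failed fits) are skipped with a warning.
#'
#' @inheritParams estimate_p_stacked_ll
#' @return A list with `powers` (the estimate), `statistic`, and the
#'   per-candidate `profile` data frame.
#' @export
estimate_p_wald <- function(mi, covariate, D = 1L,
                            grid = fp_grid_default(), other = NULL,
                            family = "gaussian") {
  oth <- mi_other_list(mi, other)
  cands <- fp_power_sets(grid, as.integer(D))
  stats <- vapply(cands, function(p)
    mi_class_wald(mi, covariate, p, oth, family)$stat, 0)
  if (anyNA(stats)) {
    warning("estimate_p_wald: ", sum(is.na(stats)),
            " candidate(s) skipped (failed fit or singular covariance)")
  }
  if (all(is.na(stats)))
    stop("estimate_p_wald: every candidate failed")
  best <- which.max(stats)
  list(powers = cands[[best]], statistic = stats[best],
       profile = data.frame(
         powers = vapply(cands, function(p) paste(p, collapse = ","), ""),
         wald = stats))
}
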