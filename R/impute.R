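#' Imputation configuration
#'
#' Settings for the bootstrap-based chained-equations imputation of
#' incomplete FP covariates.
#'
#' @param M Number of imputations (>= 2 for pooling; 1 is allowed for
#'   degenerate complete-data wrappers).
#' @param grid Power grid searched when drawing the exponent; default the
#'   fine grid -2(0.2)3.
#' @param positivity How imputed values are kept strictly positive:
#'   `"pmm"` (predictive mean matching, default) or `"truncated"`
#'   (truncated normal regression draw).
#' @param donor_k PMM donor pool size (default 3 closest individuals).
#' @param trunc_lower Lower truncation bound for the covariate on its
#'   original scale; default half the smallest observed value.
#' @param fcs_cycles Chained-equations cycles when two or more covariates
#'   are incomplete (default 10); a single incomplete covariate is imputed
#'   in one pass.
#' @param abb `"dirichlet"` for the approximate Bayesian bootstrap
#'   (Dirichlet(1,...,1)-weighted multinomial resampling) or `"simple"`
#'   for a plain bootstrap.
#' @param seed Optional integer seed fixed at the start of [mi_impute()].
#' @return A list of class `mi_config`.
#' @export
mi_config <- function(M = 10L, grid = fp_grid_fine(),
                      positivity = c("pmm", "truncated"),
                      donor_k = 3L, trunc_lower = NULL,
                      fcs_cycles = 10L, abb = c("dirichlet", "simple"),
                      seed = NULL) {
  positivity <- match.arg(positivity)
  abb <- match.arg(abb)
  stopifnot(M >= 1, donor_k >= 1, fcs_cycles >= 1)
  if (!is.null(trunc_lower) && trunc_lower <= 0)
    stop("trunc_lower must be strictly positive")
  structure(list(M = as.integer(M), grid = grid, positivity = positivity,
                 donor_k = as.integer(donor_k), trunc_lower = trunc_lower,
                 fcs_cycles = as.integer(fcs_cycles), abb = abb,
                 seed = seed),
            class = "mi_config")
}

#' Approximate Bayesian bootstrap resample
#'
#' Draws a with-replacement sample of the observed rows in which each row's
#' resampling probability is itself drawn from a flat Dirichlet
#' distribution (a Bayesian-bootstrap-weighted multinomial).  The resample
#' has the same size as the input and each row's expected inclusion count
#' is 1.
#'
#' @param ids Integer vector of observed row indices (at least 10; fewer
#'   complete cases give too little information to profile an exponent).
#' @param weights `"dirichlet"` (ABB) or `"simple"` (equal-probability
#'   bootstrap).
#' @return Integer vector of resampled ids, same length as `ids`.
#' @export
abb_resample <- function(ids, weights = c("dirichlet", "simple")) {
  weights <- match.arg(weights)
  k <- length(ids)
  if (k == 0L) stop("abb_resample: empty input")
  if (k < 10L)
    stop("abb_resample: too few complete cases (", k, " < 10)")
  prob <- if (weights == "dirichlet") {
    g <- rexp(k)
    g / sum(g)
  } else NULL
  ids[sample.int(k, k, replace = TRUE, prob = prob)]
}

#' Jacobian of a power transformation
#'
#' Log-Jacobian \eqn{J = \sum_i \log |d(x_i^p)/dx_i|} of the map
#' \eqn{x \mapsto x^p} (with \eqn{x^0 = \log x}), added to a model's
#' log-likelihood so that fits of \eqn{x^p} on the response are comparable
#' across different powers p: \eqn{J = n\log|p| + (p-1)\sum_i \log x_i} for
#' \eqn{p \neq 0} and \eqn{J = -\sum_i \log x_i} for \eqn{p = 0}.
#'
#' @param x Strictly positive numeric vector.
#' @param p A single power.
#' @return The scalar log-Jacobian.
#' @examples
#' jacobian_adjustment(1, 1)  # 0
#' jacobian_adjustment(2, 2)  # log 4
#' @export
jacobian_adjustment <- function(x, p) {
  if (any(x <= 0) || any(!is.finite(x)))
    stop("jacobian_adjustment: x must be strictly positive")
  slx <- sum(log(x))
  if (p == 0) -slx else length(x) * log(abs(p)) + (p - 1) * slx
}

# power transform of a single covariate (log at p = 0); inverse below
pow_tr <- function(x, p) if (p == 0) log(x) else x^p
pow_inv <- function(u, p) if (p == 0) exp(u) else u^(1 / p)

#' Draw an FP1 exponent from a bootstrap sample
#'
#' For every power p in the grid, fits a linear regression of \eqn{x^p} on
#' the outcome and any other covariates over the supplied (typically
#' ABB-resampled) rows, and records the Gaussian log-likelihood plus the
#' Jacobian of the transformation.  The drawn exponent `p_star` is the
#' power maximising the adjusted log-likelihood; computed from a bootstrap
#' sample it is a nonparametric draw from the approximate posterior of p.
#'
#' @param x Strictly positive covariate values of the sample.
#' @param y Outcome values of the sample.
#' @param other Optional matrix of other covariate values of the sample.
#' @param grid Candidate power grid.
#' @return A list with `p_star` and `profile`, a data frame of
#'   (p, loglik, jacobian, adjusted).
#' @export
draw_exponent <- function(x, y, other = NULL, grid = fp_grid_fine()) {
  if (any(x <= 0)) stop("draw_exponent: x must be strictly positive")
  n <- length(x)
  Z <- cbind(1, y, other)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    keep <- qz$pivot[seq_len(qz$rank)]
    warning("draw_exponent: dropping ", ncol(Z) - qz$rank,
            " collinear predictor column(s)")
    Z <- Z[, keep, drop = FALSE]
    qz <- qr(Z)
  }
  p <- as.numeric(grid)
  lx <- log(x)
  slx <- sum(lx)
  U <- outer(x, p, `^`)
  if (any(p == 0)) U[, p == 0] <- lx
  res <- qr.resid(qz, U)
  rss <- pmax(colSums(res^2), .Machine$double.eps)
  ll <- -n / 2 * (log(2 * pi * rss / n) + 1)
  jac <- ifelse(p == 0, -slx, n * log(abs(p)) + (p - 1) * slx)
  adj <- ll + jac
  list(p_star = p[which.max(adj)],
       profile = cbind(p = p, loglik = ll, jacobian = jac,
                       adjusted = adj))
}

# truncated normal draw via inverse-cdf; bounds may be -Inf/Inf
rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  plo <- pnorm(lower, mean, sd)
  phi <- pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  # clamp away from 0/1 so qnorm stays finite
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  qnorm(u, mean, sd)
}

#' One imputation of an incomplete FP1 covariate
#'
#' A single pass of the bootstrap imputation algorithm for one covariate:
#' (1) an ABB resample of the rows with observed x; (2) the exponent
#' `p_star` drawn by [draw_exponent()] on that resample; (3) a proper
#' Bayesian linear-regression imputation of \eqn{x^{p^*}} on the outcome
#' and other covariates, fitted on the observed rows of the original data
#' (residual variance from its scaled inverse-chi-square posterior,
#' coefficients from their conditional normal); (4) positivity enforced
#' either by predictive mean matching against observed donors or by
#' truncated sampling at the transformed bound; (5) the covariate restored
#' to its original scale by the \eqn{p^*}-th root (exp when
#' \eqn{p^* = 0}).
#'
#' @param x Current covariate values (observed entries authoritative;
#'   entries at `!observed` are ignored and replaced).
#' @param observed Logical vector, TRUE where x was genuinely observed.
#' @param y Complete outcome vector.
#' @param other Optional matrix of other covariates (current values).
#' @param config An [mi_config()].
#' @return A list with `x` (completed column), `p_star` and the exponent
#'   `profile`.
#' @export
impute_fp1_once <- function(x, observed, y, other = NULL,
                            config = mi_config()) {
  n <- length(x)
  stopifnot(length(observed) == n, length(y) == n)
  obs <- which(observed)
  mis <- which(!observed)
  if (length(obs) < 10L)
    stop("impute_fp1_once: fewer than 10 observed values")
  if (any(x[obs] <= 0))
    stop("impute_fp1_once: observed covariate values must be positive")
  oth_obs <- if (!is.null(other)) other[obs, , drop = FALSE]

  s <- abb_resample(obs, config$abb)
  dr <- draw_exponent(x[s], y[s],
                      if (!is.null(other)) other[s, , drop = FALSE],
                      config$grid)
  p_star <- dr$p_star
  if (length(mis) == 0L)
    return(list(x = x, p_star = p_star, profile = dr$profile))

  u_obs <- pow_tr(x[obs], p_star)
  Z_obs <- cbind(1, y[obs], oth_obs)
  Z_mis <- cbind(1, y[mis],
                 if (!is.null(other)) other[mis, , drop = FALSE])
  qz <- qr(Z_obs)
  if (qz$rank < ncol(Z_obs)) {
    keep <- qz$pivot[seq_len(qz$rank)]
    warning("impute_fp1_once: dropping collinear predictor column(s)")
    Z_obs <- Z_obs[, keep, drop = FALSE]
    Z_mis <- Z_mis[, keep, drop = FALSE]
    qz <- qr(Z_obs)
  }
  k <- ncol(Z_obs)
  beta_hat <- qr.coef(qz, u_obs)
  rss <- sum(qr.resid(qz, u_obs)^2)
  dfres <- length(obs) - k
  if (dfres < 1L) stop("impute_fp1_once: too few observed rows to impute")
  sigma2_star <- rss / rchisq(1L, dfres)
  # coefficient draw: cov = sigma2* (Z'Z)^-1, via the (pivoted) R factor
  pert <- backsolve(qr.R(qz), rnorm(k))
  delta <- numeric(k)
  delta[qz$pivot] <- pert
  beta_star <- beta_hat + sqrt(sigma2_star) * delta
  mu_mis <- drop(Z_mis %*% beta_star)

  if (config$positivity == "pmm") {
    kd <- config$donor_k
    if (kd > length(obs))
      stop("impute_fp1_once: donor_k exceeds the number of observed values")
    mu_obs <- drop(Z_obs %*% beta_hat)
    # donor search on the sorted predictions: locate each target with
    # findInterval, then scan a window of kd neighbours on each side
    ord <- order(mu_obs)
    mos <- mu_obs[ord]
    xos <- x[obs][ord]
    no <- length(mos)
    pos <- findInterval(mu_mis, mos)
    pick <- sample.int(kd, length(mis), replace = TRUE)
    imp <- numeric(length(mis))
    for (i in seq_along(mis)) {
      # expand outwards from the insertion point, always taking the
      # closer side, until kd donors are collected
      lo <- pos[i]
      hi <- pos[i] + 1L
      sel <- integer(kd)
      for (j in seq_len(kd)) {
        dlo <- if (lo >= 1L) mu_mis[i] - mos[lo] else Inf
        dhi <- if (hi <= no) mos[hi] - mu_mis[i] else Inf
        if (dlo <= dhi) {
          sel[j] <- lo
          lo <- lo - 1L
        } else {
          sel[j] <- hi
          hi <- hi + 1L
        }
      }
      imp[i] <- xos[sel[pick[i]]]
    }
    x[mis] <- imp
  } else {
    x_lb <- if (is.null(config$trunc_lower)) min(x[obs]) / 2
            else config$trunc_lower
    if (x_lb <= 0)
      stop("impute_fp1_once: truncation bound must be positive")
    u_b <- pow_tr(x_lb, p_star)
    sd_star <- sqrt(sigma2_star)
    u_star <- if (p_star < 0) {
      # decreasing transform: x > x_lb maps to 0 < x^p < x_lb^p
      rtruncnorm1(length(mis), mu_mis, sd_star, 0, u_b)
    } else {
      rtruncnorm1(length(mis), mu_mis, sd_star, u_b, Inf)
    }
    x[mis] <- pow_inv(u_star, p_star)
  }
  list(x = x, p_star = p_star, profile = dr$profile)
}

# Bayesian logistic imputation for a binary covariate: posterior-normal
# coefficient draw, then Bernoulli.
impute_binary_once <- function(x, observed, y, other = NULL) {
  obs <- which(observed)
  mis <- which(!observed)
  if (length(mis) == 0L) return(x)
  Z_obs <- cbind(1, y[obs],
                 if (!is.null(other)) other[obs, , drop = FALSE])
  Z_mis <- cbind(1, y[mis],
                 if (!is.null(other)) other[mis, , drop = FALSE])
  fit <- logit_irls(Z_obs, x[obs])
  ch <- chol(fit$vcov)
  beta_star <- fit$coefficients + drop(crossprod(ch, rnorm(ncol(Z_obs))))
  pr <- plogis(drop(Z_mis %*% beta_star))
  x[mis] <- rbinom(length(mis), 1L, pr)
  x
}

#' Multiply impute incomplete FP covariates by chained equations
#'
#' Produces `M` completed copies of an incomplete dataset.  Each imputation
#' starts from random draws from the observed margin of every incomplete
#' covariate, then cycles through the incomplete covariates (ascending
#' fraction missing), imputing each by [impute_fp1_once()] (continuous) or
#' Bayesian logistic regression (binary) conditional on the outcome and the
#' current values of all other covariates.  When two or more covariates are
#' incomplete, `fcs_cycles` full cycles are run; with one, a single pass
#' suffices.  The exponent drawn in the final visit to each covariate is
#' recorded.
#'
#' @param data An [incomplete_data()] object.
#' @param config An [mi_config()].
#' @return An object of class `mi_datasets`: the list of `M` completed data
#'   frames, the original mask, the matrix of drawn exponents, and the
#'   configuration.
#' @export
mi_impute <- function(data, config = mi_config()) {
  stopifnot(inherits(data, "incomplete_data"), inherits(config, "mi_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  covs <- data$covariates
  incomp <- covs[data$f > 0]
  if (length(incomp) == 0L)
    stop("mi_impute: no covariate has missing values")
  ord <- incomp[order(data$f[incomp])]
  cycles <- if (length(incomp) >= 2L) config$fcs_cycles else 1L
  y <- data$data[[data$outcome]]
  Xfull <- as.matrix(data$data[covs])
  mask <- data$mask

  datasets <- vector("list", config$M)
  p_star <- matrix(NA_real_, config$M, length(incomp),
                   dimnames = list(NULL, incomp))
  for (m in seq_len(config$M)) {
    Xm <- Xfull
    for (cv in ord) {
      miss <- !mask[, cv]
      Xm[miss, cv] <- sample(Xm[!miss, cv], sum(miss), replace = TRUE)
    }
    for (cy in seq_len(cycles)) {
      for (cv in ord) {
        oth <- Xm[, setdiff(covs, cv), drop = FALSE]
        if (ncol(oth) == 0L) oth <- NULL
        if (cv %in% data$binary) {
          Xm[, cv] <- impute_binary_once(Xm[, cv], mask[, cv], y, oth)
        } else {
          r <- impute_fp1_once(Xm[, cv], mask[, cv], y, oth, config)
          Xm[, cv] <- r$x
          p_star[m, cv] <- r$p_star
        }
      }
    }
    dfm <- data.frame(y, Xm)
    names(dfm) <- c(data$outcome, covs)
    datasets[[m]] <- dfm
  }
  structure(list(datasets = datasets, outcome = data$outcome,
                 covariates = covs, binary = data$binary,
                 mask = mask, f = data$f, M = config$M,
                 p_star = p_star, shifts = data$shifts,
                 config = config),
            class = "mi_datasets")
}

#' Wrap a complete dataset as degenerate multiply imputed data
#'
#' Represents a dataset without missing values as an `mi_datasets` object
#' with `M` identical copies (default 1).  Useful for running the
#' MI-based selection machinery on complete data or on the complete-record
#' subset: with no missingness the stacked weighted likelihood-ratio test
#' reduces exactly to the complete-data likelihood-ratio test.
#'
#' @param data A complete data frame.
#' @inheritParams incomplete_data
#' @param M Number of identical copies.
#' @return An `mi_datasets` object with an all-observed mask.  As in
#'   [incomplete_data()], a continuous covariate with non-positive values
#'   is shifted by the FP origin rule and the shift recorded.
#' @export
mi_from_complete <- function(data, outcome,
                             covariates = setdiff(names(data), outcome),
                             binary = character(0), M = 1L) {
  stopifnot(!anyNA(data[covariates]))
  mask <- matrix(TRUE, nrow(data), length(covariates),
                 dimnames = list(NULL, covariates))
  shifts <- stats::setNames(numeric(length(covariates)), covariates)
  for (cv in setdiff(covariates, binary)) {
    if (min(data[[cv]]) <= 0) {
      shifts[[cv]] <- shift_to_positive(data[[cv]])$shift
      data[[cv]] <- data[[cv]] + shifts[[cv]]
    }
  }
  structure(list(datasets = rep(list(data[, c(outcome, covariates),
                                          drop = FALSE]), M),
                 outcome = outcome, covariates = covariates,
                 binary = binary, mask = mask,
                 f = stats::setNames(numeric(length(covariates)),
                                     covariates),
                 M = as.integer(M),
                 p_star = NULL, shifts = shifts, config = NULL),
            class = "mi_datasets")
}

#' @export
print.mi_datasets <- function(x, ...) {
  cat("Multiply imputed data: M =", x$M, "datasets of",
      nrow(x$datasets[[1L]]), "rows\n")
  cat("Fraction missing per covariate:\n")
  print(round(x$f, 3))
  if (!is.null(x$p_star)) {
    cat("Drawn exponents p* (per imputation):\n")
    print(x$p_star)
  }
  invisible(x)
}
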