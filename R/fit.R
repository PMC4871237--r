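# Internal fitting engines -----------------------------------------------
#
# Both engines work on a plain numeric design matrix (intercept included by
# the caller) and return coefficients, covariance, and the maximised
# (weighted) log-likelihood.  The Gaussian log-likelihood is the full normal
# likelihood at the ML variance estimate (not REML), so likelihood-ratio
# statistics between nested fits are directly comparable.  Weights act as
# importance weights multiplying each observation's log-likelihood
# contribution.

unpivot <- function(fit, k) {
  cf <- numeric(k)
  cf[fit$pivot] <- fit$coefficients
  cf
}

gauss_ml <- function(X, y, w = NULL) {
  n <- length(y)
  k <- ncol(X)
  if (is.null(w)) {
    fit <- .lm.fit(X, y)
    if (fit$rank < k) stop("singular design matrix in Gaussian fit")
    coef <- unpivot(fit, k)
    res <- fit$residuals
    rss <- sum(res^2)
    sw <- n
    XtWX <- crossprod(X)
  } else {
    if (any(w < 0)) stop("negative weights")
    sw <- sum(w)
    if (sw <= 0) stop("weights sum to zero")
    sqw <- sqrt(w)
    fit <- .lm.fit(X * sqw, y * sqw)
    if (fit$rank < k) stop("singular design matrix in Gaussian fit")
    coef <- unpivot(fit, k)
    rss <- sum(fit$residuals^2)   # = sum w * e^2
    XtWX <- crossprod(X * sqw)
  }
  sigma2_ml <- rss / sw
  if (sigma2_ml <= 0) sigma2_ml <- .Machine$double.eps
  loglik <- -sw / 2 * (log(2 * pi * sigma2_ml) + 1)
  dfres <- sw - k
  vcov <- if (dfres > 0) chol2inv(chol(XtWX)) * rss / dfres
          else matrix(NA_real_, k, k)
  list(coefficients = coef, vcov = vcov, loglik = loglik,
       sigma2 = sigma2_ml, n = n, rank = k)
}

logit_irls <- function(X, y, w = NULL, maxit = 100L, tol = 1e-8) {
  n <- length(y)
  k <- ncol(X)
  if (is.null(w)) w <- rep(1, n)
  if (all(y == y[1L]))
    stop("degenerate binary response: all values equal")
  beta <- numeric(k)
  dev_old <- Inf
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    mu <- pmin(pmax(mu, 1e-12), 1 - 1e-12)
    ww <- w * mu * (1 - mu)
    z <- eta + (y - mu) / (mu * (1 - mu))
    sqw <- sqrt(ww)
    fit <- .lm.fit(X * sqw, z * sqw)
    if (fit$rank < k) stop("singular design matrix in logistic fit")
    beta <- unpivot(fit, k)
    dev <- -2 * sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
    if (is.finite(dev_old) && abs(dev - dev_old) < tol) break
    dev_old <- dev
    if (it == maxit)
      stop("logistic fit failed to converge in ", maxit, " iterations")
  }
  eta <- drop(X %*% beta)
  if (max(abs(eta)) > 30)
    stop("perfect or quasi-perfect separation in logistic fit")
  mu <- plogis(eta)
  loglik <- sum(w * (y * log(mu) + (1 - y) * log(1 - mu)))
  ww <- w * mu * (1 - mu)
  vcov <- chol2inv(chol(crossprod(X * sqrt(ww))))
  list(coefficients = beta, vcov = vcov, loglik = loglik,
       n = n, rank = k)
}

# Build the full design for one model class.  Returns the matrix plus the
# index of the FP/x columns (used for Wald statistics on the covariate under
# scrutiny).
fp_build_design <- function(x, powers, other = NULL, n = NULL) {
  if (is.null(n)) n <- if (!is.null(x)) length(x) else nrow(other)
  if (identical(powers, "null")) {
    xm <- NULL
  } else if (identical(powers, "linear")) {
    xm <- matrix(x, ncol = 1L, dimnames = list(NULL, "x"))
  } else {
    xm <- fp_transform(x, powers)
  }
  X <- cbind(`(Intercept)` = rep(1, n), xm, other)
  idx <- if (is.null(xm)) integer(0) else seq_len(ncol(xm)) + 1L
  list(X = X, fp_idx = idx)
}

#' Fit one fractional polynomial regression model
#'
#' Fits a single model of a fixed class for the covariate of interest:
#' `"null"` (covariate omitted), `"linear"`, or an FP model given by a
#' numeric power vector.  Any adjustment covariates enter linearly via
#' `other`.  Gaussian models are fitted by (weighted) least squares with the
#' full normal log-likelihood at the ML variance; logistic models by IRLS
#' (at most 100 iterations, deviance tolerance 1e-8; non-convergence and
#' separation are errors, never silent).
#'
#' @param y Response vector (numeric; 0/1 for `family = "binomial"`).
#' @param x Covariate of interest (strictly positive for FP powers).
#' @param powers `"null"`, `"linear"`, or a numeric power vector of length
#'   1 or 2.
#' @param other Optional numeric matrix of adjustment covariates (no
#'   intercept column).
#' @param family `"gaussian"` or `"binomial"`.
#' @param weights Optional non-negative importance weights.
#' @return An object of class `fp_fit`: coefficients, covariance matrix,
#'   log-likelihood, the model class and powers, and the index of the
#'   coefficients belonging to the covariate of interest.
#' @examples
#' set.seed(1)
#' x <- runif(100, 1, 5); y <- 2 * x + rnorm(100)
#' f <- fp_fit(y, x, "linear")
#' coef(f)
#' @export
fp_fit <- function(y, x = NULL, powers = "linear", other = NULL,
                   family = "gaussian", weights = NULL) {
  family <- if (length(family) > 1L) family[1L] else family
  if (!family %in% c("gaussian", "binomial"))
    stop("family must be \"gaussian\" or \"binomial\"")
  y <- as.numeric(y)
  if (!is.null(other)) {
    other <- as.matrix(other)
    if (nrow(other) != length(y)) stop("other: wrong number of rows")
  }
  if (is.null(x) && !identical(powers, "null"))
    stop("x is required unless powers = \"null\"")
  if (!is.null(x) && length(x) != length(y)) stop("x: wrong length")
  if (!is.null(weights)) {
    if (length(weights) != length(y) || any(weights < 0) ||
        all(weights == 0))
      stop("weights must be nonnegative, same length as y, not all zero")
  }
  d <- fp_build_design(x, powers, other, n = length(y))
  eng <- if (family == "gaussian") gauss_ml(d$X, y, weights)
         else logit_irls(d$X, y, weights)
  names(eng$coefficients) <- colnames(d$X)
  dimnames(eng$vcov) <- list(colnames(d$X), colnames(d$X))
  structure(list(
    coefficients = eng$coefficients,
    vcov = eng$vcov,
    loglik = eng$loglik,
    powers = powers,
    class_label = fp_class_label(powers),
    fp_idx = d$fp_idx,
    family = family,
    n = length(y),
    sigma2 = eng$sigma2
  ), class = "fp_fit")
}

fp_class_label <- function(powers) {
  if (identical(powers, "null")) "null"
  else if (identical(powers, "linear")) "linear"
  else paste0("FP", length(powers))
}

#' @export
coef.fp_fit <- function(object, ...) object$coefficients

#' @export
vcov.fp_fit <- function(object, ...) object$vcov

#' @export
logLik.fp_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$coefficients) + 1,
            class = "logLik")
}

#' @export
print.fp_fit <- function(x, ...) {
  cat("FP regression fit (", x$family, "), model class: ", x$class_label,
      sep = "")
  if (is.numeric(x$powers))
    cat(", powers (", paste(x$powers, collapse = ", "), ")", sep = "")
  cat("\n  log-likelihood:", format(x$loglik), "  n:", x$n, "\n")
  cat("  coefficients:\n")
  print(x$coefficients, ...)
  invisible(x)
}
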