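#' Pool estimates across imputations by Rubin's rules
#'
#' Combines M per-imputation estimates and covariance matrices: the pooled
#' estimate is the mean, the within-imputation variance W the mean of the
#' covariances, the between-imputation variance B the sample covariance of
#' the estimates, and the total variance \eqn{T = W + (1 + 1/M) B}.
#'
#' @param estimates A list of M numeric vectors (or an M-by-k matrix).
#' @param covariances A list of M covariance matrices (k-by-k); scalars are
#'   treated as 1-by-1 matrices.
#' @return An object of class `pooled_estimate` with components `qbar`,
#'   `W`, `B`, `T` and `M`.
#' @examples
#' p <- rubin_pool(list(1, 2, 3), list(1, 1, 1))
#' p$T  # 1 + (1 + 1/3) * 1
#' @export
rubin_pool <- function(estimates, covariances) {
  if (is.matrix(estimates))
    estimates <- lapply(seq_len(nrow(estimates)),
                        function(i) estimates[i, ])
  M <- length(estimates)
  if (M < 2L) stop("rubin_pool: need M >= 2 imputations")
  if (length(covariances) != M)
    stop("rubin_pool: estimates and covariances must have equal length")
  k <- length(estimates[[1L]])
  covariances <- lapply(covariances, function(v) {
    v <- as.matrix(v)
    if (!all(dim(v) == k)) stop("rubin_pool: nonconforming covariance")
    v
  })
  Q <- do.call(rbind, lapply(estimates, as.numeric))
  qbar <- colMeans(Q)
  W <- Reduce(`+`, covariances) / M
  B <- stats::cov(Q)
  Tm <- W + (1 + 1 / M) * B
  structure(list(qbar = qbar, W = W, B = B, T = Tm, M = M),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat("Rubin's-rules pooled estimate (M =", x$M, "):\n")
  print(data.frame(estimate = x$qbar, se = sqrt(diag(x$T))), ...)
  invisible(x)
}

wald_result <- function(statistic, df, comparison,
                        negative_flag = FALSE) {
  p <- if (statistic <= 0) 1 else
    pchisq(statistic, df, lower.tail = FALSE)
  structure(list(statistic = statistic, df = as.integer(df),
                 p.value = p, comparison = comparison,
                 negative_flag = negative_flag),
            class = "wald_result")
}

#' Pooled Wald test of a parameter block
#'
#' Quadratic-form Wald statistic \eqn{\bar{q}' T^{-1} \bar{q}} for testing
#' that the pooled parameter vector is zero, referred to the upper tail of
#' a chi-square distribution on `df` degrees of freedom (the same reference
#' df as the complete-data function selection procedure).
#'
#' @param pooled A [rubin_pool()] result (or any list with `qbar` and `T`).
#' @param df Reference degrees of freedom, typically from [test_df()].
#' @param comparison Optional label.
#' @return A `wald_result` with `statistic`, `df`, `p.value`.
#' @export
pooled_wald <- function(pooled, df, comparison = "Wald") {
  Tm <- as.matrix(pooled$T)
  Ti <- tryCatch(solve(Tm), error = function(e)
    stop("pooled_wald: singular total covariance matrix"))
  stat <- drop(crossprod(pooled$qbar, Ti %*% pooled$qbar))
  wald_result(stat, df, comparison)
}

#' Difference of two Wald statistics (delta-Wald)
#'
#' A test statistic between non-nested FP model classes formed as the
#' difference of the two models' Wald statistics against the same null
#' model, referred to chi-square on `df` degrees of freedom.  The
#' difference is not guaranteed positive; a non-positive statistic is not
#' significant at any level (p = 1) and is flagged.
#'
#' @param complex_wald,simple_wald Wald statistics of the more and less
#'   complex model against the common null.
#' @param df Reference degrees of freedom.
#' @param comparison Optional label.
#' @return A `wald_result`; `negative_flag` is TRUE when the difference is
#'   negative.
#' @examples
#' delta_wald(10, 7, 1)$p.value  # ~0.0833
#' delta_wald(5, 6, 1)$p.value   # 1
#' @export
delta_wald <- function(complex_wald, simple_wald, df,
                       comparison = "deltaWald") {
  d <- complex_wald - simple_wald
  wald_result(d, df, comparison, negative_flag = d < 0)
}

#' @export
print.wald_result <- function(x, ...) {
  cat(x$comparison, ": statistic ", format(x$statistic), " on ", x$df,
      " df, p = ", format(x$p.value),
      if (x$negative_flag) "  [negative: not significant at any level]",
      "\n", sep = "")
  invisible(x)
}
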