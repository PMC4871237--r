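#' Best-fitting FP model of a given dimension
#'
#' Exhaustively enumerates every multiset of `D` powers from the grid
#' (repeated powers included), fits each candidate model and returns the fit
#' with the largest log-likelihood.  Ties are broken in favour of the first
#' candidate in ascending lexicographic grid order, so the result is
#' deterministic.  Candidates whose fit fails (e.g. a singular design) are
#' skipped; it is an error for every candidate to fail.
#'
#' @inheritParams fp_fit
#' @param D FP dimension, 1 or 2.
#' @param grid An `fp_grid` (or numeric vector) of candidate powers.
#' @return The winning `fp_fit`, with an extra element `profile`: a data
#'   frame of every candidate's powers and log-likelihood.
#' @export
profile_best_powers <- function(y, x, other = NULL, family = "gaussian",
                                D = 1L, grid = fp_grid_default(),
                                weights = NULL) {
  family <- if (length(family) > 1L) family[1L] else family
  if (!D %in% c(1L, 2L)) stop("FP dimension D must be 1 or 2")
  cands <- fp_power_sets(grid, as.integer(D))
  best <- NULL
  lls <- rep(NA_real_, length(cands))
  for (i in seq_along(cands)) {
    f <- tryCatch(fp_fit(y, x, cands[[i]], other, family, weights),
                  error = function(e) NULL)
    if (is.null(f)) next
    lls[i] <- f$loglik
    if (is.null(best) || f$loglik > best$loglik) best <- f
  }
  if (is.null(best))
    stop("profile_best_powers: every candidate power vector failed to fit")
  best$profile <- data.frame(
    powers = vapply(cands, function(p) paste(p, collapse = ","), ""),
    loglik = lls)
  best
}

#' Degrees of freedom for tests between FP model classes
#'
#' One df is assigned to each regression coefficient and one to each
#' estimated power, so on the ladder null < linear < FP1 < FP2 the class
#' dimensions are 0, 1, 2 and 4: FPm vs null is on 2m df, FPm vs linear on
#' 2m - 1, FP2 vs FP1 on 2, linear vs null on 1.
#'
#' @param complex,simple Model class labels, each one of `"null"`,
#'   `"linear"`, `"FP1"`, `"FP2"`; `complex` must be strictly more complex.
#' @return Integer degrees of freedom.
#' @examples
#' test_df("FP2", "FP1")  # 2
#' test_df("FP1", "null") # 2
#' test_df("linear", "null") # 1
#' @export
test_df <- function(complex, simple) {
  dims <- c(null = 0L, linear = 1L, FP1 = 2L, FP2 = 4L)
  if (!complex %in% names(dims) || !simple %in% names(dims))
    stop("unknown model class")
  d <- dims[[complex]] - dims[[simple]]
  if (d <= 0L)
    stop("test_df: '", complex, "' is not strictly more complex than '",
         simple, "'")
  d
}

# Ladder of simpler classes tested against the best FPDmax model,
# simplest first.
fsp_ladder <- function(Dmax) {
  c("null", "linear", if (Dmax >= 2L) "FP1")
}

fsp_select <- function(trail, alpha_inclusion, alpha_nonlin, Dmax) {
  # closed test: the selected model is the simplest whose test against the
  # best FPDmax model is not significant; the inclusion test runs at
  # alpha_inclusion, the remaining (nonlinearity) tests at alpha_nonlin.
  alphas <- c(alpha_inclusion, rep(alpha_nonlin, nrow(trail) - 1L))
  nonsig <- which(trail$p.value > alphas)
  if (length(nonsig)) trail$simple[nonsig[1L]] else paste0("FP", Dmax)
}

#' Function selection procedure with complete data
#'
#' The closed-test procedure for choosing between the null model, a linear
#' term, and fractional polynomial models up to dimension `Dmax` for one
#' continuous covariate.  Each simpler class is tested against the
#' best-fitting FPDmax model by a likelihood-ratio test: first the null
#' model (at `alpha_inclusion`), then linear, then FP1 (at `alpha`), with
#' the reference chi-square df from [test_df()].  The selected model is the
#' simplest whose test against FPDmax is not significant; if all tests are
#' significant the FPDmax model is chosen.  The full trail of tests is
#' always computed and returned.
#'
#' @inheritParams profile_best_powers
#' @param Dmax Maximum FP dimension considered (1 or 2).
#' @param alpha_inclusion Nominal level for the test of the null model
#'   against FPDmax (the inclusion test).
#' @param alpha Nominal level for the remaining (nonlinearity) tests.
#' @return An object of class `fsp_result`: the selected class and its
#'   powers, the trail of comparisons (statistic, df, p-value), and the
#'   fitted models.
#' @examples
#' set.seed(42)
#' x <- runif(150, 0.5, 4); y <- 1 / sqrt(x) + rnorm(150, sd = 0.2)
#' fsp_complete(y, x, Dmax = 1)
#' @export
fsp_complete <- function(y, x, other = NULL,
                         family = c("gaussian", "binomial"),
                         Dmax = 2L, alpha_inclusion = 0.1, alpha = 0.1,
                         grid = fp_grid_default()) {
  family <- match.arg(family)
  if (!Dmax %in% c(1L, 2L)) stop("Dmax must be 1 or 2")
  stopifnot(alpha_inclusion > 0, alpha_inclusion < 1, alpha > 0, alpha < 1)
  Dmax <- as.integer(Dmax)

  fits <- list(null = fp_fit(y, NULL, "null", other, family),
               linear = fp_fit(y, x, "linear", other, family))
  for (d in seq_len(Dmax))
    fits[[paste0("FP", d)]] <-
      profile_best_powers(y, x, other, family, d, grid)
  top <- paste0("FP", Dmax)

  simple <- fsp_ladder(Dmax)
  trail <- data.frame(
    comparison = paste(simple, "vs", top),
    simple = simple,
    statistic = vapply(simple, function(s)
      2 * (fits[[top]]$loglik - fits[[s]]$loglik), 0),
    df = vapply(simple, function(s) test_df(top, s), 0L),
    row.names = NULL)
  trail$p.value <- pchisq(pmax(trail$statistic, 0), trail$df,
                          lower.tail = FALSE)

  selected <- fsp_select(trail, alpha_inclusion, alpha, Dmax)
  structure(list(
    selected = selected,
    powers = fits[[selected]]$powers,
    trail = trail,
    fits = fits,
    alpha_inclusion = alpha_inclusion,
    alpha = alpha,
    method = "complete-data LRT"
  ), class = "fsp_result")
}

#' @export
print.fsp_result <- function(x, ...) {
  cat("Function selection procedure (", x$method, ")\n", sep = "")
  cat("Selected model:", x$selected)
  if (is.numeric(x$powers))
    cat("  powers (", paste(x$powers, collapse = ", "), ")", sep = "")
  cat("\nTest trail (alpha_inclusion = ", x$alpha_inclusion,
      ", alpha = ", x$alpha, "):\n", sep = "")
  print(x$trail[c("comparison", "statistic", "df", "p.value")],
        row.names = FALSE, ...)
  invisible(x)
}
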