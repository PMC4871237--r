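#' Power grids for fractional polynomial models
#'
#' A power grid is the set of candidate exponents searched when fitting a
#' fractional polynomial.  Two grids are in routine use: the coarse default
#' set \eqn{S = \{-2, -1, -0.5, 0, 0.5, 1, 2, 3\}} used for model building,
#' and a fine grid from -2 to 3 in steps of 0.2 (26 values) used when drawing
#' exponents during imputation and when a finer picture of the exponent
#' profile is wanted.
#'
#' @param lo,hi Grid endpoints (inclusive).
#' @param step Grid increment; must divide `hi - lo` to within rounding.
#' @param values Alternatively, an explicit strictly increasing numeric
#'   vector of powers.
#' @return An object of class `fp_grid`: a numeric vector of powers with
#'   attributes recording its construction.
#' @examples
#' fp_grid_default()
#' length(fp_grid_fine())  # 26
#' power_grid(-2, 3, 0.5)
#' @export
power_grid <- function(lo = -2, hi = 3, step = 0.2, values = NULL) {
  if (is.null(values)) {
    stopifnot(is.numeric(lo), is.numeric(hi), is.numeric(step),
              length(lo) == 1L, length(hi) == 1L, length(step) == 1L)
    if (!(lo < hi) || step <= 0)
      stop("power_grid: need lo < hi and step > 0")
    values <- seq(lo, hi, by = step)
    # guard against floating-point droop at the upper endpoint
    if (abs(values[length(values)] - hi) > 1e-8) values <- c(values, hi)
    values <- round(values, 10)
  } else {
    values <- as.numeric(values)
    if (anyNA(values) || any(!is.finite(values)))
      stop("power_grid: values must be finite")
    if (is.unsorted(values, strictly = TRUE))
      stop("power_grid: values must be strictly increasing")
  }
  structure(values, class = "fp_grid")
}

#' @rdname power_grid
#' @export
fp_grid_default <- function() {
  power_grid(values = c(-2, -1, -0.5, 0, 0.5, 1, 2, 3))
}

#' @rdname power_grid
#' @export
fp_grid_fine <- function() {
  power_grid(-2, 3, 0.2)
}

#' @export
print.fp_grid <- function(x, ...) {
  cat("FP power grid with", length(x), "values:\n")
  print(unclass(x), ...)
  invisible(x)
}

# All multisets of `D` powers from `grid`, ascending within each multiset,
# enumerated in lexicographic order (ties in profiling are broken by this
# order: first encountered maximum wins).
fp_power_sets <- function(grid, D) {
  g <- as.numeric(grid)
  if (D == 1L) return(lapply(g, function(p) p))
  if (D == 2L) {
    out <- vector("list", length(g) * (length(g) + 1L) / 2L)
    k <- 0L
    for (i in seq_along(g)) for (j in i:length(g)) {
      k <- k + 1L
      out[[k]] <- c(g[i], g[j])
    }
    return(out)
  }
  stop("FP dimension D must be 1 or 2")
}
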