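#' Shift a covariate so that all values are strictly positive
#'
#' Fractional polynomial transforms require strictly positive arguments.
#' When a covariate contains zero or negative values the conventional remedy
#' is to add a constant so that the smallest shifted value equals the
#' smallest increment between any two distinct sorted values.  Covariates
#' that are already strictly positive are left untouched (shift 0); the
#' shift is returned so it can be re-applied to new data.
#'
#' @param x Numeric vector with at least two distinct finite values.
#' @return A list with components `x` (shifted values) and `shift`.
#' @examples
#' shift_to_positive(c(-1, 0, 3))   # shift 2 -> c(1, 2, 5)
#' shift_to_positive(c(0, 0.5, 2))  # shift 0.5
#' shift_to_positive(1:3)           # shift 0
#' @export
shift_to_positive <- function(x) {
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("shift_to_positive: x must be finite numeric")
  ux <- sort(unique(x))
  if (length(ux) < 2L)
    stop("shift_to_positive: all values identical; no increment defined")
  if (ux[1L] > 0) return(list(x = x, shift = 0))
  eps <- min(diff(ux))
  shift <- eps - ux[1L]
  list(x = x + shift, shift = shift)
}

#' Fractional polynomial basis of a positive covariate
#'
#' Builds the n-by-D design matrix of FP terms for a power vector
#' \eqn{(p_1, \dots, p_D)}.  By convention \eqn{x^0 = \log x}.  A repeated
#' power \eqn{(p, p)} contributes the columns \eqn{x^p} and
#' \eqn{x^p \log x}; more generally the k-th repeat of a power multiplies by
#' a further factor of \eqn{\log x}.
#'
#' @param x Strictly positive numeric vector.
#' @param powers Numeric vector of powers (length 1 or 2), sorted ascending.
#' @return Matrix with one column per FP term, with a `"powers"` attribute.
#' @examples
#' fp_transform(exp(1), 0)            # log scale: exactly 1
#' fp_transform(2, c(-2, -2))         # 0.25 and 0.25 * log(2)
#' all.equal(drop(fp_transform(1:5, 1)), as.numeric(1:5))
#' @export
fp_transform <- function(x, powers) {
  x <- as.numeric(x)
  bad <- which(!is.finite(x) | x <= 0)
  if (length(bad))
    stop("fp_transform: x must be strictly positive and finite; offending rows: ",
         paste(utils::head(bad, 10L), collapse = ", "),
         if (length(bad) > 10L) ", ..." else "")
  powers <- as.numeric(powers)
  if (length(powers) < 1L || length(powers) > 2L || anyNA(powers))
    stop("fp_transform: powers must have length 1 or 2")
  if (is.unsorted(powers)) powers <- sort(powers)
  lx <- log(x)
  D <- length(powers)
  out <- matrix(0, length(x), D)
  for (d in seq_len(D)) {
    if (d > 1L && powers[d] == powers[d - 1L]) {
      out[, d] <- out[, d - 1L] * lx
    } else {
      out[, d] <- if (powers[d] == 0) lx else x^powers[d]
    }
  }
  colnames(out) <- paste0("x^", powers,
                          ifelse(duplicated(powers), ".log", ""))
  attr(out, "powers") <- powers
  out
}
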