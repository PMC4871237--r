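#' Multivariable FP model building on multiply imputed data
#'
#' Cycles the MI function selection procedure over several covariates:
#' each covariate in turn is submitted to [fsp_mi()] (continuous) or an
#' inclusion test (binary), conditioning on the currently selected
#' functional forms of the other covariates, until a full cycle changes no
#' covariate's selected form or `max_cycles` is reached.  Covariates are
#' visited in ascending order of the p-value of their pooled Wald test in
#' an initial model with every covariate entered linearly.
#'
#' @param mi An `mi_datasets` object.
#' @param terms Named integer vector giving the maximum FP dimension per
#'   continuous covariate (default 2 for every non-binary covariate);
#'   binary covariates (declared in the `mi` object) receive an
#'   inclusion/exclusion test only.
#' @param method `"stack"` or `"deltawald"`.
#' @param alpha_inclusion Level of the FPDmax-vs-null (inclusion) test.
#' @param alpha Level of the remaining tests.
#' @param grid Candidate power grid.
#' @param family Model family.
#' @param max_cycles Cycle cap; exceeding it returns with
#'   `converged = FALSE` and a warning.
#' @return An object of class `mfp_mi_result`: per-covariate selection
#'   (class, powers, test trail), visiting order, number of cycles run,
#'   convergence flag, and the Rubin's-rules pooled coefficients of the
#'   final model.
#' @export
mfp_mi <- function(mi, terms = NULL,
                   method = c("stack", "deltawald"),
                   alpha_inclusion = 0.1, alpha = 0.1,
                   grid = fp_grid_default(),
                   family = c("gaussian", "binomial"),
                   max_cycles = 5L) {
  stopifnot(inherits(mi, "mi_datasets"))
  method <- match.arg(method)
  family <- match.arg(family)
  covs <- mi$covariates
  if (is.null(terms))
    terms <- stats::setNames(rep(2L, length(covs)), covs)
  if (!all(names(terms) %in% covs)) stop("unknown covariate in terms")
  active <- names(terms)
  binary <- intersect(active, mi$binary)

  state <- stats::setNames(
    rep(list(list(class = "linear", powers = "linear")), length(active)),
    active)
  results <- stats::setNames(vector("list", length(active)), active)
  order_p <- mfp_initial_order(mi, active, family)
  visit <- active[order(order_p)]

  cycles_run <- 0L
  converged <- FALSE
  for (cy in seq_len(max_cycles)) {
    cycles_run <- cy
    changed <- FALSE
    for (cv in visit) {
      oth <- mfp_other_design(mi, cv, state, active)
      res <- if (cv %in% binary) {
        inclusion_test_mi(mi, cv, oth, family, method, alpha_inclusion)
      } else {
        fsp_mi(mi, cv, oth, family, Dmax = terms[[cv]],
               alpha_inclusion = alpha_inclusion, alpha = alpha,
               method = method, grid = grid)
      }
      new <- list(class = res$selected, powers = res$powers)
      if (!identical(new, state[[cv]])) changed <- TRUE
      state[[cv]] <- new
      results[[cv]] <- res
    }
    if (!changed) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("mfp_mi: selected forms not stable after ", max_cycles,
            " cycles")

  structure(list(selection = state, results = results,
                 visit_order = visit, cycles_run = cycles_run,
                 converged = converged, method = method,
                 pooled = mfp_pooled_final(mi, state, active, family)),
            class = "mfp_mi_result")
}

# Visiting order: p-values of each covariate's (pooled) Wald test in the
# all-linear model, ascending.
mfp_initial_order <- function(mi, active, family) {
  y <- mi$datasets[[1L]][[mi$outcome]]
  fits <- lapply(mi$datasets, function(d) {
    X <- cbind(1, as.matrix(d[, active, drop = FALSE]))
    if (family == "gaussian") gauss_ml(X, y) else logit_irls(X, y)
  })
  k <- length(active)
  pvals <- vapply(seq_len(k), function(j) {
    jj <- j + 1L  # skip intercept
    if (mi$M == 1L) {
      q <- fits[[1L]]$coefficients[jj]
      v <- fits[[1L]]$vcov[jj, jj]
    } else {
      pl <- rubin_pool(lapply(fits, function(f) f$coefficients[jj]),
                       lapply(fits, function(f) f$vcov[jj, jj]))
      q <- pl$qbar
      v <- pl$T[1L, 1L]
    }
    pchisq(q^2 / v, 1L, lower.tail = FALSE)
  }, 0)
  stats::setNames(pvals, active)
}

# Per-imputation design matrices of the other covariates at their
# currently selected forms; covariates selected out ("null") are omitted,
# inactive covariates stay linear.
mfp_other_design <- function(mi, cv, state, active) {
  covs <- mi$covariates
  others <- setdiff(covs, cv)
  lapply(mi$datasets, function(d) {
    cols <- list()
    for (o in others) {
      st <- if (o %in% active) state[[o]]
            else list(class = "linear", powers = "linear")
      if (st$class == "null") next
      cols[[o]] <- if (is.numeric(st$powers))
        fp_transform(d[[o]], st$powers)
      else matrix(d[[o]], ncol = 1L, dimnames = list(NULL, o))
    }
    if (length(cols)) do.call(cbind, cols) else NULL
  })
}

# Rubin's-rules pooled coefficients of the final selected model.
mfp_pooled_final <- function(mi, state, active, family) {
  y <- mi$datasets[[1L]][[mi$outcome]]
  build <- function(d) {
    cols <- list()
    for (cv in mi$covariates) {
      st <- if (cv %in% active) state[[cv]]
            else list(class = "linear", powers = "linear")
      if (st$class == "null") next
      cols[[cv]] <- if (is.numeric(st$powers))
        fp_transform(d[[cv]], st$powers)
      else matrix(d[[cv]], ncol = 1L, dimnames = list(NULL, cv))
    }
    nm <- unlist(lapply(names(cols), function(cv) {
      k <- ncol(cols[[cv]])
      if (k == 1L) cv else paste0(cv, ".", seq_len(k))
    }))
    X <- cbind(rep(1, nrow(d)),
               if (length(cols)) do.call(cbind, cols))
    colnames(X) <- c("(Intercept)", nm)
    X
  }
  fits <- lapply(mi$datasets, function(d) {
    X <- build(d)
    f <- if (family == "gaussian") gauss_ml(X, y) else logit_irls(X, y)
    f$names <- colnames(X)
    f
  })
  if (mi$M == 1L) {
    est <- fits[[1L]]$coefficients
    se <- sqrt(diag(fits[[1L]]$vcov))
  } else {
    pl <- rubin_pool(lapply(fits, `[[`, "coefficients"),
                     lapply(fits, `[[`, "vcov"))
    est <- pl$qbar
    se <- sqrt(diag(pl$T))
  }
  data.frame(term = fits[[1L]]$names, estimate = est, se = se,
             row.names = NULL)
}

#' @export
print.mfp_mi_result <- function(x, ...) {
  cat("MFP model building on MI data (method: ", x$method, ")\n", sep = "")
  cat("Converged:", x$converged, " after", x$cycles_run, "cycle(s)\n")
  sel <- data.frame(
    covariate = names(x$selection),
    selected = vapply(x$selection, `[[`, "", "class"),
    powers = vapply(x$selection, function(s)
      if (is.numeric(s$powers)) paste(s$powers, collapse = ", ")
      else s$powers, ""),
    row.names = NULL)
  print(sel, row.names = FALSE)
  cat("Pooled final model coefficients:\n")
  print(x$pooled, row.names = FALSE, ...)
  invisible(x)
}
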