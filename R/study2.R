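#' Configuration of the model-selection simulation study
#'
#' Study conditions for evaluating the MI-based selection tests.  Two
#' continuous covariates: \eqn{(x_1^{-0.5}, x_2)} bivariate normal with
#' means (0.6, 3), standard deviations (0.2, 1) and correlation `rho12`
#' (0 or 0.5), so that x1 has mean approximately 3 and variance
#' approximately 1; the outcome is Gaussian with linear predictor
#' \eqn{\beta_0 + \beta_1 x_1^{-0.5} + \beta_2 x_2} (true FP1 exponent
#' -0.5).  `beta1 = 0` probes type I error; for power, `beta1` is
#' calibrated so the complete-data FP1-vs-null test has 90% power.
#' `beta2` is calibrated so the test for inclusion of x2 has 90% power.
#' Missingness strikes x1, x2 or both; under MCAR each value is observed
#' with probability 0.7, under MAR with probability
#' \eqn{logit^{-1}(\omega_0 + \omega_1 y)} calibrated to a 70% observation
#' rate and an AUC of 0.65 for missingness against y (with
#' \eqn{\omega_1 < 0}, so values are more often missing at high y).
#'
#' @param n Sample size (200 or 500 in the study design).
#' @param mu1,sigma1 Mean and SD of x1^-0.5.
#' @param mu2,sigma2 Mean and SD of x2.
#' @param rho12 Correlation of x1^-0.5 and x2 (0 or 0.5).
#' @param p1 True FP1 exponent for x1.
#' @param beta0,beta1,beta2 Linear-predictor coefficients; `beta2 = NULL`
#'   means "calibrate before running".
#' @param sigma_y Residual SD of y.
#' @param missing_pattern Which covariates are incomplete.
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @param pi_obs Target observation probability.
#' @param auc_target Target AUC of missingness against y under MAR.
#' @param alpha Nominal test size.
#' @param M Imputations per replicate.
#' @param fcs_cycles Chained-equation cycles (used when both covariates
#'   are incomplete).
#' @param reps Number of replicates.
#' @param seed Master seed.
#' @return A list of class `study2_config`.
#' @export
study2_config <- function(n = 200L, mu1 = 0.6, sigma1 = 0.2, mu2 = 3,
                          sigma2 = 1, rho12 = 0, p1 = -0.5, beta0 = 0,
                          beta1 = 0, beta2 = NULL, sigma_y = 1,
                          missing_pattern = c("both", "x1", "x2"),
                          mechanism = c("MAR", "MCAR"), pi_obs = 0.7,
                          auc_target = 0.65, alpha = 0.1, M = 10L,
                          fcs_cycles = 10L, reps = 500L, seed = 1L) {
  missing_pattern <- match.arg(missing_pattern)
  mechanism <- match.arg(mechanism)
  stopifnot(abs(rho12) < 1, pi_obs > 0, pi_obs < 1,
            auc_target >= 0.5, auc_target < 1, sigma_y > 0)
  structure(list(n = as.integer(n), mu1 = mu1, sigma1 = sigma1,
                 mu2 = mu2, sigma2 = sigma2, rho12 = rho12, p1 = p1,
                 beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 sigma_y = sigma_y, missing_pattern = missing_pattern,
                 mechanism = mechanism, pi_obs = pi_obs,
                 auc_target = auc_target, alpha = alpha,
                 M = as.integer(M), fcs_cycles = as.integer(fcs_cycles),
                 reps = as.integer(reps), seed = seed),
            class = "study2_config")
}

#' Generate one complete Study-2 dataset
#'
#' Draws \eqn{(x_1^{-0.5}, x_2)} bivariate normal per the configuration
#' (rows with non-positive \eqn{x_1^{-0.5}} redrawn so x1 is well defined)
#' and the Gaussian outcome from its linear predictor.  The joint
#' distribution of \eqn{(x_1^{-0.5}, x_2, y)} is trivariate normal.
#'
#' @param cfg A [study2_config()] (with `beta2` set).
#' @return A data frame with columns `y`, `x1`, `x2`.
#' @export
gen_study2 <- function(cfg) {
  if (is.null(cfg$beta2))
    stop("gen_study2: beta2 is NULL; calibrate it first")
  n <- cfg$n
  r <- cfg$rho12
  draw <- function(k) {
    s1 <- rnorm(k)
    s2 <- rnorm(k)
    z <- cfg$mu1 + cfg$sigma1 * s1
    x2 <- cfg$mu2 + cfg$sigma2 * (r * s1 + sqrt(1 - r^2) * s2)
    cbind(z, x2)
  }
  d <- draw(n)
  bad <- which(d[, 1L] <= 0)
  while (length(bad)) {
    d[bad, ] <- draw(length(bad))
    bad <- bad[d[bad, 1L] <= 0]
  }
  z <- d[, 1L]
  x2 <- d[, 2L]
  y <- cfg$beta0 + cfg$beta1 * z + cfg$beta2 * x2 +
    cfg$sigma_y * rnorm(n)
  data.frame(y = y, x1 = z^(1 / cfg$p1), x2 = x2)
}

# moments of the y marginal implied by the configuration (z ~ N(mu1,
# sigma1^2) truncation at 0 is negligible at the study parameters)
study2_y_moments <- function(cfg) {
  m <- cfg$beta0 + cfg$beta1 * cfg$mu1 + cfg$beta2 * cfg$mu2
  v <- cfg$beta1^2 * cfg$sigma1^2 + cfg$beta2^2 * cfg$sigma2^2 +
    2 * cfg$beta1 * cfg$beta2 * cfg$rho12 * cfg$sigma1 * cfg$sigma2 +
    cfg$sigma_y^2
  c(mean = m, sd = sqrt(v))
}

#' Calibrate the MAR missingness model
#'
#' Finds \eqn{(\omega_0, \omega_1)} of the missingness model
#' \eqn{logit P(R = 1 | y) = \omega_0 + \omega_1 y} such that the marginal
#' observation probability equals `pi_target` and the AUC of the
#' missingness indicator against y equals `auc_target`, for a Gaussian y
#' marginal.  \eqn{\omega_1} is constrained negative (missingness more
#' likely at high y).  Solved by nested numerical root-finding over a
#' Gauss-quadrature grid; achieved rates are checked to within `tol`.
#'
#' @param y_mean,y_sd Moments of the Gaussian y marginal.
#' @param pi_target Target observation probability.
#' @param auc_target Target AUC; 0.5 gives `omega1 = 0` (MCAR limit).
#' @param tol Calibration tolerance (default 0.005).
#' @return Named vector `c(omega0, omega1)`.
#' @export
calibrate_mar_params <- function(y_mean, y_sd, pi_target = 0.7,
                                 auc_target = 0.65, tol = 0.005) {
  stopifnot(pi_target > 0, pi_target < 1,
            auc_target >= 0.5, auc_target < 1)
  ys <- y_mean + y_sd * seq(-8, 8, length.out = 4001L)
  fw <- dnorm(ys, y_mean, y_sd)
  fw <- fw / sum(fw)
  obs_rate <- function(w0, w1) sum(fw * plogis(w0 + w1 * ys))
  solve_w0 <- function(w1)
    uniroot(function(w0) obs_rate(w0, w1) - pi_target,
            c(-50, 50), tol = 1e-10)$root
  auc_of <- function(w1) {
    w0 <- solve_w0(w1)
    pi <- plogis(w0 + w1 * ys)
    f1 <- fw * pi          # observed
    f0 <- fw * (1 - pi)    # missing
    f1 <- f1 / sum(f1)
    f0 <- f0 / sum(f0)
    # AUC = P(y_missing > y_observed), grid ascending in y
    sum(f0 * (cumsum(f1) - 0.5 * f1))
  }
  if (auc_target == 0.5) {
    out <- c(omega0 = qlogis(pi_target), omega1 = 0)
  } else {
    w1 <- uniroot(function(w) auc_of(w) - auc_target,
                  c(-30 / y_sd, -1e-10), tol = 1e-10)$root
    out <- c(omega0 = solve_w0(w1), omega1 = w1)
  }
  ach_pi <- obs_rate(out[1L], out[2L])
  ach_auc <- if (out[2L] == 0) 0.5 else auc_of(out[2L])
  if (abs(ach_pi - pi_target) > tol || abs(ach_auc - auc_target) > tol)
    stop(sprintf(paste0("calibrate_mar_params failed: achieved rate ",
                        "%.4f (target %.3f), AUC %.4f (target %.3f)"),
                 ach_pi, pi_target, ach_auc, auc_target))
  out
}

#' Impose a missingness mechanism on Study-2 data
#'
#' Applies independent per-covariate Bernoulli missingness to the
#' covariates named by the pattern; y stays complete.  Under MCAR each
#' value is observed with probability `pi_obs`; under MAR with probability
#' \eqn{logit^{-1}(\omega_0 + \omega_1 y)} (same calibrated parameters for
#' every incomplete covariate).
#'
#' @param data Complete data frame with columns `y`, `x1`, `x2`.
#' @param pattern One of `"x1"`, `"x2"`, `"both"`.
#' @param mechanism `"MCAR"` or `"MAR"`.
#' @param pi_obs MCAR observation probability.
#' @param mar_params `c(omega0, omega1)` from [calibrate_mar_params()]
#'   (required under MAR).
#' @return An [incomplete_data()] object.
#' @export
apply_mechanism <- function(data, pattern = c("both", "x1", "x2"),
                            mechanism = c("MAR", "MCAR"), pi_obs = 0.7,
                            mar_params = NULL) {
  pattern <- match.arg(pattern)
  mechanism <- match.arg(mechanism)
  targets <- switch(pattern, x1 = "x1", x2 = "x2", both = c("x1", "x2"))
  p_obs <- if (mechanism == "MCAR") rep(pi_obs, nrow(data))
  else {
    if (is.null(mar_params))
      stop("apply_mechanism: mar_params required under MAR")
    plogis(mar_params[1L] + mar_params[2L] * data$y)
  }
  for (cv in targets) {
    miss <- runif(nrow(data)) >= p_obs
    data[[cv]][miss] <- NA_real_
  }
  incomplete_data(data, outcome = "y", covariates = c("x1", "x2"))
}

# Complete-data test statistics used during effect calibration.
# fp1_vs_null: LRT of the best FP1 for x1 (coarse grid, x2 linear) against
# the null model (x2 only), 2 df.  x2_inclusion: LRT of x2 in the true-form
# model, 1 df.
calib_pvalue <- function(dat, test, grid) {
  y <- dat$y
  if (test == "fp1_vs_null") {
    o <- matrix(dat$x2, ncol = 1L)
    ll0 <- gauss_ml(cbind(1, o), y)$loglik
    ll1 <- profile_best_powers(y, dat$x1, o, "gaussian", 1L, grid)$loglik
    pchisq(2 * (ll1 - ll0), 2L, lower.tail = FALSE)
  } else {
    z <- dat$x1^(-0.5)
    ll0 <- gauss_ml(cbind(1, z), y)$loglik
    ll1 <- gauss_ml(cbind(1, z, dat$x2), y)$loglik
    pchisq(2 * (ll1 - ll0), 1L, lower.tail = FALSE)
  }
}

#' Calibrate an effect size to a target complete-data power
#'
#' Finds the coefficient (`beta1` for the FP1-vs-null test on x1, `beta2`
#' for the inclusion test on x2) whose complete-data likelihood-ratio test
#' at level `alpha` has the target power.  Power is estimated by
#' simulation with common random numbers (the same seed regenerates the
#' same covariate and noise draws at every trial coefficient, so the
#' power curve is smooth and monotone), and the coefficient is found by
#' bisection from a noncentral-chi-square starting bracket until the
#' achieved power is within `tol` of the target.
#'
#' @param cfg A [study2_config()]; the coefficient being calibrated is
#'   overridden during the search (`beta2` must be set when calibrating
#'   `beta1`).
#' @param target_power Target power (in (`alpha`, 1)).
#' @param test `"fp1_vs_null"` or `"x2_inclusion"`.
#' @param alpha Test level.
#' @param reps Replicates per power evaluation.
#' @param seed Seed for the common random numbers.
#' @param grid Power grid for the FP1 profiling.
#' @param tol Power tolerance (default 0.01).
#' @return The calibrated coefficient (positive), with the achieved power
#'   as attribute `"power"`.
#' @export
calibrate_effect <- function(cfg, target_power = 0.9,
                             test = c("fp1_vs_null", "x2_inclusion"),
                             alpha = 0.1, reps = 1000L, seed = 1L,
                             grid = fp_grid_default(), tol = 0.01) {
  test <- match.arg(test)
  stopifnot(target_power > alpha, target_power < 1)
  power_fn <- function(beta) {
    cfg2 <- cfg
    if (test == "fp1_vs_null") cfg2$beta1 <- beta else cfg2$beta2 <- beta
    if (is.null(cfg2$beta2)) cfg2$beta2 <- 0
    set.seed(seed)
    rej <- logical(reps)
    for (r in seq_len(reps))
      rej[r] <- calib_pvalue(gen_study2(cfg2), test, grid) <= alpha
    mean(rej)
  }
  # noncentral chi-square starting value
  df <- if (test == "fp1_vs_null") 2L else 1L
  crit <- qchisq(1 - alpha, df)
  ncp <- uniroot(function(l)
    pchisq(crit, df, ncp = l, lower.tail = FALSE) - target_power,
    c(1e-6, 100))$root
  resvar <- if (test == "fp1_vs_null")
    cfg$sigma1^2 * (1 - cfg$rho12^2)
  else cfg$sigma2^2 * (1 - cfg$rho12^2)
  beta_start <- sqrt(ncp * cfg$sigma_y^2 / (cfg$n * resvar))

  lo <- beta_start / 2
  hi <- beta_start * 2
  p_lo <- power_fn(lo)
  p_hi <- power_fn(hi)
  it <- 0L
  while (p_lo > target_power && it < 10L) {
    hi <- lo; p_hi <- p_lo; lo <- lo / 2; p_lo <- power_fn(lo); it <- it + 1L
  }
  while (p_hi < target_power && it < 20L) {
    lo <- hi; p_lo <- p_hi; hi <- hi * 2; p_hi <- power_fn(hi); it <- it + 1L
  }
  if (p_lo > target_power || p_hi < target_power)
    stop("calibrate_effect: failed to bracket the target power")
  repeat {
    mid <- (lo + hi) / 2
    p_mid <- power_fn(mid)
    if (abs(p_mid - target_power) <= tol || (hi - lo) < 1e-4 * beta_start)
      return(structure(mid, power = p_mid))
    if (p_mid < target_power) lo <- mid else hi <- mid
  }
}

#' Run the model-selection simulation study
#'
#' Per replicate: generate complete Study-2 data, impose the missingness
#' mechanism, multiply impute x1/x2 with the bootstrap method (fine
#' exponent grid, PMM positivity), then run the MFP selection algorithm
#' for both covariates (maximum dimension FP1, both tests at the nominal
#' `alpha`) four ways: complete data, complete records, and MI data by
#' stacking and by delta-Wald.  For x1, the p-values of the FP1-vs-null
#' and FP1-vs-linear tests in the final cycle are recorded marginally and
#' aggregated to rejection rates with binomial Monte-Carlo standard
#' errors.
#'
#' @param cfg A [study2_config()] with `beta2` (and `beta1` when probing
#'   power) already set/calibrated.
#' @param mar_params Optional pre-computed MAR parameters; calibrated from
#'   the configuration when omitted.
#' @return An object of class `selection_result`: a data frame of
#'   rejection rates per method and test, the replicate-level p-value
#'   array, failure count and configuration.
#' @export
run_selection_study <- function(cfg, mar_params = NULL) {
  stopifnot(inherits(cfg, "study2_config"))
  if (is.null(cfg$beta2)) stop("beta2 must be calibrated/set")
  if (cfg$mechanism == "MAR" && is.null(mar_params)) {
    ym <- study2_y_moments(cfg)
    mar_params <- calibrate_mar_params(ym["mean"], ym["sd"],
                                       cfg$pi_obs, cfg$auc_target)
  }
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max, cfg$reps)
  methods <- c("complete-data", "complete-records", "stack", "deltawald")
  tests <- c("fp1_vs_null", "fp1_vs_linear")
  pv <- array(NA_real_, c(cfg$reps, length(methods), length(tests)),
              dimnames = list(NULL, methods, tests))
  terms <- c(x1 = 1L, x2 = 1L)
  impcfg <- mi_config(M = cfg$M, grid = fp_grid_fine(),
                      positivity = "pmm", donor_k = 3L,
                      fcs_cycles = cfg$fcs_cycles)
  failures <- 0L

  x1_trail <- function(mfp) {
    tr <- mfp$results[["x1"]]$trail
    c(tr$p.value[tr$simple == "null"], tr$p.value[tr$simple == "linear"])
  }
  for (r in seq_len(cfg$reps)) {
    ok <- tryCatch({
      set.seed(seeds[r])
      dat <- gen_study2(cfg)
      inc <- apply_mechanism(dat, cfg$missing_pattern, cfg$mechanism,
                             cfg$pi_obs, mar_params)
      mi <- mi_impute(inc, impcfg)
      cd <- mi_from_complete(dat, "y", c("x1", "x2"))
      crd <- dat[stats::complete.cases(inc$data), , drop = FALSE]
      cr <- mi_from_complete(crd, "y", c("x1", "x2"))
      run1 <- function(mm, meth) suppressWarnings(
        mfp_mi(mm, terms, method = meth,
               alpha_inclusion = cfg$alpha, alpha = cfg$alpha))
      pv[r, "complete-data", ] <- x1_trail(run1(cd, "stack"))
      pv[r, "complete-records", ] <- x1_trail(run1(cr, "stack"))
      pv[r, "stack", ] <- x1_trail(run1(mi, "stack"))
      pv[r, "deltawald", ] <- x1_trail(run1(mi, "deltawald"))
      TRUE
    }, error = function(e) FALSE)
    if (!ok) {
      pv[r, , ] <- NA_real_
      failures <- failures + 1L
    }
  }

  rows <- expand.grid(method = methods, test = tests,
                      stringsAsFactors = FALSE)
  rows$rejections <- mapply(function(m, t)
    sum(pv[, m, t] <= cfg$alpha, na.rm = TRUE),
    rows$method, rows$test)
  rows$reps <- mapply(function(m, t) sum(!is.na(pv[, m, t])),
                      rows$method, rows$test)
  rows$rate <- rows$rejections / rows$reps
  rows$mc_se <- sqrt(rows$rate * (1 - rows$rate) / rows$reps)
  structure(list(rates = rows, p_values = pv, failures = failures,
                 mar_params = mar_params, config = cfg),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cfg <- x$config
  cat("Selection study: n =", cfg$n, ", pattern =", cfg$missing_pattern,
      ", mechanism =", cfg$mechanism, ", rho12 =", cfg$rho12,
      ", beta1 =", format(cfg$beta1), "\n")
  cat("Nominal alpha =", cfg$alpha, "; replicates =",
      cfg$reps - x$failures, "(", x$failures, "failed )\n")
  print(x$rates, row.names = FALSE, digits = 3, ...)
  invisible(x)
}
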