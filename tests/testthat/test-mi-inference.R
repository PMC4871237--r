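test_that("rubin_pool matches the textbook rules", {
  p <- rubin_pool(list(1, 2, 3), list(1, 1, 1))
  expect_equal(drop(p$qbar), 2)
  expect_equal(drop(p$W), 1)
  expect_equal(drop(p$B), 1)
  expect_equal(drop(p$T), 1 + (1 + 1 / 3) * 1)

  # identical estimates: between-variance zero, T = W
  p2 <- rubin_pool(list(c(1, 2), c(1, 2)), list(diag(2), diag(2)))
  expect_equal(p2$B, matrix(0, 2, 2))
  expect_equal(p2$T, p2$W)

  # scalar case equals the 1x1 matrix case
  p3 <- rubin_pool(list(0.3, 0.8), list(0.2, 0.4))
  p4 <- rubin_pool(list(matrix(0.3), matrix(0.8)),
                   list(matrix(0.2), matrix(0.4)))
  expect_equal(p3$T, p4$T)

  expect_error(rubin_pool(list(1), list(1)), "M >= 2")

  # independent reference implementation on random inputs
  set.seed(4)
  for (rep in 1:5) {
    M <- sample(3:8, 1)
    k <- sample(1:3, 1)
    est <- lapply(1:M, function(i) rnorm(k))
    cv <- lapply(1:M, function(i) crossprod(matrix(rnorm(k * k), k)))
    p <- rubin_pool(est, cv)
    Q <- do.call(rbind, est)
    qb <- colMeans(Q)
    W <- Reduce(`+`, cv) / M
    B <- matrix(0, k, k)
    for (i in 1:M)
      B <- B + tcrossprod(Q[i, ] - qb) / (M - 1)
    expect_equal(p$qbar, qb, tolerance = 1e-12)
    expect_equal(p$T, W + (1 + 1 / M) * B, tolerance = 1e-12)
  }
})

test_that("pooled_wald and delta_wald follow chi-square arithmetic", {
  w <- pooled_wald(list(qbar = 2, T = 4), df = 1)
  expect_equal(w$statistic, 1)
  expect_equal(w$p.value, pchisq(1, 1, lower.tail = FALSE),
               tolerance = 1e-6)
  expect_equal(round(w$p.value, 4), 0.3173)

  w0 <- pooled_wald(list(qbar = 0, T = 1), df = 1)
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p.value, 1)

  w2 <- pooled_wald(list(qbar = c(1, 1), T = diag(2)), df = 2)
  expect_equal(w2$statistic, 2)
  expect_equal(round(w2$p.value, 4), 0.3679)

  expect_error(pooled_wald(list(qbar = c(1, 1), T = matrix(1, 2, 2)), 2),
               "singular")

  d <- delta_wald(10, 7, 1)
  expect_equal(round(d$p.value, 4), 0.0833)
  expect_false(d$negative_flag)

  dn <- delta_wald(5, 6, 1)
  expect_true(dn$negative_flag)
  expect_equal(dn$p.value, 1)

  d0 <- delta_wald(4, 4, 2)
  expect_equal(d0$p.value, 1)
  expect_false(d0$negative_flag)
})

test_that("stacking produces n x M rows and the W3 weights", {
  inc <- make_study1_incomplete(seed = 6)
  mi <- mi_impute(inc, mi_config(M = 10, fcs_cycles = 1, seed = 7))
  st <- stack_mi(mi)
  expect_equal(nrow(st$data), 300 * 10)
  f <- mi$f[["x"]]
  expect_equal(st$w[["x"]], (1 - f) / 10)

  cd <- mi_from_complete(data.frame(y = rnorm(50),
                                    x = runif(50, 1, 2)), "y", M = 10)
  expect_equal(stack_mi(cd)$w[["x"]], 1 / 10)
})

test_that("with no missing cells the stacked route reproduces the complete-data FSP exactly", {
  for (seed in c(1, 2, 3)) {
    dat <- make_signal_data(seed = seed)
    ref <- fsp_complete(dat$y, dat$x1, other = cbind(x2 = dat$x2),
                        Dmax = 2L)
    mi <- mi_from_complete(dat, "y", c("x1", "x2"), M = 3L)

    s <- fsp_mi(mi, "x1", other = "x2", Dmax = 2L, method = "stack")
    expect_equal(s$selected, ref$selected)
    expect_equal(s$powers, ref$powers)
    expect_equal(s$trail$statistic, ref$trail$statistic,
                 tolerance = 1e-8)

    est_ll <- estimate_p_stacked_ll(mi, "x1", D = 1L, other = "x2")
    ref_p <- profile_best_powers(dat$y, dat$x1, cbind(dat$x2),
                                 D = 1L)$powers
    expect_equal(est_ll$powers, ref_p)
  }
})

test_that("with no missing cells the delta-Wald route equals a complete-data Wald ladder", {
  # independent oracle: single-fit Wald statistics via lm/vcov
  wald_of <- function(dat, powers) {
    X <- if (identical(powers, "linear")) cbind(x = dat$x1)
         else fp_transform(dat$x1, powers)
    fit <- lm(dat$y ~ X + dat$x2)
    idx <- 1 + seq_len(ncol(X))
    b <- coef(fit)[idx]
    drop(crossprod(b, solve(vcov(fit)[idx, idx], b)))
  }
  for (seed in c(1, 2, 3)) {
    dat <- make_signal_data(seed = seed)
    mi <- mi_from_complete(dat, "y", c("x1", "x2"), M = 2L)
    d <- fsp_mi(mi, "x1", other = "x2", Dmax = 1L, method = "deltawald")

    grid <- as.numeric(fp_grid_default())
    w_fp1 <- vapply(grid, function(p) wald_of(dat, p), 0)
    best <- grid[which.max(w_fp1)]
    expect_equal(d$class_powers$FP1, best)
    expect_equal(d$trail$statistic[d$trail$simple == "null"],
                 max(w_fp1), tolerance = 1e-8)
    expect_equal(d$trail$statistic[d$trail$simple == "linear"],
                 max(w_fp1) - wald_of(dat, "linear"), tolerance = 1e-8)
    ew <- estimate_p_wald(mi, "x1", D = 1L, other = "x2")
    expect_equal(ew$powers, best)
  }
})

test_that("delta-Wald selection agrees with the complete-data LRT decision in most replicates", {
  # asymptotic equivalence of Wald and LRT: under a strong FP1 signal and
  # no missingness the two ladders agree on the selected class in at
  # least 95% of replicates
  set.seed(44)
  reps <- 60
  agree <- logical(reps)
  for (r in seq_len(reps)) {
    dat <- make_signal_data(n = 300, seed = 1000 + r)
    ref <- fsp_complete(dat$y, dat$x1, other = cbind(dat$x2), Dmax = 1L)
    mi <- mi_from_complete(dat, "y", c("x1", "x2"), M = 2L)
    d <- fsp_mi(mi, "x1", other = "x2", Dmax = 1L, method = "deltawald")
    agree[r] <- identical(d$selected, ref$selected)
  }
  expect_gte(mean(agree), 0.95)
})

test_that("pooled Wald selection is invariant to imputation order", {
  inc <- make_study1_incomplete(seed = 8)
  mi <- mi_impute(inc, mi_config(M = 5, fcs_cycles = 1, seed = 9))
  e1 <- estimate_p_wald(mi, "x", D = 1L)
  mi_rev <- mi
  mi_rev$datasets <- rev(mi$datasets)
  e2 <- estimate_p_wald(mi_rev, "x", D = 1L)
  expect_equal(e1$powers, e2$powers)
  expect_equal(e1$statistic, e2$statistic, tolerance = 1e-10)
})

test_that("stacked log-likelihood ordering is scale-invariant in the weights", {
  dat <- make_signal_data(seed = 10)
  grid <- fp_grid_default()
  for (w in c(0.5, 2)) {
    lls1 <- vapply(as.numeric(grid), function(p)
      fp_fit(dat$y, dat$x1, p, weights = rep(1, nrow(dat)))$loglik, 0)
    llsw <- vapply(as.numeric(grid), function(p)
      fp_fit(dat$y, dat$x1, p, weights = rep(w, nrow(dat)))$loglik, 0)
    expect_equal(order(lls1), order(llsw))
    expect_equal(llsw, w * lls1, tolerance = 1e-8)
  }
})

test_that("exponent estimators honour a one-point grid", {
  inc <- make_study1_incomplete(seed = 12)
  mi <- mi_impute(inc, mi_config(M = 3, fcs_cycles = 1, seed = 13))
  g1 <- power_grid(values = 2)
  expect_equal(estimate_p_stacked_ll(mi, "x", grid = g1)$powers, 2)
  expect_equal(estimate_p_wald(mi, "x", grid = g1)$powers, 2)
})

test_that("mfp_mi reduces to fsp_mi for a single covariate and converges", {
  inc <- make_study1_incomplete(seed = 14)
  mi <- mi_impute(inc, mi_config(M = 5, fcs_cycles = 1, seed = 15))
  single <- mfp_mi(mi, c(x = 1L), method = "stack")
  direct <- fsp_mi(mi, "x", Dmax = 1L, method = "stack")
  expect_equal(single$selection$x$class, direct$selected)
  expect_equal(single$selection$x$powers, direct$powers)
  expect_true(single$converged)
  expect_lte(single$cycles_run, 5L)
})

test_that("mfp_mi keeps a strong binary covariate and drops pure noise", {
  set.seed(16)
  n <- 300
  sex <- rbinom(n, 1, 0.5)
  x1 <- runif(n, 0.5, 4)
  noise <- runif(n, 1, 2)
  y <- 2 / sqrt(x1) + 1.5 * sex + rnorm(n, sd = 0.5)
  dat <- data.frame(y, x1, sex, noise)
  mi <- mi_from_complete(dat, "y", c("x1", "sex", "noise"),
                         binary = "sex", M = 2L)
  fit <- mfp_mi(mi, c(x1 = 1L, sex = NA, noise = 1L), method = "stack",
                alpha_inclusion = 0.05, alpha = 0.05)
  expect_equal(fit$selection$sex$class, "linear")
  expect_equal(fit$selection$x1$class, "FP1")
  expect_equal(fit$selection$noise$class, "null")
  expect_true(fit$converged)
  expect_true(all(c("(Intercept)", "sex") %in% fit$pooled$term))
})
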