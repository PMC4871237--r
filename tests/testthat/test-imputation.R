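test_that("abb_resample conserves size and mean inclusion", {
  set.seed(1)
  ids <- 101:120
  s <- abb_resample(ids)
  expect_length(s, 20)
  expect_true(all(s %in% ids))

  # a single distinct row repeated k times resamples to itself
  expect_equal(abb_resample(rep(7L, 12)), rep(7L, 12))

  expect_error(abb_resample(integer(0)), "empty")
  expect_error(abb_resample(1:5), "too few")

  # each row's expected inclusion count is 1 (law of large numbers)
  draws <- 4000
  counts <- matrix(0, draws, 12)
  for (d in seq_len(draws)) {
    tb <- tabulate(abb_resample(1:12), nbins = 12)
    counts[d, ] <- tb
  }
  m <- colMeans(counts)
  se <- apply(counts, 2, sd) / sqrt(draws)
  expect_true(all(abs(m - 1) < 3 * se + 1e-8))
})

test_that("jacobian_adjustment matches the closed form", {
  expect_equal(jacobian_adjustment(1, 1), 0)
  expect_equal(jacobian_adjustment(1, 0), 0)
  expect_equal(jacobian_adjustment(2, 2), log(4))
  x <- c(0.5, 2, 3)
  p <- -0.5
  expect_equal(jacobian_adjustment(x, p),
               sum(log(abs(p)) + (p - 1) * log(x)))
  expect_equal(jacobian_adjustment(x, 0), -sum(log(x)))
  expect_error(jacobian_adjustment(c(1, -1), 2), "positive")
})

test_that("draw_exponent maximises the Jacobian-adjusted log-likelihood", {
  # a grid with a single value always returns that value
  set.seed(2)
  x <- runif(50, 1, 3)
  y <- rnorm(50)
  d <- draw_exponent(x, y, grid = power_grid(values = 0.5))
  expect_equal(d$p_star, 0.5)

  # the winner attains the maximum of the profile
  d2 <- draw_exponent(x, y, grid = fp_grid_default())
  pr <- d2$profile
  expect_equal(d2$p_star,
               unname(pr[which.max(pr[, "adjusted"]), "p"]))
  expect_equal(pr[, "adjusted"], pr[, "loglik"] + pr[, "jacobian"])

  expect_error(draw_exponent(c(-1, x), c(0, y)), "positive")
})

test_that("p* draws concentrate on the generating exponent", {
  # Study-1 conditions (n = 300, correlation 0.7), fresh dataset per draw
  set.seed(11)
  cfg <- study1_config(true_p = 1)
  ps <- replicate(200, {
    dat <- gen_study1(cfg)
    s <- abb_resample(seq_len(nrow(dat)))
    draw_exponent(dat$x[s], dat$y[s], grid = fp_grid_fine())$p_star
  })
  tab <- table(ps)
  expect_equal(as.numeric(names(tab)[which.max(tab)]), 1)
  expect_gte(mean(abs(ps - 1) <= 0.2), 0.8)
})

test_that("single imputation respects PMM membership and positivity", {
  set.seed(3)
  n <- 200
  x <- exp(rnorm(n, 0.5, 0.4))
  y <- 2 * log(x) + rnorm(n, sd = 0.5)
  observed <- runif(n) > 0.3
  xm <- x
  xm[!observed] <- NA

  r <- impute_fp1_once(xm, observed, y, config = mi_config(M = 1))
  expect_false(anyNA(r$x))
  expect_equal(r$x[observed], x[observed])
  # PMM: every imputed value is an observed value
  expect_true(all(r$x[!observed] %in% x[observed]))
  expect_true(all(r$x > 0))

  # truncated option: strictly positive, above the transformed bound
  r2 <- impute_fp1_once(xm, observed, y,
                        config = mi_config(M = 1,
                                           positivity = "truncated"))
  expect_true(all(r2$x > 0))
  expect_gte(min(r2$x[!observed]), min(x[observed]) / 2)

  # no missing values: column returned unchanged
  r3 <- impute_fp1_once(x, rep(TRUE, n), y, config = mi_config(M = 1))
  expect_identical(r3$x, x)

  expect_error(impute_fp1_once(xm, observed, y,
                               config = mi_config(donor_k = 1000)),
               "donor_k")
  expect_error(impute_fp1_once(xm[1:8], observed[1:8], y[1:8]),
               "fewer than 10")
})

test_that("regression imputation at p = 1 matches an independent oracle", {
  # with a one-point grid at p = 1 and truncated positivity, the
  # algorithm is exactly Bayesian-draw linear regression imputation of x
  # on y; replay the same RNG stream through a hand-written reference
  set.seed(31)
  n <- 150
  x <- runif(n, 2, 6)
  y <- 1.2 * x + rnorm(n)
  observed <- runif(n) > 0.35
  xm <- x
  xm[!observed] <- NA
  cfg <- mi_config(M = 1, grid = power_grid(values = 1),
                   positivity = "truncated", trunc_lower = 1e-8)

  set.seed(99)
  r <- impute_fp1_once(xm, observed, y, config = cfg)

  set.seed(99)
  k <- sum(observed)
  g <- rexp(k)                             # ABB weights
  invisible(sample.int(k, k, replace = TRUE, prob = g / sum(g)))
  fit <- lm(x[observed] ~ y[observed])
  res <- residuals(fit)
  dfres <- k - 2
  sigma2 <- sum(res^2) / rchisq(1, dfres)
  Z <- cbind(1, y[observed])
  R <- qr.R(qr(Z))
  beta <- coef(fit) + sqrt(sigma2) * backsolve(R, rnorm(2))
  mu <- cbind(1, y[!observed]) %*% beta
  lo <- pnorm(1e-8, mu, sqrt(sigma2))
  u <- runif(sum(!observed), lo, 1)
  ref <- qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12), mu, sqrt(sigma2))
  expect_equal(r$p_star, 1)
  expect_equal(r$x[!observed], drop(ref), tolerance = 1e-6)
})

test_that("mi_impute preserves observed cells and is seed-deterministic", {
  inc <- make_study1_incomplete(true_p = 1, seed = 5)
  cfg <- mi_config(M = 4, fcs_cycles = 1, seed = 17)
  mi <- mi_impute(inc, cfg)

  expect_length(mi$datasets, 4)
  obs <- inc$mask[, "x"]
  src <- inc$data$x
  for (m in 1:4) {
    expect_identical(mi$datasets[[m]]$x[obs], src[obs])
    expect_false(anyNA(mi$datasets[[m]]$x))
    expect_true(all(mi$datasets[[m]]$x > 0))
  }
  expect_true(all(mi$p_star[, "x"] %in% as.numeric(fp_grid_fine())))

  mi2 <- mi_impute(inc, cfg)
  expect_identical(mi$datasets, mi2$datasets)
  expect_identical(mi$p_star, mi2$p_star)

  cc <- incomplete_data(data.frame(y = rnorm(20), x = runif(20, 1, 2)),
                        "y")
  expect_error(mi_impute(cc, cfg), "no covariate")
})

test_that("pooled covariate mean is recovered under Study-1 MAR", {
  # MCAR-free sanity of the whole chain: pooled mean of imputed x should
  # track the complete-data mean
  set.seed(20)
  cfg1 <- study1_config(true_p = 1, seed = 20)
  dat <- gen_study1(cfg1)
  inc <- apply_mar_study1(dat, cfg1)
  mi <- mi_impute(inc, mi_config(M = 10, fcs_cycles = 1, seed = 21))
  pooled_mean <- mean(vapply(mi$datasets, function(d) mean(d$x), 0))
  se <- sd(dat$x) / sqrt(nrow(dat))
  expect_lt(abs(pooled_mean - mean(dat$x)), 4 * se)
})
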