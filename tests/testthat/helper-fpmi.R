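# Shared fixtures, built in code.

# Complete two-covariate Gaussian dataset with a clear FP1 (p = -0.5)
# signal in x1 and a linear x2 effect.
make_signal_data <- function(n = 250, beta1 = 3, beta2 = 0.5,
                             seed = 1) {
  set.seed(seed)
  x1 <- runif(n, 0.3, 4)
  x2 <- rnorm(n, 3, 1)
  y <- beta1 / sqrt(x1) + beta2 * x2 + rnorm(n, sd = 0.6)
  data.frame(y = y, x1 = x1, x2 = x2)
}

# Study-1 style incomplete data (single covariate, MAR).
make_study1_incomplete <- function(true_p = 1, seed = 1, n = 300) {
  cfg <- study1_config(n = n, true_p = true_p, seed = seed)
  set.seed(seed)
  dat <- gen_study1(cfg)
  apply_mar_study1(dat, cfg)
}

# Reference Gaussian log-likelihood at the ML variance, via lm().
lm_loglik <- function(y, X) {
  fit <- stats::lm.fit(cbind(1, X), y)
  rss <- sum(fit$residuals^2)
  n <- length(y)
  -n / 2 * (log(2 * pi * rss / n) + 1)
}
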