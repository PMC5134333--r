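test_that("logistic log-density matches the closed form and dlogis", {
  expect_equal(logistic_logpdf(6, mu = 6, s = 0.2), log(1 / (4 * 0.2)),
               tolerance = 1e-12)
  p <- seq(2, 10, by = 0.25)
  expect_equal(logistic_logpdf(p, 6, 0.3), dlogis(p, 6, 0.3, log = TRUE),
               tolerance = 1e-12)
  # symmetry about the location
  for (d in c(0.1, 1, 4)) {
    expect_equal(logistic_logpdf(6 + d, 6, 0.5), logistic_logpdf(6 - d, 6, 0.5),
                 tolerance = 1e-12)
  }
  mass <- integrate(function(x) exp(logistic_logpdf(x, 6, 0.4)),
                    -Inf, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-6)
  expect_error(logistic_logpdf(1, 6, 0), "positive")
})

test_that("log-logistic density/CDF agree with the log-transform oracle", {
  h <- 10^seq(-2, 1.5, length.out = 40)
  for (ab in list(c(1, 5), c(0.7, 2.5), c(2, 8))) {
    oracle <- dlogis(log(h), log(ab[1]), 1 / ab[2], log = TRUE) - log(h)
    expect_equal(loglogistic_logpdf(h, ab[1], ab[2]), oracle,
                 tolerance = 1e-10)
    expect_equal(loglogistic_cdf(h, ab[1], ab[2]),
                 plogis(log(h), log(ab[1]), 1 / ab[2]), tolerance = 1e-12)
  }
  # alpha is the median
  expect_equal(loglogistic_cdf(1.4, alpha = 1.4, beta = 3), 0.5,
               tolerance = 1e-12)
  expect_equal(loglogistic_quantile(0.5, 1.4, 3), 1.4, tolerance = 1e-12)
  mass <- integrate(function(x) exp(loglogistic_logpdf(x, 1, 5)),
                    0, Inf, rel.tol = 1e-10)$value
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("log-logistic support and small-h behaviour under beta > 2", {
  expect_identical(loglogistic_logpdf(-1, 1, 3), -Inf)
  expect_identical(loglogistic_logpdf(0, 1, 3), -Inf)
  # no mass and zero slope at the origin when beta > 2
  p_small <- exp(loglogistic_logpdf(1e-6, 1, 3))
  expect_lt(p_small, 1e-10)
  expect_lt(p_small / 1e-6, 1e-4)
  expect_error(loglogistic_logpdf(1, -1, 3), "alpha")
  expect_error(loglogistic_logpdf(1, 1, 0), "beta")
})

test_that("hyperprior enforces the hard support bounds", {
  expect_identical(log_hyperprior(1, 1.5, 6, 0.2, 1), -Inf)    # beta <= 2
  expect_identical(log_hyperprior(1, 5, 6, 0.2, 1e-4), -Inf)   # sigma <= 1e-3
  expect_identical(log_hyperprior(-1, 5, 6, 0.2, 1), -Inf)
  expect_identical(log_hyperprior(1, 5, -5, 0.2, 1), -Inf)     # below mu shift
  expect_true(is.finite(log_hyperprior(1, 5, 6, 0.2, 1)))
  # composition against dgamma
  cf <- hier_prior_config()
  expected <- dgamma(1, cf$alpha[["shape"]], scale = cf$alpha[["scale"]], log = TRUE) +
    dgamma(5, cf$beta[["shape"]], scale = cf$beta[["scale"]], log = TRUE) +
    dgamma(6 + 4, cf$mu[["shape"]], scale = cf$mu[["scale"]], log = TRUE) +
    dgamma(0.2, cf$s[["shape"]], scale = cf$s[["scale"]], log = TRUE) +
    dgamma(1, cf$sigma[["shape"]], scale = cf$sigma[["scale"]], log = TRUE)
  expect_equal(log_hyperprior(1, 5, 6, 0.2, 1), expected, tolerance = 1e-12)
})

test_that("default hyperprior puts little mass on very low potency", {
  cf <- hier_prior_config()
  # P(mu < -2) under the shifted gamma
  expect_lt(pgamma(-2 - cf$mu[["shift"]], cf$mu[["shape"]],
                   scale = cf$mu[["scale"]]), 0.05)
})

test_that("hierarchical posterior composes likelihood, populations and hyperprior", {
  d <- make_hier_data(ne = 3, seed = 10)
  set.seed(11)
  for (k in 1:5) {
    top <- c(alpha = runif(1, 0.5, 2), beta = runif(1, 2.5, 8),
             mu = runif(1, 4, 8), s = runif(1, 0.05, 0.5),
             sigma = runif(1, 0.3, 3))
    pic <- rnorm(3, 6, 0.3)
    hil <- runif(3, 0.5, 2)
    got <- log_posterior_hier(d, top[1], top[2], top[3], top[4], top[5],
                              pIC50_i = pic, Hill_i = hil)
    f <- hill_response(d$dose, pic[d$exp_index], hil[d$exp_index])
    want <- sum(hillbayes:::trunc_norm_loglik(d$response, f, top[5])) +
      sum(loglogistic_logpdf(hil, top[1], top[2])) +
      sum(logistic_logpdf(pic, top[3], top[4])) +
      log_hyperprior(top[1], top[2], top[3], top[4], top[5])
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("hierarchical posterior support and dimension contracts hold", {
  d <- make_hier_data(ne = 3, seed = 12)
  expect_identical(
    log_posterior_hier(d, 1, 5, 6, 0.2, 1, rnorm(3, 6, 0.1), c(1, -0.5, 1)),
    -Inf)
  expect_error(log_posterior_hier(d, 1, 5, 6, 0.2, 1, rnorm(2), c(1, 1)),
               "3")
  target <- hillbayes:::make_hier_target(d)
  expect_length(attr(target, "par_names"), 11)   # 5 + 2 * 3
})

test_that("hierarchical posterior is invariant to relabelling experiments", {
  d <- make_hier_data(ne = 4, seed = 13)
  pic <- c(5.8, 6.1, 6.3, 5.9)
  hil <- c(0.9, 1.1, 1.3, 1.0)
  base <- log_posterior_hier(d, 1, 5, 6, 0.2, 1, pic, hil)
  perm <- c(3, 1, 4, 2)
  # rebuild the dataset with experiment blocks in permuted order
  rows <- do.call(rbind, lapply(perm, function(i) d[d$exp_index == i, ]))
  d2 <- dose_response_data(rows$experiment, rows$dose, rows$response)
  got <- log_posterior_hier(d2, 1, 5, 6, 0.2, 1, pic[perm], hil[perm])
  expect_equal(got, base, tolerance = 1e-10)
})

test_that("population density at the centres grows without bound as it degenerates", {
  # s -> 0 concentrates pIC50_i at mu; beta -> Inf concentrates Hill_i at
  # alpha: the mid-level density at (mu, alpha) must increase along the way
  vals <- vapply(1:6, function(k) {
    s <- 10^(-k)
    beta <- 2^(k + 1)
    logistic_logpdf(6, 6, s) + loglogistic_logpdf(1, 1, beta)
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})
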