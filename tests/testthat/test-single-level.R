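test_that("point likelihood at the curve with unit noise matches the Gaussian peak", {
  # f = 50 sits far from both truncation bounds, so the normalising mass is
  # 1 to machine precision and the log-density is -log(sqrt(2*pi))
  ll <- log_likelihood_point(y = 50, x = 1, pIC50 = 6, Hill = 1, sigma = 1)
  expect_equal(ll, -0.918939, tolerance = 1e-6)
  expect_equal(trunc_mass(50, 1), 1, tolerance = 1e-6)
})

test_that("truncated observation density integrates to one on [0, 100]", {
  for (f in c(0, 5, 50, 95, 100)) {
    for (sigma in c(0.5, 5, 25)) {
      expect_equal(trunc_mass(f, sigma), 1, tolerance = 1e-6)
    }
  }
})

test_that("density decays in the Gaussian tail as sigma shrinks", {
  # |y - f| >> sigma: tightening the noise makes the point far less likely
  ll_wide <- log_likelihood_point(80, 1, 6, 1, sigma = 5)
  ll_tight <- log_likelihood_point(80, 1, 6, 1, sigma = 0.5)
  expect_lt(ll_tight, ll_wide)
})

test_that("point likelihood rejects out-of-range inputs", {
  expect_error(log_likelihood_point(105, 1, 6, 1, 1), "\\[0, 100\\]")
  expect_error(log_likelihood_point(-2, 1, 6, 1, 1), "\\[0, 100\\]")
  expect_error(log_likelihood_point(50, 1, 6, 1, 0), "sigma")
  expect_error(log_likelihood_point(50, 1, 6, 1, -1), "sigma")
})

test_that("uniform prior has the analytic constant inside and -Inf outside", {
  expect_equal(log_prior_single(6, 1, 5),
               -(log(16) + log(10) + log(50)), tolerance = 1e-12)
  expect_equal(log_prior_single(6, 1, 5), -8.9872, tolerance = 1e-4)
  expect_identical(log_prior_single(6, 11, 5), -Inf)   # Hill above (0,10)
  expect_identical(log_prior_single(-2, 1, 5), -Inf)   # pIC50 below -1
  expect_identical(log_prior_single(6, 1, 55), -Inf)
  # configurable support
  wide <- single_prior_config(pIC50 = c(-5, 20), Hill = c(0, 10),
                              sigma = c(0, 50))
  expect_true(is.finite(log_prior_single(-2, 1, 5, config = wide)))
})

test_that("pooled posterior is the sum of point likelihoods and the prior", {
  d1 <- dose_response_data(1, dose = 1, response = 50,
                           compound = "a", channel = "b")
  lp <- log_posterior_single(d1, 6, 1, 1)
  expect_equal(lp, log_likelihood_point(50, 1, 6, 1, 1) +
                 log_prior_single(6, 1, 1), tolerance = 1e-12)

  d <- make_pooled_data(sigma = 0.5, seed = 4)
  base <- log_posterior_single(d, 6.2, 1.3, 0.7)
  brute <- log_prior_single(6.2, 1.3, 0.7) +
    sum(vapply(sample(nrow(d)), function(j) {
      log_likelihood_point(d$response[j], d$dose[j], 6.2, 1.3, 0.7)
    }, numeric(1)))
  expect_equal(base, brute, tolerance = 1e-10)
})

test_that("posterior support coincides with the prior box", {
  d <- make_pooled_data(sigma = 0.5, seed = 5)
  expect_identical(log_posterior_single(d, 6, 11, 1), -Inf)
  expect_identical(log_posterior_single(d, -2, 1, 1), -Inf)
  expect_identical(log_posterior_single(d, 6, 1, 51), -Inf)
  expect_true(is.finite(log_posterior_single(d, 6, 1, 1)))
  expect_error(log_posterior_single(list(), 6, 1, 1), "dose_response_data")
})

test_that("grid argmax of the posterior recovers the generating parameters", {
  d <- make_pooled_data(pIC50 = 6.2, Hill = 1.3, sigma = 0.1, seed = 6)
  target <- hillbayes:::make_single_target(d)
  p_grid <- seq(5.9, 6.5, by = 0.05)
  h_grid <- seq(1.0, 1.6, by = 0.05)
  s_grid <- c(0.05, 0.1, 0.2)
  best <- c(NA, NA, NA); best_lp <- -Inf
  for (p in p_grid) for (h in h_grid) for (s in s_grid) {
    lp <- target(c(p, h, s))
    if (lp > best_lp) { best_lp <- lp; best <- c(p, h, s) }
  }
  expect_lte(abs(best[1] - 6.2), 0.05 + 1e-9)
  expect_lte(abs(best[2] - 1.3), 0.05 + 1e-9)
})

test_that("log-domain evaluation stays finite down to sigma = 1e-3", {
  # worst case: full-range residual with near-zero noise
  ll <- hillbayes:::trunc_norm_loglik(100, 0, 1e-3)
  expect_true(is.finite(ll))
  d <- make_pooled_data(sigma = 0, seed = 7)
  expect_true(is.finite(log_posterior_single(d, 2, 5, 1e-3)))
})
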