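test_that("CMA-ES finds the optimum of a smooth target in a box", {
  centre <- c(2, 5, 7)
  target <- function(th) -sum((th - centre)^2)
  got <- cmaes_start(target, init_guess = c(1, 1, 1),
                     lower = rep(0, 3), upper = rep(10, 3), seed = 1)
  expect_lt(max(abs(got - centre)), 1e-3)
  # never worse than the initial guess
  expect_gte(target(got), target(c(1, 1, 1)))
})

test_that("CMA-ES start recovers curve parameters from noiseless data", {
  d <- make_pooled_data(pIC50 = 6.5, Hill = 1.2, sigma = 0, seed = 3)
  target <- hillbayes:::make_single_target(d)
  st <- cmaes_start(target, c(5, 2, 10),
                    lower = c(-1, 1e-6, 1e-6), upper = c(15, 10, 50),
                    seed = 4)
  expect_lt(abs(st[1] - 6.5), 1e-2)
  expect_lt(abs(st[2] - 1.2), 1e-2)
})

test_that("CMA-ES is deterministic given a seed and errors off-support", {
  target <- function(th) -sum(th^2)
  a <- cmaes_start(target, c(3, 3), c(-5, -5), c(5, 5), seed = 11)
  b <- cmaes_start(target, c(3, 3), c(-5, -5), c(5, 5), seed = 11)
  expect_identical(a, b)
  expect_error(cmaes_start(function(th) -Inf, c(0.5), 0, 1, seed = 1),
               "finite")
  expect_error(cmaes_start(target, c(1, 1), c(0, 0), c(0, 0)), "box")
})

test_that("adaptive MH reproduces a standard normal target", {
  ch <- adaptive_mh(function(th) -th^2 / 2, start = 2, n_iter = 50000,
                    seed = 21)
  ch <- discard_burn_in(ch, 0.25)
  expect_lt(abs(mean(ch$samples)), 0.05)
  expect_lt(abs(sd(ch$samples) - 1), 0.05)
  expect_gt(ch$meta$acceptance_rate, 0.1)
  expect_lt(ch$meta$acceptance_rate, 0.6)
})

test_that("adaptive MH captures correlation of a 2-D Gaussian target", {
  r <- 0.9
  prec <- solve(matrix(c(1, r, r, 1), 2))
  target <- function(th) -0.5 * drop(th %*% prec %*% th)
  ch <- discard_burn_in(adaptive_mh(target, c(1, 1), 60000, seed = 22), 0.25)
  expect_lt(abs(cor(ch$samples[, 1], ch$samples[, 2]) - r), 0.05)
  expect_lt(max(abs(apply(ch$samples, 2, sd) - 1)), 0.05)
})

test_that("chains are bit-reproducible given the seed", {
  t1 <- function(th) -sum(th^2) / 2
  a <- adaptive_mh(t1, c(0.5, -0.5), 4000, seed = 30)
  b <- adaptive_mh(t1, c(0.5, -0.5), 4000, seed = 30)
  expect_identical(a$samples, b$samples)
  expect_identical(a$log_posterior, b$log_posterior)
  expect_error(adaptive_mh(function(th) -Inf, 0, 100), "finite")
})

test_that("burn-in discard retains the ceiling of the kept fraction", {
  ch <- adaptive_mh(function(th) -th^2 / 2, 0, 1000, seed = 31)
  expect_equal(nrow(discard_burn_in(ch, 0.25)$samples), 750)
  expect_equal(nrow(discard_burn_in(ch, 0)$samples), 1000)
  ch10 <- adaptive_mh(function(th) -th^2 / 2, 0, 10, seed = 32)
  expect_equal(nrow(discard_burn_in(ch10, 0.999)$samples), 1)
  expect_error(discard_burn_in(ch, 1), "fraction")
  # the retained tail is the chain's tail
  kept <- discard_burn_in(ch, 0.5)
  expect_identical(kept$samples[, 1], ch$samples[501:1000, 1])
})

test_that("fitting pipelines expose the documented parameter spaces", {
  d <- make_pooled_data(sigma = 0.5, seed = 40)
  ch <- fit_single_level(d, iterations = 3000, seed = 41, cmaes_evals = 600)
  expect_identical(colnames(ch$samples), c("pIC50", "Hill", "sigma"))
  expect_equal(ncol(ch$samples), 3)

  dh <- make_hier_data(ne = 4, seed = 42)
  chh <- fit_hierarchical(dh, iterations = 4000, seed = 43, cmaes_evals = 600)
  expect_equal(ncol(chh$samples), 13)   # 5 + 2 * 4
  expect_identical(colnames(chh$samples)[1:5],
                   c("alpha", "beta", "mu", "s", "sigma"))
  expect_identical(colnames(chh$samples)[6], "pIC50_1")
  expect_identical(colnames(chh$samples)[10], "Hill_1")
  # support constraints hold for every retained sample
  expect_true(all(chh$samples[, "beta"] > 2))
  expect_true(all(chh$samples[, "sigma"] > 1e-3))
  expect_true(all(chh$samples[, "alpha"] > 0))
  expect_true(all(chh$samples[, grep("^Hill_", colnames(chh$samples))] > 0))
  # whole pipeline reproducible from the master seed
  chh2 <- fit_hierarchical(dh, iterations = 4000, seed = 43, cmaes_evals = 600)
  expect_identical(chh$samples, chh2$samples)
})
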