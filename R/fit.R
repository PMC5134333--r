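#' Fit the single-level (pooled) model
#'
#' Composed pipeline: CMA-ES search over the prior box for a starting
#' point, adaptive Metropolis-Hastings on the pooled log-posterior, then
#' burn-in discard (default: first quarter). The chain explores exactly the
#' three parameters `(pIC50, Hill, sigma)`.
#'
#' @param data A [dose_response_data()] object.
#' @param iterations MCMC iterations (default 500000; shorter chains are
#'   adequate for exploratory fits).
#' @param burn_fraction Fraction of the chain discarded as burn-in
#'   (default 0.25).
#' @param seed Integer seed; CMA-ES and MCMC consume sub-seeds derived from
#'   it, so the whole fit is reproducible.
#' @param prior A [single_prior_config()].
#' @param cmaes_evals Optional cap on CMA-ES target evaluations.
#' @return A `posterior_chain` with columns `pIC50`, `Hill`, `sigma`
#'   (burn-in already discarded).
#' @export
fit_single_level <- function(data, iterations = 500000, burn_fraction = 0.25,
                             seed = NULL, prior = single_prior_config(),
                             cmaes_evals = NULL) {
  target <- make_single_target(data, prior)
  seeds <- derive_seeds(seed, 2)
  start0 <- single_start_guess(data, prior)
  lo <- attr(target, "lower")
  hi <- attr(target, "upper")
  eps <- 1e-6 * (hi - lo)
  start <- cmaes_start(target, start0, lo + eps, hi - eps,
                       seed = seeds[[1]], max_evals = cmaes_evals)
  chain <- adaptive_mh(target, start, n_iter = iterations, seed = seeds[[2]])
  chain$meta$model <- "single-level"
  chain$meta$compound <- attr(data, "compound")
  chain$meta$channel <- attr(data, "channel")
  chain$meta$master_seed <- seed
  discard_burn_in(chain, burn_fraction)
}

#' Fit the hierarchical model
#'
#' Each experiment receives its own `(pIC50_i, Hill_i)` pair drawn from
#' logistic / log-logistic population distributions whose parameters
#' `(mu, s)` and `(alpha, beta)`, together with the shared noise `sigma`,
#' carry gamma hyperpriors: `5 + 2 * Ne` free parameters in total.
#'
#' Initialisation runs a short CMA-ES on each experiment's own pooled
#' posterior to estimate `(pIC50_i, Hill_i, sigma_i)`; the top level starts
#' from moment matching — medians give `mu` and `alpha`, spreads give `s`
#' and `beta` (via the logistic-scale relation `scale = sd * sqrt(3)/pi`),
#' and `sigma` starts at the mean of the per-experiment noise estimates.
#' Adaptive Metropolis-Hastings then samples the joint posterior and the
#' first `burn_fraction` of the chain is discarded.
#'
#' @param data A [dose_response_data()] with experiment labels.
#' @param iterations MCMC iterations (default 500000).
#' @param burn_fraction Burn-in fraction (default 0.25).
#' @param seed Integer seed for the whole pipeline.
#' @param config A [hier_prior_config()].
#' @param cmaes_evals Optional cap on CMA-ES evaluations per experiment.
#' @return A `posterior_chain` with columns `alpha`, `beta`, `mu`, `s`,
#'   `sigma`, `pIC50_1..Ne`, `Hill_1..Ne` (burn-in already discarded).
#' @export
fit_hierarchical <- function(data, iterations = 500000, burn_fraction = 0.25,
                             seed = NULL, config = hier_prior_config(),
                             cmaes_evals = NULL) {
  stopifnot(inherits(data, "dose_response_data"))
  ne <- n_experiments(data)
  target <- make_hier_target(data, config)
  seeds <- derive_seeds(seed, ne + 1)

  prior1 <- single_prior_config()
  est <- matrix(NA_real_, ne, 3)
  for (i in seq_len(ne)) {
    sub <- data[data$exp_index == i, , drop = FALSE]
    di <- dose_response_data(sub$experiment, sub$dose, sub$response,
                             attr(data, "compound"), attr(data, "channel"))
    ti <- make_single_target(di, prior1)
    lo <- attr(ti, "lower"); hi <- attr(ti, "upper")
    eps <- 1e-6 * (hi - lo)
    est[i, ] <- cmaes_start(ti, single_start_guess(di, prior1),
                            lo + eps, hi - eps, seed = seeds[[i]],
                            max_evals = if (is.null(cmaes_evals)) 1500 else cmaes_evals)
  }
  mu0 <- median(est[, 1])
  alpha0 <- max(0.05, median(est[, 2]))
  s0 <- max(0.02, sd_or_zero(est[, 1]) * sqrt(3) / pi)
  spread_h <- sd_or_zero(log(pmax(est[, 2], 1e-6))) * sqrt(3) / pi
  beta0 <- if (spread_h > 1e-8) min(max(1 / spread_h, 2.2), 25) else 10
  sigma0 <- max(0.05, mean(est[, 3]))
  start <- c(alpha0, beta0, mu0, s0, sigma0, est[, 1], est[, 2])
  if (!is.finite(target(start))) {
    stop("hierarchical starting point has non-finite posterior; ",
         "check the data and prior configuration")
  }
  init_step <- c(0.05, 0.25, 0.05, 0.02, 0.05,
                 rep(0.05, ne), rep(0.05, ne))
  chain <- adaptive_mh(target, start, n_iter = iterations,
                       seed = seeds[[ne + 1]],
                       adapt_config = list(init_step = init_step))
  chain$meta$model <- "hierarchical"
  chain$meta$n_experiments <- ne
  chain$meta$compound <- attr(data, "compound")
  chain$meta$channel <- attr(data, "channel")
  chain$meta$master_seed <- seed
  discard_burn_in(chain, burn_fraction)
}

# One master seed -> disjoint sub-seeds for CMA-ES and MCMC stages.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

sd_or_zero <- function(x) if (length(x) > 1) sd(x) else 0

# Crude data-driven first guess inside the prior box: potency from the dose
# whose response is nearest half-block, unit slope, moderate noise.
single_start_guess <- function(data, prior) {
  pos <- data$dose > 0
  if (any(pos)) {
    j <- which(pos)[which.min(abs(data$response[pos] - 50))]
    p0 <- 6 - log10(data$dose[j])
  } else p0 <- 6
  clamp <- function(v, b) min(max(v, b[1] + 0.05 * diff(b)), b[2] - 0.05 * diff(b))
  c(clamp(p0, prior$pIC50), clamp(1, prior$Hill), clamp(5, prior$sigma))
}
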