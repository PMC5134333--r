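#' Logistic log-density (population distribution of pIC50)
#'
#' In the hierarchical model each experiment's pIC50 is drawn from a
#' logistic distribution with location `mu` and scale `s`:
#' \deqn{p(p) = \frac{e^{-(p-\mu)/s}}{s\,(1 + e^{-(p-\mu)/s})^2}.}
#' The logistic is symmetric about `mu` with heavier tails than a Normal of
#' comparable width, matching the empirical spread of potency estimates over
#' large numbers of screening repeats.
#'
#' @param p pIC50 value(s), log-molar.
#' @param mu Location (log-molar).
#' @param s Scale, strictly positive (log-molar).
#' @return Log-density, vectorised over `p`.
#' @export
logistic_logpdf <- function(p, mu, s) {
  if (!is.finite(s) || s <= 0) stop("'s' must be positive")
  z <- -(p - mu) / s
  # log[ e^z / (s (1+e^z)^2) ] with a stable log1p(exp(z))
  z - log(s) - 2 * log1pexp(z)
}

#' Log-logistic log-density and distribution function (population of Hill)
#'
#' Each experiment's Hill coefficient is drawn from a log-logistic
#' distribution with scale `alpha` (the median) and shape `beta`:
#' \deqn{p(h) = \frac{(\beta/\alpha)\,(h/\alpha)^{\beta-1}}
#'                  {(1 + (h/\alpha)^{\beta})^2}, \qquad h > 0,}
#' \deqn{F(h) = \frac{1}{1 + (h/\alpha)^{-\beta}}.}
#' Equivalently, `log(h)` follows a logistic distribution with location
#' `log(alpha)` and scale `1/beta`. `alpha` is the typical Hill value of the
#' population; for `beta > 2` the density vanishes at 0 with zero slope, so
#' degenerate zero-steepness curves carry no mass.
#'
#' @param h Hill value(s); non-positive values have density zero
#'   (`-Inf` log-density).
#' @param alpha Scale (= median), strictly positive.
#' @param beta Shape, strictly positive.
#' @return `loglogistic_logpdf()`: log-density; `loglogistic_cdf()`:
#'   distribution function; `loglogistic_quantile()`: quantile function.
#' @export
loglogistic_logpdf <- function(h, alpha, beta) {
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (!is.finite(beta) || beta <= 0) stop("'beta' must be positive")
  out <- rep(-Inf, length(h))
  ok <- is.finite(h) & h > 0
  u <- beta * (log(h[ok]) - log(alpha))
  out[ok] <- log(beta) - log(h[ok]) + u - 2 * log1pexp(u)
  out
}

#' @rdname loglogistic_logpdf
#' @export
loglogistic_cdf <- function(h, alpha, beta) {
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (!is.finite(beta) || beta <= 0) stop("'beta' must be positive")
  out <- numeric(length(h))
  ok <- is.finite(h) & h > 0
  out[ok] <- plogis(beta * (log(h[ok]) - log(alpha)))
  out[!is.finite(h) & h > 0] <- 1
  out
}

#' @rdname loglogistic_logpdf
#' @param prob Probabilities in (0, 1).
#' @export
loglogistic_quantile <- function(prob, alpha, beta) {
  if (!is.finite(alpha) || alpha <= 0) stop("'alpha' must be positive")
  if (!is.finite(beta) || beta <= 0) stop("'beta' must be positive")
  alpha * (prob / (1 - prob))^(1 / beta)
}

# log(1 + exp(x)) without overflow
log1pexp <- function(x) {
  out <- x
  small <- x < 33
  out[small] <- log1p(exp(x[small]))
  out
}

#' Gamma hyperprior configuration for the hierarchical model
#'
#' Priors for the five top-level parameters are gamma distributions: all of
#' them are positive quantities except the logistic location `mu`, whose
#' gamma prior is shifted along the axis down to `mu_shift` (default -4) so
#' that potencies corresponding to ineffective compounds remain reachable
#' while little mass lies below pIC50 = -2. Two hard support bounds are
#' enforced on top of the gamma densities: the log-logistic shape must
#' satisfy `beta > beta_min` (default 2), which removes all mass and slope
#' of the Hill population density at 0, and the observation noise must
#' satisfy `sigma > sigma_min` (default 1e-3), since a strictly positive
#' noise level always exists and `sigma = 0` is numerically singular.
#'
#' Shapes and scales are deliberately wide relative to posteriors from
#' typical screens; every value is configurable.
#'
#' @param alpha_shape,alpha_scale Gamma parameters for `alpha`.
#' @param beta_shape,beta_scale Gamma parameters for `beta`.
#' @param mu_shape,mu_scale,mu_shift Gamma parameters and location shift for
#'   `mu` (the density is evaluated at `mu - mu_shift`).
#' @param s_shape,s_scale Gamma parameters for `s`.
#' @param sigma_shape,sigma_scale Gamma parameters for `sigma`.
#' @param beta_min,sigma_min Hard lower support bounds.
#' @return A list of class `hier_prior_config`.
#' @export
hier_prior_config <- function(alpha_shape = 2.5, alpha_scale = 0.5,
                              beta_shape = 4, beta_scale = 1.5,
                              mu_shape = 6, mu_scale = 1.75, mu_shift = -4,
                              s_shape = 2, s_scale = 0.5,
                              sigma_shape = 2, sigma_scale = 3.5,
                              beta_min = 2, sigma_min = 1e-3) {
  vals <- c(alpha_shape, alpha_scale, beta_shape, beta_scale,
            mu_shape, mu_scale, s_shape, s_scale, sigma_shape, sigma_scale)
  if (any(!is.finite(vals)) || any(vals <= 0)) {
    stop("all gamma shapes and scales must be positive")
  }
  structure(list(alpha = c(shape = alpha_shape, scale = alpha_scale),
                 beta = c(shape = beta_shape, scale = beta_scale),
                 mu = c(shape = mu_shape, scale = mu_scale, shift = mu_shift),
                 s = c(shape = s_shape, scale = s_scale),
                 sigma = c(shape = sigma_shape, scale = sigma_scale),
                 beta_min = beta_min, sigma_min = sigma_min),
            class = "hier_prior_config")
}

#' Log-density of the top-level (hyper)prior
#'
#' Sum of the gamma log-densities of `alpha`, `beta`, `mu` (shifted), `s`
#' and `sigma` under `config`, with `-Inf` returned whenever a component
#' leaves its support, `beta <= beta_min`, or `sigma <= sigma_min`.
#'
#' @param alpha,beta,mu,s,sigma Top-level parameter values.
#' @param config A [hier_prior_config()].
#' @return Log-density or `-Inf`.
#' @export
log_hyperprior <- function(alpha, beta, mu, s, sigma,
                           config = hier_prior_config()) {
  cf <- config
  if (!all(is.finite(c(alpha, beta, mu, s, sigma)))) return(-Inf)
  if (alpha <= 0 || s <= 0) return(-Inf)
  if (beta <= cf$beta_min) return(-Inf)
  if (sigma <= cf$sigma_min) return(-Inf)
  mu_arg <- mu - cf$mu[["shift"]]
  if (mu_arg <= 0) return(-Inf)
  dgamma(alpha, shape = cf$alpha[["shape"]], scale = cf$alpha[["scale"]], log = TRUE) +
    dgamma(beta, shape = cf$beta[["shape"]], scale = cf$beta[["scale"]], log = TRUE) +
    dgamma(mu_arg, shape = cf$mu[["shape"]], scale = cf$mu[["scale"]], log = TRUE) +
    dgamma(s, shape = cf$s[["shape"]], scale = cf$s[["scale"]], log = TRUE) +
    dgamma(sigma, shape = cf$sigma[["shape"]], scale = cf$sigma[["scale"]], log = TRUE)
}

#' Unnormalised log-posterior of the hierarchical model
#'
#' Joint density over the top-level parameters (`alpha`, `beta`, `mu`, `s`,
#' `sigma`) and one `(pIC50_i, Hill_i)` pair per experiment: per-record
#' truncated-normal likelihood around each experiment's own Hill curve, the
#' log-logistic population density of the `Hill_i`, the logistic population
#' density of the `pIC50_i`, and the gamma hyperprior. The free parameter
#' vector has dimension `5 + 2 * Ne`.
#'
#' @param data A [dose_response_data()] with `Ne >= 1` experiments.
#' @param alpha,beta,mu,s,sigma Top-level parameters.
#' @param pIC50_i,Hill_i Numeric vectors of length `Ne` (per-experiment
#'   parameters, in `exp_index` order).
#' @param config A [hier_prior_config()].
#' @return Unnormalised log-posterior density.
#' @export
log_posterior_hier <- function(data, alpha, beta, mu, s, sigma,
                               pIC50_i, Hill_i,
                               config = hier_prior_config()) {
  if (!inherits(data, "dose_response_data") || nrow(data) == 0) {
    stop("'data' must be a non-empty dose_response_data object")
  }
  ne <- n_experiments(data)
  if (length(pIC50_i) != ne || length(Hill_i) != ne) {
    stop(sprintf("expected %d per-experiment parameter pairs, got %d/%d",
                 ne, length(pIC50_i), length(Hill_i)))
  }
  target <- make_hier_target(data, config)
  target(c(alpha, beta, mu, s, sigma, pIC50_i, Hill_i))
}

# Closure for the samplers.
# theta layout: (alpha, beta, mu, s, sigma, pIC50_1..Ne, Hill_1..Ne)
make_hier_target <- function(data, config = hier_prior_config()) {
  stopifnot(inherits(data, "dose_response_data"), nrow(data) > 0)
  ne <- n_experiments(data)
  idx <- data$exp_index
  ldose <- log10(data$dose)   # -Inf for zero doses handled below
  y <- data$response
  cf <- config
  a_sh <- cf$alpha[["shape"]]; a_sc <- cf$alpha[["scale"]]
  b_sh <- cf$beta[["shape"]];  b_sc <- cf$beta[["scale"]]
  m_sh <- cf$mu[["shape"]];    m_sc <- cf$mu[["scale"]]; m_shift <- cf$mu[["shift"]]
  s_sh <- cf$s[["shape"]];     s_sc <- cf$s[["scale"]]
  g_sh <- cf$sigma[["shape"]]; g_sc <- cf$sigma[["scale"]]
  beta_min <- cf$beta_min; sigma_min <- cf$sigma_min
  i_p <- 5 + seq_len(ne)
  i_h <- 5 + ne + seq_len(ne)

  f_target <- function(theta) {
    alpha <- theta[1]; beta <- theta[2]; mu <- theta[3]
    s <- theta[4]; sigma <- theta[5]
    if (alpha <= 0 || beta <= beta_min || s <= 0 || sigma <= sigma_min ||
        mu <= m_shift) return(-Inf)
    hh <- theta[i_h]
    if (any(hh <= 0)) return(-Inf)
    pp <- theta[i_p]
    # hyperprior
    lp <- dgamma(alpha, a_sh, scale = a_sc, log = TRUE) +
      dgamma(beta, b_sh, scale = b_sc, log = TRUE) +
      dgamma(mu - m_shift, m_sh, scale = m_sc, log = TRUE) +
      dgamma(s, s_sh, scale = s_sc, log = TRUE) +
      dgamma(sigma, g_sh, scale = g_sc, log = TRUE)
    # population densities of the mid-level parameters
    zl <- -(pp - mu) / s
    lp <- lp + sum(zl - log(s) - 2 * log1pexp(zl))
    u <- beta * (log(hh) - log(alpha))
    lp <- lp + sum(log(beta) - log(hh) + u - 2 * log1pexp(u))
    # truncated-normal likelihood around each experiment's own curve
    e <- hh[idx] * (6 - pp[idx] - ldose)
    f <- 100 / (1 + 10^e)
    z <- pnorm(100, f, sigma) - pnorm(0, f, sigma)
    lp + sum(dnorm(y, f, sigma, log = TRUE) - log(z))
  }
  attr(f_target, "par_names") <- c("alpha", "beta", "mu", "s", "sigma",
                                   paste0("pIC50_", seq_len(ne)),
                                   paste0("Hill_", seq_len(ne)))
  attr(f_target, "n_experiments") <- ne
  f_target
}
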