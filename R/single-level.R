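#' Uniform prior configuration for the single-level model
#'
#' The pooled model treats every record as a draw from one Hill curve with
#' shared observation noise, and places independent uniform priors on its
#' three parameters. The default support is pIC50 in (-1, 15) — values below
#' -1 correspond to compounds whose IC50 is so far above any screening
#' concentration that curves become indistinguishable; Hill in (0, 10), a
#' generous bound above any plausible drug binding steepness; and sigma in
#' (0, 50) percent block, far above the 5-10% noise seen in practice. Other
#' screens can widen or narrow these.
#'
#' @param pIC50 Length-2 numeric, support of the pIC50 prior.
#' @param Hill Length-2 numeric, support of the Hill prior (must stay positive).
#' @param sigma Length-2 numeric, support of the noise-SD prior.
#' @return A list of class `single_prior_config`.
#' @export
single_prior_config <- function(pIC50 = c(-1, 15),
                                Hill = c(0, 10),
                                sigma = c(0, 50)) {
  chk <- function(b, nm, lo_min = -Inf) {
    if (length(b) != 2 || any(!is.finite(b)) || b[1] >= b[2] || b[1] < lo_min) {
      stop(sprintf("invalid prior bounds for '%s'", nm))
    }
  }
  chk(pIC50, "pIC50")
  chk(Hill, "Hill", lo_min = 0)
  chk(sigma, "sigma", lo_min = 0)
  structure(list(pIC50 = pIC50, Hill = Hill, sigma = sigma),
            class = "single_prior_config")
}

# Truncated-normal log-density of observations on [0, 100].
# Gaussian log-density minus the log normalising mass on the interval; the
# mass depends on (f, sigma) and is recomputed for every point and proposal.
trunc_norm_loglik <- function(y, f, sigma) {
  z <- pnorm(100, mean = f, sd = sigma) - pnorm(0, mean = f, sd = sigma)
  dnorm(y, mean = f, sd = sigma, log = TRUE) - log(z)
}

#' Truncated-normal log-likelihood of a single observation
#'
#' The observation model is Normal around the Hill-curve value
#' `f(x; pIC50, Hill)` with standard deviation `sigma`, truncated to the
#' interval \[0, 100\] because percent-block data are capped at those bounds
#' before analysis. The returned value is the Gaussian log-density minus
#' `log(Phi((100 - f)/sigma) - Phi((0 - f)/sigma))`, the mass the untruncated
#' Normal places on \[0, 100\]; this normalising factor depends on both the
#' local curve value and `sigma`, so it differs between points.
#'
#' @param y Observed response, percent block in `[0, 100]`.
#' @param x Dose in micromolar.
#' @param pIC50,Hill,sigma Model parameters; `sigma > 0`.
#' @return Log-density of `y` (vectorised over `y`/`x`).
#' @export
log_likelihood_point <- function(y, x, pIC50, Hill, sigma) {
  if (any(!is.finite(y)) || any(y < 0) || any(y > 100)) {
    stop("'y' must lie in [0, 100]; responses are capped on ingest")
  }
  if (!is.finite(sigma) || sigma <= 0) stop("'sigma' must be positive")
  f <- hill_response(x, pIC50, Hill)
  trunc_norm_loglik(y, f, sigma)
}

#' Log-prior density for the single-level model
#'
#' Sum of independent uniform log-densities over the configured support box;
#' `-Inf` outside it.
#'
#' @param pIC50,Hill,sigma Parameter values.
#' @param config A [single_prior_config()].
#' @return Log-density (a constant inside the box), or `-Inf`.
#' @export
log_prior_single <- function(pIC50, Hill, sigma,
                             config = single_prior_config()) {
  b <- config
  inside <- is.finite(pIC50) && is.finite(Hill) && is.finite(sigma) &&
    pIC50 > b$pIC50[1] && pIC50 < b$pIC50[2] &&
    Hill > b$Hill[1] && Hill < b$Hill[2] &&
    sigma > b$sigma[1] && sigma < b$sigma[2]
  if (!inside) return(-Inf)
  -log(diff(b$pIC50)) - log(diff(b$Hill)) - log(diff(b$sigma))
}

#' Unnormalised log-posterior for the single-level model
#'
#' Pools all records of the dataset: the sum over points of the
#' truncated-normal log-likelihood plus the uniform log-prior. Returns
#' `-Inf` whenever the parameters fall outside the prior support.
#'
#' @param data A [dose_response_data()] object.
#' @param pIC50,Hill,sigma Parameter values.
#' @param config A [single_prior_config()].
#' @return Unnormalised log-posterior density.
#' @export
log_posterior_single <- function(data, pIC50, Hill, sigma,
                                 config = single_prior_config()) {
  if (!inherits(data, "dose_response_data") || nrow(data) == 0) {
    stop("'data' must be a non-empty dose_response_data object")
  }
  lp <- log_prior_single(pIC50, Hill, sigma, config)
  if (!is.finite(lp)) return(-Inf)
  f <- hill_response(data$dose, pIC50, Hill)
  lp + sum(trunc_norm_loglik(data$response, f, sigma))
}

# Closure over the data for the samplers: theta = (pIC50, Hill, sigma).
# Avoids S3 dispatch and re-validation in the MCMC hot loop.
make_single_target <- function(data, config = single_prior_config()) {
  stopifnot(inherits(data, "dose_response_data"), nrow(data) > 0)
  dose <- data$dose
  y <- data$response
  lo <- c(config$pIC50[1], config$Hill[1], config$sigma[1])
  hi <- c(config$pIC50[2], config$Hill[2], config$sigma[2])
  prior_const <- -sum(log(hi - lo))
  f_target <- function(theta) {
    if (any(theta <= lo) || any(theta >= hi)) return(-Inf)
    e <- theta[2] * (6 - theta[1] - log10(dose))
    f <- 100 / (1 + 10^e)
    z <- pnorm(100, f, theta[3]) - pnorm(0, f, theta[3])
    sum(dnorm(y, f, theta[3], log = TRUE) - log(z)) + prior_const
  }
  attr(f_target, "par_names") <- c("pIC50", "Hill", "sigma")
  attr(f_target, "lower") <- lo
  attr(f_target, "upper") <- hi
  f_target
}
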