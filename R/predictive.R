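#' Posterior-predictive distribution for a future experiment's parameters
#'
#' After hierarchical MCMC, the distribution of the Hill coefficient (or
#' pIC50) that a further, as-yet-unperformed experiment would draw is
#' approximated by the equal-weight average over retained chain iterations
#' of the population density implied by that iteration's top-level
#' parameters: a mixture of `T` log-logistic components `(alpha_t, beta_t)`
#' for Hill, or of `T` logistic components `(mu_t, s_t)` for pIC50. The
#' mixture CDF is the matching average of component CDFs.
#'
#' @param chain A `posterior_chain` from [fit_hierarchical()] (burn-in
#'   already discarded), or any chain whose columns include
#'   `alpha`/`beta`/`mu`/`s`.
#' @param which `"Hill"` (log-logistic mixture) or `"pIC50"` (logistic
#'   mixture).
#' @param thin Keep every `thin`-th iteration when forming the mixture
#'   (default 1 = all retained iterations).
#' @return An object of class `predictive_dist` with elements `family`
#'   (`"log-logistic"` or `"logistic"`) and `params` (a `T x 2` matrix of
#'   component parameters).
#' @seealso [predictive_density()], [predictive_cdf()],
#'   [sample_predictive()]
#' @export
posterior_predictive <- function(chain, which = c("Hill", "pIC50"), thin = 1L) {
  which <- match.arg(which)
  sm <- if (inherits(chain, "posterior_chain")) chain$samples else as.matrix(chain)
  if (is.null(dim(sm)) || nrow(sm) < 1) stop("chain contains no retained samples")
  cols <- if (which == "Hill") c("alpha", "beta") else c("mu", "s")
  if (!all(cols %in% colnames(sm))) {
    stop(sprintf("chain must contain columns %s (hierarchical fit)",
                 paste(cols, collapse = ", ")))
  }
  keep <- seq(1, nrow(sm), by = max(1L, as.integer(thin)))
  structure(list(family = if (which == "Hill") "log-logistic" else "logistic",
                 params = sm[keep, cols, drop = FALSE]),
            class = "predictive_dist")
}

#' Evaluate or sample a posterior-predictive mixture
#'
#' `predictive_density()` and `predictive_cdf()` evaluate the equal-weight
#' mixture pointwise. `predictive_quantile()` inverts the averaged CDF on a
#' deterministic grid of 4096 points spanning the 1e-6 to (1 - 1e-6)
#' component quantile range, with monotone interpolation; `sample_predictive()`
#' draws by pushing uniforms through that inverse (inverse-CDF method), so
#' draws are reproducible given a seed.
#'
#' @param dist A `predictive_dist` from [posterior_predictive()].
#' @param x Evaluation points.
#' @param prob Probabilities in (0, 1).
#' @param n Number of draws.
#' @param seed Optional integer seed for reproducible draws.
#' @param grid_size Number of CDF grid points used for inversion.
#' @return Densities, CDF values, quantiles, or a vector of `n` draws.
#' @export
predictive_density <- function(dist, x) {
  stopifnot(inherits(dist, "predictive_dist"))
  pr <- dist$params
  if (dist$family == "log-logistic") {
    vapply(x, function(xi) {
      if (!is.finite(xi) || xi <= 0) return(0)
      mean(exp(loglogistic_logpdf_vec(xi, pr[, 1], pr[, 2])))
    }, numeric(1))
  } else {
    vapply(x, function(xi) mean(dlogis(xi, pr[, 1], pr[, 2])), numeric(1))
  }
}

# component-vectorised log-logistic log-pdf (no arg checks; internal)
loglogistic_logpdf_vec <- function(h, alpha, beta) {
  u <- beta * (log(h) - log(alpha))
  log(beta) - log(h) + u - 2 * log1pexp(u)
}

#' @rdname predictive_density
#' @export
predictive_cdf <- function(dist, x) {
  stopifnot(inherits(dist, "predictive_dist"))
  pr <- dist$params
  if (dist$family == "log-logistic") {
    vapply(x, function(xi) {
      if (!is.finite(xi)) return(if (xi > 0) 1 else 0)
      if (xi <= 0) return(0)
      mean(plogis(pr[, 2] * (log(xi) - log(pr[, 1]))))
    }, numeric(1))
  } else {
    vapply(x, function(xi) mean(plogis(xi, pr[, 1], pr[, 2])), numeric(1))
  }
}

# Deterministic inversion grid: x locations covering the extreme component
# quantiles, mixture CDF evaluated there, made strictly monotone.
predictive_inverse_grid <- function(dist, grid_size = 4096L) {
  pr <- dist$params
  p_lo <- 1e-6
  p_hi <- 1 - 1e-6
  if (dist$family == "log-logistic") {
    lo <- min(pr[, 1] * (p_lo / (1 - p_lo))^(1 / pr[, 2]))
    hi <- max(pr[, 1] * (p_hi / (1 - p_hi))^(1 / pr[, 2]))
    xg <- exp(seq(log(lo), log(hi), length.out = grid_size))
  } else {
    lo <- min(qlogis(p_lo, pr[, 1], pr[, 2]))
    hi <- max(qlogis(p_hi, pr[, 1], pr[, 2]))
    xg <- seq(lo, hi, length.out = grid_size)
  }
  ug <- predictive_cdf(dist, xg)
  ug <- cummax(ug)
  keep <- c(TRUE, diff(ug) > 0)
  list(x = xg[keep], u = ug[keep])
}

#' @rdname predictive_density
#' @export
predictive_quantile <- function(dist, prob, grid_size = 4096L) {
  stopifnot(inherits(dist, "predictive_dist"))
  if (any(prob <= 0) || any(prob >= 1)) stop("'prob' must lie in (0, 1)")
  g <- predictive_inverse_grid(dist, grid_size)
  stats::approx(g$u, g$x, xout = prob, rule = 2)$y
}

#' @rdname predictive_density
#' @export
sample_predictive <- function(dist, n, seed = NULL, grid_size = 4096L) {
  stopifnot(inherits(dist, "predictive_dist"))
  if (!is.numeric(n) || n < 1) stop("'n' must be a positive count")
  if (!is.null(seed)) set.seed(seed)
  g <- predictive_inverse_grid(dist, grid_size)
  stats::approx(g$u, g$x, xout = runif(n), rule = 2)$y
}

#' @export
print.predictive_dist <- function(x, ...) {
  cat(sprintf("Posterior-predictive %s mixture with %d equal-weight components\n",
              x$family, nrow(x$params)))
  invisible(x)
}
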