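# Compact (mu/mu_w, lambda)-CMA-ES minimiser, standard Hansen formulation.
# Operates in a normalised coordinate system supplied by the caller; used
# only to locate a good MCMC starting point, not as a general optimiser.
cma_es_min <- function(fn, x0, sigma0 = 0.25, max_evals = NULL,
                       tol_fun = 1e-12, tol_sigma = 1e-12) {
  n <- length(x0)
  if (is.null(max_evals)) max_evals <- 600 * n + 1200
  lambda <- 4L + floor(3 * log(n))
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chi_n <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- sigma0
  pc <- ps <- numeric(n)
  C <- diag(n)
  B <- diag(n)
  D <- rep(1, n)
  inv_sqrt_C <- diag(n)
  eigen_evals <- 0
  evals <- 0
  best_x <- x0
  best_f <- fn(x0)
  evals <- evals + 1
  prev_best <- Inf
  stall <- 0

  while (evals < max_evals) {
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                       # N(0, C) steps
    X <- xmean + sigma * Y
    fvals <- apply(X, 2, fn)
    evals <- evals + lambda
    ord <- order(fvals)
    if (fvals[ord[1]] < best_f) {
      best_f <- fvals[ord[1]]
      best_x <- X[, ord[1]]
    }
    xold <- xmean
    sel <- ord[seq_len(mu)]
    xmean <- drop(X[, sel, drop = FALSE] %*% w)
    y_w <- (xmean - xold) / sigma

    ps <- (1 - cs) * ps +
      sqrt(cs * (2 - cs) * mueff) * drop(inv_sqrt_C %*% y_w)
    hsig <- sum(ps^2) / (1 - (1 - cs)^(2 * evals / lambda)) / n <
      2 + 4 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * y_w

    arty <- (X[, sel, drop = FALSE] - xold) / sigma
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * arty %*% (w * t(arty))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chi_n - 1))

    if (evals - eigen_evals > lambda / (c1 + cmu) / n / 10) {
      eigen_evals <- evals
      C <- (C + t(C)) / 2
      eg <- eigen(C, symmetric = TRUE)
      D <- sqrt(pmax(eg$values, 1e-20))
      B <- eg$vectors
      inv_sqrt_C <- B %*% ((1 / D) * t(B))
    }
    if (sigma * max(D) < tol_sigma) break
    if (abs(prev_best - best_f) < tol_fun) {
      stall <- stall + 1
      if (stall > 40 + ceiling(60 * n / lambda)) break
    } else stall <- 0
    prev_best <- best_f
  }
  list(par = best_x, value = best_f, evals = evals)
}

#' Locate an MCMC starting point with CMA-ES
#'
#' Runs a covariance matrix adaptation evolution strategy (CMA-ES) search
#' over a bounding box to find a high-density point of a log-target, used
#' as the starting state for [adaptive_mh()]. Coordinates are normalised to
#' the unit box internally; points proposed outside the box are evaluated
#' at their clamped position with a quadratic penalty. The returned point
#' is never worse than `init_guess` under the target.
#'
#' @param target Function mapping a parameter vector to a log-density
#'   (`-Inf` outside its support).
#' @param init_guess Numeric starting vector inside the box.
#' @param lower,upper Numeric vectors defining the search box; must
#'   intersect the support of `target`.
#' @param seed Optional integer seed; the search is deterministic given it.
#' @param max_evals Optional cap on target evaluations per restart.
#' @param restarts Number of additional searches launched from random
#'   points of the box (default 3). Multimodal or ridge-shaped posteriors
#'   — e.g. few-point datasets where a flat high-noise plateau competes
#'   with the sharp curve-fit optimum — are escaped by keeping the best
#'   point over all restarts.
#' @return Numeric vector: the best point found.
#' @export
cmaes_start <- function(target, init_guess, lower, upper, seed = NULL,
                        max_evals = NULL, restarts = 3L) {
  d <- length(init_guess)
  if (length(lower) != d || length(upper) != d || any(lower >= upper)) {
    stop("'lower' and 'upper' must define a non-empty box of dimension d")
  }
  if (!is.null(seed)) set.seed(seed)
  width <- upper - lower
  to_z <- function(x) (x - lower) / width
  to_x <- function(z) lower + z * width
  neg <- function(z) {
    zc <- pmin(pmax(z, 0), 1)
    pen <- sum((z - zc)^2)
    v <- target(to_x(zc))
    if (!is.finite(v)) return(1e10 + 1e6 * pen)
    -v + 1e6 * pen
  }
  starts <- c(list(to_z(init_guess)),
              replicate(max(0L, restarts), runif(d), simplify = FALSE))
  best <- NULL
  for (z0 in starts) {
    res <- cma_es_min(neg, z0, sigma0 = 0.25, max_evals = max_evals)
    if (is.null(best) || res$value < best$value) best <- res
  }
  cand <- to_x(pmin(pmax(best$par, 0), 1))
  v_cand <- target(cand)
  v_init <- target(init_guess)
  if (!is.finite(v_cand) && !is.finite(v_init)) {
    stop("CMA-ES found no point with finite target value; ",
         "check that the box intersects the support")
  }
  if (is.finite(v_cand) && (!is.finite(v_init) || v_cand >= v_init)) cand
  else init_guess
}
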