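#' Adaptive Metropolis-Hastings sampler
#'
#' Random-walk Metropolis with a multivariate Gaussian proposal centred on
#' the current state, whose covariance adapts to the chain's own history
#' (Haario-style adaptive Metropolis). Two mechanisms operate: a global
#' step-size scalar is tuned continuously by Robbins-Monro updates towards
#' a target acceptance rate (default 0.25), and after `adapt_start`
#' iterations (default `100 * d`) the proposal covariance switches from the
#' initial diagonal to `2.38^2/d` times the running empirical covariance of
#' the chain (plus a small diagonal ridge). Proposals falling outside the
#' target's support receive log-density `-Inf` and are rejected, which
#' preserves detailed balance without reflecting moves.
#'
#' @param target Function: parameter vector -> log-density (`-Inf` outside
#'   support). Must be finite at `start`.
#' @param start Numeric starting vector (e.g. from [cmaes_start()]).
#' @param n_iter Number of iterations (states stored, including rejections).
#' @param seed Optional integer seed; the chain is fully reproducible
#'   given it.
#' @param adapt_config Optional list overriding adaptation settings:
#'   `target_rate` (0.25), `adapt_start` (`100 * d`), `init_step`
#'   (per-parameter initial proposal SDs), `ridge` (covariance ridge,
#'   1e-10), `gamma_exponent` (Robbins-Monro decay, 0.6).
#' @return An object of class `posterior_chain`: a list with `samples`
#'   (`n_iter x d` matrix), `log_posterior` (length `n_iter`), `accepted`
#'   (logical), and `meta` (seed, settings, acceptance rate, parameter
#'   names).
#' @export
adaptive_mh <- function(target, start, n_iter, seed = NULL,
                        adapt_config = list()) {
  d <- length(start)
  if (!is.numeric(n_iter) || n_iter < 1) stop("'n_iter' must be >= 1")
  n_iter <- as.integer(n_iter)
  lp_cur <- target(start)
  if (!is.finite(lp_cur)) {
    stop("'target' must be finite at 'start' (got ", lp_cur, ")")
  }
  cfg <- list(target_rate = 0.25, adapt_start = 100L * d,
              init_step = NULL, ridge = 1e-10, gamma_exponent = 0.6)
  cfg[names(adapt_config)] <- adapt_config
  init_step <- cfg$init_step
  if (is.null(init_step)) init_step <- pmax(0.01, 0.05 * abs(start))
  init_step <- rep_len(init_step, d)
  if (!is.null(seed)) set.seed(seed)

  par_names <- attr(target, "par_names")
  if (is.null(par_names)) par_names <- names(start)
  if (is.null(par_names)) par_names <- paste0("par", seq_len(d))

  samples <- matrix(NA_real_, n_iter, d, dimnames = list(NULL, par_names))
  lps <- numeric(n_iter)
  acc <- logical(n_iter)

  cur <- as.numeric(start)
  scale0 <- 2.38^2 / d
  log_lambda <- 0
  # Welford running mean / scatter of the chain for covariance adaptation
  run_mean <- cur
  run_S <- matrix(0, d, d)
  L <- NULL                      # upper Cholesky factor of the base cov
  L_diag <- init_step            # diagonal phase
  ridge <- cfg$ridge * diag(d)
  n_acc <- 0L

  for (t in seq_len(n_iter)) {
    step <- exp(0.5 * log_lambda)
    z <- rnorm(d)
    if (is.null(L)) {
      prop <- cur + step * L_diag * z
    } else {
      prop <- cur + step * drop(crossprod(L, z))
    }
    lp_prop <- target(prop)
    a <- if (is.finite(lp_prop)) min(1, exp(lp_prop - lp_cur)) else 0
    if (a > 0 && runif(1) < a) {
      cur <- prop
      lp_cur <- lp_prop
      acc[t] <- TRUE
      n_acc <- n_acc + 1L
    }
    samples[t, ] <- cur
    lps[t] <- lp_cur

    # Robbins-Monro step-size tuning towards the target acceptance rate
    log_lambda <- log_lambda + t^(-cfg$gamma_exponent) * (a - cfg$target_rate)
    log_lambda <- min(max(log_lambda, -20), 10)

    # running covariance (Welford)
    delta <- cur - run_mean
    run_mean <- run_mean + delta / (t + 1)
    run_S <- run_S + tcrossprod(delta, cur - run_mean)

    if (t >= cfg$adapt_start && t > d) {
      base_cov <- scale0 * (run_S / t + ridge)
      L <- tryCatch(chol(base_cov), error = function(e) NULL)
      if (is.null(L)) {
        L <- chol(base_cov + max(diag(base_cov)) * 1e-6 * diag(d))
      }
    }
  }

  structure(list(
    samples = samples,
    log_posterior = lps,
    accepted = acc,
    meta = list(seed = seed, n_iter = n_iter, d = d,
                acceptance_rate = n_acc / n_iter,
                adapt = cfg[c("target_rate", "adapt_start", "gamma_exponent")],
                final_log_scale = log_lambda,
                par_names = par_names,
                burn_fraction = 0)
  ), class = "posterior_chain")
}

#' Discard the burn-in portion of a chain
#'
#' Drops the initial fraction of samples taken while the sampler was still
#' locating the high-density region; by default the first quarter. The last
#' `ceiling((1 - fraction) * T)` samples are retained (always at least one).
#'
#' @param chain A `posterior_chain`.
#' @param fraction Fraction in `[0, 1)` to discard from the front.
#' @return The chain with only the retained samples; `meta$burn_fraction`
#'   records the discard and `meta$n_burned` the number dropped.
#' @export
discard_burn_in <- function(chain, fraction = 0.25) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (!is.numeric(fraction) || fraction < 0 || fraction >= 1) {
    stop("'fraction' must lie in [0, 1)")
  }
  total <- nrow(chain$samples)
  keep <- ceiling((1 - fraction) * total)
  idx <- seq(total - keep + 1L, total)
  chain$samples <- chain$samples[idx, , drop = FALSE]
  chain$log_posterior <- chain$log_posterior[idx]
  chain$accepted <- chain$accepted[idx]
  chain$meta$burn_fraction <- fraction
  chain$meta$n_burned <- total - keep
  chain
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat(sprintf("Posterior chain: %d samples x %d parameters (%s)\n",
              nrow(x$samples), ncol(x$samples),
              paste(colnames(x$samples), collapse = ", ")))
  cat(sprintf("  acceptance rate %.3f", x$meta$acceptance_rate))
  if (!is.null(x$meta$n_burned)) {
    cat(sprintf("; %d burn-in samples discarded", x$meta$n_burned))
  }
  cat("\n")
  invisible(x)
}

#' Posterior summary statistics of a chain
#'
#' @param object A `posterior_chain`.
#' @param probs Credible-interval probabilities (default central 95% plus
#'   the median).
#' @param ... Unused.
#' @return A data.frame with one row per parameter: mean, sd, median and
#'   the requested quantiles.
#' @export
summary.posterior_chain <- function(object, probs = c(0.025, 0.5, 0.975), ...) {
  sm <- object$samples
  qs <- t(apply(sm, 2, quantile, probs = probs))
  colnames(qs) <- paste0("q", probs * 100)
  out <- data.frame(parameter = colnames(sm),
                    mean = colMeans(sm),
                    sd = apply(sm, 2, sd),
                    qs, row.names = NULL, check.names = FALSE)
  out
}
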