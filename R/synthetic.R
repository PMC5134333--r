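#' Specification for a synthetic dose-response study
#'
#' Describes how a synthetic screening dataset is generated: for each
#' experiment a `(pIC50_i, Hill_i)` pair is either fixed or drawn from the
#' population distributions of the hierarchical model (logistic for pIC50,
#' log-logistic for Hill), the Hill curve is evaluated at each dose, and
#' truncated-normal observation noise restricted to \[0, 100\] is added —
#' the same observation model the inference assumes, which keeps parameter
#' recovery studies well-posed. A `clip` noise mode instead adds unbounded
#' Normal noise and caps the result at 0/100, emulating how raw screening
#' data are capped before analysis.
#'
#' The default dose grid is 4 log-equispaced concentrations spanning
#' 1/30th to 30 times the IC50 implied by the population median potency,
#' which covers the informative region of the curve.
#'
#' @param mu,s Logistic population location/scale for pIC50; ignored if
#'   `pIC50_fixed` is given.
#' @param alpha,beta Log-logistic population scale/shape for Hill; ignored
#'   if `Hill_fixed` is given.
#' @param pIC50_fixed,Hill_fixed Optional fixed values used for every
#'   experiment instead of population draws.
#' @param sigma Observation noise SD in percent block, `>= 0`.
#' @param n_experiments Number of experimental repeats, `>= 1`.
#' @param concentrations Dose grid in micromolar (positive); default as
#'   described above.
#' @param noise_mode `"truncated"` (default) or `"clip"`.
#' @param compound,channel Labels written into the dataset.
#' @param seed Optional default seed used by [generate_dataset()].
#' @return A list of class `generator_spec`.
#' @export
generator_spec <- function(mu = 6, s = 0.1, alpha = 1, beta = 5,
                           pIC50_fixed = NULL, Hill_fixed = NULL,
                           sigma = 1, n_experiments = 5,
                           concentrations = NULL,
                           noise_mode = c("truncated", "clip"),
                           compound = "synthetic", channel = "synthetic",
                           seed = NULL) {
  noise_mode <- match.arg(noise_mode)
  if (!is.finite(sigma) || sigma < 0) stop("'sigma' must be >= 0")
  if (!is.numeric(n_experiments) || n_experiments < 1) {
    stop("'n_experiments' must be >= 1")
  }
  if (is.null(pIC50_fixed)) {
    if (!is.finite(mu) || !is.finite(s) || s <= 0) {
      stop("logistic population for pIC50 requires finite 'mu' and 's' > 0")
    }
  }
  if (is.null(Hill_fixed)) {
    if (!is.finite(alpha) || alpha <= 0 || !is.finite(beta) || beta <= 0) {
      stop("log-logistic population for Hill requires 'alpha' > 0, 'beta' > 0")
    }
  } else if (Hill_fixed <= 0) stop("'Hill_fixed' must be positive")
  if (is.null(concentrations)) {
    p_med <- if (is.null(pIC50_fixed)) mu else pIC50_fixed
    ic50_med <- pic50_to_ic50(p_med)
    concentrations <- exp(seq(log(ic50_med / 30), log(ic50_med * 30),
                              length.out = 4))
  }
  if (length(concentrations) < 1 || any(!is.finite(concentrations)) ||
      any(concentrations <= 0)) {
    stop("'concentrations' must be a non-empty vector of positive doses (uM)")
  }
  structure(list(mu = mu, s = s, alpha = alpha, beta = beta,
                 pIC50_fixed = pIC50_fixed, Hill_fixed = Hill_fixed,
                 sigma = sigma, n_experiments = as.integer(n_experiments),
                 concentrations = as.numeric(concentrations),
                 noise_mode = noise_mode,
                 compound = compound, channel = channel, seed = seed),
            class = "generator_spec")
}

#' Named synthetic study presets
#'
#' Three ready-made generator specifications used throughout the package's
#' validation studies:
#' \describe{
#'   \item{`"population"`}{Both parameters vary across experiments:
#'     pIC50 ~ logistic(mu = 6, s = 0.1), Hill ~ log-logistic(alpha = 1,
#'     beta = 5), noise SD 1% block, 16 experiments. Used for
#'     prior-to-posterior contraction and noise-recovery studies.}
#'   \item{`"shamiodarone"`}{A fictitious compound whose Hill coefficient
#'     is exactly 1 in every experiment while pIC50 varies:
#'     pIC50 ~ logistic(6, 0.2), noise SD 0.5, 5 experiments of 4 doses.}
#'   \item{`"shamitriptyline"`}{The mirror case: pIC50 fixed at 6, Hill ~
#'     log-logistic(alpha = 1, beta = 2.5), noise SD 0.5, 5 experiments of
#'     4 doses.}
#' }
#' The sham compounds probe whether inference assigns inter-experiment
#' variability to the correct parameter.
#'
#' @param name One of `"population"`, `"shamiodarone"`,
#'   `"shamitriptyline"`.
#' @return A [generator_spec()].
#' @export
preset <- function(name) {
  known <- c("population", "shamiodarone", "shamitriptyline")
  if (length(name) != 1 || !name %in% known) {
    stop("unknown preset '", paste(name, collapse = ","),
         "'; available presets: ", paste(known, collapse = ", "))
  }
  switch(name,
    population = generator_spec(mu = 6, s = 0.1, alpha = 1, beta = 5,
                                sigma = 1, n_experiments = 16,
                                compound = "synthetic-population",
                                channel = "synthetic"),
    shamiodarone = generator_spec(mu = 6, s = 0.2, Hill_fixed = 1,
                                  sigma = 0.5, n_experiments = 5,
                                  compound = "shamiodarone",
                                  channel = "synthetic"),
    shamitriptyline = generator_spec(pIC50_fixed = 6, alpha = 1, beta = 2.5,
                                     sigma = 0.5, n_experiments = 5,
                                     compound = "shamitriptyline",
                                     channel = "synthetic")
  )
}

#' Generate a synthetic dose-response dataset
#'
#' Draws per-experiment parameters per the spec, evaluates the Hill curve
#' at every dose, and adds observation noise (truncated-normal on
#' \[0, 100\] by default, or clipped Normal in `"clip"` mode). With
#' `sigma = 0` the responses equal the noiseless curve exactly.
#'
#' @param spec A [generator_spec()] or preset name accepted by [preset()].
#' @param seed Integer seed (overrides `spec$seed`); same seed, same
#'   dataset.
#' @return A [dose_response_data()] with
#'   `n_experiments * length(concentrations)` records and attribute
#'   `generator` holding the drawn per-experiment parameters.
#' @export
generate_dataset <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- preset(spec)
  if (!inherits(spec, "generator_spec")) {
    stop("'spec' must be a generator_spec or preset name")
  }
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  ne <- spec$n_experiments
  conc <- spec$concentrations
  k <- length(conc)
  pic50_i <- if (is.null(spec$pIC50_fixed)) {
    rlogis(ne, location = spec$mu, scale = spec$s)
  } else rep(spec$pIC50_fixed, ne)
  hill_i <- if (is.null(spec$Hill_fixed)) {
    exp(rlogis(ne, location = log(spec$alpha), scale = 1 / spec$beta))
  } else rep(spec$Hill_fixed, ne)

  experiment <- rep(seq_len(ne), each = k)
  dose <- rep(conc, times = ne)
  f <- hill_response(dose, pic50_i[experiment], hill_i[experiment])
  if (spec$sigma == 0) {
    y <- f
  } else if (spec$noise_mode == "truncated") {
    # inverse-CDF draw from Normal(f, sigma^2) restricted to [0, 100]
    u <- runif(length(f))
    p0 <- pnorm(0, f, spec$sigma)
    p1 <- pnorm(100, f, spec$sigma)
    y <- qnorm(p0 + u * (p1 - p0), f, spec$sigma)
    y <- pmin(pmax(y, 0), 100)   # guard rounding at the edges
  } else {
    y <- pmin(pmax(rnorm(length(f), f, spec$sigma), 0), 100)
  }
  out <- dose_response_data(experiment, dose, y,
                            compound = spec$compound, channel = spec$channel)
  attr(out, "generator") <- list(pIC50_i = pic50_i, Hill_i = hill_i,
                                 spec = spec, seed = seed)
  out
}
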