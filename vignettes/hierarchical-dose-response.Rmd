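---
title: "Bayesian and hierarchical inference for Hill dose-response curves"
author: "hillbayes authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian and hierarchical inference for Hill dose-response curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hillbayes)
```

## The problem

Ion-channel screening experiments apply a compound at a handful of
concentrations and measure the fraction of an ionic current that is
blocked. The standard summary is a Hill curve,

$$ f(x) = \frac{100}{1 + (IC_{50}/x)^{Hill}}, $$

reported as a single best-fit $(IC_{50}, Hill)$ pair. A point estimate
hides two very different things: *observation noise* within an experiment,
and *inter-experiment variability* — whole repeats that are systematically
more or less sensitive, a pattern clearly visible when points from the
same repeat keep their relative ordering across concentrations. When block
levels feed downstream safety simulations (for instance cardiac action
potential models), those sources of uncertainty should propagate into the
prediction instead of being averaged away.

`hillbayes` fits Hill curves in a Bayesian framework and returns posterior
distributions rather than point estimates, at two levels of modelling
ambition.

## Parameterisation

Potency is handled internally in log-molar units,
$pIC_{50} = 6 - \log_{10}(IC_{50}\,[\mu M])$, because linear changes in
$IC_{50}$ do not produce linear changes in the curve and samplers explore
the log scale far more efficiently. $IC_{50}$ appears only at input/output
boundaries ([ic50_to_pic50()] / [pic50_to_ic50()]). Responses are kept in
percent block throughout, matching the data; the curve is fixed between
bottom 0% and top 100% (no variable-slope 4-parameter logistic).

## Observation model

An observation $y$ at dose $x$ is modelled as Normal around the curve with
standard deviation $\sigma$ (percent block), *truncated* to $[0, 100]$:
screening pipelines cap raw readings at those bounds, and an untruncated
Normal would interpret a run of capped zeros as nearly noiseless data. The
per-point log-density subtracts
$\log[\Phi((100-f)/\sigma) - \Phi((0-f)/\sigma)]$, which depends on the
local curve value $f$ and must be recomputed per point and per proposal.
Truncation (rather than a censored likelihood) mirrors how the capped data
were produced; a censored variant would treat boundary values as "at
least/at most" observations and is not implemented.

## Single-level model

All records pooled: parameters $(pIC_{50}, Hill, \sigma)$ with independent
uniform priors on $(-1, 15) \times (0, 10) \times (0, 50)$. The bounds are
generous by design — a Hill coefficient above 10 is indistinguishable in
practice, a $pIC_{50}$ below $-1$ corresponds to an IC50 so far above any
tested concentration that curves cannot be distinguished (and unbounded
drift there stalls both optimisers and samplers), and 50% noise is far
above anything seen in screens. The bounds are configuration
(`single_prior_config()`), not constants.

## Hierarchical model

Each experiment $i$ has its own $(pIC50_i, Hill_i)$ drawn from population
distributions shared across experiments:

$$ Hill_i \sim \text{log-logistic}(\alpha, \beta), \qquad
   pIC50_i \sim \text{logistic}(\mu, s), $$

with one shared noise $\sigma$. Large published collections of screening
repeats are well described by exactly these families, which motivates the
choice. The paper-level densities are worth writing out since they are the
package's workhorse (the scale–shape form with median $\alpha$):

$$ p(h \mid \alpha, \beta) =
   \frac{(\beta/\alpha)(h/\alpha)^{\beta-1}}{(1 + (h/\alpha)^\beta)^2},
   \qquad
   p(p \mid \mu, s) =
   \frac{e^{-(p-\mu)/s}}{s\,(1 + e^{-(p-\mu)/s})^2}. $$

Equivalently $\log Hill_i$ is logistic with location $\log\alpha$ and
scale $1/\beta$ — the relationship the unit tests exploit as an
independent oracle. The joint posterior over
$(\alpha, \beta, \mu, s, \sigma)$ and the $N_e$ parameter pairs has
$5 + 2N_e$ dimensions.

### Hyperpriors

The five top-level parameters carry gamma priors; $\mu$'s gamma is shifted
down to $-4$ so that ineffective compounds (very low potency) remain
reachable while little mass lies below $\mu = -2$. Two hard bounds are
enforced as support constraints (proposals outside are simply rejected,
which preserves detailed balance): $\beta > 2$, so the Hill population
density has no mass *and* zero slope at 0, preventing degenerate
zero-steepness draws; and $\sigma > 10^{-3}$, since some observation error
always exists and $\sigma = 0$ is numerically singular.

The numeric shapes and scales are a design decision of this package
(`hier_prior_config()` defaults: $\alpha \sim \Gamma(2.5, 0.5)$,
$\beta \sim \Gamma(4, 1.5)$, $\mu + 4 \sim \Gamma(6, 1.75)$,
$s \sim \Gamma(2, 0.5)$, $\sigma \sim \Gamma(2, 3.5)$, shape/scale). They
were chosen once to be weakly informative: wide relative to the posteriors
a typical screen produces, covering the ranges seen in large published
repeat collections, and satisfying the little-mass-below-$-2$ requirement
for $\mu$ (the shifted-gamma CDF at $-2$ is about $10^{-4}$). Every value
is exposed, and analyses that have better prior information should set
them.

## Inference

MCMC needs the posterior only up to a constant, so everything is computed
in the log domain. The pipeline is:

1. **Starting point by CMA-ES.** A covariance matrix adaptation evolution
   strategy search over the (normalised) prior box. Few-point
   dose-response posteriors have a characteristic pathology: a flat
   high-noise ridge (any curve "fits" if $\sigma$ is large) competing with
   the sharp curve-fit optimum. A single CMA-ES run can stall on the
   ridge, so `cmaes_start()` launches three additional restarts from
   random box points and keeps the best; the whole search is deterministic
   given its seed.
2. **Adaptive Metropolis–Hastings.** Random-walk Metropolis with Gaussian
   proposals centred on the current state. Two standard adaptation
   mechanisms (the literature the method descends from leaves the exact
   schedule open; ours is documented and configurable): a global step-size
   scalar tuned by Robbins–Monro updates towards 25% acceptance, and —
   from iteration $100\,d$ on — a proposal covariance equal to
   $2.38^2/d$ times the running empirical covariance of the chain plus a
   tiny diagonal ridge. Out-of-support proposals get $-\infty$ and are
   rejected rather than reflected.
3. **Burn-in.** The first quarter of the chain is discarded by default
   (`discard_burn_in()`), keeping the last $\lceil 0.75\,T \rceil$
   samples.

For the hierarchical model the starting state is assembled from short
single-level CMA-ES fits to each experiment alone, with the top level
moment-matched: medians give $\mu$ and $\alpha$; spreads give $s$ and
$\beta$ through the logistic relation $\text{scale} = \text{sd}\sqrt{3}/\pi$
(floored/clamped so the start respects $\beta > 2$ and $s > 0$);
$\sigma$ starts at the mean per-experiment estimate.

The default chain length is 500,000 iterations, appropriate for final
analyses of datasets with a handful of repeats; the validation studies in
this package's test-suite use 50,000–100,000 iterations, which the
diagnostics (acceptance near target, agreement between independently
seeded chains, stability under tripled chain length) show is sufficient at
these problem sizes (up to 16 experiments, 64 records, 37 parameters).
Random-walk Metropolis mixing degrades as $N_e$ grows far beyond that, and
no alternative sampler is provided.

## Posterior-predictive distributions

What would the parameters of a *future* experiment look like? Averaging
the population density over retained iterations $t = 1..T$ gives

$$ p(Hill_{N_e+1} \mid \text{data}) \approx
   \frac{1}{T} \sum_t \text{log-logistic}(\alpha_t, \beta_t), $$

and the analogous logistic mixture for $pIC50_{N_e+1}$. These mixtures are
not directly samplable, so `sample_predictive()` inverts the averaged CDF:
a deterministic grid of 4096 points spanning the $10^{-6}$ to $1-10^{-6}$
component quantile range (log-spaced for the Hill mixture), mixture CDF
evaluated there, monotone interpolation, uniforms pushed through the
inverse. The approximation error is bounded by the grid resolution; at
$10^5$ draws the empirical CDF agrees with the analytic mixture CDF to a
Kolmogorov–Smirnov distance well below 0.01.

Percent-block predictions at a concentration (`chain_block_samples()`)
come in three flavours: pushing single-level posterior samples through the
curve; pushing the hierarchical $(\mu_t, \alpha_t)$ samples through
("underlying" effect, measurement-level variability discounted); or
pushing posterior-predictive draws through ("future experiment",
variability included). Which is appropriate depends on whether
inter-experiment variability is believed to exist in the system being
predicted or to be an artefact of measurement. The predictive mode draws
Hill and pIC50 from their marginal mixtures independently.

## Synthetic data generator

`generate_dataset()` draws per-experiment parameters from the same
population families the model assumes and adds truncated-normal noise on
$[0, 100]$ — deliberately the inference's own observation model, so
parameter-recovery studies are well-posed; a `clip` mode instead caps
unbounded Normal draws, emulating how raw screening data are actually
truncated. Three presets encode the package's validation studies:

* `population`: $pIC50 \sim \text{logistic}(6, 0.1)$,
  $Hill \sim \text{log-logistic}(1, 5)$, $\sigma = 1$, 16 experiments.
* `shamiodarone`: $Hill$ fixed at 1, $pIC50 \sim \text{logistic}(6, 0.2)$,
  $\sigma = 0.5$, 5 experiments.
* `shamitriptyline`: $pIC50$ fixed at 6,
  $Hill \sim \text{log-logistic}(1, 2.5)$, $\sigma = 0.5$, 5 experiments.

Each experiment measures 4 concentrations. The dose grid is a design
choice of this package: 4 log-equispaced doses from $IC50_{med}/30$ to
$30 \cdot IC50_{med}$ (population median potency), spanning roughly the
3%–97% response region where the curve is informative.

The generator emulates the statistical structure of screening data, not
its physiology: no rundown, series-resistance artefacts, concentration
errors, or plate effects. Passing the recovery tests therefore shows the
inference machinery is self-consistent under its assumed model — it does
not certify behaviour on real patch-clamp data, where the noise model may
be misspecified.

## What the validation studies show

The test suite re-runs, at reduced chain lengths, the package's three
synthetic studies:

* **Noise recovery and contraction** (`population`, $N_e = 16$): the
  posterior mean of $\sigma$ lands near the generating value, and the
  posterior SD of $\mu$ is non-increasing as the fit sees
  $N_e \in \{1, 2, 4, 8, 16\}$ experiments — the prior's influence fades
  as data accumulate. With only 64 observations the posterior mean of
  $\sigma$ inherits the sampling variability of a 64-point SD estimate
  (standard error $\approx \sigma/\sqrt{2 \cdot 64} \approx 0.09$), so
  individual data realisations legitimately land a tenth or two away from
  the generating value.
* **Variability assignment** (the sham compounds): when only $pIC50$
  varied across experiments, the hierarchical fit concentrates the Hill
  population ($\alpha$ median at the fixed value, small spread) while its
  $pIC50_i$ differ; the single-level fit, forced to explain
  inter-experiment spread with a single curve, inflates its Hill posterior
  instead — its SD exceeds the hierarchical $\alpha$ SD. The mirrored
  study (fixed $pIC50$, varying Hill) recovers $\mu$ at the fixed potency.

## Numerical notes and edge cases

* Zero doses return exactly 0% block (the analytic limit); zero-dose
  controls therefore pass through the likelihood unremarkably.
* The curve is evaluated as $100/(1 + 10^{Hill(6 - pIC50 - \log_{10} x)})$;
  at extreme exponents ($\gtrsim 14$ decades) the response rounds to
  exactly 0 or 100 in double precision.
* Log-densities remain finite down to $\sigma = 10^{-3}$ with residuals
  spanning the full 0–100 range.
* `log1p(exp(z))` is used wherever logistic-type terms appear, so very
  small population scales do not overflow.
* The averaged-CDF inversion grid is clamped at its ends (probabilities
  outside the grid return the nearest grid point); mass beyond the
  $10^{-6}$ component quantiles is unrepresented, a deliberate truncation
  of the sampler's range.
* Chain files store 17 significant digits, so write/read round-trips are
  bit-exact.

## Limitations

* One shared $\sigma$ across experiments; no heteroscedastic or
  per-experiment noise.
* Random-walk adaptive Metropolis only; mixing becomes impractical for
  $N_e$ in the several dozens.
* The predictive draws treat the Hill and pIC50 mixtures as independent
  marginals, ignoring posterior correlation between $(\alpha_t, \mu_t)$.
* Priors are tuned for ion-channel screening scales; other assay types
  should revisit both the uniform boxes and the gamma hyperpriors.
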