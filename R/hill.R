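#' Hill dose-response curve evaluated in pIC50 space
#'
#' Percent block of an ion current at concentration `x` under the Hill model
#' \deqn{f(x) = \frac{100}{1 + (IC_{50}/x)^{Hill}},}
#' with the potency held internally as
#' \eqn{pIC_{50} = 6 - \log_{10}(IC_{50}\,[\mu M])}, so that
#' \eqn{IC_{50} = 10^{6 - pIC_{50}}\ \mu M}. The curve is fixed between 0%
#' (no block) and 100% (full block); at the IC50 it passes exactly through
#' 50% for every Hill coefficient.
#'
#' All potency arithmetic is carried out in pIC50 (log-molar) space, where
#' parameter exploration is much better behaved than in raw IC50: the
#' exponent is computed as `Hill * (6 - pIC50 - log10(x))` and never forms
#' `IC50/x` directly, so very potent and very weak compounds are handled
#' symmetrically.
#'
#' @param x Concentration in micromolar; vector, each element `>= 0`. A zero
#'   dose returns exactly 0 (the analytic limit of the curve).
#' @param pIC50 Log-molar potency, `6 - log10(IC50 in uM)`. Finite.
#' @param Hill Hill coefficient (curve steepness), strictly positive.
#' @return Numeric vector of percent block values in `[0, 100)`.
#' @examples
#' hill_response(1, pIC50 = 6, Hill = 1)   # at the IC50: 50
#' hill_response(9, pIC50 = 6, Hill = 1)   # 90
#' hill_response(0, pIC50 = 6, Hill = 2)   # zero-dose control: 0
#' @seealso [ic50_to_pic50()], [pic50_to_ic50()]
#' @export
hill_response <- function(x, pIC50, Hill) {
  if (any(!is.finite(pIC50))) stop("'pIC50' must be finite")
  if (any(!is.finite(Hill)) || any(Hill <= 0)) {
    stop("'Hill' must be a positive finite number")
  }
  if (any(is.na(x)) || any(x < 0)) stop("'x' must be non-negative")
  n <- max(length(x), length(pIC50), length(Hill))
  x <- rep_len(x, n)
  pIC50 <- rep_len(pIC50, n)
  Hill <- rep_len(Hill, n)
  out <- numeric(n)
  pos <- x > 0
  # (IC50/x)^Hill = 10^(Hill * (6 - pIC50 - log10 x)); exact 50 at x = IC50
  e <- Hill[pos] * (6 - pIC50[pos] - log10(x[pos]))
  out[pos] <- 100 / (1 + 10^e)
  out
}

#' Convert between IC50 (micromolar) and pIC50 (log-molar)
#'
#' `ic50_to_pic50()` maps an IC50 in micromolar to the log-molar potency
#' scale, `pIC50 = 6 - log10(IC50)`; `pic50_to_ic50()` is its inverse,
#' `IC50 = 10^(6 - pIC50)`. Larger pIC50 means a more potent compound.
#'
#' @param ic50 IC50 in micromolar, strictly positive.
#' @param pIC50 Log-molar potency, finite.
#' @return `ic50_to_pic50()`: pIC50 in log(Molar) units.
#'   `pic50_to_ic50()`: IC50 in micromolar.
#' @examples
#' ic50_to_pic50(1)      # 6
#' ic50_to_pic50(1000)   # 3
#' pic50_to_ic50(6)      # 1
#' @export
ic50_to_pic50 <- function(ic50) {
  if (any(!is.finite(ic50)) || any(ic50 <= 0)) {
    stop("'ic50' must be a positive finite concentration in uM")
  }
  6 - log10(ic50)
}

#' @rdname ic50_to_pic50
#' @export
pic50_to_ic50 <- function(pIC50) {
  if (any(!is.finite(pIC50))) stop("'pIC50' must be finite")
  10^(6 - pIC50)
}
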