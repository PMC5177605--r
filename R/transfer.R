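# Elementary transfer functions: the logistic wave-to-pulse sigmoid, the
# population firing-rate function, Michaelis-Menten uptake, and the dynamic
# excitability thresholds induced by extracellular neurotransmitters.

#' Logistic activation sigmoid
#'
#' `S(x, x_th, r_sl) = 1 / (1 + exp(r_sl * (x_th - x)))`, the saturating
#' transfer used throughout the model for wave-to-pulse conversion, uptake
#' activation and feedback modulation. Evaluation is overflow-safe: the
#' exponent is branched on its sign so arguments with `|r_sl*(x_th-x)|` up to
#' (and beyond) 700 return 0 or 1 instead of overflowing.
#'
#' @param x input (same units as `x_th`); vectorized.
#' @param x_th threshold (inflection point location).
#' @param r_sl stiffness (slope scale, 1/units of `x`); must be > 0.
#' @return Values in (0, 1), strictly increasing in `x`.
#' @examples
#' sigmoidGate(6, 6, 0.56)   # 0.5 at the inflection point
#' @export
sigmoidGate <- function(x, x_th, r_sl) {
  if (!all(is.finite(x), is.finite(x_th), is.finite(r_sl)))
    stop("sigmoidGate: non-finite input")
  if (r_sl <= 0) stop("sigmoidGate: r_sl must be > 0")
  u <- r_sl * (x_th - x)
  u <- pmin(pmax(u, -700), 700)
  ifelse(u > 0, exp(-u) / (1 + exp(-u)), 1 / (1 + exp(u)))
}

#' Population firing rate
#'
#' Average pulse density of a population at membrane potential `x` and
#' excitability threshold `v`: `2 * e0 * sigmoidGate(x, v, r)`. Bounded in
#' `(0, 2 e0)`.
#'
#' @param x average membrane potential (mV); vectorized.
#' @param v excitability threshold (mV).
#' @param params a [modelParams()] object (uses `e0` and `r`).
#' @return Firing rate (1/s).
#' @export
firingRate <- function(x, v, params) {
  validateParams(params)
  2 * params$e0 * sigmoidGate(x, v, params$r)
}

#' Michaelis-Menten saturation
#'
#' `H(x, k) = x / (x + k)`, the fractional transporter occupancy used for
#' GABA uptake kinetics.
#'
#' @param x concentration (uM); vectorized. Physically `x >= 0`; negative
#'   values (possible under the unclamped equations) are evaluated as
#'   written.
#' @param k Michaelis constant (uM), > 0.
#' @return Fraction in `[0, 1)` for `x >= 0`.
#' @export
hillUptake <- function(x, k) {
  if (k <= 0) stop("hillUptake: k must be > 0")
  if (any(x + k == 0)) stop("hillUptake: x + k = 0")
  x / (x + k)
}

#' Dynamic excitability thresholds from extracellular concentrations
#'
#' Maps extracellular glutamate and GABA to the feedback modulations
#' `v1 = mG_I * S([Glu]_e, v_G, r_G)` and
#' `v2 = m_gamma * S([GABA]_e, v_gamma, r_gamma)`, and to the instantaneous
#' excitability thresholds of the three populations:
#' `vP = v0 + v2 - (mG_P/mG_I) * v1`, `vPprime = v0`, `vI = v0 - v1`.
#'
#' @param glu_e extracellular glutamate (uM); vectorized.
#' @param gaba_e extracellular GABA (uM); vectorized (recycled with `glu_e`).
#' @param params a [modelParams()] object.
#' @return List with components `v1`, `v2`, `vP`, `vPprime`, `vI` (mV).
#' @examples
#' feedbackThresholds(0, 0, modelParams())
#' @export
feedbackThresholds <- function(glu_e, gaba_e, params) {
  validateParams(params)
  glu_e <- unname(glu_e); gaba_e <- unname(gaba_e)
  v1 <- params$mG_I * sigmoidGate(glu_e, params$v_G, params$r_G)
  v2 <- params$m_gamma * sigmoidGate(gaba_e, params$v_gamma, params$r_gamma)
  list(v1 = v1, v2 = v2,
       vP = params$v0 + v2 - (params$mG_P / params$mG_I) * v1,
       vPprime = rep(params$v0, length.out = max(length(v1), length(v2))),
       vI = params$v0 - v1)
}
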