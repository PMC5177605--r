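# Dependence of the activation threshold p_SNIC on the glutamate-induced
# modulation v1, and classification of astrocytic glutamate-uptake
# deficiency regimes through the feedback-gain ratio mG_P/mG_I.
#
# Key quantities: chi = B e0 r C4 / (2 b) bounds the admissible ratio; the
# stationarity condition d p_SNIC / d v1 = 0 reduces to the quadratic
# ratio * X^2 + 2 (ratio - 2 chi) X + ratio = 0 in
# X = exp(r (v0 - v1 - C3 y0)), with roots V+- satisfying V+ V- = 1; the
# extremum locations follow as v1 = v0 - C3 y0 - ln(V+-)/r at the fold y0.

#' Threshold constant for the feedback-gain ratio
#'
#' `chi = B e0 r C4 / (2 b)`. The ratio `mG_P/mG_I` of the glutamate
#' feedback gains on pyramidal cells and interneurons admits interior
#' extrema of `p_SNIC(v1)` only when it is smaller than `chi`.
#'
#' @param params a [modelParams()] object.
#' @return Dimensionless scalar.
#' @examples
#' chiConstant(modelParams())
#' @export
chiConstant <- function(params) {
  validateParams(params)
  params$B * params$e0 * params$r * params$C4 / (2 * params$b)
}

#' Roots of the extremum quadratic
#'
#' Solves `ratio * X^2 + 2 (ratio - 2 chi) X + ratio = 0` for
#' `X = exp(r (v0 - v1 - C3 y0))`:
#' `V+- = 2 chi / ratio - 1 +- 2 sqrt((chi/ratio) (chi/ratio - 1))`.
#' The roots satisfy `V+ V- = 1`; they are real iff `0 < ratio <= chi`.
#'
#' @param ratio feedback-gain ratio `mG_P / mG_I` (dimensionless), in
#'   `(0, chi)`.
#' @param chi the threshold constant [chiConstant()].
#' @return Named numeric `c(V_plus, V_minus)`.
#' @export
vPlusMinus <- function(ratio, chi) {
  if (!(ratio > 0 && ratio < chi))
    stop(sprintf(paste("vPlusMinus: admissibility condition",
                       "0 < ratio < chi violated (ratio = %.4g, chi = %.4g):",
                       "discriminant is not positive"), ratio, chi))
  cc <- chi / ratio
  d <- 2 * sqrt(cc * (cc - 1))
  c(V_plus = 2 * cc - 1 + d, V_minus = 2 * cc - 1 - d)
}

#' Extremum locations of the activation threshold in v1
#'
#' Solves the coupled stationarity system `df/dy0 = 0` (fold condition) and
#' `df/dv1 = 0` (threshold extremum) for the two candidate extrema of
#' `p_SNIC(v1)` at fixed `v2`: the local minimum `v1*` (paired with the SN1
#' fold and the root `V+`) and the local maximum `v1**` (paired with the SN2
#' fold and `V-`). A damped fixed-point iteration alternates between the
#' fold location at the current `v1` and the closed-form update
#' `v1 = v0 - C3 y0 - ln(V+-)/r`; a 2-D root solve is used as fallback.
#'
#' The extremum type is confirmed numerically by sampling `p_SNIC` on a
#' local `v1` grid around each converged candidate.
#'
#' @param params a [modelParams()] object; requires `mG_P/mG_I < chi`.
#' @param v2 frozen GABA-induced modulation (mV). The fold condition does
#'   not depend on `v2`, so the extremum locations are `v2`-independent;
#'   the default 0 is used throughout.
#' @param damping damping factor of the fixed-point update.
#' @param maxit iteration budget per extremum.
#' @param tol convergence tolerance on `v1` (mV).
#' @return List with elements `v1_star` and `v1_dstar`, each
#'   `list(v1, y0, exists, in_range, confirmed, residuals)`: `exists` is
#'   `FALSE` when the branch's stationarity system has no solution inside
#'   the fold-existence region (the iteration then reports the `v1` at
#'   which the fold was lost), `in_range` flags `v1` within `[0, mG_I]`,
#'   and `confirmed` is the numeric local-min/max check of `p_SNIC(v1)`
#'   (`NA` when not computable); plus `ratio`, `chi`, `v2`.
#' @export
findV1Extrema <- function(params, v2 = 0, damping = 0.5, maxit = 200,
                          tol = 1e-11) {
  validateParams(params)
  p <- params
  ratio <- p$mG_P / p$mG_I
  chi <- chiConstant(p)
  V <- vPlusMinus(ratio, chi)   # errors when ratio >= chi

  solveBranch <- function(Vroot, fold) {
    Vroot <- unname(Vroot)
    v1 <- p$mG_I / 2
    y0 <- NA_real_
    converged <- FALSE
    lost <- FALSE
    for (it in seq_len(maxit)) {
      sn <- tryCatch(findSaddleNodes(v1, v2, p),
                     gliamass_fold_error = function(e) NULL)
      if (is.null(sn)) {
        # the iteration left the fold-existence region: the stationarity
        # system has no solution on this branch for these parameters
        lost <- TRUE
        break
      }
      y0 <- if (fold == 1) sn$sn1$y0 else sn$sn2$y0
      v1_new <- p$v0 - p$C3 * y0 - log(Vroot) / p$r
      step <- v1_new - v1
      v1 <- v1 + damping * step
      if (abs(step) < tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged && !lost) {
      # trust-region fallback on the raw 2-D stationarity system
      sol <- pracma::fsolve(function(x) {
        c(dfdy0(x[1], x[2], p), dfdv1(x[1], x[2], p))
      }, c(y0, v1))
      y0 <- sol$x[1]; v1 <- sol$x[2]
      converged <- TRUE
    }
    if (converged && !lost) {
      # polish: undamped closed-form updates with the fold recomputed, so
      # both stationarity residuals are driven to solver precision
      for (it in 1:8) {
        sn <- tryCatch(findSaddleNodes(v1, v2, p),
                       gliamass_fold_error = function(e) NULL)
        if (is.null(sn)) break
        y0 <- if (fold == 1) sn$sn1$y0 else sn$sn2$y0
        v1_new <- p$v0 - p$C3 * y0 - log(Vroot) / p$r
        if (abs(v1_new - v1) < 1e-14) { v1 <- v1_new; break }
        v1 <- v1_new
      }
    }
    res <- if (lost) c(dfdy0 = NA_real_, dfdv1 = NA_real_) else
      c(dfdy0 = abs(dfdy0(y0, v1, p)), dfdv1 = abs(dfdv1(y0, v1, p)))
    list(v1 = v1, y0 = y0, exists = converged,
         in_range = converged && v1 >= 0 && v1 <= p$mG_I,
         residuals = res)
  }

  star <- solveBranch(V["V_plus"], fold = 1)
  dstar <- solveBranch(V["V_minus"], fold = 2)

  confirm <- function(v1c, minimum, delta = 1e-3) {
    ps <- tryCatch(
      vapply(c(v1c - delta, v1c, v1c + delta),
             function(v) pSnic(v, v2, p), numeric(1)),
      error = function(e) NULL)
    if (is.null(ps)) return(NA)
    if (minimum) ps[2] < ps[1] && ps[2] < ps[3]
    else ps[2] > ps[1] && ps[2] > ps[3]
  }
  star$confirmed <- if (star$exists) confirm(star$v1, minimum = TRUE) else NA
  dstar$confirmed <- if (dstar$exists) confirm(dstar$v1, minimum = FALSE)
    else NA

  list(v1_star = star, v1_dstar = dstar, ratio = ratio, chi = chi, v2 = v2)
}

#' Admissible interval of the feedback-gain ratio
#'
#' Endpoints of the interval `[I1, I2]` of ratios `mG_P/mG_I` for which the
#' interior minimum `v1*` of the activation threshold lies within
#' `[0, mG_I]`: `I = 4 chi (1 - S) S` with `S` the interneuron activation
#' sigmoid evaluated at the SN1 fold for the boundary modulations `v1 = 0`
#' (giving `I1`) and `v1 = mG_I` (giving `I2`). Computed at `v2 = 0`; the
#' fold condition is `v2`-independent, so the endpoints are too.
#'
#' @param params a [modelParams()] object.
#' @return Named numeric `c(I1, I2)` with the fold outputs attached as
#'   attribute `y0`.
#' @examples
#' ratioInterval(modelParams())
#' @export
ratioInterval <- function(params) {
  validateParams(params)
  p <- params
  chi <- chiConstant(p)
  sn0 <- findSaddleNodes(0, 0, p)
  sn1 <- findSaddleNodes(p$mG_I, 0, p)
  s0 <- sigmoidGate(p$C3 * sn0$sn1$y0, p$v0, p$r)
  s1 <- sigmoidGate(p$C3 * sn1$sn1$y0, p$v0 - p$mG_I, p$r)
  out <- c(I1 = 4 * chi * (1 - s0) * s0, I2 = 4 * chi * (1 - s1) * s1)
  attr(out, "y0") <- c(v1_0 = sn0$sn1$y0, v1_mGI = sn1$sn1$y0)
  out
}

#' Classify the glutamate-uptake deficiency regime
#'
#' Scenario label from the feedback-gain ratio:
#' \describe{
#'   \item{`"a"`}{`ratio < I1`: `p_SNIC` increases with `v1`; uptake
#'     deficiency reduces neural activity.}
#'   \item{`"b"`}{`ratio > I2`: `p_SNIC` decreases with `v1`; sustained
#'     hyperexcitability.}
#'   \item{`"c"`}{`I1 <= ratio <= I2`: interior minimum `v1*`; transient
#'     hyperexcitability with recovery.}
#'   \item{`"none"`}{`ratio >= chi`: no extremum structure.}
#' }
#'
#' @param ratio feedback-gain ratio `mG_P / mG_I`; defaults to the ratio of
#'   `params`.
#' @param params a [modelParams()] object (the ratio interval is computed
#'   from its other parameters).
#' @return Character scalar with attributes `chi`, `I1`, `I2`.
#' @examples
#' classifyRegime(2.43, modelParams())
#' @export
classifyRegime <- function(ratio = NULL, params) {
  validateParams(params)
  if (is.null(ratio)) ratio <- params$mG_P / params$mG_I
  chi <- chiConstant(params)
  if (ratio >= chi) {
    lab <- "none"
    I <- c(I1 = NA_real_, I2 = NA_real_)
  } else {
    I <- ratioInterval(params)
    lab <- if (ratio < I["I1"]) "a" else if (ratio > I["I2"]) "b" else "c"
  }
  structure(lab, chi = chi, I1 = unname(I["I1"]), I2 = unname(I["I2"]))
}

#' Full regime report
#'
#' Gathers the quantities governing the shape of `p_SNIC(v1, v2)` for a
#' parameter set: `chi`, the ratio, the quadratic roots `V+-`, the extremum
#' locations with their folds, the admissible interval `[I1, I2]` and the
#' scenario label.
#'
#' @param params a [modelParams()] object.
#' @param v2 frozen GABA-induced modulation (mV).
#' @return List of class `"gliamass_regimes"`.
#' @export
regimeReport <- function(params, v2 = 0) {
  validateParams(params)
  ratio <- params$mG_P / params$mG_I
  chi <- chiConstant(params)
  scenario <- classifyRegime(ratio, params)
  out <- list(chi = chi, ratio = ratio, scenario = as.character(scenario),
              I1 = attr(scenario, "I1"), I2 = attr(scenario, "I2"),
              V = NULL, extrema = NULL, v2 = v2)
  if (ratio < chi) {
    out$V <- vPlusMinus(ratio, chi)
    out$extrema <- tryCatch(findV1Extrema(params, v2 = v2),
                            error = function(e) NULL)
  }
  class(out) <- "gliamass_regimes"
  out
}

#' @export
print.gliamass_regimes <- function(x, ...) {
  cat("<gliamass_regimes>\n")
  cat(sprintf("  chi = %.4f, ratio mG_P/mG_I = %.4f\n", x$chi, x$ratio))
  if (!is.na(x$I1))
    cat(sprintf("  admissible interval [I1, I2] = [%.4f, %.4f]\n",
                x$I1, x$I2))
  lbl <- c(a = "reduced activity", b = "sustained hyperexcitability",
           c = "transient hyperexcitability", none = "no extremum")
  cat(sprintf("  scenario: %s (%s)\n", x$scenario, lbl[[x$scenario]]))
  if (!is.null(x$extrema)) {
    e <- x$extrema
    cat(sprintf("  v1* = %.4f (in range: %s), v1** = %.4f (in range: %s)\n",
                e$v1_star$v1, e$v1_star$in_range,
                e$v1_dstar$v1, e$v1_dstar$in_range))
  }
  invisible(x)
}

#' Activation-threshold surface over the feedback modulations
#'
#' Evaluates `p_SNIC` on a `(v1, v2)` grid. Cells where the fold is lost
#' are `NA` (with a single warning); every `v1` row is affine in `v2` with
#' slope `a/A`.
#'
#' @param v1_grid,v2_grid numeric grids, within `[0, mG_I]` and
#'   `[0, m_gamma]` respectively.
#' @param params a [modelParams()] object.
#' @return Matrix (`length(v1_grid)` x `length(v2_grid)`) with dimnames.
#' @export
pSnicSurface <- function(v1_grid, v2_grid, params) {
  validateParams(params)
  if (any(v1_grid < 0 | v1_grid > params$mG_I))
    stop("pSnicSurface: v1_grid must lie within [0, mG_I]")
  if (any(v2_grid < 0 | v2_grid > params$m_gamma))
    stop("pSnicSurface: v2_grid must lie within [0, m_gamma]")
  m <- matrix(NA_real_, length(v1_grid), length(v2_grid),
              dimnames = list(signif(v1_grid, 8), signif(v2_grid, 8)))
  lost <- 0L
  for (i in seq_along(v1_grid)) for (j in seq_along(v2_grid)) {
    m[i, j] <- tryCatch(pSnic(v1_grid[i], v2_grid[j], params),
                        gliamass_fold_error = function(e) {
                          lost <<- lost + 1L
                          NA_real_
                        })
  }
  if (lost > 0)
    warning(sprintf("pSnicSurface: fold lost in %d grid cell(s)", lost))
  m
}
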