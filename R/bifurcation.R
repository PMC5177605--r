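# Equilibrium curve of the neural compartment with the feedback modulations
# (v1, v2) as quasi-static parameters; saddle-node / SNIC and Hopf
# localization; the activation-threshold map p_SNIC(v1, v2).
#
# At an equilibrium, the drive p is an explicit function of the pyramidal
# output y0:
#   p = f(y0, v1, v2)
#     = (a/A) (v0 - (mG_P/mG_I) v1 + v2)
#       - (a/(A r)) ln((2 A e0 - a y0)/(a y0))
#       - (a G / A) y0 - C2 Shat(C1 y0, v0)
#       + (a B/(b A)) C4 Shat(C3 y0, v0 - v1),
# on the domain 0 < y0 < 2 A e0 / a. The curve is a graph over y0; its two
# folds are the saddle-nodes SN1 (local max, = SNIC) and SN2 (local min).

y0Domain <- function(params) 2 * params$A * params$e0 / params$a

shat <- function(x, v, params) 2 * params$e0 * sigmoidGate(x, v, params$r)

#' Equilibrium drive for a given pyramidal output
#'
#' Evaluates `p = f(y0, v1, v2)`, the unique drive at which `y0` is the
#' pyramidal output of a neural equilibrium, for quasi-static feedback
#' modulations `v1` (glutamate) and `v2` (GABA). The decomposition
#' `f(y0, v1, v2) = (a/A) v2 + q(y0, v1)` holds exactly: `v2` enters only
#' through the additive linear term.
#'
#' @param y0 pyramidal output (mV), in the open domain `(0, 2 A e0 / a)`;
#'   vectorized.
#' @param v1 glutamate-induced modulation (mV).
#' @param v2 GABA-induced modulation (mV).
#' @param params a [modelParams()] object.
#' @return Drive `p` (1/s).
#' @export
equilibriumInput <- function(y0, v1, v2, params) {
  validateParams(params)
  p <- params
  ymax <- y0Domain(p)
  if (any(y0 <= 0 | y0 >= ymax))
    stop(sprintf("equilibriumInput: y0 must lie in (0, %.6g)", ymax))
  (p$a / p$A) * (p$v0 - (p$mG_P / p$mG_I) * v1 + v2) -
    (p$a / (p$A * p$r)) * log((2 * p$A * p$e0 - p$a * y0) / (p$a * y0)) -
    (p$a * p$G / p$A) * y0 -
    p$C2 * shat(p$C1 * y0, p$v0, p) +
    (p$a * p$B / (p$b * p$A)) * p$C4 * shat(p$C3 * y0, p$v0 - v1, p)
}

# d f / d y0 (independent of v2) and second derivative; dS denotes
# d/dx S(x, th, r) = r S (1 - S).
dfdy0 <- function(y0, v1, params) {
  p <- params
  S1 <- sigmoidGate(p$C1 * y0, p$v0, p$r)
  S3 <- sigmoidGate(p$C3 * y0, p$v0 - v1, p$r)
  (p$a / (p$A * p$r)) * (p$a / (2 * p$A * p$e0 - p$a * y0) + 1 / y0) -
    p$a * p$G / p$A -
    p$C2 * p$C1 * 2 * p$e0 * p$r * S1 * (1 - S1) +
    (p$a * p$B / (p$b * p$A)) * p$C4 * p$C3 * 2 * p$e0 * p$r *
      S3 * (1 - S3)
}

d2fdy02 <- function(y0, v1, params) {
  p <- params
  S1 <- sigmoidGate(p$C1 * y0, p$v0, p$r)
  S3 <- sigmoidGate(p$C3 * y0, p$v0 - v1, p$r)
  (p$a / (p$A * p$r)) *
    (p$a^2 / (2 * p$A * p$e0 - p$a * y0)^2 - 1 / y0^2) -
    p$C2 * p$C1^2 * 2 * p$e0 * p$r^2 * S1 * (1 - S1) * (1 - 2 * S1) +
    (p$a * p$B / (p$b * p$A)) * p$C4 * p$C3^2 * 2 * p$e0 * p$r^2 *
      S3 * (1 - S3) * (1 - 2 * S3)
}

# d f / d v1 = -(a/A) (mG_P/mG_I - 4 chi S3 (1 - S3)) with
# chi = B e0 r C4 / (2 b); independent of v2.
dfdv1 <- function(y0, v1, params) {
  p <- params
  S3 <- sigmoidGate(p$C3 * y0, p$v0 - v1, p$r)
  chi <- chiConstant(p)
  -(p$a / p$A) * (p$mG_P / p$mG_I - 4 * chi * S3 * (1 - S3))
}

#' Inverse of the population firing-rate function
#'
#' Returns the membrane potential `x` such that
#' `firingRate(x, v, params) = u`.
#'
#' @param u firing rate (1/s), in `(0, 2 e0)`.
#' @param v excitability threshold (mV).
#' @param params a [modelParams()] object.
#' @return Membrane potential (mV).
#' @export
invFiringRate <- function(u, v, params) {
  validateParams(params)
  if (any(u <= 0 | u >= 2 * params$e0))
    stop("invFiringRate: rate must lie strictly in (0, 2 e0)")
  v - (1 / params$r) * log(2 * params$e0 / u - 1)
}

#' Neural equilibrium for a given pyramidal output
#'
#' Closed-form equilibrium of the six neural variables: `y3 = y4 = y5 = 0`;
#' `y2` annihilates the inhibitory block, `y1` inverts the pyramidal
#' wave-to-pulse sigmoid at threshold `vP`. The drive at which this state is
#' an equilibrium is [equilibriumInput()] and is attached as attribute `p`.
#'
#' @inheritParams equilibriumInput
#' @return Named numeric vector `y0..y5` with attribute `p`.
#' @export
equilibriumState <- function(y0, v1, v2, params) {
  validateParams(params)
  p <- params
  ymax <- y0Domain(p)
  if (length(y0) != 1 || y0 <= 0 || y0 >= ymax)
    stop(sprintf("equilibriumState: y0 must lie in (0, %.6g)", ymax))
  vP <- p$v0 + v2 - (p$mG_P / p$mG_I) * v1
  vI <- p$v0 - v1
  y2 <- (p$B / p$b) * p$C4 * shat(p$C3 * y0, vI, p)
  # pyramidal rate at equilibrium is a y0 / A; invert the sigmoid for y1 - y2
  y1 <- y2 + invFiringRate(p$a * y0 / p$A, vP, p)
  st <- c(y0 = y0, y1 = y1, y2 = y2, y3 = 0, y4 = 0, y5 = 0)
  attr(st, "p") <- equilibriumInput(y0, v1, v2, params)
  st
}

#' Locate the saddle-node bifurcations of the equilibrium curve
#'
#' Scans `f(., v1, v2)` for its two critical points on a dense `y0` grid and
#' refines each by bisection on the analytic derivative. SN1 (smaller `y0`,
#' local maximum of `f`, negative curvature) is the fold involved in the
#' SNIC connection and defines the activation threshold; SN2 is the local
#' minimum. The fold positions `y_SN1`, `y_SN2` do not depend on `v2`; the
#' fold drives shift linearly, `p_SN(v2) = p_SN(0) + (a/A) v2`.
#'
#' @inheritParams equilibriumInput
#' @param n_grid scan resolution (default 4001 points over the open domain).
#' @return List with `sn1` and `sn2`, each `list(p, y0)`, plus `v1`, `v2`.
#'   If the number of critical points differs from 2 (fold lost for extreme
#'   `v1`), an error of class `"gliamass_fold_error"` naming the count is
#'   raised.
#' @export
findSaddleNodes <- function(v1, v2, params, n_grid = 4001) {
  validateParams(params)
  ymax <- y0Domain(params)
  eps <- 1e-6 * ymax
  ys <- seq(eps, ymax - eps, length.out = n_grid)
  fp <- dfdy0(ys, v1, params)
  sgn <- sign(fp)
  idx <- which(sgn[-1] * sgn[-n_grid] < 0)
  if (length(idx) != 2) {
    stop(structure(class = c("gliamass_fold_error", "error", "condition"),
                   list(message = sprintf(
                     paste("findSaddleNodes: expected 2 critical points of",
                           "the equilibrium curve, found %d (v1 = %.4g)"),
                     length(idx), v1), call = NULL)))
  }
  refine <- function(i) {
    uniroot(function(y) dfdy0(y, v1, params), c(ys[i], ys[i + 1]),
            tol = .Machine$double.eps)$root
  }
  yc <- vapply(idx, refine, numeric(1))
  curv <- d2fdy02(yc, v1, params)
  if (!(curv[1] < 0 && curv[2] > 0))
    stop(structure(class = c("gliamass_fold_error", "error", "condition"),
                   list(message = paste("findSaddleNodes: fold curvature",
                                        "pattern is not (max, min)"),
                        call = NULL)))
  ps <- equilibriumInput(yc, v1, v2, params)
  list(sn1 = list(p = ps[1], y0 = yc[1]),
       sn2 = list(p = ps[2], y0 = yc[2]),
       v1 = v1, v2 = v2)
}

#' Activation threshold of the neural compartment
#'
#' `p_SNIC(v1, v2)`: the drive at the saddle-node-on-invariant-circle
#' bifurcation (the SN1 fold). For `p < p_SNIC` the population is quiescent;
#' for `p > p_SNIC` it oscillates. `p_SNIC` is exactly affine in `v2` with
#' slope `a/A` and, depending on the feedback-gain ratio `mG_P/mG_I`, is
#' monotone or has an interior extremum in `v1` (see [regimeReport()]).
#'
#' @inheritParams equilibriumInput
#' @return The threshold drive (1/s).
#' @examples
#' pSnic(0, 0, modelParams())
#' @export
pSnic <- function(v1, v2, params) {
  findSaddleNodes(v1, v2, params)$sn1$p
}

#' Analytic Jacobian of the neural block at an equilibrium
#'
#' 6x6 Jacobian of the neural vector field at
#' [equilibriumState()]`(y0, v1, v2)`, with the feedback modulations frozen
#' (quasi-static glial state).
#'
#' @inheritParams equilibriumInput
#' @return 6x6 numeric matrix.
#' @export
neuralJacobian <- function(y0, v1, v2, params) {
  validateParams(params)
  p <- params
  st <- equilibriumState(y0, v1, v2, params)
  vP <- p$v0 + v2 - (p$mG_P / p$mG_I) * v1
  vI <- p$v0 - v1
  dS <- function(x, v) {
    s <- sigmoidGate(x, v, p$r)
    2 * p$e0 * p$r * s * (1 - s)
  }
  dP <- dS(st["y1"] - st["y2"], vP)   # d Shat / dx at pyramidal input
  d1 <- dS(p$C1 * st["y0"], p$v0)
  d3 <- dS(p$C3 * st["y0"], vI)
  a <- p$a; b <- p$b
  J <- matrix(0, 6, 6)
  J[1, 4] <- 1; J[2, 5] <- 1; J[3, 6] <- 1
  J[4, 1] <- -a^2
  J[4, 2] <- p$A * a * dP
  J[4, 3] <- -p$A * a * dP
  J[4, 4] <- -2 * a
  J[5, 1] <- p$A * a * p$C2 * p$C1 * d1
  J[5, 2] <- p$A * a * p$G * dP - a^2
  J[5, 3] <- -p$A * a * p$G * dP
  J[5, 5] <- -2 * a
  J[6, 1] <- p$B * b * p$C4 * p$C3 * d3
  J[6, 3] <- -b^2
  J[6, 6] <- -2 * b
  J
}

#' Linear stability of a neural equilibrium
#'
#' Eigenvalues of the analytic Jacobian at the equilibrium with pyramidal
#' output `y0`, and the branch label derived from the count of eigenvalues
#' with positive real part: lower-branch points are stable, middle-branch
#' points have one unstable eigenvalue, upper-branch points two (before the
#' Hopf bifurcation).
#'
#' @inheritParams equilibriumInput
#' @return List with `eigenvalues` (complex, sorted by decreasing real
#'   part), `n_unstable`, and `label` (`"stable"`, `"saddle"`,
#'   `"unstable"`).
#' @export
stabilitySpectrum <- function(y0, v1, v2, params) {
  J <- neuralJacobian(y0, v1, v2, params)
  ev <- eigen(J, only.values = TRUE)$values
  ev <- ev[order(-Re(ev))]
  n_un <- sum(Re(ev) > 0)
  list(eigenvalues = ev, n_unstable = n_un,
       label = c("stable", "saddle", "unstable")[pmin(n_un, 2) + 1])
}

#' Locate the supercritical Hopf bifurcation on the upper branch
#'
#' Scans the upper branch (`y0 > y_SN2`) for the sign change of the real
#' part of the complex-conjugate eigenvalue pair and refines it by
#' bisection. Returns `NULL` when no crossing exists.
#'
#' @inheritParams equilibriumInput
#' @param n_scan scan resolution along the upper branch.
#' @return `list(p, y0, omega)` (with `omega` the imaginary part of the
#'   critical pair) or `NULL`.
#' @export
findHopf <- function(v1, v2, params, n_scan = 400) {
  sn <- findSaddleNodes(v1, v2, params)
  ymax <- y0Domain(params)
  eps <- 1e-6 * ymax
  lo <- sn$sn2$y0 + 10 * eps
  hi <- ymax - eps
  reC <- function(y0) {
    ev <- stabilitySpectrum(y0, v1, v2, params)$eigenvalues
    cx <- ev[abs(Im(ev)) > 1e-8]
    if (!length(cx)) return(NA_real_)
    max(Re(cx))
  }
  ys <- seq(lo, hi, length.out = n_scan)
  vals <- vapply(ys, reC, numeric(1))
  ok <- which(!is.na(vals))
  if (length(ok) < 2) return(NULL)
  # downward (+ to -) crossing where the complex pair stabilizes; the last
  # one bounds the stable upper segment from above in p
  flip <- which(vals[ok][-length(ok)] > 0 & vals[ok][-1] < 0)
  if (!length(flip)) return(NULL)
  i <- ok[flip[length(flip)]]; j <- ok[flip[length(flip)] + 1]
  y_h <- uniroot(reC, c(ys[i], ys[j]), tol = 1e-12)$root
  ev <- stabilitySpectrum(y_h, v1, v2, params)$eigenvalues
  cx <- ev[abs(Im(ev)) > 1e-8]
  list(p = equilibriumInput(y_h, v1, v2, params), y0 = y_h,
       omega = max(abs(Im(cx))))
}

#' Equilibrium curve with stability labels
#'
#' Tabulates the singular-point locus `p = f(y0, v1, v2)` over a `y0` grid
#' together with the local spectrum, for bifurcation-diagram plots and CSV
#' export.
#'
#' @inheritParams equilibriumInput
#' @param n number of grid points.
#' @return `data.frame` of class `"gliamass_bifdiag"` with columns `y0`,
#'   `p`, `n_unstable`, `re_max`; the saddle-node and Hopf points are
#'   attached as attributes `sn` and `hopf`.
#' @export
equilibriumCurve <- function(v1, v2, params, n = 401) {
  ymax <- y0Domain(params)
  eps <- 1e-5 * ymax
  ys <- seq(eps, ymax - eps, length.out = n)
  spec <- lapply(ys, function(y) stabilitySpectrum(y, v1, v2, params))
  df <- data.frame(
    y0 = ys,
    p = equilibriumInput(ys, v1, v2, params),
    n_unstable = vapply(spec, `[[`, integer(1), "n_unstable"),
    re_max = vapply(spec, function(s) max(Re(s$eigenvalues)), numeric(1))
  )
  attr(df, "sn") <- tryCatch(findSaddleNodes(v1, v2, params),
                             gliamass_fold_error = function(e) NULL)
  attr(df, "hopf") <- tryCatch(findHopf(v1, v2, params),
                               error = function(e) NULL)
  class(df) <- c("gliamass_bifdiag", "data.frame")
  df
}

#' @export
plot.gliamass_bifdiag <- function(x, ...) {
  cols <- c("blue", "cyan3", "green3")[pmin(x$n_unstable, 2) + 1]
  graphics::plot(x$p, x$y0, col = cols, pch = 16, cex = 0.4,
                 xlab = "p (1/s)", ylab = "y0 (mV)", ...)
  sn <- attr(x, "sn")
  if (!is.null(sn)) {
    graphics::points(c(sn$sn1$p, sn$sn2$p), c(sn$sn1$y0, sn$sn2$y0),
                     pch = 19)
    graphics::abline(v = sn$sn1$p, lty = 2, col = "orange")
  }
  h <- attr(x, "hopf")
  if (!is.null(h)) graphics::points(h$p, h$y0, pch = 19, col = "red")
  invisible(x)
}
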