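# Time integration of the coupled system: stochastic drive construction,
# event schedules (boluses, parameter switches), the fixed-step integrator
# wrapper, and fixed points of the astrocytic / full system.

#' External drive specification
#'
#' Describes the excitatory input `p(t)` on the pyramidal population: either
#' a constant, or a piecewise-constant Gaussian process resampled every
#' `dt_noise` seconds from `Normal(p_bar, sigma^2)` (frozen noise). The NIS
#' (noise-induced spiking) regime arises when the band `p_bar +/- sigma`
#' straddles the activation threshold `p_SNIC`.
#'
#' @param kind `"gaussian"` or `"constant"` (`sigma` ignored for constant).
#' @param p_bar mean drive (1/s). `NULL` (default) resolves at simulation
#'   time to `pSnic(0, 0, params) - 5`, placing the confidence band across
#'   the activation threshold.
#' @param sigma noise standard deviation (1/s), >= 0.
#' @param dt_noise noise refresh interval (s), > 0. The default 0.1 s is of
#'   the order of the spike duration near threshold, which lets
#'   supra-threshold excursions complete the SNIC escape and produces
#'   sparse, isolated NIS spikes; much shorter refresh intervals average
#'   out before a spike can be initiated.
#' @param seed integer seed for the drive realization.
#' @return List of class `"gliamass_input"`.
#' @export
inputSpec <- function(kind = c("gaussian", "constant"), p_bar = NULL,
                      sigma = 10, dt_noise = 0.1, seed = 1L) {
  kind <- match.arg(kind)
  if (sigma < 0) stop("inputSpec: sigma must be >= 0")
  if (dt_noise <= 0) stop("inputSpec: dt_noise must be > 0")
  structure(list(kind = kind, p_bar = p_bar, sigma = sigma,
                 dt_noise = dt_noise, seed = as.integer(seed)),
            class = "gliamass_input")
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withLocalSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

resolveInput <- function(spec, params) {
  stopifnot(inherits(spec, "gliamass_input"))
  if (is.null(spec$p_bar)) spec$p_bar <- pSnic(0, 0, params) - 5
  spec
}

# Per-step drive values on the uniform integration grid: the step over
# [t_{i-1}, t_i) uses the process value at t_{i-1}.
realizeDrive <- function(spec, n_steps, dt) {
  if (spec$kind == "constant") return(rep(spec$p_bar, n_steps))
  k <- floor((seq_len(n_steps) - 1) * dt / spec$dt_noise + 1e-9) + 1L
  z <- withLocalSeed(spec$seed, rnorm(max(k)))
  spec$p_bar + spec$sigma * z[k]
}

#' Realized drive as a function of time
#'
#' Materializes the drive process of an [inputSpec()] over a time span and
#' returns it as a right-continuous step function `p(t)`. Identical
#' `(spec, t_span)` (in particular the same seed) give bitwise-identical
#' sample paths.
#'
#' @param spec an [inputSpec()]; `p_bar` must be set (or pass `params`).
#' @param t_span numeric length-2 time span (s).
#' @param params optional [modelParams()], used to resolve a `NULL` `p_bar`.
#' @return Function of `t` returning the drive (1/s), vectorized.
#' @export
makeInput <- function(spec, t_span = c(0, 60), params = NULL) {
  stopifnot(inherits(spec, "gliamass_input"))
  if (is.null(spec$p_bar)) {
    if (is.null(params))
      stop("makeInput: p_bar unset; supply params to resolve the default")
    spec <- resolveInput(spec, params)
  }
  if (spec$kind == "constant") {
    p_bar <- spec$p_bar
    return(function(t) rep(p_bar, length(t)))
  }
  n_int <- ceiling((t_span[2] - t_span[1]) / spec$dt_noise) + 1L
  vals <- spec$p_bar + spec$sigma * withLocalSeed(spec$seed, rnorm(n_int))
  t0 <- t_span[1]
  dtn <- spec$dt_noise
  function(t) vals[pmin(floor((t - t0) / dtn + 1e-9) + 1L, n_int)]
}

#' Event schedule: boluses and parameter switches
#'
#' Boluses are instantaneous increments of a state variable (e.g. a GABA
#' injection into the extracellular space); switches replace a parameter
#' value from a given time onward (e.g. an uptake knockout `Vgamma_ae = 0`).
#'
#' @param boluses `data.frame` with columns `time` (s), `var` (a state name
#'   in [STATE_VARS]), `amount` (increment, uM), or `NULL`.
#' @param switches `data.frame` with columns `time` (s), `param` (a name in
#'   the parameter set), `value`, or `NULL`.
#' @return List of class `"gliamass_events"`.
#' @examples
#' eventSchedule(boluses = data.frame(time = 0, var = "GABA_e", amount = 20))
#' @export
eventSchedule <- function(boluses = NULL, switches = NULL) {
  chk <- function(df, cols, what) {
    if (is.null(df)) return(NULL)
    df <- as.data.frame(df)
    if (!all(cols %in% names(df)))
      stop("eventSchedule: ", what, " needs columns ",
           paste(cols, collapse = ", "))
    if (is.unsorted(df$time, strictly = TRUE))
      stop("eventSchedule: ", what, " times must be strictly increasing")
    df
  }
  boluses <- chk(boluses, c("time", "var", "amount"), "boluses")
  switches <- chk(switches, c("time", "param", "value"), "switches")
  if (!is.null(boluses) && !all(boluses$var %in% STATE_VARS))
    stop("eventSchedule: unknown state variable in boluses")
  if (!is.null(switches) && !all(switches$param %in% PARAM_NAMES))
    stop("eventSchedule: unknown parameter in switches")
  structure(list(boluses = boluses, switches = switches),
            class = "gliamass_events")
}

#' Simulate the coupled neuron-astrocyte model
#'
#' Fixed-step RK4 integration of the 14-dimensional vector field with the
#' stochastic drive held piecewise-constant over each noise interval
#' (`dt <= dt_noise` required). Boluses are applied as instantaneous state
#' increments at their scheduled grid step; parameter switches take effect
#' from their time onward. The LFP output is `y1 - y2`.
#'
#' By default concentrations are not clamped: the equations are integrated
#' as written, and a warning of class `"gliamass_negative_concentration"` is
#' emitted if any concentration drifts below 0 (possible under near-zero
#' drive because the glutamate efflux sigmoid never vanishes). `clamp = TRUE`
#' instead truncates concentrations at 0 after each step.
#'
#' @param params a [modelParams()] object.
#' @param input an [inputSpec()].
#' @param events an [eventSchedule()] or `NULL`.
#' @param t_span numeric length-2 simulation span (s).
#' @param dt integration step (s); must not exceed `input$dt_noise`.
#' @param mode `"feedback"` (bilateral coupling) or `"feedforward"` (glial
#'   compartment driven by, but not influencing, the neural one).
#' @param init initial [makeState()] vector, or `NULL` for the full-system
#'   fixed point at `p = p_bar` (see [fullFixedPoint()]).
#' @param clamp clamp concentrations at 0 after each step?
#' @return Object of class `"gliamass_sim"`: list with `t` (uniform grid),
#'   `states` (`(n+1) x 14` matrix, columns [STATE_VARS]), `lfp`
#'   (`y1 - y2`, mV), `input_trace` (realized drive, 1/s), and `metadata`
#'   (resolved input, events, `dt`, `mode`, `clamp`, initial parameters).
#' @examples
#' \donttest{
#' sim <- simulateModel(modelParams(), inputSpec(seed = 7), t_span = c(0, 5))
#' range(sim$lfp)
#' }
#' @export
simulateModel <- function(params, input = inputSpec(), events = NULL,
                          t_span = c(0, 60), dt = 1e-3,
                          mode = c("feedback", "feedforward"),
                          init = NULL, clamp = FALSE) {
  mode <- match.arg(mode)
  validateParams(params)
  input <- resolveInput(input, params)
  if (dt <= 0) stop("simulateModel: dt must be > 0")
  if (dt > input$dt_noise + 1e-15)
    stop("simulateModel: dt must not exceed the noise interval dt_noise")
  if (length(t_span) != 2 || t_span[2] <= t_span[1])
    stop("simulateModel: invalid t_span")
  n <- round((t_span[2] - t_span[1]) / dt)
  t <- t_span[1] + dt * (0:n)
  p_seq <- realizeDrive(input, n, dt)

  if (is.null(init)) {
    init <- tryCatch(fullFixedPoint(params, input$p_bar, mode)$state,
                     error = function(e) NULL)
    if (is.null(init)) {
      # fall back to the origin plus a discarded 5-s transient
      burn <- .integrate_core(unname(makeState()),
                              rep(input$p_bar, round(5 / dt)), dt,
                              unname(flatParams(params)),
                              mode == "feedback", clamp)
      if (!burn$completed) stop("simulateModel: burn-in diverged")
      init <- burn$states[nrow(burn$states), ]
    }
  }
  init <- asState(init)
  if (any(!is.finite(init))) stop("simulateModel: non-finite initial state")

  ev_steps <- data.frame(step = integer(), type = character(), i = integer())
  if (!is.null(events)) {
    stopifnot(inherits(events, "gliamass_events"))
    for (kind in c("boluses", "switches")) {
      df <- events[[kind]]
      if (is.null(df)) next
      stp <- round((df$time - t_span[1]) / dt)
      if (any(stp < 0 | stp > n))
        stop("simulateModel: event times must lie within t_span")
      ev_steps <- rbind(ev_steps,
                        data.frame(step = stp, type = kind,
                                   i = seq_len(nrow(df))))
    }
  }

  pars_now <- flatParams(params)
  state <- unname(init)
  breaks <- sort(unique(c(0L, ev_steps$step, n)))
  states <- matrix(NA_real_, n + 1, 14, dimnames = list(NULL, STATE_VARS))
  neg <- FALSE
  for (k in seq_len(length(breaks) - 1)) {
    s0 <- breaks[k]; s1 <- breaks[k + 1]
    here <- ev_steps[ev_steps$step == s0, , drop = FALSE]
    for (j in seq_len(nrow(here))) {
      if (here$type[j] == "boluses") {
        b <- events$boluses[here$i[j], ]
        state[match(b$var, STATE_VARS)] <- state[match(b$var, STATE_VARS)] +
          b$amount
      } else {
        sw <- events$switches[here$i[j], ]
        pars_now[sw$param] <- sw$value
        ok <- do.call(modelParams, as.list(pars_now))  # re-validate
        pars_now <- flatParams(ok)
      }
    }
    if (s0 == 0L) states[1, ] <- state
    res <- .integrate_core(state, p_seq[(s0 + 1):s1], dt, unname(pars_now),
                           mode == "feedback", clamp)
    if (!res$completed)
      stop(sprintf(
        "simulateModel: integration blew up at t = %.4f s (non-finite state)",
        t_span[1] + (s0 + res$steps_done) * dt))
    neg <- neg || res$neg_conc
    states[(s0 + 2):(s1 + 1), ] <- res$states[-1, , drop = FALSE]
    state <- res$states[nrow(res$states), ]
  }
  if (neg && !clamp)
    warning(structure(class = c("gliamass_negative_concentration",
                                "warning", "condition"),
                      list(message = paste("a concentration went negative",
                                           "during integration"),
                           call = NULL)))

  structure(list(
    t = t,
    states = states,
    lfp = states[, "y1"] - states[, "y2"],
    input_trace = c(p_seq, p_seq[n]),
    metadata = list(params = params, input = input, events = events,
                    dt = dt, mode = mode, clamp = clamp, t_span = t_span,
                    final_params = do.call(modelParams, as.list(pars_now)))
  ), class = "gliamass_sim")
}

#' @export
print.gliamass_sim <- function(x, ...) {
  md <- x$metadata
  cat(sprintf(
    "<gliamass_sim> %s mode, t in [%g, %g] s, dt = %g s (%d samples)\n",
    md$mode, md$t_span[1], md$t_span[2], md$dt, length(x$t)))
  cat(sprintf("  drive: %s, p_bar = %.3f, sigma = %.3f, seed = %d\n",
              md$input$kind, md$input$p_bar, md$input$sigma, md$input$seed))
  cat(sprintf("  LFP range: [%.2f, %.2f] mV\n",
              min(x$lfp), max(x$lfp)))
  invisible(x)
}

#' @export
plot.gliamass_sim <- function(x, vars = c("lfp", "Glu_e", "GABA_e"), ...) {
  op <- graphics::par(mfrow = c(length(vars), 1), mar = c(3, 4, 1, 1))
  on.exit(graphics::par(op))
  for (v in vars) {
    y <- if (v == "lfp") x$lfp else x$states[, v]
    graphics::plot(x$t, y, type = "l", xlab = "t (s)", ylab = v, ...)
  }
  invisible(x)
}

# Neural state producing prescribed pyramidal / interneuron firing rates
# under feedforward thresholds (used to probe the glial sub-field through
# the full vector field).
driveState <- function(rate_p, rate_i, params) {
  two_e0 <- 2 * params$e0
  if (rate_p <= 0 || rate_p >= two_e0 || rate_i <= 0 || rate_i >= two_e0)
    stop("rates must lie strictly in (0, 2 e0)")
  inv <- function(u, v) v - (1 / params$r) * log(two_e0 / u - 1)
  makeState(y0 = inv(rate_i, params$v0) / params$C3,
            y1 = inv(rate_p, params$v0))
}

#' Fixed point of the astrocytic compartment at frozen neural drive
#'
#' For prescribed population firing rates, the glial subsystem admits a
#' unique fixed point, obtained in closed form for the release fluxes and
#' glutamate balance and by monotone root bracketing for the GABA balance.
#' Local stability is verified numerically (all eigenvalues of the glial
#' Jacobian have negative real part).
#'
#' @param rate_p pyramidal population firing rate (1/s), in `(0, 2 e0)`.
#' @param rate_i interneuron population firing rate (1/s), in `(0, 2 e0)`.
#' @param params a [modelParams()] object.
#' @return List with `state` (named 8-vector: `J_G, dJ_G, Glu_e, Glu_a,
#'   J_gamma, dJ_gamma, GABA_e, GABA_a`), `eigenvalues`, and the input
#'   rates.
#' @export
steadyStateAstro <- function(rate_p, rate_i, params) {
  validateParams(params)
  p <- params
  J_G <- p$W * rate_p / p$w2          # annihilates the J_G block
  J_g <- p$Z * rate_i / p$z2
  Vsum <- p$VG_ae + p$VG_ne
  if (J_G <= 0 || J_G >= Vsum)
    stop(sprintf(paste("steadyStateAstro: glutamate balance unsolvable:",
                       "J_G = %.4g not in (0, total uptake %.4g)"),
                 J_G, Vsum))
  # (VG_ae + VG_ne) * S(Glu_e, s_g, r_g) = J_G
  glu_e <- p$s_g - (1 / p$r_g) * log(Vsum / J_G - 1)
  glu_a <- (p$VG_ae / p$VG_c) * (J_G / Vsum)
  upt_sup <- p$Vgamma_ae + p$Vgamma_ne
  if (J_g >= upt_sup)
    stop(sprintf(paste("steadyStateAstro: GABA balance unsolvable:",
                       "J_gamma = %.4g >= total uptake capacity %.4g"),
                 J_g, upt_sup))
  bal <- function(g) p$Vgamma_ae * hillUptake(g, p$Kgamma_ae) +
    p$Vgamma_ne * hillUptake(g, p$Kgamma_ne) - J_g
  if (J_g <= 0) {
    gaba_e <- 0
  } else {
    hi <- 1
    while (bal(hi) < 0) hi <- hi * 2
    gaba_e <- uniroot(bal, c(0, hi), tol = 1e-13)$root
  }
  gaba_a <- (p$Vgamma_ae / p$Vgamma_c) * hillUptake(gaba_e, p$Kgamma_ae)
  st <- c(J_G = J_G, dJ_G = 0, Glu_e = glu_e, Glu_a = glu_a,
          J_gamma = J_g, dJ_gamma = 0, GABA_e = gaba_e, GABA_a = gaba_a)

  # numerical stability check through the full vector field (glial block)
  gidx <- 7:14
  base <- driveState(rate_p = min(max(rate_p, 1e-9), 2 * p$e0 - 1e-9),
                     rate_i = min(max(rate_i, 1e-9), 2 * p$e0 - 1e-9),
                     params)
  gfun <- function(g) {
    full <- base
    full[gidx] <- g
    unname(vectorField(full, p = 0, params, mode = "feedforward")[gidx])
  }
  J <- pracma::jacobian(gfun, unname(st))
  ev <- eigen(J, only.values = TRUE)$values
  if (any(Re(ev) >= 0))
    warning("steadyStateAstro: fixed point not verified stable")
  list(state = st, eigenvalues = ev, rate_p = rate_p, rate_i = rate_i)
}

#' Fixed point of the full coupled system
#'
#' Computes the 14-dimensional equilibrium at constant drive `p`. In
#' feedforward mode the neural equilibrium (thresholds at `v0`) is found on
#' the stable lower branch when it exists (upper branch otherwise) and the
#' glial fixed point follows from [steadyStateAstro()]. In feedback mode the
#' neural and glial blocks are solved self-consistently by damped fixed-point
#' iteration on the extracellular concentrations.
#'
#' @param params a [modelParams()] object.
#' @param p constant drive (1/s).
#' @param mode `"feedback"` or `"feedforward"`.
#' @param tol convergence tolerance on the concentration update (uM).
#' @param maxit iteration budget.
#' @return List with `state` (named 14-vector), `converged`, `iterations`.
#' @export
fullFixedPoint <- function(params, p, mode = c("feedback", "feedforward"),
                           tol = 1e-12, maxit = 200) {
  mode <- match.arg(mode)
  validateParams(params)
  neuralEq <- function(v1, v2) {
    sn <- findSaddleNodes(v1, v2, params)
    ymax <- 2 * params$A * params$e0 / params$a
    eps <- 1e-9 * ymax
    froot <- function(y) equilibriumInput(y, v1, v2, params) - p
    if (p < sn$sn1$p) {
      y0 <- uniroot(froot, c(eps, sn$sn1$y0), tol = 1e-14)$root
    } else if (p > sn$sn2$p) {
      y0 <- uniroot(froot, c(sn$sn2$y0, ymax - eps), tol = 1e-14)$root
    } else stop("fullFixedPoint: no equilibrium branch found at this p")
    y0
  }
  if (mode == "feedforward") {
    y0 <- neuralEq(0, 0)
    neq <- equilibriumState(y0, 0, 0, params)
    rate_p <- params$a * y0 / params$A
    rate_i <- firingRate(params$C3 * y0, params$v0, params)
    ast <- steadyStateAstro(rate_p, rate_i, params)
    return(list(state = asState(c(neq, ast$state)), converged = TRUE,
                iterations = 0L))
  }
  glu <- 0; gaba <- 0
  for (it in seq_len(maxit)) {
    th <- feedbackThresholds(glu, gaba, params)
    y0 <- neuralEq(th$v1, th$v2)
    rate_p <- params$a * y0 / params$A
    rate_i <- firingRate(params$C3 * y0, params$v0 - th$v1, params)
    ast <- steadyStateAstro(rate_p, rate_i, params)
    glu_new <- unname(ast$state["Glu_e"])
    gaba_new <- unname(ast$state["GABA_e"])
    delta <- max(abs(glu_new - glu), abs(gaba_new - gaba))
    glu <- glu + 0.5 * (glu_new - glu)
    gaba <- gaba + 0.5 * (gaba_new - gaba)
    if (delta < tol) {
      th <- feedbackThresholds(glu, gaba, params)
      y0 <- neuralEq(th$v1, th$v2)
      neq <- equilibriumState(y0, th$v1, th$v2, params)
      rate_p <- params$a * y0 / params$A
      rate_i <- firingRate(params$C3 * y0, params$v0 - th$v1, params)
      ast <- steadyStateAstro(rate_p, rate_i, params)
      return(list(state = asState(c(neq, ast$state)), converged = TRUE,
                  iterations = it))
    }
  }
  stop("fullFixedPoint: fixed-point iteration did not converge")
}
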