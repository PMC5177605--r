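test_that("drive construction honors the constant/degenerate/seed contracts", {
  p <- defaultParams()
  f <- makeInput(inputSpec(kind = "constant", p_bar = 90), c(0, 10))
  expect_identical(f(c(0, 3.3, 10)), c(90, 90, 90))
  # zero-variance gaussian degenerates to the constant drive
  g0 <- makeInput(inputSpec(p_bar = 90, sigma = 0, seed = 2), c(0, 10))
  expect_identical(g0(seq(0, 10, 0.05)), rep(90, 201))
  # same seed -> bitwise-identical sample path; different seed differs
  g1 <- makeInput(inputSpec(p_bar = 90, seed = 7), c(0, 10))
  g2 <- makeInput(inputSpec(p_bar = 90, seed = 7), c(0, 10))
  g3 <- makeInput(inputSpec(p_bar = 90, seed = 8), c(0, 10))
  tt <- seq(0, 10, 0.01)
  expect_identical(g1(tt), g2(tt))
  expect_false(identical(g1(tt), g3(tt)))
  # piecewise-constant over the refresh interval
  expect_identical(g1(0.31), g1(0.39))
  expect_error(inputSpec(sigma = -1), "sigma")
})

test_that("a full-system fixed point persists under constant drive", {
  p <- defaultParams()
  fp <- fullFixedPoint(p, 85, "feedback")
  sim <- simulateModel(p, inputSpec(kind = "constant", p_bar = 85),
                       t_span = c(0, 10), init = fp$state)
  expect_lt(max(abs(sweep(sim$states, 2, fp$state))), 1e-8)
  expect_equal(sim$lfp, sim$states[, "y1"] - sim$states[, "y2"])
})

test_that("the integrator self-converges at high order in dt", {
  p <- defaultParams()
  init <- makeState(y0 = 0.05, y1 = 5, y2 = 2, Glu_e = 3, GABA_e = 1)
  endp <- function(dt) {
    s <- simulateModel(p, inputSpec(kind = "constant", p_bar = 95),
                       t_span = c(0, 5), dt = dt, init = init)
    s$states[nrow(s$states), ]
  }
  d12 <- max(abs(endp(2e-3) - endp(1e-3)))
  d23 <- max(abs(endp(1e-3) - endp(5e-4)))
  # RK4: halving dt should shrink the error by ~2^4
  expect_gt(d12 / d23, 8)
})

test_that("identical seed, params and events reproduce the trajectory", {
  p <- defaultParams()
  ev <- eventSchedule(boluses = data.frame(time = 1, var = "GABA_e",
                                           amount = 5))
  s1 <- simulateModel(p, inputSpec(seed = 3), events = ev, t_span = c(0, 4))
  s2 <- simulateModel(p, inputSpec(seed = 3), events = ev, t_span = c(0, 4))
  expect_identical(s1$states, s2$states)
  expect_identical(s1$input_trace, s2$input_trace)
})

test_that("boluses increment state and switches change parameters mid-run", {
  p <- defaultParams()
  ev <- eventSchedule(
    boluses = data.frame(time = 2, var = "GABA_e", amount = 20),
    switches = data.frame(time = 3, param = "VG_ae", value = 0))
  sim <- simulateModel(p, inputSpec(kind = "constant", p_bar = 85),
                       t_span = c(0, 4), events = ev)
  i2 <- which.min(abs(sim$t - 2))
  jump <- sim$states[i2 + 1, "GABA_e"] - sim$states[i2, "GABA_e"]
  expect_gt(jump, 19)  # instantaneous 20-unit increment (minus one dt decay)
  expect_equal(sim$metadata$final_params$VG_ae, 0)
  expect_equal(sim$metadata$params$VG_ae, 4.5)  # initial params preserved
  expect_error(
    simulateModel(p, inputSpec(), t_span = c(0, 1), events =
      eventSchedule(boluses = data.frame(time = 5, var = "GABA_e",
                                         amount = 1))),
    "within t_span")
})

test_that("event schedules validate their tables", {
  expect_error(eventSchedule(boluses = data.frame(time = c(2, 1),
                                                  var = "GABA_e",
                                                  amount = 1)),
               "strictly increasing")
  expect_error(eventSchedule(boluses = data.frame(time = 1, var = "nope",
                                                  amount = 1)),
               "unknown state variable")
  expect_error(eventSchedule(switches = data.frame(time = 1, param = "zz",
                                                   value = 0)),
               "unknown parameter")
})

test_that("astrocytic fixed point solves the glial balances and is stable", {
  p <- defaultParams()
  ss <- steadyStateAstro(0.5, 0.3, p)
  st <- ss$state
  # release-flux balances
  expect_equal(unname(st["J_G"]), p$W * 0.5 / p$w2)
  expect_equal(unname(st["J_gamma"]), p$Z * 0.3 / p$z2)
  # astrocytic glutamate mirrors the uptake fraction
  expect_equal(unname(st["Glu_a"]),
               (p$VG_ae / p$VG_c) *
                 sigmoidGate(st[["Glu_e"]], p$s_g, p$r_g),
               tolerance = 1e-10)
  expect_true(all(Re(ss$eigenvalues) < 0))
  # vanishing interneuron drive: GABA balance collapses to zero
  ss0 <- steadyStateAstro(0.5, 1e-12, p)
  expect_lt(ss0$state[["J_gamma"]], 1e-11)
  expect_lt(ss0$state[["GABA_e"]], 1e-10)
  # unsolvable glutamate balance reported explicitly
  expect_error(steadyStateAstro(4.9, 0.3, p), "glutamate balance")
})

test_that("the astrocytic fixed point is unique and stationary dynamically", {
  p <- defaultParams()
  ss <- steadyStateAstro(0.4, 0.25, p)
  # embed at frozen neural drive and integrate 20 s: must stay put
  two_e0 <- 2 * p$e0
  inv <- function(u, v) v - (1 / p$r) * log(two_e0 / u - 1)
  init <- makeState(y0 = inv(0.25, p$v0) / p$C3, y1 = inv(0.4, p$v0))
  init[7:14] <- ss$state
  d <- vectorField(init, 0, p, "feedforward")
  expect_lt(max(abs(d[7:14])), 1e-9)
  # integrate the glial block 20 s at frozen neural drive (RK4 oracle loop)
  gfield <- function(g) {
    st <- init; st[7:14] <- g
    unname(vectorField(st, 0, p, "feedforward")[7:14])
  }
  g <- unname(ss$state); dt <- 0.01
  for (i in seq_len(2000)) {
    k1 <- gfield(g); k2 <- gfield(g + dt / 2 * k1)
    k3 <- gfield(g + dt / 2 * k2); k4 <- gfield(g + dt * k3)
    g <- g + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  expect_lt(max(abs(g - unname(ss$state))), 1e-8)
  # uniqueness: multi-start root searches all land on the same fixed point
  gfun <- function(g) {
    if (any(!is.finite(g)) || any(abs(g) > 1e4)) return(rep(1e8, 8))
    gfield(g)
  }
  set.seed(21)
  for (i in 1:5) {
    x0 <- unname(ss$state) * runif(8, 0.3, 2) + runif(8, 0, 0.3)
    sol <- pracma::fsolve(gfun, x0)
    expect_lt(max(abs(sol$x - unname(ss$state))), 1e-6)
  }
})

test_that("negative-concentration drift warns and clamping suppresses it", {
  p <- defaultParams()
  # from the origin the glutamate efflux sigmoid is positive while the
  # release flux is still zero, so Glu_e dips below 0 transiently
  init <- makeState()
  expect_warning(
    simulateModel(p, inputSpec(kind = "constant", p_bar = 1e-6),
                  t_span = c(0, 2), init = init),
    class = "gliamass_negative_concentration")
  simc <- suppressWarnings(
    simulateModel(p, inputSpec(kind = "constant", p_bar = 1e-6),
                  t_span = c(0, 2), init = init, clamp = TRUE))
  expect_true(all(simc$states[, c("Glu_e", "Glu_a", "GABA_e", "GABA_a")]
                  >= 0))
})
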