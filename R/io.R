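# Configuration files, trajectory serialization, and the synthetic LFP
# fixture generator used to test the spike-detection stage in isolation.

CONFIG_SECTIONS <- c("params", "input", "integration", "events")

#' Load a run configuration
#'
#' Reads a YAML configuration with optional sections `params` (flat
#' key-value overrides named by the parameter symbols), `input` (fields of
#' [inputSpec()]), `integration` (`dt`, `dt_noise`, `t_span`, `mode`,
#' `clamp`) and `events` (`boluses` / `switches` tables). Unknown sections
#' or keys are rejected with the offending key path; omitted parameters take
#' the reference defaults, so an empty file yields the default model. The
#' bundled file `system.file("extdata", "default_params.yaml", package =
#' "gliamass")` reproduces the default parameter set exactly.
#'
#' @param path YAML file path.
#' @return List of class `"gliamass_config"` with elements `params`
#'   ([modelParams()]), `input` ([inputSpec()]), `integration` (list) and
#'   `events` ([eventSchedule()] or `NULL`).
#' @export
loadConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), CONFIG_SECTIONS)
  if (length(unknown))
    stop("loadConfig: unknown section(s): ", paste(unknown, collapse = ", "))

  params <- do.call(modelParams, as.list(raw$params %||% list()))

  in_args <- raw$input %||% list()
  bad <- setdiff(names(in_args),
                 c("kind", "p_bar", "sigma", "dt_noise", "seed"))
  if (length(bad))
    stop("loadConfig: unknown input key(s): input.",
         paste(bad, collapse = ", input."))
  input <- do.call(inputSpec, in_args)

  integ <- raw$integration %||% list()
  bad <- setdiff(names(integ), c("dt", "dt_noise", "t_span", "mode", "clamp"))
  if (length(bad))
    stop("loadConfig: unknown integration key(s): integration.",
         paste(bad, collapse = ", integration."))
  integ <- modifyList(list(dt = 1e-3, t_span = c(0, 60),
                           mode = "feedback", clamp = FALSE), integ)
  if (integ$dt <= 0)
    stop("loadConfig: integration.dt must be > 0")
  if (length(integ$t_span) != 2 || integ$t_span[2] <= integ$t_span[1])
    stop("loadConfig: integration.t_span must be an increasing pair")

  events <- NULL
  if (!is.null(raw$events)) {
    bad <- setdiff(names(raw$events), c("boluses", "switches"))
    if (length(bad))
      stop("loadConfig: unknown events key(s): events.",
           paste(bad, collapse = ", events."))
    tab <- function(x) if (is.null(x)) NULL else
      do.call(rbind, lapply(x, as.data.frame))
    events <- eventSchedule(boluses = tab(raw$events$boluses),
                            switches = tab(raw$events$switches))
  }
  structure(list(params = params, input = input, integration = integ,
                 events = events), class = "gliamass_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration
#'
#' Writes a `"gliamass_config"` back to YAML so that
#' `loadConfig(saveConfig(cfg, path))` reproduces `cfg`.
#'
#' @param config a `"gliamass_config"` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
saveConfig <- function(config, path) {
  stopifnot(inherits(config, "gliamass_config"))
  out <- list(params = lapply(unclass(config$params), as.numeric),
              input = Filter(Negate(is.null), unclass(config$input)),
              integration = config$integration)
  if (!is.null(config$events)) {
    df2l <- function(df) if (is.null(df)) NULL else
      lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
    out$events <- Filter(Negate(is.null),
                         list(boluses = df2l(config$events$boluses),
                              switches = df2l(config$events$switches)))
  }
  yaml::write_yaml(out, path)
  invisible(path)
}

#' Export a simulated trajectory as tidy CSV
#'
#' One row per time sample; columns `t`, the 14 state variables in the
#' canonical order ([STATE_VARS]), `lfp`, and the realized drive `p`.
#'
#' @param sim a [simulateModel()] result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSimulationCsv <- function(sim, path) {
  stopifnot(inherits(sim, "gliamass_sim"))
  df <- data.frame(t = sim$t, sim$states, lfp = sim$lfp,
                   p = sim$input_trace)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Synthetic LFP fixture with known spike times
#'
#' Gaussian baseline noise plus `n_spikes` stereotyped Gaussian bumps at
#' well-separated, jittered times — a ground-truth signal for testing
#' [detectSpikes()] in isolation from the dynamical model.
#'
#' @param n_spikes number of bumps (>= 0).
#' @param amplitude bump amplitude (mV).
#' @param noise_sd baseline noise standard deviation (mV).
#' @param duration record length (s).
#' @param dt sampling interval (s).
#' @param width bump width parameter (s).
#' @param seed integer seed.
#' @return List with `t`, `lfp`, and the ground-truth `spike_times`.
#' @export
makeFixtureLfp <- function(n_spikes, amplitude = 10, noise_sd = 0.5,
                           duration = 60, dt = 1e-3, width = 0.05,
                           seed = 1L) {
  if (n_spikes < 0) stop("makeFixtureLfp: n_spikes must be >= 0")
  t <- seq(0, duration, by = dt)
  withLocalSeed(seed, {
    lfp <- rnorm(length(t), sd = noise_sd)
    times <- numeric(0)
    if (n_spikes > 0) {
      slots <- seq(0.1, 0.9, length.out = n_spikes) * duration
      times <- slots + runif(n_spikes, -0.02, 0.02) * duration / n_spikes
      times <- round(times / dt) * dt  # align peaks to the sampling grid
      for (tc in times)
        lfp <- lfp + amplitude * exp(-0.5 * ((t - tc) / width)^2)
    }
    list(t = t, lfp = lfp, spike_times = times)
  })
}
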