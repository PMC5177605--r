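# Scripted in-silico protocols (GABA bolus, astrocytic uptake knockouts),
# the quasi-static p_SNIC(t) trace, and LFP spike / frequency analysis.

#' Detect LFP spikes by robust threshold crossing
#'
#' Upward crossings of `median + k * MAD` of a baseline segment, with a
#' refractory period: each detection is placed at the local maximum of the
#' supra-threshold excursion, and detections closer than `min_isi` to the
#' previous accepted one are discarded. The default `k = 5` targets the NIS
#' regime, where isolated large-amplitude spikes stand far above the
#' quiescent fluctuation.
#'
#' @param lfp numeric series (mV), uniformly sampled.
#' @param t time grid (s) of the same length.
#' @param k MAD multiplier of the detection threshold.
#' @param min_isi refractory period (s).
#' @param baseline optional length-2 time window used for the
#'   median/MAD estimate (defaults to the whole record).
#' @param threshold optional explicit threshold (mV), overriding the robust
#'   estimate.
#' @return Numeric vector of spike (peak) times, strictly increasing.
#' @export
detectSpikes <- function(lfp, t, k = 5, min_isi = 0.3, baseline = NULL,
                         threshold = NULL) {
  stopifnot(length(lfp) == length(t))
  if (is.null(threshold)) {
    base <- if (is.null(baseline)) lfp else
      lfp[t >= baseline[1] & t <= baseline[2]]
    threshold <- median(base) + k * mad(base)
  }
  above <- lfp > threshold
  if (!any(above)) return(numeric(0))
  d <- diff(c(FALSE, above))
  starts <- which(d == 1)
  ends <- which(d == -1) - 1
  if (length(ends) < length(starts)) ends <- c(ends, length(lfp))
  # noise can fragment one excursion into several brief segments; merge
  # segments separated by much less than the refractory period, take the
  # peak of each merged event, then apply the refractory rule
  merge_gap <- min_isi / 4
  grp_start <- starts[1]; grp_end <- ends[1]
  peaks <- numeric(0)
  flush <- function(s, e) {
    seg <- s:e
    t[seg[which.max(lfp[seg])]]
  }
  if (length(starts) > 1) {
    for (i in 2:length(starts)) {
      if (t[starts[i]] - t[grp_end] < merge_gap) {
        grp_end <- ends[i]
      } else {
        peaks <- c(peaks, flush(grp_start, grp_end))
        grp_start <- starts[i]; grp_end <- ends[i]
      }
    }
  }
  peaks <- c(peaks, flush(grp_start, grp_end))
  out <- numeric(0)
  last <- -Inf
  for (tp in peaks) {
    if (tp - last >= min_isi) {
      out <- c(out, tp)
      last <- tp
    }
  }
  out
}

#' Sliding-window spike frequency
#'
#' Spike count in a centered window of width `window`, divided by the
#' effective window length (windows are truncated at the span boundaries),
#' evaluated on a regular grid over `span`.
#'
#' @param spike_times numeric spike times (s).
#' @param window window width (s), > 0.
#' @param span length-2 evaluation span (s).
#' @param dt_out spacing of the evaluation grid (s).
#' @return `data.frame` with columns `t` and `freq` (1/s).
#' @export
spikeFrequency <- function(spike_times, window = 5, span, dt_out = 0.1) {
  if (window <= 0) stop("spikeFrequency: window must be > 0")
  tt <- seq(span[1], span[2], by = dt_out)
  lo <- pmax(tt - window / 2, span[1])
  hi <- pmin(tt + window / 2, span[2])
  cnt <- vapply(seq_along(tt), function(i)
    sum(spike_times >= lo[i] & spike_times < hi[i]), numeric(1))
  data.frame(t = tt, freq = cnt / (hi - lo))
}

#' Settling time of a perturbed series
#'
#' The plateau is estimated as the mean over the final `plateau_frac` of the
#' record; the settling time is the first time `>= t_off` from which the
#' series stays within `rel_tol * |plateau|` of the plateau for the rest of
#' the record. `NA` if the series never settles.
#'
#' @param x numeric series.
#' @param t time grid (s).
#' @param t_off perturbation time (s).
#' @param rel_tol relative tolerance band around the plateau.
#' @param plateau_frac final fraction of the record defining the plateau.
#' @return Settling time (s) or `NA`.
#' @export
settleTime <- function(x, t, t_off, rel_tol = 0.05, plateau_frac = 0.2) {
  stopifnot(length(x) == length(t))
  n <- length(t)
  plat <- mean(x[t >= t[n] - plateau_frac * (t[n] - t[1])])
  within <- abs(x - plat) <= rel_tol * abs(plat)
  # last index with a violation; settled from the next sample onward
  viol <- which(!within)
  first_ok <- if (!length(viol)) 1L else max(viol) + 1L
  if (first_ok > n) return(NA_real_)
  max(t[first_ok], t_off)
}

#' Quasi-static activation-threshold trace along a trajectory
#'
#' Maps the stored extracellular concentrations at every `stride`-th sample
#' to the feedback modulations `(v1, v2)` and to `p_SNIC(v1, v2)`. This is a
#' quasi-static readout: the glial state is treated as frozen at each
#' sample. For a feedforward simulation the neural compartment is uncoupled
#' from the concentrations, so the trace is the constant `p_SNIC(0, 0)`.
#'
#' @param result a [simulateModel()] result.
#' @param params a [modelParams()] object (defaults to the simulation's).
#' @param stride sampling stride (samples).
#' @return `data.frame` with columns `t`, `v1`, `v2`, `p_snic` (fold-loss
#'   samples are `NA`).
#' @export
pSnicTrace <- function(result, params = NULL, stride = 100) {
  stopifnot(inherits(result, "gliamass_sim"))
  if (is.null(params)) params <- result$metadata$params
  idx <- seq(1, length(result$t), by = stride)
  if (result$metadata$mode == "feedforward") {
    p0 <- pSnic(0, 0, params)
    return(data.frame(t = result$t[idx], v1 = 0, v2 = 0, p_snic = p0))
  }
  th <- feedbackThresholds(result$states[idx, "Glu_e"],
                           result$states[idx, "GABA_e"], params)
  key <- paste(signif(th$v1, 10), signif(th$v2, 10))
  uk <- !duplicated(key)
  pu <- vapply(which(uk), function(i)
    tryCatch(pSnic(th$v1[i], th$v2[i], params),
             gliamass_fold_error = function(e) NA_real_), numeric(1))
  data.frame(t = result$t[idx], v1 = th$v1, v2 = th$v2,
             p_snic = pu[match(key, key[uk])])
}

analyzeOutcome <- function(result, params, t_off = NA, settle_var = NULL,
                           spike_k = 5, min_isi = 0.3, window = 5,
                           stride = 100, baseline = NULL) {
  trace <- pSnicTrace(result, params, stride = stride)
  spikes <- detectSpikes(result$lfp, result$t, k = spike_k,
                         min_isi = min_isi, baseline = baseline)
  freq <- spikeFrequency(spikes, window = window,
                         span = range(result$t))
  settle <- NA_real_
  if (!is.na(t_off) && !is.null(settle_var))
    settle <- settleTime(result$states[, settle_var], result$t, t_off)
  structure(list(result = result,
                 v1_trace = trace$v1, v2_trace = trace$v2,
                 p_snic_trace = trace,
                 spike_times = spikes, freq_trace = freq,
                 settle_time = settle, t_off = t_off,
                 settle_var = settle_var),
            class = "gliamass_experiment")
}

#' @export
print.gliamass_experiment <- function(x, ...) {
  cat("<gliamass_experiment>\n")
  print(x$result)
  cat(sprintf("  %d LFP spikes detected", length(x$spike_times)))
  if (!is.na(x$t_off))
    cat(sprintf("; perturbation at t = %g s, settle time = %s s",
                x$t_off,
                if (is.na(x$settle_time)) "NA" else
                  format(x$settle_time, digits = 4)))
  cat("\n")
  invisible(x)
}

#' GABA bolus protocol
#'
#' Injects an instantaneous amount of GABA into the extracellular space at
#' `t = 0` and simulates the response. In feedforward mode the neural
#' trajectory is unaffected by construction (decoupling control); in
#' feedback mode the raised GABA concentration lifts the activation
#' threshold `p_SNIC` above the mean drive and silences the population
#' until the concentration has relaxed.
#'
#' @param params a [modelParams()] object.
#' @param amount bolus amount (uM), >= 0.
#' @param input an [inputSpec()].
#' @param mode `"feedback"` or `"feedforward"`.
#' @param t_span simulation span (s); the bolus is applied at its start.
#' @param dt integration step (s).
#' @param stride sampling stride of the `p_SNIC` trace.
#' @return Object of class `"gliamass_experiment"` (simulation, feedback
#'   traces, `p_SNIC` trace, spike times, frequency trace).
#' @export
gabaBolusExperiment <- function(params, amount = 20, input = inputSpec(),
                                mode = c("feedback", "feedforward"),
                                t_span = c(0, 40), dt = 1e-3,
                                stride = 100) {
  mode <- match.arg(mode)
  if (amount < 0) stop("gabaBolusExperiment: amount must be >= 0")
  ev <- if (amount > 0)
    eventSchedule(boluses = data.frame(time = t_span[1], var = "GABA_e",
                                       amount = amount)) else NULL
  sim <- simulateModel(params, input = input, events = ev, t_span = t_span,
                       dt = dt, mode = mode)
  analyzeOutcome(sim, params, stride = stride)
}

#' Astrocytic uptake-deficiency protocol
#'
#' Disables the astrocytic uptake of GABA (`Vgamma_ae = 0`, default switch
#' time 40 s) or glutamate (`VG_ae = 0`, default switch time 20 s) partway
#' through a feedback-mode simulation under Gaussian drive, and returns the
#' full outcome: spike times, windowed spike frequency, the `p_SNIC(t)`
#' trace, and the settling time of the perturbed extracellular
#' concentration (`GABA_e` or `Glu_e`).
#'
#' @param params a [modelParams()] object.
#' @param which `"gaba"` or `"glutamate"`.
#' @param t_off knockout time (s); defaults 40 (gaba) / 20 (glutamate).
#' @param input an [inputSpec()].
#' @param mode coupling mode (the protocol is meaningful in `"feedback"`).
#' @param t_span simulation span (s); default `c(0, 100)` for gaba,
#'   `c(0, 60)` for glutamate.
#' @param dt integration step (s).
#' @param stride sampling stride of the `p_SNIC` trace.
#' @return Object of class `"gliamass_experiment"`.
#' @export
uptakeDeficiencyExperiment <- function(params,
                                       which = c("gaba", "glutamate"),
                                       t_off = NULL, input = inputSpec(),
                                       mode = c("feedback", "feedforward"),
                                       t_span = NULL, dt = 1e-3,
                                       stride = 100) {
  which <- match.arg(which)
  mode <- match.arg(mode)
  if (is.null(t_off)) t_off <- if (which == "gaba") 40 else 20
  if (is.null(t_span)) t_span <- if (which == "gaba") c(0, 100) else c(0, 60)
  if (t_off <= t_span[1] || t_off >= t_span[2])
    stop("uptakeDeficiencyExperiment: t_off must lie inside t_span")
  par_name <- if (which == "gaba") "Vgamma_ae" else "VG_ae"
  settle_var <- if (which == "gaba") "GABA_e" else "Glu_e"
  ev <- eventSchedule(switches = data.frame(time = t_off, param = par_name,
                                            value = 0))
  sim <- simulateModel(params, input = input, events = ev, t_span = t_span,
                       dt = dt, mode = mode)
  analyzeOutcome(sim, params, t_off = t_off, settle_var = settle_var,
                 stride = stride, baseline = c(t_span[1], t_off))
}

#' Pre/post spike-frequency comparison around a perturbation
#'
#' Mean spike frequency in a pre-perturbation window
#' `[t_off - pre_len, t_off]`, a transient window immediately after the
#' perturbation, and a steady post window starting at the settling time of
#' the perturbed concentration (or, if it never settles, at the midpoint
#' between `t_off` and the end of the record).
#'
#' @param exp_out a `"gliamass_experiment"` from
#'   [uptakeDeficiencyExperiment()].
#' @param pre_len length of the pre window (s).
#' @param transient_len length of the transient window (s).
#' @return Named numeric `c(pre, transient, post)` mean frequencies (1/s).
#' @export
frequencyShift <- function(exp_out, pre_len = 15, transient_len = 10) {
  stopifnot(inherits(exp_out, "gliamass_experiment"),
            !is.na(exp_out$t_off))
  t_off <- exp_out$t_off
  tr <- range(exp_out$result$t)
  post_start <- exp_out$settle_time
  if (is.na(post_start)) post_start <- t_off + (tr[2] - t_off) / 2
  post_start <- min(post_start, tr[2] - 1)
  win_rate <- function(a, b) {
    a <- max(a, tr[1]); b <- min(b, tr[2])
    sum(exp_out$spike_times >= a & exp_out$spike_times < b) / (b - a)
  }
  c(pre = win_rate(t_off - pre_len, t_off),
    transient = win_rate(t_off, t_off + transient_len),
    post = win_rate(post_start, tr[2]))
}
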