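# Full state vector and vector field of the coupled system.

#' State variable ordering
#'
#' The 14 dynamical variables, in the fixed order used by every function and
#' serialized trajectory in the package:
#' `y0, y1, y2` (population output / excitatory input / inhibitory input of
#' the pyramidal population, mV), `y3, y4, y5` (their time derivatives,
#' mV/s), `J_G, dJ_G` (glutamate release flux, uM/s, and its derivative),
#' `Glu_e, Glu_a` (extracellular / astrocytic glutamate, uM), `J_gamma,
#' dJ_gamma` (GABA release flux and derivative), `GABA_e, GABA_a`
#' (extracellular / astrocytic GABA, uM).
#'
#' @format Character vector of length 14.
#' @export
STATE_VARS <- c("y0", "y1", "y2", "y3", "y4", "y5",
                "J_G", "dJ_G", "Glu_e", "Glu_a",
                "J_gamma", "dJ_gamma", "GABA_e", "GABA_a")

#' Build a full model state
#'
#' @param ... named components among [STATE_VARS]; unspecified entries are 0.
#' @return Named numeric vector of length 14 in canonical order.
#' @examples
#' makeState(GABA_e = 20)
#' @export
makeState <- function(...) {
  s <- setNames(numeric(14), STATE_VARS)
  over <- list(...)
  if (length(over)) {
    unknown <- setdiff(names(over), STATE_VARS)
    if (length(unknown))
      stop("unknown state variable(s): ", paste(unknown, collapse = ", "))
    s[names(over)] <- unlist(over)
  }
  s
}

asState <- function(x) {
  if (length(x) != 14) stop("state must have length 14")
  if (!is.null(names(x)) && !identical(names(x), STATE_VARS) &&
      all(names(x) %in% STATE_VARS))
    x <- x[STATE_VARS]
  setNames(as.numeric(x), STATE_VARS)
}

#' Vector field of the coupled neuron-astrocyte model
#'
#' Time derivatives of the 14 state variables at one instant. In
#' `"feedforward"` mode the excitability thresholds are fixed at `v0` (the
#' glial compartment is driven by, but does not influence, the neural one);
#' in `"feedback"` mode `vP` and `vI` are computed from the current
#' extracellular glutamate and GABA concentrations via
#' [feedbackThresholds()].
#'
#' @param state named numeric state vector (see [STATE_VARS], [makeState()]).
#' @param p external excitatory drive on the pyramidal population (1/s).
#' @param params a [modelParams()] object.
#' @param mode `"feedback"` (default) or `"feedforward"`.
#' @return Named numeric vector of the 14 time derivatives.
#' @examples
#' vectorField(makeState(), p = 90, modelParams())
#' @export
vectorField <- function(state, p, params,
                        mode = c("feedback", "feedforward")) {
  mode <- match.arg(mode)
  s <- asState(state)
  if (any(!is.finite(s)) || !is.finite(p))
    stop("vectorField: non-finite state or input")
  d <- .rhs_core(unname(s), p, unname(flatParams(params)),
                 mode == "feedback")
  setNames(d, STATE_VARS)
}
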