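# Parameter handling for the coupled neuron-astrocyte mass model.
#
# All parameters are stored flat, keyed by their conventional symbols, in a
# fixed canonical order shared with the compiled core. Defaults reproduce the
# reference parameterization of the model (NIS regime).

PARAM_NAMES <- c(
  # neuronal compartment
  "A", "B", "a", "b", "e0", "v0", "r", "C1", "C2", "C3", "C4", "G",
  # glial compartment
  "W", "Z", "w1", "w2", "z1", "z2", "VG_ne", "VG_ae", "s_g", "r_g",
  "Vgamma_ae", "Kgamma_ae", "Vgamma_ne", "Kgamma_ne", "VG_c", "Vgamma_c",
  # excitability-modulation feedbacks
  "v_G", "r_G", "mG_P", "mG_I", "v_gamma", "r_gamma", "m_gamma"
)

NEURONAL_PARAMS <- PARAM_NAMES[1:12]
GLIAL_PARAMS    <- PARAM_NAMES[13:28]
FEEDBACK_PARAMS <- PARAM_NAMES[29:35]

# Parameters that knockout protocols may legitimately set to zero.
ZERO_OK_PARAMS <- c("VG_ae", "Vgamma_ae")

DEFAULT_PARAM_VALUES <- c(
  A = 3.25, B = 22, a = 100, b = 50, e0 = 2.5, v0 = 6, r = 0.56,
  C1 = 135, C2 = 108, C3 = 33.75, C4 = 33.75, G = 40,
  W = 53.6, Z = 53.6, w1 = 90, w2 = 33, z1 = 90, z2 = 33,
  VG_ne = 0.5, VG_ae = 4.5, s_g = 6, r_g = 0.9,
  Vgamma_ae = 2, Kgamma_ae = 8, Vgamma_ne = 5, Kgamma_ne = 24,
  VG_c = 9, Vgamma_c = 9,
  v_G = 30, r_G = 0.15, mG_P = 2.5, mG_I = 1,
  v_gamma = 25, r_gamma = 0.12, m_gamma = 1
)

#' Model parameter set
#'
#' Builds a validated parameter set for the coupled neuron-astrocyte mass
#' model. Any parameter can be overridden by name; unspecified parameters take
#' the reference values (NIS regime of the neural compartment).
#'
#' Parameter groups:
#' \describe{
#'   \item{neuronal}{`A`, `B` (mV): excitatory/inhibitory synaptic gains;
#'     `a`, `b` (1/s): inverse synaptic time constants; `e0` (1/s): half the
#'     maximum population discharge rate; `v0` (mV): basic excitability
#'     threshold; `r` (1/mV): sigmoid stiffness; `C1`--`C4`: connectivity
#'     gains; `G`: direct excitatory self-feedback gain.}
#'   \item{glial}{`W`, `Z` (uM/s) and `w1`, `w2`, `z1`, `z2` (1/s): amplitude
#'     and rate constants of the glutamate/GABA release-flux transfer
#'     dynamics; `VG_ne`, `VG_ae` (uM/s), `s_g` (uM), `r_g` (1/uM):
#'     neuronal/astrocytic glutamate uptake; `Vgamma_ae`, `Vgamma_ne` (uM/s),
#'     `Kgamma_ae`, `Kgamma_ne` (uM): Michaelis-Menten GABA uptake;
#'     `VG_c`, `Vgamma_c` (1/s): astrocytic degradation rates.}
#'   \item{feedback}{`v_G` (uM), `r_G` (1/uM), `mG_P`, `mG_I` (mV): glutamate
#'     feedback on pyramidal cells and interneurons; `v_gamma` (uM),
#'     `r_gamma` (1/uM), `m_gamma` (mV): GABA feedback on pyramidal cells.}
#' }
#'
#' All parameters must be strictly positive, except the astrocytic uptake
#' maxima `VG_ae` and `Vgamma_ae`, which knockout protocols may set to 0.
#'
#' @param ... named numeric overrides, e.g. `modelParams(mG_P = 3.2)`.
#' @param base an existing `"gliamass_params"` object to start from.
#' @return A named list of class `"gliamass_params"`.
#' @examples
#' p <- modelParams()
#' p$A
#' p32 <- modelParams(mG_P = 3.2)
#' @export
modelParams <- function(..., base = NULL) {
  vals <- if (is.null(base)) as.list(DEFAULT_PARAM_VALUES) else {
    stopifnot(inherits(base, "gliamass_params"))
    unclass(base)
  }
  over <- list(...)
  if (length(over)) {
    if (is.null(names(over)) || any(names(over) == ""))
      stop("all parameter overrides must be named")
    unknown <- setdiff(names(over), PARAM_NAMES)
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    vals[names(over)] <- lapply(over, as.numeric)
  }
  p <- structure(vals[PARAM_NAMES], class = "gliamass_params")
  validateParams(p)
  p
}

#' Validate a parameter set
#'
#' Checks finiteness and sign constraints of every model parameter:
#' strictly positive everywhere except the astrocytic uptake maxima
#' (`VG_ae`, `Vgamma_ae`), which may be 0 (knockout).
#'
#' @param params a `"gliamass_params"` object.
#' @return `params`, invisibly; errors on violation.
#' @export
validateParams <- function(params) {
  stopifnot(inherits(params, "gliamass_params"))
  v <- unlist(params)
  if (length(v) != length(PARAM_NAMES) || !identical(names(v), PARAM_NAMES))
    stop("parameter set is missing entries or out of order")
  if (any(!is.finite(v)))
    stop("non-finite parameter(s): ",
         paste(names(v)[!is.finite(v)], collapse = ", "))
  strict <- setdiff(PARAM_NAMES, ZERO_OK_PARAMS)
  bad <- strict[v[strict] <= 0]
  if (length(bad))
    stop("parameter(s) must be strictly positive: ",
         paste(bad, collapse = ", "))
  if (any(v[ZERO_OK_PARAMS] < 0))
    stop("uptake rates VG_ae and Vgamma_ae must be >= 0")
  invisible(params)
}

#' @export
print.gliamass_params <- function(x, ...) {
  cat("<gliamass_params> coupled neuron-astrocyte mass model parameters\n")
  grp <- list(neuronal = NEURONAL_PARAMS, glial = GLIAL_PARAMS,
              feedback = FEEDBACK_PARAMS)
  for (g in names(grp)) {
    v <- unlist(x[grp[[g]]])
    cat("  ", g, ":\n    ", sep = "")
    cat(paste0(names(v), "=", format(v, trim = TRUE)), sep = " ", fill = TRUE)
  }
  invisible(x)
}

# Flat numeric vector in the canonical order consumed by the compiled core.
flatParams <- function(params) {
  validateParams(params)
  unlist(params)[PARAM_NAMES]
}

#' Extract a parameter block
#'
#' @param params a `"gliamass_params"` object.
#' @return Named list with the requested block.
#' @rdname paramBlocks
#' @export
neuronBlock <- function(params) unclass(params)[NEURONAL_PARAMS]

#' @rdname paramBlocks
#' @export
glialBlock <- function(params) unclass(params)[GLIAL_PARAMS]

#' @rdname paramBlocks
#' @export
feedbackBlock <- function(params) unclass(params)[FEEDBACK_PARAMS]
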