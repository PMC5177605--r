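# Shared fixtures for the gliamass test suite.

defaultParams <- function(...) modelParams(...)

# Extracellular concentration producing a prescribed glutamate modulation v1
# (inverse of the feedback sigmoid); likewise for GABA/v2.
gluForV1 <- function(v1, p) p$v_G - (1 / p$r_G) * log(p$mG_I / v1 - 1)
gabaForV2 <- function(v2, p) {
  p$v_gamma - (1 / p$r_gamma) * log(p$m_gamma / v2 - 1)
}

# Neural block of the vector field as a function of (y0..y5) with the glial
# concentrations frozen at prescribed modulations -- used for brute-force
# root finding and finite-difference Jacobians.
neuralField <- function(p, pdrive, v1 = 0, v2 = 0) {
  if (v1 > 0 || v2 > 0) {
    st0 <- makeState(Glu_e = gluForV1(v1, p), GABA_e = gabaForV2(v2, p))
    mode <- "feedback"
  } else {
    st0 <- makeState()
    mode <- "feedforward"
  }
  function(x) {
    st <- st0
    st[1:6] <- x
    unname(vectorField(st, pdrive, p, mode)[1:6])
  }
}
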