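# Reference parameter set of the coupled neuron-astrocyte mass model
# (NIS regime of the neural compartment). Keys are the conventional symbols.
params:
  A: 3.25
  B: 22.0
  a: 100.0
  b: 50.0
  e0: 2.5
  v0: 6.0
  r: 0.56
  C1: 135.0
  C2: 108.0
  C3: 33.75
  C4: 33.75
  G: 40.0
  W: 53.6
  Z: 53.6
  w1: 90.0
  w2: 33.0
  z1: 90.0
  z2: 33.0
  VG_ne: 0.5
  VG_ae: 4.5
  s_g: 6.0
  r_g: 0.9
  Vgamma_ae: 2.0
  Kgamma_ae: 8.0
  Vgamma_ne: 5.0
  Kgamma_ne: 24.0
  VG_c: 9.0
  Vgamma_c: 9.0
  v_G: 30.0
  r_G: 0.15
  mG_P: 2.5
  mG_I: 1.0
  v_gamma: 25.0
  r_gamma: 0.12
  m_gamma: 1.0
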