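// Compiled core: vector field of the coupled neuron-astrocyte mass model and
// a fixed-step RK4 integrator with piecewise-constant (frozen) stochastic drive.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Parameter layout (must match PARAM_NAMES in R/params.R)
enum {
  iA, iB, ia, ib, ie0, iv0, ir, iC1, iC2, iC3, iC4, iG,
  iW, iZ, iw1, iw2, iz1, iz2, iVG_ne, iVG_ae, is_g, ir_g,
  iVg_ae, iKg_ae, iVg_ne, iKg_ne, iVG_c, iVg_c,
  iv_G, ir_G, imG_P, imG_I, iv_gamma, ir_gamma, im_gamma,
  NPAR
};

// Overflow-safe logistic: 1 / (1 + exp(r * (th - x)))
static inline double sig(double x, double th, double r) {
  double u = r * (th - x);
  if (u > 700.0) u = 700.0;
  if (u < -700.0) u = -700.0;
  if (u > 0.0) {
    double e = std::exp(-u);
    return e / (1.0 + e);
  }
  return 1.0 / (1.0 + std::exp(u));
}

// State layout: y0 y1 y2 y3 y4 y5 J_G dJ_G Glu_e Glu_a J_gamma dJ_gamma GABA_e GABA_a
static void rhs(const double* s, double p, const double* P, bool feedback,
                double* d) {
  double vP = P[iv0], vI = P[iv0];
  if (feedback) {
    double v1 = P[imG_I] * sig(s[8], P[iv_G], P[ir_G]);
    double v2 = P[im_gamma] * sig(s[12], P[iv_gamma], P[ir_gamma]);
    vP = P[iv0] + v2 - (P[imG_P] / P[imG_I]) * v1;
    vI = P[iv0] - v1;
  }
  const double twoe0 = 2.0 * P[ie0];
  const double a = P[ia], b = P[ib], A = P[iA], B = P[iB];
  double ratP  = twoe0 * sig(s[1] - s[2], vP, P[ir]);
  double ratPp = twoe0 * sig(P[iC1] * s[0], P[iv0], P[ir]);
  double ratI  = twoe0 * sig(P[iC3] * s[0], vI, P[ir]);

  d[0] = s[3];
  d[1] = s[4];
  d[2] = s[5];
  d[3] = A * a * ratP - 2.0 * a * s[3] - a * a * s[0];
  d[4] = A * a * P[iC2] * ratPp + A * a * P[iG] * ratP
         - 2.0 * a * s[4] - a * a * s[1] + A * a * p;
  d[5] = B * b * P[iC4] * ratI - 2.0 * b * s[5] - b * b * s[2];

  d[6] = s[7];
  d[7] = P[iW] * P[iw1] * ratP - (P[iw1] + P[iw2]) * s[7]
         - P[iw1] * P[iw2] * s[6];
  double sg = sig(s[8], P[is_g], P[ir_g]);
  d[8] = s[6] - (P[iVG_ae] + P[iVG_ne]) * sg;
  d[9] = P[iVG_ae] * sg - P[iVG_c] * s[9];

  d[10] = s[11];
  d[11] = P[iZ] * P[iz1] * ratI - (P[iz1] + P[iz2]) * s[11]
          - P[iz1] * P[iz2] * s[10];
  double hae = s[12] / (s[12] + P[iKg_ae]);
  double hne = s[12] / (s[12] + P[iKg_ne]);
  d[12] = s[10] - P[iVg_ae] * hae - P[iVg_ne] * hne;
  d[13] = P[iVg_ae] * hae - P[iVg_c] * s[13];
}

// [[Rcpp::export(name = ".rhs_core")]]
NumericVector rhs_core(NumericVector state, double p, NumericVector pars,
                       bool feedback) {
  if (state.size() != 14) stop("state must have length 14");
  if (pars.size() != NPAR) stop("parameter vector has wrong length");
  NumericVector out(14);
  rhs(REAL(state), p, REAL(pars), feedback, REAL(out));
  return out;
}

// Fixed-step RK4 over n = length(p_seq) steps; p held constant within a step.
// Returns the trajectory including the initial state ((n+1) x 14).
// [[Rcpp::export(name = ".integrate_core")]]
List integrate_core(NumericVector init, NumericVector p_seq, double dt,
                    NumericVector pars, bool feedback, bool clamp) {
  if (init.size() != 14) stop("init must have length 14");
  if (pars.size() != NPAR) stop("parameter vector has wrong length");
  const int n = p_seq.size();
  NumericMatrix traj(n + 1, 14);
  double s[14], k1[14], k2[14], k3[14], k4[14], tmp[14];
  for (int j = 0; j < 14; ++j) {
    s[j] = init[j];
    traj(0, j) = s[j];
  }
  bool neg_conc = false;
  const int conc_idx[4] = {8, 9, 12, 13};
  const double* P = REAL(pars);

  for (int i = 0; i < n; ++i) {
    const double p = p_seq[i];
    rhs(s, p, P, feedback, k1);
    for (int j = 0; j < 14; ++j) tmp[j] = s[j] + 0.5 * dt * k1[j];
    rhs(tmp, p, P, feedback, k2);
    for (int j = 0; j < 14; ++j) tmp[j] = s[j] + 0.5 * dt * k2[j];
    rhs(tmp, p, P, feedback, k3);
    for (int j = 0; j < 14; ++j) tmp[j] = s[j] + dt * k3[j];
    rhs(tmp, p, P, feedback, k4);
    for (int j = 0; j < 14; ++j)
      s[j] += dt / 6.0 * (k1[j] + 2.0 * k2[j] + 2.0 * k3[j] + k4[j]);

    for (int c = 0; c < 4; ++c) {
      int j = conc_idx[c];
      if (s[j] < 0.0) {
        neg_conc = true;
        if (clamp) s[j] = 0.0;
      }
    }
    bool bad = false;
    for (int j = 0; j < 14; ++j)
      if (!std::isfinite(s[j])) bad = true;
    if (bad) {
      return List::create(_["states"] = traj, _["completed"] = false,
                          _["steps_done"] = i, _["neg_conc"] = neg_conc);
    }
    for (int j = 0; j < 14; ++j) traj(i + 1, j) = s[j];
  }
  return List::create(_["states"] = traj, _["completed"] = true,
                      _["steps_done"] = n, _["neg_conc"] = neg_conc);
}
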