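---
title: "A bilaterally coupled neuron-astrocyte mass model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A bilaterally coupled neuron-astrocyte mass model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliamass)
```

## The model

`gliamass` implements a mesoscopic model of a local neural circuit coupled to
its surrounding astrocytes. The neural compartment is a neural mass with
three populations: a main pyramidal population $P$, a secondary pyramidal
population $P'$ providing an indirect excitatory feedback loop, and an
inhibitory interneuron population $I$; $P$ additionally excites itself
through a direct feedback of gain $G$. Synaptic conversion of pulse density
into postsynaptic potential is the classical second-order ("alpha-kernel")
dynamics with gains $A$, $B$ and rate constants $a$, $b$; conversion of
membrane potential into firing uses the logistic wave-to-pulse function

$$\hat S(x, v) = \frac{2 e_0}{1 + e^{r (v - x)}},$$

with half-maximum rate $e_0$, threshold $v$ and stiffness $r$. The state
variables $y_0$ (output of $P$), $y_1$ (excitatory input to $P$), $y_2$
(inhibitory input to $P$) and their derivatives $y_3, y_4, y_5$ follow the
standard six-dimensional first-order form; the model's principal output is
the local field potential $\mathrm{LFP}(t) = y_1(t) - y_2(t)$. The external
drive $p(t)$ enters the excitatory input equation.

The glial compartment tracks eight further variables: the release fluxes
$J_G$, $J_\gamma$ of glutamate and GABA (each with second-order transfer
dynamics driven by the pyramidal and interneuron firing rates), the
extracellular concentrations $[\mathrm{Glu}]_e$, $[\mathrm{GABA}]_e$, and
the astrocytic pools $[\mathrm{Glu}]_a$, $[\mathrm{GABA}]_a$. Glutamate
clearance (astrocytic $V_G^{ae}$ plus neuronal $V_G^{ne}$) is a sigmoid in
$[\mathrm{Glu}]_e$; GABA clearance is Michaelis-Menten with separate
astrocytic ($V_\gamma^{ae}, K_\gamma^{ae}$) and neuronal
($V_\gamma^{ne}, K_\gamma^{ne}$) transporter kinetics; astrocytic pools
degrade linearly at rates $V_G^c$, $V_\gamma^c$.

The bilateral coupling closes the loop through the excitability thresholds.
The extracellular concentrations define two bounded modulations

$$v_1 = m_G^I\, S([\mathrm{Glu}]_e, v_G, r_G), \qquad
  v_2 = m_\gamma\, S([\mathrm{GABA}]_e, v_\gamma, r_\gamma),$$

and the population thresholds become
$v_P = v_0 + v_2 - (m_G^P / m_G^I)\, v_1$, $v_{P'} = v_0$,
$v_I = v_0 - v_1$: extracellular glutamate facilitates both pyramidal cells
and interneurons (with separate maximal gains $m_G^P$, $m_G^I$), while
extracellular GABA inhibits the pyramidal population. In `"feedforward"`
mode the thresholds stay at $v_0$ and the glial compartment is a pure
read-out; the two modes are the experimental control pair used throughout
the package.

All parameters (`modelParams()`) default to the reference set, which places
the neural compartment in the noise-induced spiking (NIS) regime.

## Bifurcation structure and the activation threshold

For quasi-static $(v_1, v_2)$ the neural equilibria form a graph over
$y_0$: `equilibriumInput()` evaluates the closed form $p = f(y_0, v_1,
v_2)$, obtained by annihilating the six neural equations, on the domain
$0 < y_0 < 2 A e_0 / a$. The curve is S-shaped: two folds (saddle-nodes)
$\mathrm{SN}_1$ and $\mathrm{SN}_2$ bound a middle branch with one unstable
eigenvalue; the upper branch carries an unstable focus that stabilizes at a
supercritical Hopf point. The stable large-amplitude limit cycle born there
terminates at $\mathrm{SN}_1$ in a saddle-node-on-invariant-circle (SNIC)
connection, so $p_{\mathrm{SNIC}} = p_{\mathrm{SN}_1}$ acts as an
activation threshold: below it the population is quiescent, above it the
LFP oscillates. With the reference parameters
$p_{\mathrm{SNIC}}(0, 0) \approx 89.96\,\mathrm{s^{-1}}$ and the Hopf point
sits at $p \approx 354\,\mathrm{s^{-1}}$.

Driving the model with a noisy input whose band straddles
$p_{\mathrm{SNIC}}$ produces NIS: quiescence interrupted by isolated
large-amplitude LFP spikes.

Two structural facts organize everything the package computes about the
threshold map $p_{\mathrm{SNIC}}(v_1, v_2)$:

* **Exact linearity in $v_2$.** $v_2$ enters $f$ only through the additive
  term $(a/A) v_2$ and the fold condition $\partial f / \partial y_0 = 0$
  does not involve $v_2$; hence $y_{\mathrm{SNIC}}$ is $v_2$-independent
  and $p_{\mathrm{SNIC}}$ is affine in $v_2$ with slope $a/A$. Raised
  extracellular GABA always raises the activation threshold.
* **Shape in $v_1$ governed by the gain ratio.** With
  $\chi = B e_0 r C_4 / (2b)$ ($\chi = 10.395$ at the defaults), the
  stationarity condition $\partial f / \partial v_1 = 0$ reduces to a
  quadratic in $X = e^{r (v_0 - v_1 - C_3 y_0)}$ whose roots
  $V_\pm = 2\chi\rho^{-1} - 1 \pm 2\sqrt{\chi\rho^{-1}(\chi\rho^{-1} - 1)}$
  (with $\rho = m_G^P / m_G^I$) are real exactly when $0 < \rho < \chi$ and
  satisfy $V_+ V_- = 1$. `findV1Extrema()` solves the coupled fold +
  stationarity system by a damped fixed-point iteration (factor 0.5,
  budget 200, closed-form update $v_1 = v_0 - C_3 y_0 - \ln V_\pm / r$)
  with a trust-region 2-D root solve as fallback, and confirms the
  extremum type numerically by sampling $p_{\mathrm{SNIC}}$ on a local
  grid — a deliberate numeric stand-in for the bordered-Hessian argument,
  equivalent and directly testable.

A point worth flagging: for the reference parameter family the local
*maximum* candidate $v_1^{**}$ (root $V_-$, paired with the
$\mathrm{SN}_2$ fold) has no solution inside the region where the folds
exist — the iteration exits it at $v_1 \approx 4.5$, well outside the
physical range $[0, m_G^I]$ — so only the minimum $v_1^*$ is realized.
`findV1Extrema()` reports this with `exists = FALSE` rather than erroring.

The interval $[I_1, I_2] = [1.831, 3.161]$ returned by `ratioInterval()`
(endpoints $4\chi (1 - S) S$ with $S$ the interneuron sigmoid at the
$\mathrm{SN}_1$ fold for $v_1 = 0$ and $v_1 = m_G^I$) decides the response
to astrocytic glutamate-uptake deficiency: ratios below $I_1$ give a
monotonically rising threshold (scenario a, reduced activity), above $I_2$
a monotonically falling one (scenario b, sustained hyperexcitability), and
inside the interval an interior minimum (scenario c, transient
hyperexcitability with recovery). All Prop-level quantities are computed at
$v_2 = 0$; since the fold condition is $v_2$-independent, so are $v_1^*$,
$I_1$ and $I_2$.

## Numerical integration and the stochastic drive

The integrator is fixed-step RK4 on the 14-dimensional field, with the
stochastic drive held piecewise constant: `inputSpec()` resamples
$p \sim \mathcal N(\bar p, \sigma^2)$ every `dt_noise` seconds, and the
deterministic field is integrated exactly through each frozen-noise
interval. This keeps the stochastic process well defined (no Ito/
Stratonovich ambiguity) while the deterministic error is $O(\Delta t^4)$;
the suite verifies ~16-fold error reduction per halving of `dt`. Defaults:
`dt = 1e-3` s, `dt_noise = 0.1` s.

The noise refresh interval deserves its own paragraph because it is the one
drive parameter with no principled closed-form choice. The SNIC escape that
produces an LFP spike takes a few hundred milliseconds (the limit-cycle
period just above threshold is about 0.5 s); a drive that decorrelates much
faster than this averages out before an escape can complete, and the model
stays silent no matter how often the band crosses the threshold. A refresh
interval of the order of the spike duration (0.1 s) yields sparse, isolated
spikes at roughly 0.5-1 s$^{-1}$ — the NIS phenomenology — and is the
package default. $\sigma$ is interpreted as a standard deviation (the band
$\bar p \pm \sigma$ is then dimensionally a confidence band), and the
default mean drive is $\bar p = p_{\mathrm{SNIC}}(0,0) - 5$, placing the
band across the threshold.

Boluses are instantaneous state increments at their scheduled grid step;
parameter switches (e.g. the uptake knockouts $V_\gamma^{ae} \to 0$,
$V_G^{ae} \to 0$) re-validate the parameter set and apply from their time
onward. Identical (parameters, seed, dt, events) reproduce trajectories
bitwise. Default initial conditions come from `fullFixedPoint()` — damped
self-consistent iteration between the closed-form neural equilibrium and
the glial fixed point — falling back to the origin plus a discarded 5-s
transient.

Concentrations are integrated as written, without clamping: because the
glutamate efflux sigmoid is strictly positive at zero concentration,
$[\mathrm{Glu}]_e$ can dip below zero under near-zero drive. The simulator
then emits a structured warning (`gliamass_negative_concentration`); an
optional `clamp = TRUE` truncates concentrations at zero after each step.
The published equations are thus preserved by default while degenerate
protocols stay guarded.

## Fold, Hopf and fixed-point localization

`findSaddleNodes()` scans the analytic $\partial f / \partial y_0$ on a
4001-point uniform grid over the open $y_0$ domain (margin
$10^{-6}$ of the domain width) and refines each sign change by bisection to
machine tolerance; exactly two critical points are required, and any other
count raises a structured `gliamass_fold_error` — the analysis presumes the
S-shape, and silently picking folds in other regimes would be misleading.
`stabilitySpectrum()` uses the analytic 6x6 neural Jacobian (checked
against finite differences to $10^{-6}$ relative). `findHopf()` bisects the
real part of the complex eigenvalue pair along the upper branch, taking the
last downward crossing (the first scan point above the fold can carry a
different, spurious pair). Limit-cycle properties are verified by direct
simulation rather than continuation — simpler, and adequate for the checks
the package makes.

## In-silico protocols and LFP analysis

`gabaBolusExperiment()` injects GABA (default 20 uM, treating the model's
arbitrary concentration units as uM throughout) into the extracellular
space at the start of the run. In feedback mode the threshold jumps above
the drive band, the population falls silent, and activity resumes as the
bolus is cleared; in feedforward mode the neural trajectory is — exactly,
bitwise — unaffected.

`uptakeDeficiencyExperiment()` switches an astrocytic uptake maximum to
zero mid-run (defaults: GABA at 40 s in a 100-s run, glutamate at 20 s).
Spike detection uses upward crossings of a robust threshold (baseline
median plus $k = 5$ MADs; NIS spikes are an order of magnitude above the
quiescent fluctuation), a short merge gap for noise-fragmented excursions,
and a 0.3-s refractory period; rates are sliding-window counts. Settling
of a perturbed concentration is defined as the first time after the switch
from which the series stays within 5% of its final plateau (the mean over
the last 20% of the record).

Two timescales matter when interpreting these protocols. First, the
post-knockout GABA relaxation time is approximately
$(G + K_\gamma^{ne})^2 / (V_\gamma^{ne} K_\gamma^{ne})$, a few seconds at
the concentrations reached under the default drive; the settling estimate
is therefore dominated by spike-driven concentration fluctuations unless
the trace is averaged across seeds — the acceptance protocol averages the
concentration over 20 independent drives before measuring settling.
Second, after a glutamate-uptake knockout the extracellular glutamate
rises at roughly 0.5-1 uM/s and must traverse the feedback sigmoid
(threshold $v_G = 30$ uM), which takes of the order of a minute; the
scenario-c signature (transient rise, then recovery) is therefore run on a
160-s horizon with the knockout at 20 s. Problem sizes used by the test
suite — 10-20 seeds per stochastic assertion, 100-160-s runs at 1-ms
steps — were chosen as the smallest that make these signatures
reproducible across seeds.

## What the synthetic fixtures do and do not show

`makeFixtureLfp()` generates Gaussian baseline noise with stereotyped
Gaussian bumps at known times; it is the ground truth for the spike
detector in isolation. It emulates the amplitude separation of NIS spikes,
not their waveform asymmetry, afterhyperpolarization, or rate modulation,
so detector tests on fixtures certify threshold/refractory logic only —
performance on real LFP recordings (drifting baselines, artifacts,
non-stationary noise) is out of scope. Likewise, simulated NIS shares the
paper-level phenomenology (sparse large spikes, threshold modulation by
neurotransmitters) but none of the measurement noise or electrode physics
of experimental LFP, and the model is not subtype-specific for
interneurons nor fitted to any recording.

## Known limitations

* The SNIC is verified through its fold plus the large-period limit cycle,
  not by computing the homoclinic connection itself.
* Fold-loss regions (extreme $v_1$ with the S-shape destroyed) are
  reported as structured errors or `NA` cells, not analyzed.
* The quasi-static $p_{\mathrm{SNIC}}(t)$ trace treats the glial state as
  frozen at each sample; it is a diagnostic, not an exact threshold of the
  coupled nonautonomous system.
* Event times snap to the integration grid; `dt` must not exceed
  `dt_noise`.
* The Hopf criticality is taken as supercritical (confirmed by simulation
  at nearby drives), without center-manifold computation.
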