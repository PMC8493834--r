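---
title: "Modelling and rapid characterization of hERG channel kinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and rapid characterization of hERG channel kinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(hergkinetics)
```

## The model

hERG (Kv11.1) channels carry the rapid delayed-rectifier potassium current
I~Kr~, the dominant repolarizing current of phase 3 of the ventricular
action potential. The package models the current with the standard Ohmic
expression

$$I_{Kr} = g_{Kr}\, O\, (V - E_K),$$

where $g_{Kr}$ is the maximal conductance (µS), $O$ the open probability,
$V$ the transmembrane voltage (mV) and $E_K$ the Nernst potential of K^+^.
Gating factorizes into a three-state activation chain
$C_{2a} \leftrightarrow C_{1a} \leftrightarrow O_a$ — which gives hERG its
characteristic bi-exponential deactivation — and an independent
Hodgkin–Huxley availability (inactivation) gate $h$, with $O = O_a h$:

$$\dot C_{1a} = b_2 O_a + a_1 C_{2a} - (a_2 + b_1) C_{1a}, \qquad
  \dot O_a = a_2 C_{1a} - b_2 O_a, \qquad
  \dot h = (h_\infty - h)/\tau_h,$$

with $C_{2a} = 1 - O_a - C_{1a}$, $h_\infty = a_h/(a_h+b_h)$ and
$\tau_h = 1/(a_h+b_h)$. The six transition rates are exponential in
voltage and defined by twelve kinetic parameters:

| rate | role | expression |
|------|------|------------|
| $a_1$ | $C_{2a} \to C_{1a}$ activation | $p_1 e^{p_2 V}$ |
| $b_1$ | $C_{1a} \to C_{2a}$ deactivation | $p_3 e^{-p_4 V}$ |
| $b_h$ | inactivation | $p_5 e^{p_6 V}$ |
| $a_h$ | recovery from inactivation | $p_7 e^{-p_8 V}$ |
| $a_2$ | $C_{1a} \to O_a$ activation | $p_9 e^{p_{10} V}$ |
| $b_2$ | $O_a \to C_{1a}$ deactivation | $p_{11} e^{-p_{12} V}$ |

Odd-indexed parameters are prefactors (ms^-1^), even-indexed ones voltage
slopes (mV^-1^). The factorized system is exactly equivalent to a
six-state Markov model (states $O, IO, C_1, IC_1, C_2, IC_2$, with
occupancies given by products such as $IO = O_a(1-h)$); the package keeps
both formulations, integrates the factorized one for speed, and retains
the six-state master-equation integrator purely as an equivalence oracle
— a property asserted numerically in the test suite to $10^{-6}$.

This rate-to-parameter mapping is a convention the bundled parameter
values depend on: it assigns $p_{11}$ to deactivation along the
$O \to C_1$ pathway and $(p_3, p_4)$ to the $C_1 \to C_2$ pathway (the
transition whose voltage dependence the activator RPR260243 switches on
by raising $p_4$), with forward rates carrying $e^{+pV}$ and
backward/recovery rates $e^{-pV}$. It is validated numerically: with the
bundled WT values it reproduces the independently measured recovery time
constant at -90 mV (model 1.55 ms vs. measured 1.5 ± 0.3 ms) and the
inactivation midpoint (-32.9 mV vs. -34.3 mV). The bundled parameter
files are only meaningful under this mapping.

### Plausibility band

Evaluated rates are required to lie in $[10^{-7}, 10^3]$ ms^-1^ over
$V \in [-120, +60]$ mV, the voltage range actually visited by the
calibration protocol. Candidate parameter sets violating the band are
rejected, not clipped. (Over a wider range such as $[-140, +60]$ mV the
bundled WT set itself leaves the band — $a_1$ falls to
$7.4\times10^{-8}$ ms^-1^ at $-140$ mV — which is why the band is defined
over the calibration range.)

## Simulation

At fixed voltage the gating system is linear, so the package propagates
states exactly: the 2×2 activation subsystem by eigendecomposition, the
$h$ gate by its closed-form exponential. Voltage protocols are piecewise
constant (steps), linear (ramps, zero-order-hold subdivided at 0.2 ms by
default) or sampled waveforms, so whole traces are computed without
truncation error and integrator restarts at segment boundaries avoid
step smearing. An adaptive stiff integrator (`deSolve::lsoda`, default
tolerances $10^{-8}$) is retained as `method = "ode"`; the two paths
agree to better than $10^{-6}$ in open probability, which the test suite
asserts. A compiled (Rcpp) version of the closed-form propagation drives
the inference inner loop, where a joint fit evaluates on the order of
$10^5$ simulated traces; it is bit-identical to the R implementation.

Default output sampling is 0.1 ms, matching the 10 kHz acquisition of
the experimental design the synthetic data emulate. Multi-sweep step
protocols reset the state to the holding-potential steady state between
sweeps (the experimental inter-sweep interval is "long enough for full
closure"); AP-train and premature-stimulation protocols embed their
holding periods explicitly inside a sweep, so rate-dependent
accumulation across beats is preserved.

## Voltage protocols

Built-in protocols reproduce the standard characterization suite:
step activation (two variants: 250-ms oocyte-style steps at 21 °C;
1,500-ms steps at 37 °C), deactivation (250 ms at +40 mV, then 750-ms
tails), inactivation (500-ms prepulse to +20 mV, 800-ms repolarizing
steps), a premature-stimulation protocol (stylized action potential, then
40-ms steps to 0 mV at coupling intervals from -80 to +380 ms relative to
90 % repolarization), action-potential trains, and a staircase
calibration protocol.

Two waveforms are package-constructed stand-ins rather than published
tables. The stylized action potential is a step to +40 mV, a shallow
plateau ramp to +20 mV and a 320-ms linear repolarization to -100 mV,
sized so the 90 %-repolarization time is ~353 ms after the upstroke; all
of its parameters are user-configurable, and analyses depend on it only
through the 90 %-repolarization anchor. The complex action-potential
train (validation protocol V3) is a deterministic sequence of beats of
varied morphology with one premature depolarization and one
EAD-like interruption; the bundled CSV fixture is generated by
`build_complex_ap_protocol()` and labelled synthetic.

The staircase step table is configuration, not logic: it ships as a CSV
and any table can be substituted. The default table was designed once,
on identifiability grounds, to contain a saturating +40 mV step with a
deep -120 mV tail, an ascending/descending staircase of 250–500-ms steps
spanning -120 to +60 mV, and post-descent tails at -70/-110 mV; with it,
the expected standard errors of the identifiable kinetic parameters
under the reference noise model are 1–6 %.

## Synthetic three-sweep recordings

`generate_cell_recording()` emulates the experimental design used for
rapid characterization: each cell is recorded three times over the full
protocol sequence (staircase C, activation V1, inactivation V2, complex
AP train V3, staircase repeat C2) — first in control solution, then
after wash-in of the activator RPR260243, then after a saturating dose of
the blocker dofetilide. Dofetilide is modelled as complete block, so
sweep 3 contains only leak (and noise) and subtracting it from sweeps 1
and 2 isolates channel current exactly when rundown is off — an identity
the tests exploit. Endogenous currents are folded into the linear leak
term, noise is white Gaussian at the output rate (no 4-kHz filter
emulation), and per-cell variability enters through the conductance, a
voltage offset $V_{\rm off}$ (the channel sees $V_{\rm cmd} - V_{\rm off}$),
and the noise realization. The cell's apparent reversal potential is
reported as $E_K + V_{\rm off}$, which is what a reversal measurement on
its tails recovers — so the inference module can estimate offsets the
same way the experimental analysis does. A rundown knob (fractional
conductance loss per minute of experiment clock, default off) produces
the subtraction residual that rundown causes in practice; its magnitude
is a user choice, not a measured value.

Simplifications to keep in mind: real recordings have capacitive
transients, series-resistance error, filtered (colored) noise, partial
rather than complete block, and drifting leak. Passing tests on this
generator therefore demonstrate correctness of the analysis chain under
its stated assumptions, not robustness to every experimental artifact;
the 1-ms post-step blanking windows used by the biomarker fits exist so
the same code applies unchanged to real traces.

## Joint maximum-likelihood inference

With iid Gaussian noise, maximizing the likelihood of a recording is
least squares, independent of the noise variance ($\sigma$ is profiled
out and reported post hoc from residual variance). The joint scheme
shares one control kinetics block and one activator kinetics block
across cells, with one conductance per cell: $12 + 12 + N$ free
parameters ($27$ for the reference three-cell design). Voltage offsets
are fixed beforehand from measured reversal potentials
($V_{\rm off} = E_{K,\rm measured} - E_K$), not co-estimated.

Because the current is linear in $g_{Kr}$, the per-cell conductances are
profiled out in closed form at every objective evaluation, reducing the
search to the 24 transformed kinetic parameters (log prefactors, linear
slopes; bounds $[10^{-7}, 10^3]$ ms^-1^ and $[0, 0.4]$ mV^-1^). The
optimizer is configuration, not contract: the default is multi-start
(log-uniform/uniform sampling, rejection-resampled to the plausibility
band, which factorizes across the six rate pairs and is therefore
sampled exactly) with a successive-halving allocation — every start
gets a short CMA-ES screen per kinetics block on a coarsened grid, the
best few starts per block get a deep CMA-ES run, survivors are polished
by Levenberg–Marquardt on the full grid, and the best pair is polished
jointly. The landscape genuinely needs the global phase: local
optimization from random starts, and CMA-ES at small evaluation
budgets, reproducibly stall at about twice the statistical noise floor
with near-plausible but wrong kinetics, while the deep runs reach the
floor. During iteration band violations are discouraged by a smooth
penalty (a hard rejection would break the least-squares machinery); the
returned optimum is projected back if it grazes the band along a flat
direction and validated. The calibration fit uses only the
staircase protocol, thinned to 1-ms sampling — thinning iid noise loses
statistical efficiency linearly but leaves estimates unbiased, and the
problem sizes (≈14,000 samples per trace, six traces) keep a
ten-start joint fit to a few minutes on one CPU.

### What is, and is not, identifiable

A Fisher-information analysis at the generating parameters (available in
the test suite's expectations) shows the staircase pins most parameters
to 1–6 % under the reference noise level (2 % of peak current), with two
structural exceptions:

* $p_4$ — the voltage slope of $b_1$ — is effectively zero in the
  control kinetics (~$10^{-7}$ mV^-1^), consistent with a
  voltage-independent $C_1 \to C_2$ transition. Its absolute effect over
  the whole voltage range is ~$10^{-5}$ relative, so its *relative*
  recovery error is unbounded; only an upper bound is learned.
* Under activator kinetics the $O \leftrightarrow C_1$ rates become very
  fast ($p_9, p_{11}$ in the hundreds of ms^-1^), making that transition
  a fast pre-equilibrium with a ~2-µs relaxation time — far below the
  10-kHz bandwidth. Only the ratio $a_2/b_2$ (and the slope sum
  $p_{10}+p_{12}$) is observable; the magnitudes drift freely along a
  likelihood ridge. No protocol sampled at realistic rates can recover
  them individually.

The parameter-recovery tests therefore report errors both over all
parameters and over the practically identifiable subset, and the
prediction-transfer test — fit on the staircase only, predict the
held-out activation, inactivation and complex-AP traces — is the
decisive check that the fitted model is right where it matters: ridge
displacement in unidentifiable directions does not degrade predictions.

## Biomarker analyses

All trace analyses exclude the first 1 ms after each voltage step
(configurable blanking; synthetic traces have no capacitive transient,
but the contract must match real-data use).

* **Deactivation**: two-term exponential fits of tail decays with
  multi-start initialization (log-linear regression on the segment's
  head and tail, eight jittered restarts), time constants relabelled so
  $\tau_f \le \tau_s$, fast fraction $A_f/(A_f+A_s)$; fits with
  amplitude ratio < $10^{-3}$ or $\tau$ ratio < 1.2 are flagged
  effectively mono-exponential.
* **Activation**: peak tail currents after each test step, normalized to
  the maximum, fitted with $y = s/\{1+\exp[(V_{1/2}-V)/k]\}$.
* **Inactivation (rectification method)**: maximal current amplitudes
  during repolarizing steps give the fully activated I–V; the slope of
  its linear region (-140 to -110 mV) is the whole-cell conductance
  $G$; $R = I/[G\,n\,(V_t - E_{\rm rev})]$ with $n$ the activation
  variable at +40 mV; voltages within 5 mV of $E_{\rm rev}$ are masked.
  A characterized bias of this method at physiological-temperature
  kinetics: deactivation at the deep tails used for $G$ is fast enough
  (~6 ms at -140 mV) to truncate the tail peaks, underestimating $G$,
  inflating mid-range $R$, and shifting the fitted midpoint several mV
  depolarized of the instantaneous $h_\infty$ midpoint. The tests pin
  the implementation to a procedure-matched oracle and assert the bias
  direction rather than pretending the closed-form midpoint is
  recovered.
* **Recovery from inactivation**: mono-exponential fit to the rising
  hook phase of the -90 mV tail, from the end of blanking to the hook
  peak — a declared interpretation of the standard hook analysis.
* **Protective currents**: during each 40-ms premature step, a
  single-exponential fit (with offset) extrapolated back to the step
  onset (a flag switches the reference point to the end of blanking),
  normalized to whole-cell conductance; non-decaying segments are
  flagged and fall back to the in-step maximum.
* **AP-clamp metrics**: peak early transient current in a 20-ms window
  after the upstroke of the selected beat, peak resurgent current during
  that beat's repolarization, and the command voltage at the resurgent
  peak; normalization by whole-cell conductance or peak tail current.
  Peaks are signed maxima of outward current, ties broken earliest.
  Note a rate dependence of the transient metric under these kinetics:
  at 1-Hz pacing the diastolic interval is long enough that both
  wild-type and fast-deactivating mutant channels close essentially
  completely, and the upstroke window is dominated by the
  construct-insensitive activation/inactivation race; the
  leftover-open-channel transient that separates constructs emerges at
  rapid pacing (around 2.5 Hz with a short action potential), which is
  also where whole-cell simulations of this model family report the
  difference.

## Numerical choices

* Integration tolerances default to $10^{-8}$ (absolute and relative)
  for the adaptive path; the analytic path is exact.
* Simplex invariants (occupancies in $[0,1]$, sums equal to 1) hold to
  $10^{-10}$ at construction and $10^{-8}$ along trajectories.
* Rate evaluation guards its exponents at ±700 and raises a rate-named
  overflow error instead of returning infinities.
* Degenerate activation chains (both directions of a transition zero)
  are rejected; the chain steady state is computed from spanning-tree
  weights, which stays well-defined when single rates underflow.
* Exponential-fit degeneracy thresholds: amplitude ratio $10^{-3}$,
  $\tau$ ratio 1.2. Boltzmann fits try both slope signs from three
  starts. Ties in peak detection resolve to the earliest sample.
* Conductance profiling clamps to $(10^{-6}, 10]$ µS.

## Problem sizes used by the shipped experiments

The packaged recovery and prediction experiments (tests and the
acceptance script) use the reference three-cell design: generation at
0.5-ms sampling over the five-protocol sequence, fitting on the
staircase thinned to 1 ms (≈14,200 samples per trace, six traces,
26–27 free parameters), ten optimizer starts. These sizes were chosen as
the smallest at which the Fisher-information predictions above are
comfortably resolved; generating at 0.1 ms quadruples cost without
changing any conclusion, because the thinned fitting grid is identical.

## Known limitations

* The generator's noise is white; filtered experimental noise has
  shorter effective sample size per unit time, so real-data parameter
  uncertainties will be somewhat larger than the synthetic ones.
* Dofetilide block is complete and instantaneous; wash-in dynamics and
  partial or state-dependent block are out of scope.
* No temperature scaling of rates (Q10): parameter sets are
  temperature-specific.
* The exported model description (JSON/plain-text equation listing) is a
  hand-off for embedding I~Kr~ in external action-potential simulators;
  whole-cell action-potential simulation itself is out of scope.
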