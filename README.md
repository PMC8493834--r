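# hergkinetics

Kinetic modelling and rapid characterization of hERG (Kv11.1) channel
currents in R.

hERG channels carry I<sub>Kr</sub>, the rapid delayed-rectifier K⁺
current that repolarizes the cardiac action potential; loss of
I<sub>Kr</sub> — by inherited variants such as R56Q or by drug block —
causes long-QT syndrome type 2. This package provides the computational
side of a *rapid characterization* workflow for such variants and for
channel activators (e.g. RPR260243, which slows deactivation): a
mechanistic gating model, the voltage-clamp protocols used to calibrate
and validate it, a generator of realistic synthetic patch-clamp
recordings, joint maximum-likelihood inference of channel kinetics
across cells, and the standard electrophysiological biomarker analyses.

## The model

Current follows the Ohmic expression

$$I_{Kr} = g_{Kr}\,O\,(V - E_K), \qquad O = O_a\,h,$$

with activation described by a three-state Markov chain
$C_{2a}\!\leftrightarrow\!C_{1a}\!\leftrightarrow\!O_a$ (hence
bi-exponential deactivation) and inactivation by a Hodgkin–Huxley
availability gate $h$. The six voltage-dependent transition rates are
two-parameter exponentials, $a = p_{\rm odd}\,e^{\pm p_{\rm even} V}$,
giving twelve kinetic parameters per condition. The factorized system
is exactly equivalent to a six-state Markov model
($O, IO, C_1, IC_1, C_2, IC_2$); the package integrates the factorized
form (closed-form propagation on piecewise-constant voltage) and keeps
the six-state master-equation integrator as a numerical equivalence
oracle. Reference parameter sets for WT and R56Q channels, with and
without the activator RPR260243, ship with the package together with
the cell conductances of the reference three-cell design.

Inference follows the joint scheme used for rapid characterization:
iid-Gaussian noise makes maximum likelihood a least-squares problem;
control and activator kinetics are shared across cells while maximal
conductance is cell-specific (12 + 12 + N parameters — 27 for three
cells); per-cell voltage offsets are fixed from measured reversal
potentials, $V_{\rm off} = E_{K,\rm meas} - E_K$. Models are calibrated
on a single information-rich staircase protocol and validated by
predicting held-out activation, inactivation and complex
action-potential-train recordings.

## Worked example

Simulate a wild-type cell on the staircase calibration protocol, then
measure its deactivation kinetics from a deactivation protocol:

```r
library(hergkinetics)

wt   <- herg_reference_params("WT")
cell <- cell_config(g_kr = 0.0847,            # uS
                    K_out = 4, K_in = 130,    # mM
                    temperature = 310.15)     # K
cell$E_K
#> [1] -93.04192

stair <- build_staircase_protocol()
trace <- simulate_current(wt, stair, cell)
range(trace$current)                           # nA, outward positive
#> [1] -1.748125  3.374013

# deactivation: +40 mV step, 750-ms tail at -60 mV
dea <- build_deactivation_protocol(-60)
tail_trace <- simulate_current(wt, dea, cell)
w <- segment_table(dea)                        # tail segment window
fit <- fit_exponential_decay(tail_trace, n_terms = 2,
                             window = c(w$t_start[2] + 5, w$t_end[2]))
c(tau_f = fit$tau_f, tau_s = fit$tau_s, fast_fraction = fit$fast_fraction)
#>         tau_f         tau_s fast_fraction
#>   40.30732323  644.16479606    0.04476518
```

The two time constants (ms) are the hallmark fast and slow components
of hERG deactivation; the fast fraction is the relative amplitude of
the fast component (for these wild-type kinetics at −60 mV the decay is
dominated by the slow component). A full synthetic characterization — generate a
three-sweep (control / activator / blocker) cohort, subtract, fit the
joint model on the staircase, predict the validation protocols, and
compare phenotypes — runs as one call:

```r
report <- run_characterization(pipeline_config(construct = "WT", seed = 1))
head(report$recovery)      # true vs fitted kinetic parameters
report$prediction          # normalized RMSE vs the noise floor, per protocol
report$phenotypes          # deactivation tau, AP-clamp metrics, control vs activator
```

Fitted models export to a self-contained JSON/plain-text description
(`export_model()`) for embedding I<sub>Kr</sub> in external
action-potential simulators.

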