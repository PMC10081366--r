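---
title: "Models and methods for serotonin voltammetry analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for serotonin voltammetry analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(serovolt)
```

This vignette is the package's own account of the science it implements:
the kinetic and pharmacokinetic models, the signal-processing conventions,
the parameters that matter, and the places where the design was genuinely
open and a choice had to be made.

## The dual-uptake kinetic model

Evoked extracellular serotonin is modelled as

$$\frac{dC}{dt} = R(t)\,\bigl(1 - A(t)\bigr)
  - \alpha\,\frac{V_{max1}\,C}{K_{m1} + C}
  - \beta\,\frac{V_{max2}\,C}{K_{m2} + C},$$

a release term shaped by autoreceptor feedback minus two saturable
Michaelis–Menten clearance routes. Uptake 1 is the high-affinity,
low-capacity serotonin-transporter route; Uptake 2 the low-affinity,
high-capacity route through promiscuous transporters. The default control
parameterisation is $K_{m1} = 2$ nM, $V_{max1} = 12$ nM/s,
$K_{m2} = 170$ nM, $V_{max2} = 780$ nM/s — a regime where Uptake 2 carries
most clearance at evoked (tens of nM) concentrations while Uptake 1
dominates the approach to a low ambient level.

Two pieces of the model have no canonical published functional form, so the
package makes explicit, configurable choices:

* **Release envelope** $R(t)$: a smoothed boxcar,
  $R_{max}(1 - e^{-(t-t_{on})/\tau_{on}})$ during the stimulus and
  exponential relaxation with $\tau_{off}$ afterwards (defaults
  $\tau_{on} = \tau_{off} = 0.3$ s against the 2-s, 60-Hz stimulus train).
  A constant basal release `R_basal` (default 0) can sustain a non-zero
  resting level; when `C0` is not given the simulation starts at the
  resting steady state implied by `R_basal`.
* **Autoreceptor occupancy** $A(t)$: a delayed Hill function of
  concentration, $A_{max}\,C(t-\delta)^h / (A_{ec50}^h + C(t-\delta)^h)$,
  bounded in $[0, 1)$ as an occupancy must be. It defaults to *off*
  ($A_{max} = 0$): the release-envelope and autoreceptor parameters are
  strongly confounded in a single evoked transient, so feedback is opt-in
  for scenario work rather than silently active.

$\alpha$ and $\beta$ are pure multipliers of the respective $V_{max}$ and
therefore jointly non-identifiable; they are fixed at 1 and excluded from
fitting, remaining available for scenario construction.

### Numerics

The ODE is integrated with the explicit Euler method at `dt = 0.01` s and
resampled to the 10 Hz acquisition grid by nearest-step lookup. Euler is
first order: halving `dt` halves the error, and at the default step the
solution stays within 1% (sup-norm, relative to peak) of a
`deSolve::lsoda` reference at tolerance 1e-10 — the test suite asserts
both. A step that would undershoot zero is clamped at 0 and counted in the
trace metadata (`clamp_events`) rather than silently clipped; a non-finite
state aborts with the offending step index. The steady state under constant
release has a closed form (the positive root of a quadratic when both
uptake terms are active), implemented in `mm_steady_state()` and used as an
independent oracle against long simulations.

### Fitting

`mm_fit()` minimises the RMSE between the Euler simulation and the observed
trace. The optimiser is deliberately simple and transparent: coordinates
are log-transformed (positivity by construction), gradients come from
forward finite differences, and a backtracking line search accepts only
descent steps. Convergence is declared when the relative RMSE improvement
drops below 1e-6 (or after `max_iter = 2000` iterations; divergence is
reported, best iterate returned). The interactive step of semi-automatic
fitting is replaced by a seeded multi-start: five inits (the supplied one
plus four log-normal jitters, SD 0.15), best final RMSE wins. Freezing is
explicit: everything outside the free set stays at its initial value, and
`param_ratios()` reports post/control fold changes with frozen terms pinned
at 1.

Identifiability caveat: with the control parameterisation, $K_{m1}$ has
little leverage on an evoked transient (Uptake 2 dominates), so its
recovery from noisy data is poor even though noiseless recovery is exact.
The test suite therefore probes noise robustness on $K_{m2}$, where the
data are informative, and checks local injectivity of the parameter-to-trace
map by finite-difference Jacobian rank.

## The four-compartment pharmacokinetic model

Intraperitoneal escitalopram distributes between peritoneum, plasma, brain
and periphery with first-order rate constants $k_{01}, k_{10}, k_{12},
k_{21}, k_{13}, k_{31}$ (min⁻¹); plasma protein binding $P_B = 0.56$ and
SERT binding in brain $SERT_B = 0.15$ reduce the freely exchanging
fraction; bioavailability is 0.80, volumes are 2 / 2 / 0.41 / 15 mL, the
mouse weighs 20 g, and the molecular weight defaults to the escitalopram
free base (324.4 g/mol — the salt actually dosed is the oxalate, so this is
configurable). The initial peritoneal concentration for a 10 mg/kg dose is
then $0.8 \times 0.2\,\mathrm{mg} / (324.4\,\mathrm{g/mol} \times
2\,\mathrm{mL}) \approx 2.47 \times 10^5$ nM.

Two formulations are implemented because the source equations do not close:

* The printed plasma equation contains the outflow term
  $-k_{12} C_1 (1-P_B)$ twice while the periphery equation uses $k_{13}$.
  The default *repaired* reading takes the duplicate as the
  plasma-to-periphery flow ($k_{13}$), which balances the system; the
  *as-printed* variant is selectable (`variant = "as_printed"`) for
  fidelity audits. With $k_{12} = k_{13}$ the two readings coincide, which
  the tests exploit.
* The printed equations exchange *concentrations* without volume scaling,
  so they do not conserve drug amount across unequal compartments. The
  default `amount-conserving` mode integrates amounts (nmol) and divides by
  compartment volume for reporting; with secretion off the total amount is
  conserved to numerical precision (asserted at 0.01% over 240 min). The
  concentration-mode equations remain available.

The integrator is classic fixed-step RK4 at `dt = 0.01` min; the system is
small, linear and non-stiff at tested parameters, and the suite
cross-checks trajectories against `deSolve::lsoda`. No authoritative rate
constants ship with the package (the published values live in a figure
table not transcribed in text): `fcm_params()` requires them, and
`synthetic_fcm_rates()` provides a clearly labelled synthetic set
($k_{01}=0.10$, $k_{10}=0.03$, $k_{12}=0.10$, $k_{21}=0.15$, $k_{13}=0.20$,
$k_{31}=0.05$ min⁻¹), chosen once for a plausible murine profile — fast
peritoneal absorption, plasma elimination half-life of tens of minutes, and
a brain peak a few tens of minutes post-injection — and not revisited.

Competitive inhibition enters through
$K_m^{app} = K_m (1 + [I]/K_i)$ with $K_i = 1.1$ nM:
`predict_post_drug_trace()` substitutes $K_{m1} \to K_m^{app}$ at the
simulated brain concentration and re-runs the forward model. Because brain
concentration is linear in dose (the system is linear) and $K_m^{app}$ is
linear in concentration, the apparent-Km ratio is monotone in dose at fixed
time — a property the grid summary (`temporo_dose_grid()`) asserts rather
than assumes. Note the scale: at the synthetic rate constants a 10 mg/kg
dose yields brain concentrations of order $10^5$ nM, which with
$K_i = 1.1$ nM inflates $K_{m1}$ by five orders of magnitude. That is the
model's honest prediction under pure competitive inhibition, not an
artefact.

## FSCV signal processing

Colour plots are filtered with a separable frequency-domain Butterworth
magnitude response ($|H| = (1 + (f/f_c)^{2n})^{-1/2}$, $n = 3$) at
37.5 kHz along the intra-sweep axis and 2.5 Hz across sweeps, applied via
FFT with symmetric padding — zero-phase, unit DC gain, no edge transients
on short recordings. Calibrated traces take the current at the analyte's
peak sample index, subtract the mean of the first ten sweeps, and scale by
an electrode factor (49.5 μM/nA is the standard serotonin factor on the
serotonin-specific waveform). Factors are opaque "concentration units per
nA" scalars with a units tag: the published constants mix μM/nA and nM/nA
across waveforms, and the package surfaces rather than resolves that
ambiguity.

Amplitude detection searches local maxima from stimulation onset to 30 s
after it and requires the excursion over the pre-stimulation baseline mean
to exceed 3 baseline SDs; the tallest qualifying maximum wins, and a trace
with none yields a not-found result, not an error. The 30-s window, the
20-s inhibition window and the 3-SD prominence rule are package defaults
chosen to match typical displayed trace extents; all are arguments. The
decay fit adds a baseline offset to the textbook single exponential
($C_{peak} e^{-k(t-t_{peak})} + C_{base}$) because traces return to a
non-zero ambient level; the offset can be pinned to zero. For each
candidate rate the amplitude and offset are profiled out analytically, so
the optimisation is one-dimensional in $k$ (bracketed in
$[10^{-4}, 10^3]$ s⁻¹); a non-decaying segment is flagged `degenerate`.
The identity $t_{1/2} \cdot k = \ln 2$ holds by construction.

## FSCAV charge integration and calibration

Per 60-s measurement file: the mean of the first ten CVs is subtracted from
every sweep; the **third** CV after the controlled-adsorption boundary is
selected; the Faradaic peak charge is the composite-Simpson integral of
current between integration bounds, minus the trapezoid under the straight
line joining the endpoint currents (the capacitive baseline). Bounds are
the local minima nearest the window's global maximum, detected on a 5-point
moving-average smoothed copy (smoothing is used only for bound detection,
never for integration); ties break toward the peak by construction, and
when a flank has no minimum the bound falls back to the window edge with a
logged warning. Simpson's rule is exact on quadratics — the tests integrate
a parabolic peak against its closed-form area at machine precision. An even
number of samples is closed with a trapezoid on the final interval.

Calibration is ordinary least squares of charge on standard concentration
(free intercept; whether the original software forces the origin is
unstated, so the more general model is used and $r^2$ stored), with the
classic 10 / 25 / 50 / 100 nM standard grid in examples and tests. A
non-positive slope marks the model invalid. Concentrations are floored at
0 with a logged count: negative ambient concentrations are unphysical.

## Oscillation analysis

Basal series are bandpassed with a zero-phase (forward–backward) 3rd-order
Butterworth, passband 0.0008–0.005 Hz: below, drug-driven baseline drift;
above, measurement noise; inside, the 6–10-minute oscillation band. The
series is centred and reflect-padded before filtering to suppress the
forward–backward transient; the effective magnitude response is the squared
3rd-order Butterworth. One consequence of the fixed 60-s sampling is a
Nyquist frequency of 1/120 Hz ≈ 0.0083 Hz, so the fastest representable
out-of-band tone has a 2-minute period; the stopband tests use it.

Autocorrelation uses the full-series mean and full sum of squares in the
denominator, so $r_0 = 1$ exactly and $|r_p| \le 1$; sliding-window
correlation (default window 25 min) centres each window on its own mean,
with zero-variance windows yielding `NA` entries. The Welch PSD uses
segments of half the series length with 50% overlap, periodic Hann taper
and per-segment mean detrending (all configurable); the zero-frequency bin
is dropped. The weighted frequency is implemented as the
normalised-power-weighted mean frequency
$WF = \sum_i f_i P_i / \sum_i P_i$ — the spectral centre of mass — with the
unnormalised $\sum_i f_i P_i$ available behind a flag since "sum of
power-weighted frequencies" is ambiguous about normalisation. Pre/post
comparisons compute one WF per animal per phase (a per-window variant of
the distribution question is deliberately not the default) and classify a
positive group shift as Uptake-1-like, negative as Uptake-2-like.

## The synthetic-data generator

The generator is first-class, tested code; it emulates:

* **Evoked traces**: the forward model itself plus white Gaussian noise at
  the 10-Hz grid — so at zero noise the generator and the solver agree
  bit-for-bit by construction, and fitting tests are exact round trips.
* **Basal series**: baseline (default 60 nM, a typical hippocampal ambient
  scale) + a single sinusoid with period drawn in [6, 10] min + AR(1)
  noise (marginal SD 2 nM, coefficient 0.5) + an optional piecewise-linear
  post-drug ramp. The single-sinusoid-plus-AR(1) form is parsimonious: the
  phenomenon being modelled is characterised only by period band and
  spectral displacement, so a richer generative model would add untestable
  structure.
* **Voltammograms**: a polynomial capacitive background plus a Gaussian
  Faradaic peak whose integrated charge is exactly
  `calibration_slope × concentration` — linearity by construction, which
  is what makes the charge-integration round trip a genuine test of the
  processing chain rather than of the generator. No electrochemical physics
  (adsorption isotherms, double-layer dynamics) is simulated, and no noise
  model is asserted: real noise amplitudes are not published for either
  modality, so they are configurable and never load-bearing in tests.

All randomness flows through one explicit integer seed per call
(`withr::with_seed`); there is no hidden global state, and identical spec +
seed reproduce bit-identical outputs. Consequently, passing tests show that
the *processing chain* is correct on data whose ground truth is known; they
do not show that real electrodes, drift, fouling or biological variability
are captured.

## Pipeline and problem sizes

`run_experiment()` validates its configuration against the known stage set
before any computation, executes the stages in a fixed order, stamps every
output with a configuration hash, and is byte-deterministic under fixed
seed — the suite compares files across reruns. Statistical hypothesis
testing is deliberately delegated: `export_tidy_stats()` emits a long
(animal, phase, time, value, stage) table for standard ANOVA/ANCOVA
tooling, because those tests are library calls, not methods this package
contributes.

Default problem sizes were chosen so the whole suite and the acceptance
script each run in a few minutes on one CPU: 25-s evoked traces at
`dt = 0.01` s, 120-min basal series, 240-min compartmental runs, five-start
fits, and 10-seed direction-recovery replicates. These are the package's
standing study conditions, stated here so results are reproducible, and all
are arguments.

## Known limitations

* Euler is first-order; the default step is validated against a reference
  but stiff parameterisations (very large $V_{max}/K_m$) would need a
  smaller `dt`.
* The fitter is a local optimiser with multi-start, not a global one, and
  makes no claim of equivalence to the original interactive fitting
  procedure.
* Constant binding fractions ($P_B$, $SERT_B$) are used as printed;
  SERT binding does not saturate at high brain concentration.
* Only the linear-regression FSCAV calibration path is implemented; the
  neural-network calibration alternative is out of scope.
* Calibration-factor unit ambiguity on the histamine waveform is surfaced,
  not resolved.
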