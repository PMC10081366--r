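# serovolt

Analysis tools for in vivo serotonin voltammetry. The package is aimed at
electrochemists and neuropharmacologists who measure extracellular serotonin
with fast-scan cyclic voltammetry (FSCV, evoked transients at 10 Hz) and
fast-scan controlled-adsorption voltammetry (FSCAV, ambient levels once per
minute), and who want to interpret drug effects mechanistically — in
particular, how uptake inhibitors reshape evoked release/clearance kinetics
and slow ambient oscillations.

## The models

**Dual-uptake Michaelis–Menten kinetics.** Evoked extracellular serotonin
C(t) follows

    dC/dt = R(t) (1 − A(t)) − α Vmax1 C/(Km1 + C) − β Vmax2 C/(Km2 + C)

with an evoked release envelope R(t), an optional delayed autoreceptor
occupancy A(t) ∈ [0, 1), and two saturable clearance routes: Uptake 1
(high-affinity, low-capacity; serotonin transporters) and Uptake 2
(low-affinity, high-capacity; OCT/DAT/NET/PMAT). The ODE is solved with the
explicit Euler method and fitted to traces by RMSE gradient descent in
log-parameter space with seeded multi-start (`mm_simulate()`, `mm_fit()`).
Amplitude and clearance summaries come from local-maxima detection and an
exponential decay fit with half-life t½ = ln(2)/k (`detect_amp_max()`,
`fit_half_life()`).

**Four-compartment pharmacokinetics + competitive inhibition.** An
intraperitoneal escitalopram dose distributes over peritoneum, plasma,
brain and periphery with first-order exchange, plasma protein binding
(P_B = 0.56) and SERT binding in brain (SERT_B = 0.15) (`fcm_simulate()`).
The simulated brain drug concentration inflates the Uptake 1 Michaelis
constant by the competitive-inhibition law

    Km_app = Km (1 + [I]/Ki),   Ki = 1.1 nM

and the substituted model predicts post-drug evoked responses over a
dose × time grid (`apparent_km()`, `predict_post_drug_trace()`,
`temporo_dose_grid()`).

**Signal processing.** Colour plots are low-pass filtered with a separable
frequency-domain 3rd-order Butterworth (37.5 kHz fast axis, 2.5 Hz slow
axis); FSCAV sweeps are background-subtracted, the third post-adsorption CV
is selected, and the Faradaic peak charge is integrated with Simpson's rule
between automatically detected local-minima bounds, minus a straight-line
capacitive baseline, then calibrated by per-electrode linear regression.
Ambient oscillations (6–10 min period) are characterised by a
0.0008–0.005 Hz Butterworth bandpass, autocorrelation, 25-min
sliding-window correlation, Welch power spectral density and the
power-weighted mean frequency (WF); paired pre/post WF shifts separate
Uptake-1-like (positive) from Uptake-2-like (negative) drug signatures
(`compare_pre_post()`).

Every input the pipeline consumes can be generated synthetically with known
ground truth and explicit seeds (`simulate_evoked_trace()`,
`simulate_basal_series()`, `synthesize_voltammograms()`), and
`run_experiment()` orchestrates configured end-to-end runs into commented
CSV bundles with tidy long-format export for external statistics.

## Worked example

```r
library(serovolt)

ctrl  <- mm_params()   # control kinetics: Km1 = 2, Vmax1 = 12, Km2 = 170, Vmax2 = 780
trace <- simulate_evoked_trace(ctrl, stim_protocol(), duration = 25,
                               noise_sd = 1, seed = 42)
amp  <- detect_amp_max(trace)
half <- fit_half_life(trace, amp$t_peak)
sprintf("Amp_max %.1f nM at t = %.1f s;  k = %.2f 1/s, t1/2 = %.2f s",
        amp$amp_max, amp$t_peak, half$k, half$t_half)
#> "Amp_max 72.7 nM at t = 6.9 s;  k = 1.81 1/s, t1/2 = 0.38 s"
```

The stimulus (60 Hz, 2 s — 120 pulses) starts at 5 s, so the transient peaks
just before stimulation ends and clears within a couple of seconds. Fitting
the model back to the noisy trace from a deliberately wrong starting point
recovers the clearance constants:

```r
fit <- mm_fit(trace, init = modify_params(ctrl, K_m2 = 300, V_max2 = 500),
              frozen = c("tau_on", "tau_off", "K_m1", "V_max1"), seed = 1)
glance(fit)
#>    rmse iterations converged n_free n_starts
#> 1 0.976        167 TRUE           3        5
tidy(fit)[c(6, 7), ]
#>   term   estimate init frozen
#> 6 V_max2     827.  500 FALSE
#> 7 K_m2       185.  300 FALSE
```

(truth: V_max2 = 780, K_m2 = 170; the residual RMSE ≈ the injected 1 nM
noise). Coupling to the pharmacokinetic model predicts the evoked response
60 minutes after a 10 mg/kg dose:

```r
pk   <- synthetic_fcm_rates(dose_mg_kg = 10)   # synthetic rate constants
traj <- fcm_simulate(pk, duration = 120)
cb   <- brain_concentration_at(traj, 60)
apparent_km(ctrl$K_m1, cb, pk$K_i)
#> 1.9e+05  (brain escitalopram 1.04e+05 nM)

pred <- predict_post_drug_trace(ctrl, traj, 60, duration = 25)
```

Against the noiseless control simulation (Amp_max 72.5 nM, t½ 0.331 s) the
prediction rises to Amp_max 77.5 nM and t½ 0.354 s: pure competitive SERT
inhibition raises both the peak and the clearance half-life, increasingly
so with dose.

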