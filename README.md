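# photowd

Fiber photometry and behavioral analysis of nicotine withdrawal, as an R
package plus a numbered analysis workflow.

In the paradigm this package serves, mice drink nicotine (or tartrate
control) for four weeks and withdrawal is precipitated with a 2 mg/kg
mecamylamine (MEC) injection at a controlled time. Neural activity (GCaMP6s
in the laterodorsal tegmentum) or dopamine release (GRAB-DA in the nucleus
accumbens) is recorded by dual-channel fiber photometry — a 465 nm
activity-dependent channel and a 405 nm isosbestic control sampled at
1,017.3 Hz with an 8 Hz low-pass — while the animal explores a novel object
or simply sits through the injection. The analysis questions are: does
withdrawal suppress spontaneous transients and novel-object responses, and
how separable are saline (SAL) and MEC days from per-interaction signal
scores?

## What the package computes

For a recording \(F_{465}, F_{405}\):

- **ΔF/F** — each channel is low-passed (zero-phase Butterworth, 8 Hz),
  photobleaching is removed by a double-exponential fit
  \(p_1 e^{-t/\tau_1} + p_2 e^{-t/\tau_2} + p_3\) (the fitted operating level
  is retained), a smoothed 405 trace is regressed onto the 465 trace, and
  \(\Delta F/F = (F_{465} - F_{fit405})/F_{fit405}\).
- **Robust z** — one scaler per animal from the concatenated ΔF/F of all
  its sessions: high-amplitude events (>2×MAD from the median) are removed,
  the center is the filtered median, and the scale is the filtered MAD
  rescaled to a consistent Gaussian SD.
- **Transients** — local maxima with topographic prominence ≥ 2.9 × SD of
  the analyzed segment, with half-width at half prominence, per-transient
  trapezoidal AUC, and post-minus-pre comparisons over 5-min windows around
  the injection (Δ peak #, Δ AUC, Δ amplitude).
- **Peri-event metrics** — for each novel-object interaction at \(t\):
  mean z over \([t-5,t)\) and \((t,t+5]\), their difference
  \(\Delta z\), the 500-ms post-event AUC, whether a detected peak falls in
  \((t, t+2]\), and an increase/decrease/no-change category from
  \(\Delta z\) against a ±1 z threshold.
- **Discriminability** — probability densities (0.2-unit bins) and
  empirical ROC curves of per-event scores, MEC day as the positive class;
  AUC equals the Mann–Whitney U over \(n_+ n_-\), CI by Hanley–McNeil.
- **Behavior** — place preference score (% time paired − % time unpaired),
  Δ preference vs pretest, the >70% pretest exclusion, center-zone visits
  and distance in the open field, novel-object approaches (≤2 cm,
  inclusive), somatic-sign summaries with the >3-occurrence inclusion rule,
  and blinded/live scorer reconciliation (>0.5 s discrepancy → blinded
  score, else average).

A synthetic-data module generates dual-channel recordings with known ground
truth — double-exponential bleach, shared step artifacts, kernel-shaped
transients (Poisson background plus event-locked responses), a
condition-dependent suppression after a simulated MEC injection, and biased
random-walk behavior tracks — so every stage is validated against truth it
must recover.

## Worked example

```r
library(photowd)

# a 10-min dual-channel session with known transients and a MEC injection
p <- sim_params(background_rate_hz = 0.1, amp_mean = 0.04, amp_sd = 0.004,
                kernel = list(tau_rise_s = 0.1, tau_decay_s = 0.5),
                sensor = "GRAB-DA", seed = 2)
sim <- simulate_recording(p)

tr <- process_recording(sim$recording)        # lowpass, detrend, dF/F
sc <- fit_robust_scaler(tr$dff)               # per-animal robust scaler
z  <- apply_zscore(tr$dff, sc)
ts <- detect_transients(z, tr$time_s)         # 2.9 x SD prominence
match_peaks(ts$peak_time_s, sim$truth$transient_times_s)
#> $n_matched
#> [1] 48
#> $recall
#> [1] 0.9056604
#> $precision
#> [1] 1
```

The full cohort analysis is a sequence of thin drivers over the package:

```sh
Rscript analysis/01_simulate.R 1      # 2x2 cohorts (tartrate/nicotine x SAL/MEC)
Rscript analysis/02_preprocess.R      # dF/F + per-animal robust z
Rscript analysis/03_transients.R      # detection vs truth + injection windows
Rscript analysis/04_event_locked.R    # peri-event metrics + classification
Rscript analysis/05_discriminability.R
Rscript analysis/06_behavior.R 1
```

each writing tables under `results/` and printing its findings, e.g.:

```
pooled detection: recall 0.942, precision 0.820
nicotine MEC: mean delta peak # +66.7, delta AUC -5.40, delta amplitude -9.99
tartrate MEC: mean delta peak # +0.8, delta AUC -0.42, delta amplitude -0.51
...
nicotine_MEC: peak-matched 0.53, delta z mean +0.65 (incr/decr/none 0.36/0.02/0.62)
nicotine_SAL: peak-matched 0.90, delta z mean +2.93 (incr/decr/none 0.87/0.01/0.12)
...
tartrate: AUC 0.512 (95% CI 0.428-0.597), |AUC - 0.5| = 0.012
nicotine: AUC 0.138 (95% CI 0.083-0.192), |AUC - 0.5| = 0.362
nicotine minus tartrate distance from the equivalency line: +0.350
```

Read: the simulated withdrawal (nicotine + MEC) sessions show the
constructed suppression — peak amplitudes drop by ~10 z after the injection
while control groups stay near zero, the fraction of interactions answered
by a peak falls from ~0.9 to ~0.5, and the nicotine group's SAL/MEC days
are far more separable (|AUC − 0.5| = 0.362) than the tartrate group's
(0.012).
The rise in post-injection peak *count* under suppression is a documented
consequence of the per-window SD threshold (see the methods vignette);
amplitude and AUC are the robust suppression readouts.

`run_pipeline()` performs the same chain from one config (list or YAML) and
`report()` renders summary text and figures.

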