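---
title: "Methods: dual-channel photometry and behavioral scoring in photowd"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dual-channel photometry and behavioral scoring in photowd}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photowd)
```

photowd implements the analysis chain used to characterize neural activity
and dopamine release during mecamylamine-precipitated nicotine withdrawal:
dual-channel fiber photometry (a 465 nm activity-dependent channel and a
405 nm isosbestic control), robust z-scoring, prominence-based transient
detection, peri-event analysis around novel-object interactions, ROC
discriminability between saline (SAL) and mecamylamine (MEC) sessions, and
the behavioral scoring formulas of the paradigm (real-time place preference,
open field, novel object, somatic signs). This vignette documents the models,
the defaults and why they were chosen, the numerical decisions, and the
limits of what the synthetic validation shows.

## The signal model

The synthetic generator and the preprocessing chain share one signal model.
Each channel is

$$F_{ch}(t) = B_{ch}(t)\,\bigl[1 + s_{ch}\,C(t) + m_{ch}\,A(t)\bigr] + \varepsilon_{ch}(t),$$

where $B_{ch}$ is a double-exponential photobleaching curve with a floor,
$C(t)$ is the activity signal (a sum of transients; $s_{465} = 1$,
$s_{405} = 0$ because the isosbestic excitation is insensitive to
calcium/dopamine binding), $A(t)$ is a motion artifact shared by both
channels, and $\varepsilon$ is sensor/photon noise. Transients use a
difference-of-exponentials kernel
$K(t) = (1 - e^{-t/\tau_r})\,e^{-t/\tau_d}$, normalized to unit peak.
Defaults are $\tau_r = 0.1$ s with $\tau_d = 1.5$ s for a GCaMP6s-like
sensor and $\tau_d = 0.5$ s for a faster GRAB-DA-like sensor — plausible
published kinetics, configurable because neither is a measured property of
any one preparation.

Spontaneous transients arrive as a Poisson process (default 0.1 Hz);
novel-object interactions trigger a response with probability
`p_respond` (default 0.9). Dopamine-style sessions can draw each response
from a mixture of *increase* (a kernel transient), *decrease* (a linear
pre-event ramp over 4 s that terminates at the interaction and collapses
with a 0.3 s fall time — the signature of dopamine that is elevated before
the approach and drops at contact), and *none*. The withdrawal condition
multiplies all transient amplitudes by `amp_scale_post` (default 0.5) and
replaces the response probability with `p_respond_post` (default 0.44)
after the injection time, and only then. Those two numbers mirror the
observed halving of response prevalence (~90% of interactions answered by
a peak in control recordings vs ~44% in withdrawal) and the reported
reduction in peak amplitude; they are effect *directions and sizes used for
validation*, not claims about mechanism.

The motion artifact is a piecewise-constant jump process (Poisson step
times, Gaussian step sizes) added identically to both channels. This is
deliberately the simplest artifact that the isosbestic regression can
identify; its sharp edges also expose the limits of that correction (below).

## Preprocessing

The chain is: 8 Hz low-pass -> double-exponential detrend per channel ->
isosbestic regression -> dF/F -> robust z. The acquisition low-pass (8 Hz)
is implemented as a zero-phase Butterworth filter (order 2, applied forward
and backward) with odd-reflection padding so that filter start-up transients
decay in the padding rather than the data; DC gain is exactly 1.

**Photobleach removal.** Each channel is fit with
$y(t) = p_1 e^{-t/\tau_1} + p_2 e^{-t/\tau_2} + p_3$ over the whole session.
The fit uses variable projection — for any candidate $(\tau_1, \tau_2)$ the
linear coefficients are solved exactly, so the nonlinear search runs over
just the two taus (Nelder-Mead, three deterministic multi-starts, on a
deterministic subsample of at most 350 points normalized to unit scale) —
with the coefficients constrained nonnegative, since bleaching decays to a
nonnegative floor. Over sessions short relative to the slow tau, a
near-flat exponential and the constant $p_3$ are not separately
identifiable; a tiny ridge on $p_1, p_2$ breaks exact collinearity, and the
detrended trace is defined as $y - \mathrm{trend}(t) +
\mathrm{trend}(t_{end})$: the within-session variation of the fitted decay
is removed while the fitted *terminal fluorescence* is retained. Whenever
the decay completes inside the session this equals the usual
"residual + $p_3$"; when it does not, it still leaves a positive, physical
operating level for the dF/F division, which "residual + $p_3$" does not
guarantee. Division refuses (rather than clips) references at or below
$10^{-6}\times$ the median fitted reference.

**Isosbestic regression and dF/F.** The detrended 405 trace is smoothed
with a centered moving average (default 1.0 s — the smoothing window is not
a measured quantity; it trades isosbestic noise against artifact bandwidth,
and it is configurable) and regressed onto the detrended 465 trace. The
numerator of dF/F is the classical \(F_{465} - F_{fit405}\). For the
divisor, the pipeline uses the 465 channel's *fitted bleach curve* rather
than the constant post-detrend fit405 level: transients ride
multiplicatively on the decaying fluorescence, so only a reference that
tracks that decay keeps a transient of a given fractional size the same
height in dF/F early and late in a session. With a constant divisor,
late-session transients measure systematically smaller, which biases every
post-minus-pre comparison negative even when nothing changed — the package
quantifies exactly this bias in its validation cohort and the
time-tracking reference removes it. `compute_dff()` itself defaults to the
literal \((F_{465} - F_{fit405})/F_{fit405}\) for standalone use.

A consequence worth knowing: a step artifact is corrected only up to the
smoothing bandwidth. The smoothed 405 ramps across each step over the
window width while the 465 jumps, leaving a brief residual at every step
edge that robust z-scoring then magnifies. With the smoothing window at one
sample, steps cancel through the regression (the package tests assert
this); with the 1 s default, transient-free traces are clean *between*
steps but carry short residuals *at* them. Real motion artifacts are slower
than ideal steps, which is why smoothing is the field's default; the
generator's steps are a worst case.

**Robust z.** One scaler per animal is fitted on the concatenated dF/F of
all its sessions: samples beyond $2\times$MAD of the raw median are removed
as high-amplitude events, the center is the median of the filtered trace,
and the scale is the MAD of the filtered trace rescaled to estimate the
Gaussian SD. Because the $2\times$MAD filter truncates a Gaussian at
$1.349\sigma$, the familiar 1.4826 constant would converge to
$\approx 0.80\sigma$ on event-free data — an inconsistent estimator that
silently inflates every downstream z value by 25%. The constant used is
therefore the truncation-corrected
$1/\Phi^{-1}\!\bigl(\tfrac12 + \tfrac{2\Phi(c)-1}{4}\bigr) \approx 1.848$
with $c = 2\,\Phi^{-1}(0.75)$, which makes the robust z have unit variance
on clean Gaussian noise while keeping full resistance to transients. The z
is invariant to shifting or positively scaling the input, and the median of
z over the filter-passing samples is 0 by construction.

## Transient detection

Peaks are local maxima of the z-scored trace (plateaus resolved to their
floor-middle sample) kept when their topographic prominence reaches
$2.9\times$ the SD of the analyzed segment. Prominence follows the
topographic definition — walk from the peak to the nearest strictly higher
sample or the trace edge on each side, take the minimum on each walk, and
subtract the higher of the two minima from the peak height. The production
implementation compresses the trace to its run-length extrema and sweeps a
monotonic stack (linear time); an independent $O(n^2)$ oracle implements
the definition literally, and the test suite requires exact agreement
between the two on random traces, including plateaus and random walks.

"SD of the data" is read as the SD of the segment under analysis, so the
5-min pre- and post-injection windows each use their own SD (the
whole-session alternative is selectable). This choice has a visible
consequence in the suppression scenario: when post-injection amplitudes
shrink, the post-window SD shrinks too, the threshold drops, and more small
peaks clear it — so the *count* of detected peaks can rise even though the
underlying event rate is unchanged, while the mean *amplitude* of detected
peaks still falls. Amplitude and AUC deltas are therefore the robust
readouts of suppression under this convention, matching how the effect is
reported. A subtler second-order effect remains even in control sessions:
additive sensor noise divided by the decaying bleach level makes dF/F noise
grow over a session, and because the threshold's false-positive rate is
steeply noise-dependent, late windows admit a few more near-threshold noise
peaks than early ones, diluting the late-window mean amplitude by about 1%
of the transient amplitude under the validation conditions. Threshold-based
peak statistics are biased at that order whenever noise is nonstationary;
the package's cohort validation quantifies the effect rather than hiding
it.

Each kept peak gets a half-width at half prominence (linear interpolation)
and a per-transient AUC: the trapezoidal integral of z over the
half-prominence extent. The integration extent for per-transient AUC is not
uniquely determined by the source description; the half-prominence extent
is the package's choice, and whole-window integrals remain available
through `transient_auc()` directly. Pre/post-injection comparisons report
post-minus-pre differences in peak count, mean per-transient AUC, and mean
amplitude over 300 s windows; mean-based deltas are flagged absent (NA)
when a window holds no peak.

## Peri-event analysis

For each interaction at time $t$: `mean_pre` is the mean z over
$[t-5, t)$, `mean_post` over $(t, t+5]$,
$\Delta z = \texttt{mean\_post} - \texttt{mean\_pre}$, and `auc_500ms` is
the trapezoid of z over samples in $(t, t+0.5]$ — a post-only window, so
rewriting pre-event samples can never change it (tested). Events whose
windows leave the recording are dropped and counted. A peri-event matrix
aligns rows so that offset 0 is the first sample at or after the event.

`has_peak` marks interactions with a detected transient peak inside
$(t, t+2]$; the 2 s response window is a configurable choice, since the
matching rule behind "an interaction answered by a peak" is not stated
precisely in the source description. Note that `has_peak` has a floor set
by spontaneous transients and near-threshold noise peaks that happen to
land in the window — measured response proportions sit above the
generator's `p_respond` by that floor, which is itself measurable from
event-free traces (`shuffle_null()` serves this purpose for $\Delta z$).
The dopamine-style category is `increase` if $\Delta z \ge \theta$,
`decrease` if $\Delta z \le -\theta$, else `no_change`, with
$\theta = 1$ z by default — again a configurable threshold standing in for
an unstated rule, not an asserted value. Group summaries average per
subject first (the subject is the unit), then across subjects, with SEM
across subjects flagged absent for singleton groups.

## Discriminability

Per-event scores (`mean_post_5s` for the calcium-style analysis, `delta_z`
for the dopamine-style analysis) are pooled across subjects within an
exposure group, and an empirical ROC discriminates the MEC day (positive
class) from the SAL day. Ties follow the rank/midpoint convention, so the
area equals the Mann-Whitney U statistic over $n_+ n_-$; the reported AUC
is the trapezoid of the curve, which coincides with it, and an all-pairs
brute force must agree to $10^{-12}$ in tests. The 95% CI uses the
Hanley-McNeil variance formula truncated to $[0, 1]$; a seeded stratified
bootstrap (2,000 resamples, percentile interval) is selectable, since the
CI convention in the original analysis is unstated. A subject-stratified
ROC summary (`roc_stratified()`) is provided as the non-default alternative
to pooling events across animals. Suppressed
MEC-day scores push the AUC *below* 0.5 under this orientation; the
direction is deliberately not flipped, and group comparisons report
$|AUC - 0.5|$, the distance from the line of equivalency. Probability
densities of the same scores use fixed 0.2-unit bins aligned to multiples
of 0.2 and normalize to unit integral.

## Behavioral scoring

The formulas are implemented exactly as defined by the paradigm: preference
score = % session time in the light-paired chamber minus % in the unpaired
chamber (samples on the divider belong to neither; the denominator is total
session time — the source leaves the denominator ambiguous when the animal
straddles the boundary); $\Delta$ preference = test-day minus pretest-day
score; animals with >70% pretest preference for either chamber (strictly
greater) are excluded; somatic signs are included per sign only when
observed more than 3 times, while pooled totals always include everything;
blinded/live sniff-time discrepancies over 0.5 s resolve to the blinded
score, otherwise the two are averaged. The open-field center zone is the
centered 21 x 21 cm square of the 43 x 43 cm arena; a visit is a maximal
run of in-zone samples; novel-object interaction is distance <= 2 cm from
the object (inclusive), with entry timestamps feeding the peri-event
analysis. Synthetic tracks carry a single center point, standing in for
nose-point tracking; the interaction radius is configurable to absorb the
nose/center offset.

Simulated tracks are reflected Gaussian random walks (30 Hz, 1 cm step SD)
with a constant drift toward the paired chamber scaled by a bias in
$[-1, 1]$ (0.15 cm per sample at full bias); occupancy rises monotonically
with bias, which is what the preference tests exercise.

## Problem sizes and what the validation shows

The generator's defaults are the study's recording conditions: 1,017.3 Hz
sampling, 600 s sessions, 8 Hz low-pass. Detection-recovery tests run at
exactly those conditions. The 100-seed effect-direction experiments (2 x 2
cohort, n = 6 per group, amp_scale_post = 0.5, p_respond 0.90 -> 0.44) run
at 25.4325 Hz (1,017.3/40) with 320 s novel-object sessions and 620 s
injection sessions — the package's chosen simulation scale for cohort-level
Monte Carlo, since every quantity involved (window means, peak amplitudes,
event scores) is band-limited far below that Nyquist rate.

Detection-recovery conditions use the faster dopamine-sensor kernel
($\tau_d = 0.5$ s): with GCaMP6s kinetics at a 0.1 Hz event rate, roughly a
third of transients arrive close enough to a neighbor that the pair merges
into a single local maximum or robs it of prominence — a structural ceiling
of the prominence method (recall plateaus near 0.65 regardless of
amplitude), not an implementation defect. With the 0.5 s kernel the merging
fraction is ~6% and pooled recall/precision exceed 0.9.

What passing these tests does and does not show: the synthetic data have
exactly the structure the pipeline assumes (double-exponential bleach,
shared additive artifact, kernel-shaped transients, Gaussian noise). Real
recordings add hemodynamic contamination, sensor nonlinearity, slow drifts
that are not double-exponential, and artifacts that are neither shared
exactly nor additive — none of which the generator emulates, and none of
which these tests certify. The validation establishes that the
implementation computes the stated quantities correctly and recovers known
ground truth under the stated model, not that the model captures any
particular preparation.

## Degenerate inputs and edge rules

Constant traces z-score to all zeros by convention; non-constant traces
with zero robust scale are an error. Zero-variance smoothed isosbestic
traces regress to slope 0 with a warning. Reversed or out-of-range
integration extents, windows that leave the recording, events without a
full peri-event window, one-class ROC label sets, and sub-Nyquist cutoff
violations are all errors that name the offending quantity. Unsorted event
logs sort on load with a notice; out-of-arena track points are counted in
the error message. All simulation, shuffling, and pipeline entry points
take explicit integer seeds, and equal seeds reproduce outputs bitwise.
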