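---
title: "Quantifying gut mechanosensation: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying gut mechanosensation: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gutwave)
```

`gutwave` analyses experiments in which a participant swallows a
remotely activated vibrating capsule, reports felt sensations with a
button, and is recorded with 31-channel EEG, ECG, electrogastrogram
(EGG), skin conductance, and an abdominal digital stethoscope. This
vignette explains the science implemented in each stage, the tunable
parameters and their defaults, what the synthetic-data generator does
and does not emulate, and the numerical decisions a maintainer should
know about.

## The measurement model

A session holds a ~30-min resting baseline and two 13-min stimulation
blocks, *normal* and *enhanced* intensity in counterbalanced order, with
60 three-second vibrations per block (57 in the enhanced block) at
pseudorandom intervals, each vibration ramping up over ~0.25 s. Three
families of dependent measures are extracted:

1. **Perception.** Counting each vibration and one matched
   non-vibration interval per vibration as trials, the true-positive
   rate TP and false-positive rate FP give the nonparametric
   sensitivity index
   $$A' = \tfrac12 + \frac{(TP-FP)(1+TP-FP)}{4\,TP\,(1-FP)}, \qquad TP \ge FP,$$
   reflected symmetrically when FP > TP so that
   $A'(TP,FP)+A'(FP,TP)=1$. $A'$ is variance-stabilized as
   $2\arcsin\sqrt{A'} \in [0,\pi]$. Individual above-chance performance
   uses the exact binomial tail: the smallest $k$ with
   $P(X \ge k) < 0.05$, $X \sim \mathrm{Bin}(n, 0.5)$ — 70 of 120
   trials for the normal block and 67 of 114 for the enhanced block.
2. **Brain.** Vibration-locked EEG epochs from correctly detected
   stimulations show a late positive deflection over posterior midline
   channels (Cz, CP1, CP2, Pz, POz, O1, Oz, O2), emerging ~400 ms after
   onset, peaking ~600 ms, decaying over the 3 s of stimulation. Its
   amplitude is summarized as the time-mean over 400–720 ms of the
   channel-mean waveform; condition differences are tested with a
   spatiotemporal cluster-based permutation test.
3. **Body.** Gastric myoelectric rhythm (EGG band powers around the
   ~3 cycles-per-minute slow wave), tonic and phasic heart rate, SDNN
   and spectral heart-rate variability, breathing rate estimated from
   respiratory sinus arrhythmia, and deconvolution-based phasic skin
   conductance.

## Stage-by-stage parameters

### Vibration detection

The stethoscope channel is rectified and low-passed (4th-order
Butterworth, default 10 Hz — the envelope time constant is therefore
0.1 s) and segmented by greedy binary least-squares change-point
search with a budget of two change points per expected vibration.
Segments are classified active/quiet against a threshold one quarter of
the way from the envelope median (the quiet floor; vibrations occupy a
minority of the recording) to the largest segment mean — a fixed
fraction rather than 2-means because the two vibration intensities
would otherwise be split apart. Onsets/offsets are refined to the 5%
envelope-contrast crossing at the full envelope rate, which places the
onset at the start of the amplitude ramp rather than mid-ramp. Events
whose duration misses the nominal 3 s by more than `duration_tol`
(default 0.5 s) are *flagged*, never silently dropped; a curation table
(`apply_overrides()`) supports shift/set/add/delete with provenance.
Detection degrades gracefully: a flat channel, or one whose
active/quiet contrast is within 4 SD of the envelope noise, yields an
empty list with a warning.

### Behavioural scoring

A press is credited to a vibration if its onset falls in
`[onset, offset + grace]`. The grace window defaults to 1.0 s: mean
response latencies are ~1 s in the normal condition, so a shorter
window would miscount slow but genuine detections as false positives.
Non-vibration trials are the complementary intervals after each trial
window, truncated to the block, giving matched trial counts. Latency is
press onset minus vibration onset (press releases are recorded but not
scored; a press held across two trials counts once, at its onset). A
block with zero presses is a valid non-responder: TP = 0 and latency
fields are absent.

### EEG

Preprocessing: anti-aliased decimation to the 250 Hz analysis rate,
60 Hz band-rejection (1 Hz bandwidth, 4th order), and a 0.1–80 Hz
bandpass realised as a 4th-order high-pass plus 4th-order low-pass.
All filters run forward–backward; zero-phase filtering doubles the
effective order, which is how the nominal 48 dB/octave edges are met.
The high-pass at 0.1 Hz relative to 125 Hz Nyquist is numerically
delicate; the cascade (rather than a single bandpass design) keeps the
polynomial coefficients well-conditioned.

Epochs are half-open `[-0.2, 3.0)` s windows — exactly 800 samples at
250 Hz, onset sample included at t = 0 — baseline-corrected to the mean
of the 200 ms before onset. Re-referencing to the mastoid average
(TP9/TP10) happens before epoching; baseline correction after.
Artifact rejection is fully automatic and threshold-based: a >50 µV
sample-to-sample step, a >200 µV peak-to-peak range in any sliding
200 ms window, or a <0.5 µV flatline in any 200 ms window rejects the
epoch with a reason code. Manual independent-component curation is
deliberately out of scope — it is visual and irreproducible — and the
epoch thresholds carry the artifact burden; a pluggable hook can
replace them for real recordings with heavier contamination.

The LPP latency is the time of the maximum of the cluster-average
waveform within a configurable search window defaulting to the
400–720 ms amplitude window; "ERP latency" has no unique field
definition, so the search window is exposed rather than fixed.

### Cluster-based permutation test

The unit of exchange is the subject-level condition mean (paired
design): per permutation the two condition labels are swapped within
subjects, equivalently the paired differences are sign-flipped. The
cluster-forming threshold is the two-tailed paired-t critical value at
`cf_alpha = 0.05` per (channel, time) point — the common toolbox
convention. Suprathreshold points connect through temporal contiguity
and spatial adjacency (neighbours = montage distance ≤ 0.4 head radii
in the projected 10-20 layout, which links nearest neighbours such as
Pz–POz without skipping rings); positive and negative clusters form
separately; cluster mass is the sum of member t values; the null
statistic is the per-permutation maximum |mass|; p-values carry the +1
correction so p ≥ 1/(n_perm+1). Defaults: 5000 permutations for real
analyses; the package also enumerates all $2^n$ sign patterns exactly
(`n_perm = "all"`) for small samples, which the tests use to validate
the Monte Carlo path. Time bins are native 4 ms samples; no coarse
binning is applied by default since any presentation-window widths
would be arbitrary.

### EGG

All gastric operations run on an internally decimated 10 Hz copy of
the channel: every band of interest lies below 0.2 Hz, and a windowed
sinc of three low-cutoff cycles at 1000 Hz would need ~90 000 taps.
Spectra use a single Hann taper over the whole block (~0.077 cpm
resolution for 13 min) with power normalization, so summed bin power
equals signal variance and band powers are variance contributions in
µV²; band powers are integrated (summed) over bradygastria
(0.5–2.25 cpm), normogastria (2.5–3.5), tachygastria (3.75–9.75) and
total (0.5–11). The peak frequency is the argmax of the raw (unsmoothed)
spectrum within normogastria. Phase comes from a linear-phase
windowed-sinc FIR bandpass of ±1 cpm around the peak (order = three
cycles of the low cutoff, applied forward–backward) followed by the
FFT analytic signal. Cycles are delimited by upward zero-phase
crossings on the sample grid (no sub-sample interpolation — see below).
A cycle is an artifact if its duration falls strictly outside
mean ± 1 SD of the block's cycle-duration distribution (closed
interval: boundary ties are kept) or if its unwrapped phase decreases
anywhere. This literal mean ± 1 SD rule flags roughly a third of
cycles whenever durations vary at all; only strictly regular rhythms
pass untouched, and keeping boundaries on the sample grid is what lets
an exactly periodic signal come through with zero flags instead of
machine-epsilon duration jitter. Clean-segment power re-estimates
spectra per contiguous clean run on a common frequency grid (direct
DFT) and averages with duration weights.

### Peripheral physiology

R peaks: 5–25 Hz bandpass, squaring, 150 ms moving-window integration,
thresholding at 0.3 × the 99th percentile, refinement to the raw-signal
maximum, 250 ms refractory. IBIs outside ±25% of an 11-beat rolling
median are masked (the standard normal-to-normal cleaning family).
SDNN is the sample SD of clean IBIs; pLF/pHF are Hann-spectrum band
fractions (LF 0.04–0.15 Hz, HF 0.15–0.4 Hz, conventional edges) of the
4 Hz cubic-spline-resampled, linearly detrended tachogram. Tonic HR
averages 60-s windows of 60000 / mean clean IBI. Phasic HR is the
IBI-overlap-weighted instantaneous HR in the 3 s stimulation window
minus the preceding 3 s (beat counting is the alternative; the
weighted form is smoother at these short windows). Sixty pseudo-events
at 3 s spacing, starting 120 s into the baseline, provide the
no-stimulation reference. Breathing rate: per 60-s window, the
detrended resampled tachogram is autocorrelated; the first dominant
positive-lag peak in the 6–30 breaths/min band with a confirming
harmonic at twice the lag gives BR = 60/lag, with parabolic
interpolation refining the lag below the 0.25 s grid. Windows whose
tachogram SD is under 2 ms are skipped: below that the series is
dominated by R-peak sampling quantization, whose ripple is itself
periodic and would otherwise masquerade as breathing. Phasic SCR uses
continuous deconvolution: decimate to 20 Hz, 200 ms moving average,
rolling-median (20 s) tonic removal, Tikhonov-regularized inverse
filtering with a bi-exponential impulse response (rise 0.75 s, decay
2 s — canonical electrodermal constants, exposed in the call), negative
drivers clipped, and the phasic conductance reconvolved so the
per-event maximum over the 3 s stimulation window is in µS; values
under 0.01 µS report as 0. The regularization weight (`lambda = 0.02`
of the spectral peak) attenuates recovered peaks by roughly 10%;
ratios between conditions are unaffected, which is what the group
contrasts consume.

### Group statistics

Outliers are flagged in a single pass per (block, measure) at ±3 SD and
excluded; paired contrasts drop incomplete subjects pairwise and report
two-tailed t, Cohen's d = mean(diff)/SD(diff), and a caller-supplied
Bonferroni family. A constant nonzero difference reports t = ±Inf,
p = 0 (documented convention). The condition-controlled Spearman
correlation rank-transforms both variables, residualizes the ranks on
the condition indicator, and correlates the residuals; p uses the t
approximation with n − 3 df, with a condition-stratified permutation
option. Linear mixed-effects modelling is intentionally delegated: the
package's contract is the tidy long-format measure table
(subject × block × measure), which drops directly into `lme4`-style
tooling.

## The synthetic-data generator

`simulate_session()` emulates the statistical structure the analysis
assumes: the block plan and stimulation schedule (uniform-jitter
pseudorandom onsets with a 4 s minimum gap so non-vibration intervals
always exist); a behavioural responder with per-condition hit rates
(defaults 0.80 normal / 0.95 enhanced, which place normalized A' near
2.5 and 2.8), false-press probabilities per inter-stimulus interval
(0.10 / 0.05), and Gaussian latencies (1.06 ± 0.46 s / 0.74 ± 0.28 s);
an LPP template — half-sine rise from 400 to a 600 ms peak, exponential
decay (τ = 0.8 s) truncated at 3 s — planted on the eight posterior
channels at responded events only, scaled 5 µV normal / 10 µV enhanced
with 30% trial-to-trial amplitude jitter (single-trial LPP variance is
not an observable we can calibrate against, so the 30% default is a
stated guess and a parameter); 1/f background EEG (SD 10 µV) plus
10 Hz alpha, stronger occipitally; a 3 cpm sinusoidal gastric slow wave
in 1/f noise; ECG with per-block tonic HR (70/74/75 bpm), +2 bpm phasic
bumps during stimulation, and 40 ms respiratory sinus arrhythmia at 15
breaths/min; SCR drivers 0.5 s after responded onsets (0.02 / 0.10 µS;
none at baseline) on a slow drift; and an amplitude-modulated 80 Hz
stethoscope burst with the 0.25 s ramp, enhanced amplitude twice
normal. EEG is generated directly at the 250 Hz analysis rate (a
1000 Hz mode exercises the downsampler). Identical (config, seed) pairs
are bit-identical; each channel draws from an independent derived RNG
stream, so dropping channels never perturbs the schedule or the others.

What it does *not* emulate — hence what green tests do and do not show
about real data: no volume-conducted artifact topographies (ocular,
muscle), no electrode drift or pops beyond what the threshold rules
catch, no gastric frequency drift or ectopic beats, no capsule
transit/position effects, and independent noise across EEG channels
rather than spatially correlated background. Parameter-recovery results
therefore validate the *estimators*, not robustness to every artifact
class of ambulatory recordings.

## Problem sizes used by the validation suite

The stochastic checks run at sizes chosen to make their Monte Carlo
error small relative to the tolerance being asserted while staying
desk-scale: null calibration of the cluster test uses 500 independent
20-subject null cohorts at 500 permutations each (the empirical
family-wise rate is compared to 0.05 within its binomial 95% interval);
planted-LPP recovery uses a 20-subject EEG-only cohort with 30/28
trials per block in 240 s blocks and asserts ≥80% cluster-mass
concentration in the planted channels × 400–720 ms bins and amplitude
recovery within 10%; responder calibration pools ≥1000 simulated events
across nine seeds; the end-to-end determinism and direction checks run
a 5-subject full-channel cohort (240 s blocks, 15/14 stimulations)
twice and compare the report bundles byte-for-byte. Stimulation
density, SNRs, and effect sizes in all of these are the generator
defaults.

## Known limitations

* The 5% false positives the generator can place shortly after a trial
  window may fall inside the 1 s grace window of a missed vibration and
  be scored as (very slow) hits; at default rates this biases hit-rate
  recovery by well under one percentage point.
* The EGG cycle boundary convention (sample-grid upward zero-phase
  crossings) quantizes cycle durations to the decimated sampling step;
  this is intentional (see the artifact-rule discussion) but means
  duration statistics carry ±0.1 s granularity.
* The BrainVision and EDF readers cover the common continuous 16-bit /
  float32 subsets used by the supported acquisition systems; EDF+
  annotations and segmented BrainVision files are not parsed.
* Phasic SCR amplitudes are regularization-attenuated (~10%); absolute
  electrodermal amplitudes should be interpreted accordingly, while
  within-session contrasts are unaffected.
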