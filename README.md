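# gutwave

Analysis of gut mechanosensation from vibrating-capsule experiments.

## The problem

How well can people consciously feel their own stomach? One minimally
invasive way to ask is to have participants swallow a capsule that
vibrates on command, press a button whenever they feel it, and record
EEG, electrogastrogram (EGG), ECG, and skin conductance throughout. A
session consists of a resting baseline followed by two stimulation
blocks — *normal* and *enhanced* vibration intensity, counterbalanced —
with 60 three-second vibrations per block (57 in the enhanced block)
delivered pseudorandomly over 13 minutes, each vibration ramping up over
about a quarter second. A digital stethoscope on the abdomen records the
actual vibration timing.

`gutwave` implements the full analysis for this paradigm, for
psychophysiologists who want a tested, scriptable pipeline:

* **Vibration detection** — envelope extraction plus least-squares
  change-point segmentation of the stethoscope trace, with a manual
  override table for curation.
* **Behavioural scoring** — hits, false positives, and response
  latencies per block; the nonparametric sensitivity index

  A' = 1/2 + ((TP − FP)(1 + TP − FP)) / (4 TP (1 − FP))   for TP ≥ FP

  (reflected symmetrically when FP > TP), its variance-stabilizing
  normalization 2·arcsin(√A') ∈ [0, π], and exact binomial above-chance
  thresholds (≥ 70/120 correct trials for the normal block, ≥ 67/114
  for the enhanced block at p < 0.05).
* **Gastric evoked potentials** — 250 Hz analysis rate, 60 Hz
  band-rejection and 0.1–80 Hz Butterworth filtering (zero-phase),
  mastoid re-referencing, epoching of correctly detected vibrations over
  [−0.2, 3.0) s with 200 ms baseline correction, threshold artifact
  rejection (50 µV steps, 200 µV ranges, < 0.5 µV flatlines in 200 ms
  windows), and late-positive-potential metrics over the 400–720 ms
  window on the posterior midline channels {Cz, CP1, CP2, Pz, POz, O1,
  Oz, O2}.
* **Cluster-based permutation statistics** — a from-scratch paired
  spatiotemporal cluster permutation test (channel adjacency ∧ temporal
  contiguity, cluster mass = Σt, Monte Carlo max-mass null with sign
  flips, exhaustive enumeration for small samples).
* **EGG** — Hann-taper spectra with bradygastric (0.5–2.25 cpm),
  normogastric (2.5–3.5 cpm), tachygastric (3.75–9.75 cpm) and total
  (0.5–11 cpm) band powers, FIR + Hilbert instantaneous phase, the
  cycle-regularity artifact decision tree (mean ± SD cycle length,
  nonmonotonic phase), and clean-segment power recomputation.
* **Peripheral physiology** — R-peak detection, interbeat-interval
  cleaning, SDNN and pLF/pHF heart-rate variability, tonic (60-s
  windows) and phasic (3 s stimulation vs 3 s pre-stimulation) heart
  rate with pseudo-events in the baseline, autocorrelation breathing-rate
  estimation from the tachogram, and deconvolution-based phasic skin
  conductance (bi-exponential impulse response, 0.01 µS threshold).
* **Group statistics** — ±3 SD outlier flagging, paired contrasts with
  Cohen's d and Bonferroni correction, and condition-controlled partial
  Spearman correlations.
* **Synthetic sessions** — `simulate_session()` generates complete
  multi-rate recordings (31-channel EEG + ECG + EGG + SCR + stethoscope)
  with known ground truth, so every stage is testable by parameter
  recovery without any participant data.

## Worked example

```r
library(gutwave)

cfg <- session_config(
  block_plan = data.frame(label = c("baseline", "normal", "enhanced"),
                          duration = c(300, 480, 480)),
  n_stims = c(normal = 60, enhanced = 57),
  seed = 7)
sim <- simulate_session(cfg)

## recover vibration timings from the stethoscope trace
det <- detect_vibrations(get_channel(sim$recording, "stetho"),
                         expected_count = 117)
summary(det$offset - det$onset)
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>   2.961   2.969   2.976   2.981   2.992   2.998

## score the button presses for the enhanced block
sc <- score_block(det[det$onset > 780, ], sim$presses,
                  block_span(sim$recording, "enhanced"))
print(sc)
#> <gw_scored_behavior> 57+57 trials TP=0.930 FP=0.088 A'=0.957 (norm 2.725)
#>   latency 0.737 +- 0.308 s; above chance (>=67/114 correct)

## gastric rhythm
sp <- egg_spectrum(get_channel(sim$recording, "egg"),
                   block_span(sim$recording, "baseline"))
#> EGG peak 3.00 cpm; normogastric fraction 0.99

## late positive potential, enhanced block
eeg <- rereference_mastoids(preprocess_eeg(get_channel(sim$recording, "eeg")))
ev  <- classify_events(det[det$onset > 780, ], sc)
ep  <- reject_artifacts(epoch_eeg(eeg, ev, class_filter = "true_positive"))
lpp <- lpp_metrics(average_erp(ep))
#> LPP amplitude 8.64 muV, latency 568 ms (n = 53 epochs)
```

The numbers mean: all 117 vibrations were found with durations tight
around the nominal 3 s; the simulated responder detected 93% of enhanced
vibrations with an 8.8% false-positive rate, i.e. A' = 0.957 (normalized
2.73 radians, comfortably above the 67/114 chance threshold), with a
mean response latency of 0.74 s; the gastric slow wave peaks at the
planted 3 cycles/min with 99% of in-band power in the normogastric
range; and the stimulation-locked late positive potential over the
posterior midline channels averages 8.6 µV in the 400–720 ms window
(the generator planted 10 µV at the template peak, which corresponds to
≈ 8.7 µV after window averaging), peaking near 570 ms.

`run_pipeline(pipeline_config(...))` chains all of the above over a
synthetic cohort and emits a tidy measure table, cluster statistics, and
group contrasts; with a fixed seed the report bundle is byte-identical
across runs.

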