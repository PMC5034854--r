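---
title: "Seizure morphology under phenobarbital: models, measurements and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Seizure morphology under phenobarbital}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(neoseize)
```

## The scientific question

Phenobarbital is the usual first-line anticonvulsant for neonatal
seizures, yet it abolishes seizures in only a minority of babies and
frequently *uncouples* them — the clinical signs disappear while
electrographic seizure activity continues. If the drug damps the cortical
discharge (lower amplitude, less spatial spread) without stopping it, two
practical questions follow: can human readers still see the seizures, and
does an automated detector's performance degrade after the drug?

`neoseize` implements the full desk-scale analysis of these questions:
paired pre/post-drug cohorts, a ten-feature quantification of each
seizure, an SVM-based detector, event-based scoring, and paired
nonparametric statistics. Because clinical neonatal EEG with gold-standard
annotations is not publicly deposited, the package includes a synthetic
cohort generator whose seizures carry known ground truth, plus the
published per-subject summary tables as in-repo fixtures so the group
statistics can be recomputed exactly.

## The synthetic cohort model

A simulated subject is a background process plus a list of seizure
specifications per period.

**Background.** Band-limited (0.5–70 Hz) Gaussian noise with a 1/f-weighted
spectrum — the simplest process that satisfies the clinical grading
criteria. Grade 1 is continuous activity (default 12 µV RMS, i.e. roughly
40–50 µV peak-to-peak, a normal/mildly abnormal term background). Grades
2–4 alternate generalized bursts (default 40 µV RMS) with low-amplitude
inter-burst intervals: under 10 s (grade 2), 10–60 s (grade 3), over 60 s
with inter-burst amplitude below 10 µV (grade 4). Bursts are gated with
0.2 s raised-cosine ramps to avoid spectral splatter.

**Seizures.** Each seizure is a cycle-by-cycle discharge train. The
instantaneous frequency follows a piecewise-linear sweep through the
start/mid/end values (neonatal seizures typically slow); each cycle's
period is jittered multiplicatively (`rhythmicity_jitter` = relative SD).
Morphologies: categories 1–3 are sinusoidal cycles classified by band —
delta [0.5, 4), theta [4, 8), alpha [8, 13] Hz, the standard clinical
convention for the unstated band limits;
category 4 is a ~70 ms biphasic sharp transient per cycle; category 5
appends a slow half-wave filling the cycle. Every cycle is normalised to
peak-to-trough 2 before enveloping, so `peak_amplitude_uV` always means
the peak-to-trough excursion at the envelope maximum regardless of shape.
The envelope is `0.25 + 0.75·sin(πt/D)^0.75`, maximal at the temporal
midpoint — seizures wax and wane, and the midpoint is the measurement
reference. The waveform follows the onset morphology for the first third
and the peak morphology thereafter. `channels_onset` channels are active
from onset; the remainder join after the 10 s onset analysis window
(ramped over 2 s) so the middle third shows `channels_peak` channels.
Non-lead channels are scaled by Uniform(0.65, 0.95).

**The drug effect** multiplies `peak_amplitude_uV` by `amplitude_scale`
and subtracts `channel_delta` from both channel counts (floored at one
channel). In paired generation the post-period specifications *are* the
pre-period ones transformed this way, re-timed on their own record — the
treatment effect is exact at the level of ground truth, and every test of
recovery is a test of the measurement pipeline alone.

**Free parameters** not fixed by the clinical grading scheme, chosen once at
values a neonatal electrophysiologist would call realistic: seizure
durations log-normal with median 103 s; per-subject median amplitude
log-normal around 120 µV with per-seizure scatter (floor 30 µV);
seizure counts per subject truncated-geometric on [1, 68] with mean 6;
background grades drawn with probabilities (0.5, 0.25, 0.15, 0.10);
morphology mix dominated by rhythmic delta; 45 % of seizures change
morphology from onset to peak.

## The ten-feature measurement scheme

Clinical practice makes these measurements by eye with a graticule;
every "visual" criterion here gets a quantitative surrogate so the scheme is
reproducible. The thresholds are deliberate design decisions, calibrated
against the generator and exposed as arguments.

* **Peak amplitude** — in a 10 s window centred on the seizure midpoint,
  each channel is band-limited around its dominant frequency and
  single-cycle peak-to-trough excursions are collected; the reported value
  is the maximum across channels. Two numerical choices matter at low
  signal-to-noise: the per-channel value is the 90th percentile of cycle
  excursions rather than the literal maximum (identical on clean rhythmic
  trains, robust to noise spikes), and when a pre-seizure baseline exists
  the in-band background power is subtracted before converting power to
  sinusoid-geometry amplitude. Transient-dominated discharges instead use
  the median per-complex excursion on a 1–45 Hz band, minus an estimate of
  the baseline excursion contribution.
* **Segment frequencies** — periodogram argmax (zero-padded FFT, 0.5–13.5
  Hz) on the strongest channel over the first 5 s, 5 s around the
  midpoint, and the last 5 s; seizures under 15 s use thirds. Spike
  morphologies use the transient repetition rate, with missed-transient
  gaps normalised by their nearest integer multiple of the base interval.
  A `low_confidence` attribute flags windows whose spectral peak is less
  than 15× the band median (a broadband-noise periodogram peaks at ~5–8×
  its median).
* **Frequency variability** — sample SD (n−1) of the three segment
  frequencies; n−1 is the convention statistical software applies to the
  three-point SD.
* **Morphology** (onset = first 10 s, peak = 10 s around the midpoint) —
  transients are detected on an 8–45 Hz band (where slow rhythmic activity
  carries little energy) with a sparsity criterion (duty cycle < 0.25,
  which excludes rhythmic alpha whose fundamental also falls in the band)
  and a < 200 ms width criterion. If transients dominate, the amplitude of
  the rhythmic component at the repetition rate relative to the transient
  amplitude separates spike-and-wave (ratio > 0.45 → category 5) from
  spikes alone (4); otherwise the dominant-frequency band gives 1–3.
* **Rhythmicity** — discharge times over the whole seizure
  (envelope-normalised peak picking on a deliberately wide band — a narrow
  filter rings through irregular cycles and under-reports dysrhythmia),
  then the CV of successive inter-discharge intervals after removing the
  slow frequency-sweep trend (running-median detrend) with a robust
  (MAD-based) CV. Mapping: CV < 0.15 → 3, 0.15–0.35 → 2, > 0.35 → 1.
* **Background grade** — channel-averaged 0.5 s moving-RMS envelope on
  ≥ 5 min of seizure-free signal around the annotation; suppressed
  stretches (envelope < 5 µV RMS, ≥ 2 s) are inter-burst intervals; the
  median IBI gives the grade, with the grade-4 label additionally
  requiring inter-burst amplitude below 10 µV.
* **Channel involvement** (onset = first 10 s, peak = middle third) — a
  channel is involved when its power in a band centred on the dominant
  discharge frequency exceeds k = 4 × that channel's pre-seizure baseline
  power in the same band (no quantitative criterion exists for
  "showing seizure discharges"; k is a design default); transient-dominated seizures count channels with
  detectable transients above twice that margin on the baseline noise
  scale.

**What closure shows, and does not.** On rendered seizures the pipeline
recovers amplitude within ±10 %, segment frequencies within ±0.25 Hz,
channel counts exactly for rhythmic morphologies at adequate
signal-to-noise, and the injected rhythmicity class. Channel counts in
the onset window (envelope minimum) for sparse spike trains can be off by
one, and amplitude measurement on burst-suppression backgrounds whose
bursts exceed the seizure amplitude is unreliable — both are limitations
of any fixed quantitative surrogate at SNR below ~1, and the validation
suite asserts exactness only where the estimator is defensible. None of
this guarantees performance on real EEG: the generator contains no
artifacts beyond high-energy transients, no electrode noise, and no
non-stationary background.

## The detector

The architecture mirrors the standard neonatal SVM detector: artifact
masking by an epoch-energy threshold, anti-alias filtering and resampling
to 32 Hz, 8 s epochs with 50 % overlap, per-channel features, an SVM with
sigmoid probability output, moving-average smoothing, per-epoch maximum
across channels, and a threshold adjustable in steps of 0.1 (default
0.3). In place of a proprietary large feature set with pre-trained
weights, a documented 16-feature subset spanning the same three groups
is used and the model is retrained on synthetic data: RMS, variance, line
length, zero crossings, Hjorth mobility/complexity, AR(9) residual
variance, nonlinear energy; total/delta/theta/alpha power, peak frequency,
80 % spectral edge (configurable); histogram Shannon entropy and spectral
entropy. The claims tested here concern the robustness of the
SVM-probability architecture to the drug effect, not any particular set of
weights.

Numerical choices: the anti-alias filter is a zero-phase FFT lowpass with
a raised-cosine transition from 12.8 to ~13.95 Hz (a stable IIR cascade
cannot deliver 20 dB attenuation 9 % above its cutoff); training epochs
are labelled seizure when at least half-covered by a gold annotation and
boundary epochs (partial overlap) are excluded so mixed content dilutes
neither class, while evaluation labels use any overlap; the artifact
threshold is the 97.5th percentile of training epoch energies, floored
above the observed seizure-epoch energies so ictal activity itself is
never masked; the smoothing window is 15 epochs (~60 s); class weights are
inverse-frequency; the RBF width defaults to the 1/d heuristic, with an
optional small cross-validated grid (`tuneGamma = TRUE`); the default
keeps training cheap and exactly reproducible.

Event scoring: a gold seizure is detected if at least one detector event
overlaps it by ≥ 1 s (a seizure split across detections counts once);
unmatched detections are false detections. The detection rate per subject
and period is the detected proportion.

## Statistics

Pre/post seizure counts are matched by truncating both periods to the
first min(n_pre, n_post) seizures in time order. Per-subject summaries:
median for amplitude, duration, channel counts and frequency variability;
maximum for the two small ordinal scales (rhythmicity, background);
proportion for detection rate and morphology change. Group dispersion uses
the weighted-average percentile at position (n+1)p — the one convention
that reproduces every published IQR bound from the per-subject tables
(46.13, 89.25, 1.38). Rounding for display is half-away-from-zero, as
statistical packages print (46.125 → 46.13). The paired comparison is the
Wilcoxon signed-rank test with zeros dropped, mid-ranks for ties, and the
tie-corrected normal approximation without continuity correction (the
default pathway of standard commercial statistics packages); an exact
enumeration path (n ≤ 16) validates the asymptotic one. The two paths
always agree in W⁺; their p-values can only agree up to the granularity of
the discrete null — at n = 15–16 the largest point mass of |W−µ| is of
order 0.01–0.03, and the test suite asserts agreement at exactly that
bound rather than an arbitrary constant. Ties in per-subject change counts
(post = pre) count as "not reduced".

## Problem sizes

The validation suite and the acceptance script use desk-scale sizes chosen
as the package's own defaults: the repeated-seed effect study runs 50
cohorts of 18 subjects with amplitude scale 0.435 and one channel lost,
measuring per-subject medians over the first eight matched seizures from
single-channel snippet renders on continuous background; the detector
study uses one 18-subject cohort at 1200 s of EEG per subject and period
(a four-subject training cohort, disjoint seed stream), threshold 0.3. On
synthetic records — which are cleaner than clinical EEG — detection rates
sit near the ceiling in both periods; the meaningful read-out is the
*difference* between periods, not the absolute level, and absolute
detection rates on real recordings are expected to be substantially lower.

## Known limitations

* The generator emulates the statistical structure of neonatal ictal EEG,
  not its biophysics; no neural-mass modelling, no artifacts beyond
  high-energy transients, no ECG/respiration channels (irrelevant to every
  measured feature).
* Quantitative surrogates for visual criteria are calibrated on the
  generator; their thresholds (CV breaks, involvement ratio k = 4,
  suppression envelope 5 µV RMS, spike-wave coupling ratio 0.45) are
  exposed as arguments and would need re-calibration for real data.
* Amplitude measurement on grade 3–4 backgrounds whose bursts exceed the
  seizure amplitude is unreliable; the per-subject median mitigates but
  does not remove this.
* The detector is retrained per study on synthetic data; its absolute
  operating points are not comparable to any clinically validated system.
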