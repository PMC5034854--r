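# neoseize

Quantitative analysis of how phenobarbital — the first-line anticonvulsant
for neonatal seizures — changes the morphology of electrographic seizures,
and whether those changes affect automated seizure detection.

Phenobarbital often *uncouples* seizures: the clinical signs disappear
while the electrographic discharge continues. A plausible mechanism is that
the drug damps the amplitude and spatial spread of the cortical discharge.
`neoseize` implements the complete desk-scale analysis around that
question, for clinical neurophysiologists and algorithm developers:

* **Synthetic neonatal EEG.** An 8-channel bipolar cohort generator
  (9-electrode neonatal 10–20 montage, 250/256 Hz, 0.5–70 Hz band) with
  graded background abnormality (1 = continuous … 4 = inactive, inter-burst
  interval > 60 s), five ictal morphologies (rhythmic delta/theta/alpha,
  spikes/sharp waves, spike-and-wave complexes), mid-seizure amplitude
  envelopes, within-seizure frequency slowing, channel spread from onset to
  peak, and a configurable drug effect (amplitude factor, channel-count
  reduction). Every seizure's ground truth is retained, so measured
  features can be validated by closure.
* **Ten-feature seizure quantification.** Peak-to-trough amplitude at the
  seizure midpoint, rhythmicity score (1–3, from the CV of inter-discharge
  intervals), background grade (1–4, envelope-threshold inter-burst
  detection), discharge morphology at onset and peak (1–5), duration,
  frequency variability (SD of start/mid/end segment frequencies),
  morphology change, and channels involved at onset and peak.
* **An SVM seizure detector.** Anti-alias filtering to a 32 Hz working
  rate, 8 s epochs with 50 % overlap, 16 features per channel and epoch
  (time-domain, spectral and information-theoretic), a Gaussian-kernel SVM
  with Platt sigmoid probabilities, moving-average smoothing, and an
  adjustable detection threshold in steps of 0.1 (default 0.3).
* **Event-based scoring and paired statistics.** Gold/detector event
  matching (≥ 1 s overlap), per-subject summaries (median / maximum /
  proportion), weighted-average `(n+1)p` percentiles, and a Wilcoxon
  signed-rank test (zeros dropped, mid-ranks, tie-corrected normal
  approximation, exact enumeration path for validation):

  W⁺ = Σ rank(|dᵢ|) over dᵢ > 0,  z = (W⁺ − n(n+1)/4) / √(n(n+1)(2n+1)/24 − Σ(t³−t)/48)

* **In-repo per-subject tables.** The published per-baby values (matched
  seizure counts; median peak amplitude and median channels at seizure
  peak, pre and post phenobarbital) ship as plain-text fixtures so the
  group statistics can be recomputed exactly.

## Worked example

```r
library(neoseize)

rt <- reproduceTables()
rt$table
#>            variable pre_median      pre_iqr post_median    post_iqr     p_value
#> 1 peak_amplitude_uV        123 62.50-225.00        53.5 46.13-89.25 0.001176564
#> 2     channels_peak          4    3.00-8.00         3.0   1.38-4.00 0.018062656
rt$amplitude_drop_pct        # 56.50407  (% drop in group median amplitude)
rt$amplitude$n_reduced       # 14    (of 18 babies with reduced amplitude)
rt$channels$n_reduced        # 10    (of 18 with fewer channels at peak)
rt$matched_total             # pre 262 / post 262 matched seizures
```

The amplitude comparison says: across 18 neonates the median peak seizure
amplitude fell from 123 µV to 53.5 µV after phenobarbital (p ≈ 0.001), and
the median number of channels involved at the seizure peak fell from 4 to
3 (p ≈ 0.018).

A small synthetic round trip:

```r
sp  <- seizureSpec(onset_s = 60, duration_s = 90, peak_amplitude_uV = 123,
                   channels_onset = 1, channels_peak = 5)
sn  <- renderSeizureSnippet(sp, seed = 1)
peakAmplitude(sn$record, sn$annotation)   # ~123 (within ±10 %)
applyDrugEffect(sp, drugEffect(0.435, 1))$peak_amplitude_uV  # 53.5
```

The full pipeline (simulate → train → detect → score → compare) is
`runPipeline(defaultConfig())`; a thin CLI with the same stages lives at
`inst/scripts/neoseize` (`simulate`, `features`, `train`, `detect`,
`evaluate`, `compare`, `reproduce-tables`).

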