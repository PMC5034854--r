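#' Background EEG specification
#'
#' Parameters of the simulated background activity, graded 1-4 after the
#' clinical scheme used to score background abnormality at seizure time:
#' 1 = normal/mildly abnormal continuous EEG; 2 = moderate abnormality with
#' inter-burst intervals (IBIs) under 10 s; 3 = severe abnormality, IBI
#' 10-60 s; 4 = inactive, inter-burst amplitude below 10 uV with IBI over
#' 60 s.
#'
#' @param grade integer background grade 1-4.
#' @param burst_amplitude_uV RMS amplitude of burst (or, for grade 1,
#'   continuous) activity in uV.
#' @param ibi_s characteristic inter-burst interval in seconds; required for
#'   grades 2-4 and must fall in the grade's range. Defaults: 5 s (grade 2),
#'   30 s (grade 3), 80 s (grade 4).
#' @param interburst_rms_uV RMS of inter-burst activity; kept low enough that
#'   the inter-burst amplitude envelope stays below 10 uV.
#' @return A validated list of class `backgroundSpec`.
#' @examples
#' backgroundSpec(3)
#' @export
backgroundSpec <- function(grade, burst_amplitude_uV = if (grade == 1) 12 else 40,
                           ibi_s = c(NA, 5, 30, 80)[grade],
                           interburst_rms_uV = 2) {
  if (length(grade) != 1L || !grade %in% 1:4)
    stop("background grade must be 1, 2, 3 or 4, got ", grade)
  if (burst_amplitude_uV <= 0) stop("burst_amplitude_uV must be positive")
  if (grade == 2 && !(ibi_s > 0 && ibi_s < 10))
    stop("grade 2 requires inter-burst interval < 10 s")
  if (grade == 3 && !(ibi_s >= 10 && ibi_s <= 60))
    stop("grade 3 requires inter-burst interval in [10, 60] s")
  if (grade == 4 && !(ibi_s > 60))
    stop("grade 4 requires inter-burst interval > 60 s")
  if (grade == 4 && interburst_rms_uV > 3)
    stop("grade 4 inter-burst activity must stay below a 10 uV envelope")
  structure(list(grade = as.integer(grade),
                 burst_amplitude_uV = burst_amplitude_uV,
                 ibi_s = ibi_s,
                 interburst_rms_uV = interburst_rms_uV),
            class = "backgroundSpec")
}

#' Ground-truth specification of one ictal discharge
#'
#' Describes a single simulated seizure: where it lies in the record, the
#' waveform morphology at onset and at the seizure peak, a within-seizure
#' frequency trajectory (neonatal seizures typically slow towards the end),
#' the peak-to-trough amplitude at the envelope maximum, how many channels
#' are involved at onset and at peak, and the cycle-to-cycle rhythmicity
#' jitter.
#'
#' Morphology categories: 1 = rhythmic delta (RDD, 0.5 to <4 Hz),
#' 2 = rhythmic theta (RDT, 4 to <8 Hz), 3 = rhythmic alpha (RDA, 8-13 Hz),
#' 4 = spikes/sharp waves (transients shorter than 200 ms), 5 = spike-and-wave
#' or sharp-and-slow-wave complexes. For categories 4 and 5 the frequency
#' fields give the discharge repetition rate.
#'
#' @param onset_s seizure onset, seconds from record start.
#' @param duration_s seizure duration, seconds (> 0).
#' @param morphology_onset,morphology_peak categories 1-5.
#' @param freq_start,freq_mid,freq_end dominant discharge frequency (Hz) in
#'   the first 5 s, at mid-seizure and in the last 5 s.
#' @param peak_amplitude_uV peak-to-trough amplitude (uV) at the envelope
#'   maximum (mid-seizure) on the most involved channel.
#' @param channels_onset,channels_peak number of involved channels in the
#'   onset window and in the middle third (1-8, onset <= peak: seizures
#'   spread, they do not retract before their peak).
#' @param rhythmicity_jitter relative SD of the cycle period (dimensionless);
#'   0 is metronomic, ~0.25 minimal dysrhythmia, ~0.5 marked dysrhythmia.
#' @param nyquist_hz frequency ceiling for validation (half the sampling
#'   rate of the target record).
#' @return A validated list of class `seizureSpec`.
#' @examples
#' seizureSpec(onset_s = 60, duration_s = 90, peak_amplitude_uV = 120)
#' @export
seizureSpec <- function(onset_s, duration_s,
                        morphology_onset = 1L, morphology_peak = 1L,
                        freq_start = 2, freq_mid = 1.6, freq_end = 1.2,
                        peak_amplitude_uV = 100,
                        channels_onset = 2L, channels_peak = 4L,
                        rhythmicity_jitter = 0.1,
                        nyquist_hz = 125) {
  if (duration_s <= 0) stop("duration_s must be > 0")
  if (onset_s < 0) stop("onset_s must be >= 0")
  if (!morphology_onset %in% 1:5 || !morphology_peak %in% 1:5)
    stop("morphology categories must be in 1..5")
  fr <- c(freq_start, freq_mid, freq_end)
  if (any(fr <= 0) || any(fr >= nyquist_hz))
    stop("frequencies must be positive and below Nyquist")
  if (peak_amplitude_uV <= 0) stop("peak_amplitude_uV must be positive")
  if (channels_onset < 1 || channels_peak < 1 ||
      channels_onset > 8 || channels_peak > 8)
    stop("channel counts must lie in 1..8")
  if (channels_onset > channels_peak)
    stop("channels_onset must not exceed channels_peak (spread only)")
  if (rhythmicity_jitter < 0) stop("rhythmicity_jitter must be >= 0")
  structure(list(onset_s = onset_s, duration_s = duration_s,
                 morphology_onset = as.integer(morphology_onset),
                 morphology_peak = as.integer(morphology_peak),
                 freq_start = freq_start, freq_mid = freq_mid,
                 freq_end = freq_end,
                 peak_amplitude_uV = peak_amplitude_uV,
                 channels_onset = as.integer(channels_onset),
                 channels_peak = as.integer(channels_peak),
                 rhythmicity_jitter = rhythmicity_jitter),
            class = "seizureSpec")
}

#' Phenobarbital effect on seizure specifications
#'
#' The simulated drug effect: a multiplicative factor on peak seizure
#' amplitude and an integer reduction of the involved-channel counts
#' (floored at one channel). The headline empirical effect is an amplitude
#' factor of 0.435 (a 56.5 percent drop in the group median) together with
#' reduced channel involvement.
#'
#' @param amplitude_scale multiplicative factor on `peak_amplitude_uV` (> 0).
#' @param channel_delta non-negative integer subtracted from both channel
#'   counts, floored at 1.
#' @return A list of class `drugEffect`.
#' @examples
#' drugEffect(amplitude_scale = 0.435, channel_delta = 1)
#' @export
drugEffect <- function(amplitude_scale = 0.435, channel_delta = 1L) {
  if (amplitude_scale <= 0) stop("amplitude_scale must be positive")
  if (channel_delta < 0 || channel_delta != round(channel_delta))
    stop("channel_delta must be a non-negative integer")
  structure(list(amplitude_scale = amplitude_scale,
                 channel_delta = as.integer(channel_delta)),
            class = "drugEffect")
}

#' Apply a drug effect to a seizure specification
#'
#' Scales the peak amplitude and reduces the channel counts (floored at 1).
#' All other ground-truth parameters are untouched.
#'
#' @param spec a [seizureSpec()].
#' @param effect a [drugEffect()].
#' @return A new `seizureSpec`.
#' @examples
#' s <- seizureSpec(0, 60, peak_amplitude_uV = 123, channels_peak = 4)
#' applyDrugEffect(s, drugEffect(0.435, 1))$peak_amplitude_uV
#' @export
applyDrugEffect <- function(spec, effect) {
  stopifnot(inherits(spec, "seizureSpec"), inherits(effect, "drugEffect"))
  spec$peak_amplitude_uV <- spec$peak_amplitude_uV * effect$amplitude_scale
  spec$channels_onset <- max(1L, spec$channels_onset - effect$channel_delta)
  spec$channels_peak <- max(1L, spec$channels_peak - effect$channel_delta)
  spec
}
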