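# One discharge cycle, unit peak-to-trough of 2 (matching a unit-amplitude
# sine), n_c samples. Categories 1-3 are a full sine cycle; 4 is a biphasic
# sharp transient (< 200 ms) followed by silence; 5 is the transient followed
# by a slow half-wave filling the cycle.
dischargeCycle <- function(n_c, morphology, fs) {
  if (morphology <= 3L) return(sin(2 * pi * (seq_len(n_c) - 1) / n_c))
  w <- max(6L, round(0.07 * fs))            # ~70 ms sharp transient
  k1 <- max(4L, round(2 * w / 3)); k2 <- max(2L, w - k1 + w %/% 2)
  spike <- c(sin(pi * seq(0, 1, length.out = k1)),
             -0.5 * sin(pi * seq(0, 1, length.out = k2)))
  rest <- n_c - length(spike)
  if (rest < 0) { spike <- spike[seq_len(n_c)]; rest <- 0 }
  if (morphology == 4L) {
    cyc <- c(spike, numeric(rest))
  } else {
    wave <- 0.75 * sin(pi * seq(0, 1, length.out = max(rest, 1)))[seq_len(rest)]
    cyc <- c(spike, wave)
  }
  cyc * 2 / diff(range(cyc))
}

# piecewise-linear instantaneous frequency start -> mid -> end
freqAt <- function(t, D, f0, f1, f2) {
  ifelse(t < D / 2,
         f0 + (f1 - f0) * t / (D / 2),
         f1 + (f2 - f1) * (t - D / 2) / (D / 2))
}

#' Render one ictal discharge waveform
#'
#' Produces the channel-resolved seizure waveform described by a
#' [seizureSpec()]: a cycle-by-cycle discharge train whose instantaneous
#' frequency sweeps `freq_start` -> `freq_mid` -> `freq_end`, whose cycle
#' periods carry the specified rhythmicity jitter, modulated by an amplitude
#' envelope that peaks mid-seizure at `peak_amplitude_uV` (peak-to-trough).
#' The waveform morphology follows `morphology_onset` in the first third of
#' the seizure and `morphology_peak` thereafter. Exactly `channels_onset`
#' channels are active from onset; the remaining `channels_peak -
#' channels_onset` channels join at the spread time (after the onset analysis
#' window) so the middle third shows `channels_peak` active channels.
#'
#' @param spec a [seizureSpec()].
#' @param montage a [neonatalMontage()].
#' @param seed integer seed.
#' @return A list: `waveform` (samples x 8 matrix, uV; zero outside active
#'   channels), `fs`, `discharge_times` (s, cycle starts on the lead
#'   channel), `lead_channel`, `onset_channels`, `peak_channels`.
#' @examples
#' w <- renderSeizure(seizureSpec(0, 30, peak_amplitude_uV = 80),
#'                    neonatalMontage(), seed = 3)
#' dim(w$waveform)
#' @export
renderSeizure <- function(spec, montage = neonatalMontage(), seed = 1L) {
  stopifnot(inherits(spec, "seizureSpec"))
  validateMontage(montage)
  if (spec$channels_peak > nrow(montage$pairs))
    stop("channels_peak exceeds montage size")
  fs <- montage$samplingRate
  D <- spec$duration_s
  n <- round(D * fs)
  set.seed(as.integer(seed))

  # lead-channel discharge train
  x <- numeric(n)
  times <- numeric(0)
  t <- 0
  while (t < D) {
    f <- freqAt(t, D, spec$freq_start, spec$freq_mid, spec$freq_end)
    period <- (1 / f) * max(0.3, 1 + spec$rhythmicity_jitter * stats::rnorm(1))
    n_c <- max(2L, round(period * fs))
    morph <- if (t < D / 3) spec$morphology_onset else spec$morphology_peak
    cyc <- dischargeCycle(n_c, morph, fs)
    i0 <- round(t * fs) + 1L
    i1 <- min(n, i0 + n_c - 1L)
    if (i0 > n) break
    x[i0:i1] <- cyc[seq_len(i1 - i0 + 1L)]
    times <- c(times, t)
    t <- t + n_c / fs
  }

  # amplitude envelope: maximal (= pp/2) at the temporal midpoint
  tt <- (seq_len(n) - 0.5) / fs
  env <- (0.25 + 0.75 * sin(pi * tt / D)^0.75) * spec$peak_amplitude_uV / 2
  x <- x * env

  chans <- sample.int(8L, spec$channels_peak)
  onset_ch <- chans[seq_len(spec$channels_onset)]
  spread_ch <- setdiff(chans, onset_ch)
  gains <- c(1, stats::runif(length(chans) - 1L, 0.65, 0.95))

  # spread channels join after the onset analysis window
  t_spread <- if (D > 13) max(10, D / 3.5) else D / 3
  ramp <- rep(1, n)
  i_sp <- min(n, round(t_spread * fs) + 1L)
  if (i_sp > 1L) {
    ramp[seq_len(i_sp - 1L)] <- 0
    k <- min(n - i_sp, round(2 * fs))
    if (k > 0)
      ramp[i_sp:(i_sp + k - 1L)] <- 0.5 - 0.5 * cos(pi * seq_len(k) / k)
  }

  wf <- matrix(0, n, 8L)
  for (j in seq_along(chans)) {
    g <- gains[j] * x
    if (chans[j] %in% spread_ch) g <- g * ramp
    wf[, chans[j]] <- g
  }
  colnames(wf) <- montage$channels
  list(waveform = wf, fs = fs, discharge_times = times,
       lead_channel = chans[1L], onset_channels = sort(onset_ch),
       peak_channels = sort(chans))
}
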