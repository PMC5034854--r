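# ---- low-level signal helpers ------------------------------------------

# Zero-phase FFT bandpass with raised-cosine band edges and reflection
# padding. Frequency-domain filtering is used because the analysis bands can
# be very narrow relative to the sampling rate (e.g. 1-3 Hz at 256 Hz),
# where high-order IIR filters are numerically fragile.
bandpass <- function(x, fs, lo, hi) {
  hi <- min(hi, 0.49 * fs)
  lo <- max(lo, 0.05)
  if (lo >= hi) lo <- hi / 2
  n <- length(x)
  pad <- min(n, round(3 * fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  m <- 2^ceiling(log2(length(xp)))
  xp <- c(xp, numeric(m - length(xp)))
  f <- (0:(m - 1)) * fs / m
  f <- pmin(f, fs - f)
  H <- numeric(m)
  tw_lo <- 0.25 * lo
  tw_hi <- 0.1 * hi
  H[f >= lo & f <= hi] <- 1
  selL <- f >= lo - tw_lo & f < lo
  H[selL] <- 0.5 - 0.5 * cos(pi * (f[selL] - (lo - tw_lo)) / tw_lo)
  selH <- f > hi & f <= hi + tw_hi
  H[selH] <- 0.5 + 0.5 * cos(pi * (f[selH] - hi) / tw_hi)
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

# zero-padded periodogram peak in [flo, fhi]; returns freq with a
# low-confidence attribute when the peak does not dominate the band
psdPeak <- function(x, fs, flo = 0.5, fhi = 13.5) {
  x <- x - mean(x)
  n <- length(x)
  nfft <- 2^ceiling(log2(max(n * 8L, 1024L)))
  X <- stats::fft(c(x * signal::hanning(n), numeric(nfft - n)))
  half <- nfft %/% 2
  p <- Mod(X[seq_len(half)])^2
  f <- (seq_len(half) - 1) * fs / nfft
  sel <- f >= flo & f <= fhi
  ps <- p[sel]; fsel <- f[sel]
  i <- which.max(ps)
  conf <- ps[i] / (stats::median(ps) + .Machine$double.eps)
  # a broadband (noise-only) periodogram peaks at ~5-8x its median; a real
  # rhythmic discharge is one to two orders of magnitude above it
  structure(fsel[i], low_confidence = conf < 15)
}

# moving RMS envelope, window in seconds
movingRMS <- function(x, fs, win_s = 0.5) {
  k <- max(3L, round(win_s * fs))
  sq <- as.numeric(stats::filter(x^2, rep(1 / k, k), sides = 2))
  sq[is.na(sq)] <- stats::ave(x^2, FUN = mean)[is.na(sq)]
  sqrt(pmax(sq, 0))
}

# successive-extrema peak-to-trough excursions of a (narrowband) signal
cycleExcursions <- function(x) {
  d <- diff(x)
  turn <- which(d[-1] * d[-length(d)] < 0) + 1L
  if (length(turn) < 2L) return(numeric(0))
  abs(diff(x[turn]))
}

# Sharp-transient detector. Spikes/sharp waves are brief (< 200 ms)
# high-slope excursions: they are detected on a high band (8-45 Hz) where
# rhythmic delta/theta discharges and slow waves carry little energy, must
# be sparse in time (low duty cycle, unlike rhythmic alpha whose fundamental
# also falls in the band), and must be brief at half height. Peak-to-trough
# amplitudes are then measured on the broadband (1-45 Hz) signal around
# each transient, so spike-and-wave complexes report the full complex
# amplitude. Returns times (s), amplitudes and the repetition rate.
detectTransients <- function(x, fs, min_rate = 0.3) {
  none <- list(times = numeric(0), pp = numeric(0), rate = NA_real_)
  hp <- bandpass(x, fs, 8, 45)
  a <- abs(hp)
  # the floor term keeps numerically tiny high-band residue of smooth
  # rhythmic discharges from registering as transients
  thr <- max(4 * stats::mad(hp), 0.25 * stats::sd(x))
  if (thr == 0) return(none)
  pk <- pracma::findpeaks(a, minpeakheight = thr,
                          minpeakdistance = max(2L, round(0.25 * fs)))
  if (is.null(pk) || nrow(pk) < 3L) return(none)
  loc <- sort(pk[, 2])
  # sparsity: transients occupy a small fraction of the window
  duty <- mean(a > 0.3 * stats::median(a[loc]))
  if (duty > 0.25) return(none)
  widths <- vapply(loc, function(i) {
    h <- a[i] / 2
    lo <- i; hi <- i
    while (lo > 1 && a[lo - 1] > h) lo <- lo - 1L
    while (hi < length(a) && a[hi + 1] > h) hi <- hi + 1L
    (hi - lo + 1L) / fs
  }, numeric(1))
  loc <- loc[widths < 0.2]
  if (length(loc) < 3L) return(none)
  wb <- bandpass(x, fs, 1, 45)
  pp <- vapply(loc, function(i) {
    i0 <- max(1L, i - round(0.1 * fs))
    i1 <- min(length(wb), i + round(0.1 * fs))
    diff(range(wb[i0:i1]))
  }, numeric(1))
  rate <- 1 / fundamentalInterval(diff(loc) / fs)
  span <- (loc[length(loc)] - loc[1]) / fs
  if (length(loc) / max(span, 1e-9) < min_rate) return(none)
  list(times = (loc - 1) / fs, pp = pp, rate = rate)
}

# Fundamental repetition interval from inter-transient intervals that may
# include integer-multiple gaps where weak transients went undetected: each
# interval is divided by its nearest multiple of the base interval.
fundamentalInterval <- function(iti) {
  if (!length(iti)) return(NA_real_)
  T0 <- stats::quantile(iti, 0.15, names = FALSE)
  if (T0 <= 0) return(stats::median(iti))
  k <- pmax(1, round(iti / T0))
  stats::median(iti / k)
}

transientDominated <- function(tr, win_s) {
  length(tr$times) >= max(3L, floor(0.3 * win_s))
}

# window bounds (seconds, record clock) for the three analysis windows
annWindow <- function(ann, at = c("onset", "peak", "midthird")) {
  at <- match.arg(at)
  on <- ann$onset_s; D <- ann$duration_s
  switch(at,
    onset = c(on, on + min(10, D)),
    peak = {
      mid <- on + D / 2
      c(max(on, mid - 5), min(on + D, mid + 5))
    },
    midthird = c(on + D / 3, on + 2 * D / 3))
}

checkAnnotation <- function(record, ann) {
  if (is.null(ann$onset_s) || is.null(ann$duration_s))
    stop("annotation must have onset_s and duration_s")
  if (ann$duration_s <= 0) stop("annotation duration must be > 0")
  if (ann$onset_s < 0 ||
      ann$onset_s + ann$duration_s > recordDuration(record) + 1e-6)
    stop("annotation window lies outside the record")
  invisible(TRUE)
}

# channel with the strongest discharge activity in a window
leadChannel <- function(record, from_s, to_s) {
  w <- windowSamples(record, from_s, to_s)
  pw <- apply(w, 2, function(x)
    mean(bandpass(x, samplingRate(record), 0.5, 20)^2))
  which.max(pw)
}

noInvolvedChannel <- function(msg) {
  stop(errorCondition(msg, class = c("noInvolvedChannel", "error")))
}

# ---- the ten seizure features ------------------------------------------

#' Peak seizure amplitude
#'
#' Peak-to-trough amplitude (uV) of the highest-amplitude discharge in a
#' 10 s window centred on the seizure's temporal midpoint, the common
#' reference point for seizure "strength". Each channel is band-limited
#' around its dominant discharge frequency (or, for transient-dominated
#' discharges, 1-45 Hz around detected transients) and single-cycle
#' peak-to-trough excursions are collected; the per-channel amplitude is a
#' high quantile (90th percentile) of those excursions, which equals the
#' maximum on clean rhythmic discharges but resists background noise. The
#' result is the maximum across channels.
#'
#' @param record an [EEGRecord-class].
#' @param ann one annotation (list/row with `onset_s`, `duration_s`).
#' @return amplitude in uV.
#' @examples
#' m <- neonatalMontage()
#' fs <- m$samplingRate
#' t <- (1:(fs * 30)) / fs
#' sig <- matrix(0, length(t), 8)
#' sig[, 3] <- 50 * sin(2 * pi * 2 * t)
#' rec <- EEGRecord(sig, fs, m$channels)
#' peakAmplitude(rec, list(onset_s = 0, duration_s = 30))  # ~100
#' @export
peakAmplitude <- function(record, ann) {
  checkAnnotation(record, ann)
  wdw <- annWindow(ann, "peak")
  w <- windowSamples(record, wdw[1], wdw[2])
  fs <- samplingRate(record)
  # pre-seizure baseline (post-seizure fallback) for background-noise
  # subtraction; NULL when the annotation leaves no baseline
  bl <- NULL
  b1 <- max(0, ann$onset_s - 30)
  e <- ann$onset_s + ann$duration_s
  if (ann$onset_s - b1 >= 5) {
    bl <- windowSamples(record, b1, ann$onset_s)
  } else if (recordDuration(record) - e >= 5) {
    bl <- windowSamples(record, e, min(recordDuration(record), e + 30))
  }
  amp <- vapply(seq_len(ncol(w)), function(j) {
    x <- w[, j]
    if (stats::sd(x) == 0) return(0)
    tr <- detectTransients(x, fs)
    if (transientDominated(tr, diff(wdw))) {
      ppv <- stats::median(tr$pp)
      if (!is.null(bl)) {
        # background excursions inflate per-transient ranges; subtract the
        # typical baseline excursion over a comparable time span
        nb <- bandpass(bl[, j], fs, 1, 45)
        k <- round(0.2 * fs)
        nwin <- floor(length(nb) / k)
        exc <- vapply(seq_len(nwin), function(wn)
          diff(range(nb[((wn - 1) * k + 1):(wn * k)])), numeric(1))
        # the median transient sees roughly a third of the full baseline
        # range (noise at the two fixed extremum times, not the windowed
        # maximum over the whole chunk)
        ppv <- max(ppv - 0.35 * stats::median(exc), 0)
      }
      return(ppv)
    }
    f0 <- as.numeric(psdPeak(x, fs, 0.5, 16))
    y <- bandpass(x, fs, 0.55 * f0, 1.9 * f0)
    # drop the window edges: reflection-padding kinks can ring, and the
    # impulse response of a narrow band is long at low frequencies
    trim <- round(1.5 * fs)
    if (length(y) > 3 * trim) y <- y[(trim + 1L):(length(y) - trim)]
    if (!is.null(bl)) {
      # sinusoid-geometry amplitude from in-band power with the baseline
      # background power subtracted: robust at low signal-to-noise
      vb <- stats::var(bandpass(bl[, j], fs, 0.55 * f0, 1.9 * f0))
      vs <- max(stats::var(y) - vb, 0)
      ppn <- 2 * sqrt(2 * vs)
      # wideband excursion fallback: weak sparse discharges (spike trains
      # below the transient detector's threshold) put almost no power in
      # any narrow band, but their excursions survive broadband
      win <- round(max(0.3, 0.7 / f0) * fs)
      rng <- function(v) {
        nw <- floor(length(v) / win)
        vapply(seq_len(nw), function(wn)
          diff(range(v[((wn - 1) * win + 1):(wn * win)])), numeric(1))
      }
      wbx <- rng(bandpass(x, fs, 1, 45))
      wbb <- rng(bandpass(bl[, j], fs, 1, 45))
      ppw <- max(stats::median(wbx) - 0.35 * stats::median(wbb), 0)
      return(if (ppn >= 0.5 * ppw) ppn else ppw)
    }
    exc <- cycleExcursions(y)
    if (!length(exc)) return(diff(range(y)))
    stats::quantile(exc, 0.9, names = FALSE)
  }, numeric(1))
  max(amp)
}

#' Dominant discharge frequency of a seizure segment
#'
#' Frequency (Hz) of the dominant discharge in the start (first 5 s), mid
#' (5 s around the midpoint) or end (last 5 s) segment, measured on the
#' channel with the strongest discharge activity. Seizures shorter than
#' 15 s use three equal thirds instead. Rhythmic discharges are measured by
#' periodogram peak over 0.5-13.5 Hz; transient-dominated discharges by the
#' repetition rate of detected transients. A `low_confidence` attribute is
#' set when no clear spectral peak dominates (e.g. noise-only input).
#'
#' @inheritParams peakAmplitude
#' @param segment one of "start", "mid", "end".
#' @return frequency in Hz with attribute `low_confidence`.
#' @export
segmentFrequency <- function(record, ann, segment = c("start", "mid", "end")) {
  segment <- match.arg(segment)
  checkAnnotation(record, ann)
  on <- ann$onset_s; D <- ann$duration_s
  seg_len <- if (D >= 15) 5 else D / 3
  wdw <- switch(segment,
    start = c(on, on + seg_len),
    mid = c(on + D / 2 - seg_len / 2, on + D / 2 + seg_len / 2),
    end = c(on + D - seg_len, on + D))
  fs <- samplingRate(record)
  ch <- leadChannel(record, wdw[1], wdw[2])
  x <- windowSamples(record, wdw[1], wdw[2])[, ch]
  if (stats::sd(x) == 0)
    noInvolvedChannel("segment contains no involved channel (flat signal)")
  # transient repetition rates need more events than a 5 s segment holds:
  # detect on a 12 s window around the segment, estimate the rate from the
  # intervals there
  half <- max(6, diff(wdw) / 2)
  mid <- mean(wdw)
  exp0 <- max(ann$onset_s, mid - half)
  exp1 <- min(ann$onset_s + ann$duration_s, mid + half)
  xe <- windowSamples(record, exp0, exp1)[, ch]
  tr <- detectTransients(xe, fs)
  if (transientDominated(tr, exp1 - exp0) && !is.na(tr$rate))
    return(structure(tr$rate, low_confidence = FALSE))
  f <- psdPeak(x, fs, 0.5, 13.5)
  structure(as.numeric(f), low_confidence = attr(f, "low_confidence"))
}

#' Frequency variability over the whole seizure
#'
#' Sample standard deviation (n-1 denominator) of the start, mid and end
#' segment frequencies, an index of within-seizure frequency evolution
#' (neonatal seizures commonly slow towards their end).
#'
#' @inheritParams peakAmplitude
#' @return standard deviation in Hz.
#' @export
frequencyVariability <- function(record, ann) {
  f <- vapply(c("start", "mid", "end"),
              function(s) as.numeric(segmentFrequency(record, ann, s)),
              numeric(1))
  stats::sd(f)
}

#' Classify seizure discharge morphology
#'
#' Categorises the dominant discharge morphology in the onset window (first
#' 10 s) or at the seizure peak (10 s around the midpoint): 1 = rhythmic
#' delta (0.5 to <4 Hz), 2 = rhythmic theta (4 to <8 Hz), 3 = rhythmic alpha
#' (8-13 Hz), 4 = spikes/sharp waves, 5 = spike-and-wave or
#' sharp-and-slow-wave complexes. Transients (< 200 ms, brief relative to
#' their repetition interval) are detected first; if they dominate, the
#' amplitude of the rhythmic component at the repetition rate decides
#' between category 4 (no slow-wave coupling) and 5 (slow-wave coupling);
#' otherwise the dominant frequency band decides among 1-3.
#'
#' @inheritParams peakAmplitude
#' @param at "onset" or "peak".
#' @return integer category 1-5.
#' @export
classifyMorphology <- function(record, ann, at = c("onset", "peak")) {
  at <- match.arg(at)
  checkAnnotation(record, ann)
  wdw <- annWindow(ann, if (at == "onset") "onset" else "peak")
  fs <- samplingRate(record)
  ch <- leadChannel(record, wdw[1], wdw[2])
  x <- windowSamples(record, wdw[1], wdw[2])[, ch]
  if (stats::sd(x) == 0)
    noInvolvedChannel("no involved channel in morphology window")
  tr <- detectTransients(x, fs)
  if (transientDominated(tr, diff(wdw)) && !is.na(tr$rate)) {
    # slow-wave coupling: rhythmic component at the repetition rate,
    # relative to the transient amplitude
    y <- bandpass(x, fs, 0.6 * tr$rate, 1.4 * tr$rate)
    exc <- cycleExcursions(y)
    slow_pp <- if (length(exc)) stats::quantile(exc, 0.9, names = FALSE)
               else diff(range(y))
    ratio <- slow_pp / stats::median(tr$pp)
    return(if (ratio > 0.45) 5L else 4L)
  }
  f0 <- as.numeric(psdPeak(x, fs, 0.5, 13.5))
  if (f0 < 4) 1L else if (f0 < 8) 2L else 3L
}

#' Morphology change from onset to peak
#'
#' @param onset_cat,peak_cat categories 1-5.
#' @return `TRUE` iff the categories differ.
#' @export
morphologyChange <- function(onset_cat, peak_cat) {
  stopifnot(onset_cat %in% 1:5, peak_cat %in% 1:5)
  onset_cat != peak_cat
}

#' Rhythmicity score of a seizure
#'
#' Scores how regular the discharge train is over the whole seizure:
#' 3 = highly rhythmic, 2 = minimal dysrhythmia, 1 = significant
#' dysrhythmia. Discharge times are detected on the lead channel
#' (envelope-normalised peak picking, or transient times for spike
#' morphologies) and the coefficient of variation (CV) of successive
#' inter-discharge intervals is mapped: CV < 0.15 -> 3; 0.15-0.35 -> 2;
#' > 0.35 -> 1.
#'
#' @inheritParams peakAmplitude
#' @param cv_breaks the two CV thresholds.
#' @return integer score 1-3.
#' @export
rhythmicityScore <- function(record, ann, cv_breaks = c(0.15, 0.35)) {
  checkAnnotation(record, ann)
  fs <- samplingRate(record)
  on <- ann$onset_s; D <- ann$duration_s
  ch <- leadChannel(record, max(0, on + D / 2 - 5), on + D / 2 + 5)
  x <- windowSamples(record, on, on + D)[, ch]
  tr <- detectTransients(x, fs)
  if (transientDominated(tr, D)) {
    iti <- diff(tr$times)
    # undetected weak transients leave integer-multiple gaps; normalise so
    # misses do not masquerade as dysrhythmia
    T0 <- fundamentalInterval(iti)
    iti <- iti / pmax(1, round(iti / T0))
  } else {
    fr <- vapply(c("start", "mid", "end"), function(s)
      as.numeric(segmentFrequency(record, ann, s)), numeric(1))
    f_hi <- max(fr); f_lo <- min(fr)
    # deliberately wide band: a narrow filter rings through irregular
    # cycles and under-reports dysrhythmia
    y <- bandpass(x, fs, 0.3 * f_lo, 4 * f_hi)
    env <- movingRMS(y, fs, 1)
    z <- y / (env + 1e-9)
    pk <- pracma::findpeaks(z, minpeakheight = 0.45,
                            minpeakdistance = max(2L, round(0.2 / f_hi * fs)))
    if (is.null(pk) || nrow(pk) < 6L)
      stop("fewer than 5 discharge cycles detectable")
    iti <- diff(sort(pk[, 2])) / fs
  }
  if (length(iti) < 5L) stop("fewer than 5 discharge cycles detectable")
  # detrend so the slow within-seizure frequency sweep does not register as
  # dysrhythmia: the CV is taken on intervals relative to their local trend
  k <- min(15L, length(iti) - (1 - length(iti) %% 2))
  trend <- if (k >= 3) stats::runmed(iti, k) else rep(stats::median(iti),
                                                      length(iti))
  rel <- iti / pmax(trend, 1e-9)
  # robust CV: occasional missed/split discharge detections would otherwise
  # dominate the plain SD
  cv <- stats::mad(rel) / stats::median(rel)
  if (cv < cv_breaks[1]) 3L else if (cv <= cv_breaks[2]) 2L else 1L
}

#' Background EEG grade at seizure time
#'
#' Grades the seizure-free background around an annotation on the 1-4
#' clinical scale using envelope-threshold burst detection: the
#' channel-averaged moving-RMS envelope is thresholded to find suppressed
#' stretches (inter-burst intervals, IBIs) of at least 2 s; no IBIs gives
#' grade 1 (continuous), median IBI < 10 s grade 2, 10-60 s grade 3, and
#' > 60 s with inter-burst amplitude below 10 uV grade 4.
#'
#' @inheritParams peakAmplitude
#' @param exclude data.frame of all seizure annotations on the record to
#'   exclude from the background (defaults to `ann` alone).
#' @param suppression_rms_uV envelope threshold (moving-RMS, uV) defining
#'   suppression.
#' @return integer grade 1-4.
#' @export
backgroundScore <- function(record, ann, exclude = NULL,
                            suppression_rms_uV = 5) {
  checkAnnotation(record, ann)
  fs <- samplingRate(record)
  n <- nrow(signalMatrix(record))
  mask <- rep(TRUE, n)  # TRUE = seizure-free
  if (is.null(exclude))
    exclude <- data.frame(onset_s = ann$onset_s, duration_s = ann$duration_s)
  for (i in seq_len(nrow(exclude))) {
    i0 <- max(1L, floor((exclude$onset_s[i] - 5) * fs))
    i1 <- min(n, ceiling((exclude$onset_s[i] + exclude$duration_s[i] + 5) * fs))
    mask[i0:i1] <- FALSE
  }
  if (sum(mask) < 300 * fs)
    stop("insufficient seizure-free background (< 5 min) around annotation")
  env <- rowMeans(apply(signalMatrix(record), 2, movingRMS, fs = fs,
                        win_s = 0.5))
  # IBIs are measured within contiguous seizure-free segments only
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ibis <- numeric(0)
  inter_amp <- numeric(0)
  for (j in which(runs$values)) {
    seg <- env[starts[j]:ends[j]]
    supp <- seg < suppression_rms_uV
    r <- rle(supp)
    len_s <- r$lengths / fs
    ibis <- c(ibis, len_s[r$values & len_s >= 2])
    if (any(r$values)) inter_amp <- c(inter_amp, seg[supp])
  }
  if (!length(ibis)) return(1L)
  m <- stats::median(ibis)
  if (m < 10) return(2L)
  if (m <= 60) return(3L)
  if (stats::quantile(inter_amp, 0.95) * 2.8 < 10) 4L else 3L
}

#' Number of EEG channels involved in a seizure
#'
#' Counts the channels showing seizure discharges in the onset window
#' (first 10 s) or at the seizure peak (middle third): a channel is
#' involved when its discharge-band power in the window exceeds `k` times
#' that channel's pre-seizure baseline power in the same band. The
#' discharge band is centred on the dominant frequency of the strongest
#' channel; transient-dominated seizures instead count channels with
#' detectable transients above `k`/2 times the baseline noise scale.
#'
#' @inheritParams peakAmplitude
#' @param at "onset" or "peak".
#' @param k involvement threshold (power ratio), default 4.
#' @return integer count 0-8.
#' @export
channelsInvolved <- function(record, ann, at = c("onset", "peak"), k = 4) {
  at <- match.arg(at)
  checkAnnotation(record, ann)
  fs <- samplingRate(record)
  wdw <- annWindow(ann, if (at == "onset") "onset" else "midthird")
  w <- windowSamples(record, wdw[1], wdw[2])
  # baseline: up to 30 s immediately pre-onset (post-offset fallback)
  b1 <- max(0, ann$onset_s - 30)
  if (ann$onset_s - b1 >= 5) {
    bl <- windowSamples(record, b1, ann$onset_s)
  } else {
    e <- ann$onset_s + ann$duration_s
    bl <- windowSamples(record, e, min(recordDuration(record), e + 30))
  }
  lead <- which.max(apply(w, 2, stats::var))
  if (stats::sd(w[, lead]) == 0) return(0L)
  tr_lead <- detectTransients(w[, lead], fs)
  if (transientDominated(tr_lead, diff(wdw))) {
    inv <- vapply(seq_len(ncol(w)), function(j) {
      tr <- detectTransients(w[, j], fs)
      if (length(tr$times) < 3L) return(FALSE)
      noise <- stats::mad(bandpass(bl[, j], fs, 1, 45))
      stats::median(tr$pp) > (k / 2) * 2 * noise
    }, logical(1))
    return(as.integer(sum(inv)))
  }
  f0 <- as.numeric(psdPeak(w[, lead], fs, 0.5, 16))
  lo <- 0.6 * f0; hi <- min(1.7 * f0, 20)
  inv <- vapply(seq_len(ncol(w)), function(j) {
    pw <- mean(bandpass(w[, j], fs, lo, hi)^2)
    pb <- mean(bandpass(bl[, j], fs, lo, hi)^2)
    if (pb <= .Machine$double.eps) pw > .Machine$double.eps else pw / pb > k
  }, logical(1))
  as.integer(sum(inv))
}

#' Extract all ten seizure features
#'
#' Applies the full quantification scheme to one annotated seizure:
#' peak amplitude, rhythmicity score, background grade, morphology at onset
#' and peak, duration (taken from the annotation), frequency variability,
#' morphology change, and channel involvement at onset and peak. Component
#' failures are reported per field (`NA` with the message collected in the
#' `errors` attribute); the remaining fields are still computed.
#'
#' @inheritParams peakAmplitude
#' @param exclude all annotations on the record (for background grading).
#' @return one-row data.frame with the ten feature columns (and any
#'   per-field error messages in `attr(, "errors")`).
#' @export
extractFeatures <- function(record, ann, exclude = NULL) {
  checkAnnotation(record, ann)
  errs <- character(0)
  grab <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      errs[[name]] <<- conditionMessage(e)
      NA
    })
  }
  m_on <- grab("morphology_onset", classifyMorphology(record, ann, "onset"))
  m_pk <- grab("morphology_peak", classifyMorphology(record, ann, "peak"))
  out <- data.frame(
    peak_amplitude_uV = grab("peak_amplitude", peakAmplitude(record, ann)),
    rhythmicity_score = grab("rhythmicity", rhythmicityScore(record, ann)),
    background_score = grab("background",
                            backgroundScore(record, ann, exclude)),
    morphology_onset = m_on,
    morphology_peak = m_pk,
    duration_s = ann$duration_s,
    frequency_variability_hz = grab("frequency_variability",
                                    frequencyVariability(record, ann)),
    morphology_changed = if (is.na(m_on) || is.na(m_pk)) NA
                         else morphologyChange(m_on, m_pk),
    channels_onset = grab("channels_onset",
                          channelsInvolved(record, ann, "onset")),
    channels_peak = grab("channels_peak",
                         channelsInvolved(record, ann, "peak"))
  )
  attr(out, "errors") <- errs
  out
}

#' Feature table for all annotated seizures of a record
#'
#' @param record an [EEGRecord-class].
#' @param annotations data.frame with one row per seizure (`onset_s`,
#'   `duration_s`, optionally `subject`, `period`).
#' @return data.frame, one row per seizure: identifiers plus the ten
#'   feature columns.
#' @export
extractFeatureTable <- function(record, annotations) {
  rows <- lapply(seq_len(nrow(annotations)), function(i) {
    f <- extractFeatures(record, as.list(annotations[i, ]),
                         exclude = annotations)
    cbind(annotations[i, intersect(c("subject", "period"),
                                   names(annotations)), drop = FALSE],
          seizure = i, onset_s = annotations$onset_s[i], f,
          row.names = NULL)
  })
  do.call(rbind, rows)
}
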