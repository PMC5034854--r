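# Band-limited 1/f-weighted Gaussian noise, exact target RMS.
# Synthesised in the frequency domain: random phases, amplitude ~ f^(-alpha/2)
# inside [fmin, fmax], zero outside. Uses the caller's RNG stream.
bandNoise <- function(n, fs, rms, fmin = 0.5, fmax = 70, alpha = 1) {
  if (n < 4) return(rep(0, n))
  m <- 2^ceiling(log2(n))
  half <- m %/% 2
  fpos <- (1:(half - 1)) * fs / m
  w <- numeric(half - 1)
  sel <- fpos >= fmin & fpos <= min(fmax, 0.999 * fs / 2)
  w[sel] <- fpos[sel]^(-alpha / 2)
  ph <- stats::runif(half - 1, 0, 2 * pi)
  pos <- w * exp(1i * ph)
  X <- c(0, pos, 0, Conj(rev(pos)))
  x <- Re(stats::fft(X, inverse = TRUE))[seq_len(n)]
  x <- x - mean(x)
  s <- stats::sd(x)
  if (s == 0) return(x)
  x * rms / s
}

# Raised-cosine smoothing of a 0/1 gate to avoid spectral splatter at
# burst edges. ramp_s is the 10-90% transition time.
smoothGate <- function(gate, fs, ramp_s = 0.2) {
  k <- max(3L, round(ramp_s * fs))
  if (k %% 2 == 0) k <- k + 1L
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(k) / (k + 1))
  w <- w / sum(w)
  as.numeric(stats::filter(c(rep(gate[1], k), gate, rep(gate[length(gate)], k)),
                           w, sides = 2))[(k + 1):(k + length(gate))]
}

#' Generate graded neonatal background EEG
#'
#' Simulates 8-channel background activity of a given abnormality grade.
#' Grade 1 is continuous mixed-frequency activity; grades 2-4 alternate
#' generalized bursts with low-amplitude inter-burst intervals whose
#' durations fall in the grade's range (grade 2: < 10 s; grade 3: 10-60 s;
#' grade 4: > 60 s with inter-burst amplitude below 10 uV). The process is
#' band-limited Gaussian noise with a 1/f-weighted spectrum restricted to
#' the 0.5-70 Hz acquisition bandwidth.
#'
#' @param spec a [backgroundSpec()].
#' @param duration_s record length in seconds (> 0).
#' @param montage a [neonatalMontage()].
#' @param seed integer seed; identical seeds give identical records.
#' @return An [EEGRecord-class].
#' @examples
#' rec <- generateBackground(backgroundSpec(2), 60, neonatalMontage(), seed = 7)
#' recordDuration(rec)
#' @export
generateBackground <- function(spec, duration_s, montage = neonatalMontage(),
                               seed = 1L) {
  if (!inherits(spec, "backgroundSpec"))
    stop("spec must be a backgroundSpec (invalid grade objects are rejected ",
         "by backgroundSpec() itself)")
  if (duration_s <= 0) stop("duration_s must be > 0")
  validateMontage(montage)
  fs <- montage$samplingRate
  n <- round(duration_s * fs)
  set.seed(as.integer(seed))

  if (spec$grade == 1L) {
    sig <- vapply(seq_len(8L),
                  function(ch) bandNoise(n, fs, spec$burst_amplitude_uV),
                  numeric(n))
    return(EEGRecord(sig, fs, montage$channels))
  }

  # burst-suppression gate shared across channels (bursts are generalized)
  gate <- numeric(n)
  t <- 0
  in_burst <- TRUE
  lims <- switch(spec$grade,
                 NULL,
                 c(1.5, 9.5),
                 c(10, 60),
                 c(61, max(62, 1.6 * spec$ibi_s)))
  while (t < duration_s) {
    len <- if (in_burst) stats::runif(1, 1.5, 5) else
      pmin(lims[2], pmax(lims[1], spec$ibi_s * stats::runif(1, 0.75, 1.25)))
    i0 <- floor(t * fs) + 1L
    i1 <- min(n, ceiling((t + len) * fs))
    if (in_burst && i0 <= n) gate[i0:i1] <- 1
    t <- t + len
    in_burst <- !in_burst
  }
  g <- smoothGate(gate, fs)
  sig <- vapply(seq_len(8L), function(ch) {
    burst <- bandNoise(n, fs, spec$burst_amplitude_uV)
    quiet <- bandNoise(n, fs, spec$interburst_rms_uV)
    g * burst + (1 - g) * quiet
  }, numeric(n))
  EEGRecord(sig, fs, montage$channels)
}
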