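# ---- preprocessing ------------------------------------------------------

#' Preprocess a record for the epoch classifier
#'
#' Anti-alias filters at 12.8 Hz and resamples the record to the 32 Hz
#' working rate, and computes per-epoch signal energies on the 8 s / 50%
#' overlap grid so high-energy artifact epochs can be masked before feature
#' extraction.
#'
#' @param record an [EEGRecord-class] at 250 or 256 Hz.
#' @return A list: `record` (32 Hz [EEGRecord-class]), `epochStarts`
#'   (seconds), `energy` (epochs x channels matrix of mean squared
#'   amplitude at the working rate).
#' @export
preprocessRecord <- function(record) {
  fs <- samplingRate(record)
  if (!fs %in% c(250, 256))
    stop("unsupported sampling rate ", fs, " Hz (expected 250 or 256)")
  target <- 32
  # sharp zero-phase FFT anti-alias filter: 12.8 Hz is only 9% below the
  # tested stopband (14 Hz), beyond what a stable IIR cascade delivers
  sig <- apply(signalMatrix(record), 2, function(x)
    antiAliasFilter(x, fs, cutoff = 12.8))
  if (fs == 256) {
    ds <- sig[seq(1, nrow(sig), by = 8L), , drop = FALSE]
  } else {
    ds <- apply(sig, 2, function(x)
      as.numeric(signal::resample(x, p = 16, q = 125)))
  }
  rec32 <- EEGRecord(ds, target, channelLabels(record))
  grid <- epochGrid(rec32)
  list(record = rec32, epochStarts = grid$starts, energy = grid$energy)
}

# zero-phase FFT lowpass with a raised-cosine transition ending at
# cutoff * (1 + 0.09): ~40 dB down at 14 Hz for a 12.8 Hz cutoff
antiAliasFilter <- function(x, fs, cutoff = 12.8) {
  n <- length(x)
  pad <- min(n, round(3 * fs))
  xp <- c(rev(x[seq_len(pad)]), x, rev(x[(n - pad + 1L):n]))
  m <- 2^ceiling(log2(length(xp)))
  xp <- c(xp, numeric(m - length(xp)))
  f <- (0:(m - 1)) * fs / m
  f <- pmin(f, fs - f)
  tw <- 0.09 * cutoff
  H <- numeric(m)
  H[f <= cutoff] <- 1
  sel <- f > cutoff & f <= cutoff + tw
  H[sel] <- 0.5 + 0.5 * cos(pi * (f[sel] - cutoff) / tw)
  y <- Re(stats::fft(stats::fft(xp) * H, inverse = TRUE)) / m
  y[(pad + 1L):(pad + n)]
}

# 8 s epochs, 4 s hop; returns start times and per-epoch/channel energy
epochGrid <- function(rec32, epoch_s = 8, hop_s = 4) {
  fs <- samplingRate(rec32)
  n <- nrow(signalMatrix(rec32))
  len <- epoch_s * fs
  hop <- hop_s * fs
  n_ep <- floor((n - len) / hop) + 1L
  if (n_ep < 1L) stop("record shorter than one epoch")
  starts <- (seq_len(n_ep) - 1L) * hop_s
  energy <- matrix(NA_real_, n_ep, ncol(signalMatrix(rec32)))
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1L) * hop + 1L):((i - 1L) * hop + len)
    energy[i, ] <- colMeans(signalMatrix(rec32)[idx, , drop = FALSE]^2)
  }
  list(starts = starts, energy = energy, epoch_s = epoch_s, hop_s = hop_s)
}

# ---- epoch features -----------------------------------------------------

#' Per-epoch, per-channel EEG features
#'
#' Computes a documented representative feature set for each 8 s epoch
#' (50% overlap) of a preprocessed 32 Hz record, spanning the three
#' classical groups: time domain (RMS amplitude, variance, line length,
#' zero-crossing rate, Hjorth mobility and complexity, autoregressive
#' model residual error, nonlinear energy), frequency domain (total power
#' 0.5-12.8 Hz, delta/theta/alpha band powers, peak frequency, spectral
#' edge frequency), and information theory (Shannon entropy of the
#' amplitude histogram, spectral entropy). Epochs whose energy exceeds
#' `energyThreshold` on a channel are masked (all features `NA`).
#'
#' @param prep output of [preprocessRecord()].
#' @param energyThreshold artifact energy threshold (uV^2); `Inf` disables
#'   masking.
#' @param edgeFraction cumulative-power fraction defining the spectral
#'   edge frequency.
#' @return A list: `features` (epochs*channels x n_features matrix),
#'   `epoch` and `channel` index vectors, `starts` (epoch start times, s),
#'   `masked` logical vector.
#' @export
epochFeatures <- function(prep, energyThreshold = Inf, edgeFraction = 0.8) {
  rec <- prep$record
  fs <- samplingRate(rec)
  len <- 8L * fs
  hop <- 4L * fs
  sig <- signalMatrix(rec)
  n_ep <- length(prep$epochStarts)
  n_ch <- ncol(sig)
  feats <- vector("list", n_ep * n_ch)
  epoch <- integer(n_ep * n_ch)
  channel <- integer(n_ep * n_ch)
  masked <- logical(n_ep * n_ch)
  k <- 0L
  for (i in seq_len(n_ep)) {
    idx <- ((i - 1L) * hop + 1L):((i - 1L) * hop + len)
    for (j in seq_len(n_ch)) {
      k <- k + 1L
      epoch[k] <- i; channel[k] <- j
      if (prep$energy[i, j] > energyThreshold) {
        masked[k] <- TRUE
        feats[[k]] <- rep(NA_real_, length(epochFeatureNames()))
      } else {
        feats[[k]] <- singleEpochFeatures(sig[idx, j], fs, edgeFraction)
      }
    }
  }
  m <- do.call(rbind, feats)
  colnames(m) <- epochFeatureNames()
  list(features = m, epoch = epoch, channel = channel,
       starts = prep$epochStarts, masked = masked)
}

epochFeatureNames <- function() {
  c("rms", "variance", "line_length", "zero_crossings", "hjorth_mobility",
    "hjorth_complexity", "ar_error", "nonlinear_energy",
    "total_power", "delta_power", "theta_power", "alpha_power",
    "peak_frequency", "spectral_edge", "shannon_entropy",
    "spectral_entropy")
}

singleEpochFeatures <- function(x, fs, edgeFraction = 0.8) {
  n <- length(x)
  x <- x - mean(x)
  v <- stats::var(x)
  if (v < .Machine$double.eps) {
    out <- numeric(length(epochFeatureNames()))
    names(out) <- epochFeatureNames()
    out["peak_frequency"] <- 0; out["spectral_edge"] <- 0
    return(out)
  }
  d1 <- diff(x); d2 <- diff(d1)
  mob <- sqrt(stats::var(d1) / v)
  cplx <- sqrt(stats::var(d2) / stats::var(d1)) / mob
  ar_err <- tryCatch({
    fit <- stats::ar.yw(x, aic = FALSE, order.max = 9L)
    fit$var.pred
  }, error = function(e) v)
  nle <- mean(abs(x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]))
  # periodogram
  X <- stats::fft(x * signal::hanning(n))
  p <- Mod(X[seq_len(n %/% 2)])^2
  f <- (seq_len(n %/% 2) - 1) * fs / n
  sel <- f >= 0.5 & f <= 12.8
  ps <- p[sel]; fsel <- f[sel]
  tp <- sum(ps)
  bandp <- function(lo, hi) sum(ps[fsel >= lo & fsel < hi])
  cum <- cumsum(ps) / tp
  sef <- fsel[which(cum >= edgeFraction)[1]]
  pn <- ps / tp
  spec_ent <- -sum(pn[pn > 0] * log(pn[pn > 0])) / log(length(pn))
  h <- graphics::hist(x, breaks = 16, plot = FALSE)$counts
  hp <- h[h > 0] / n
  shan <- -sum(hp * log(hp))
  out <- c(sqrt(mean(x^2)), v, sum(abs(d1)), sum(d1[-1] * d1[-length(d1)] < 0),
           mob, cplx, ar_err, nle,
           tp, bandp(0.5, 4), bandp(4, 8), bandp(8, 12.8),
           fsel[which.max(ps)], sef, shan, spec_ent)
  names(out) <- epochFeatureNames()
  out
}

# ---- training -----------------------------------------------------------

# label epochs by overlap with gold annotations (any overlap of the 8 s
# epoch with a seizure interval)
labelEpochs <- function(starts, annotations, epoch_s = 8) {
  epochOverlapFraction(starts, annotations, epoch_s) > 0
}

# fraction of the epoch covered by a seizure interval
epochOverlapFraction <- function(starts, annotations, epoch_s = 8) {
  ov <- rep(0, length(starts))
  if (is.null(annotations) || nrow(annotations) == 0L) return(ov)
  for (i in seq_len(nrow(annotations))) {
    a <- annotations$onset_s[i]
    b <- a + annotations$duration_s[i]
    ov <- pmax(ov, pmin(b, starts + epoch_s) - pmax(a, starts))
  }
  pmax(ov, 0) / epoch_s
}

#' Train the seizure epoch classifier
#'
#' Fits a Gaussian-kernel support vector machine on z-scored epoch features
#' from a set of annotated records, with a Platt sigmoid fitted on held-out
#' folds to convert SVM outputs into seizure probabilities. Epochs are
#' labelled seizure when they overlap a gold annotation. The artifact
#' energy threshold is set at the 97.5th percentile of training epoch
#' energies.
#'
#' @param records list of [EEGRecord-class]s.
#' @param annotations list (parallel to `records`) of gold annotation
#'   data.frames; an entry may have zero rows for seizure-free records,
#'   but the pooled training set must contain both classes.
#' @param threshold default probability threshold of the resulting model.
#' @param smoothingEpochs moving-average smoothing span (epochs).
#' @param maxEpochs cap on training rows (balanced subsampling keeps the
#'   class mix workable).
#' @param cost SVM cost parameter.
#' @param tuneGamma if `TRUE`, pick the kernel width from a small grid by
#'   internal cross-validation; default uses the 1/n_features heuristic.
#' @param seed integer seed: training is deterministic given the seed.
#' @return A [DetectorModel-class].
#' @export
trainDetector <- function(records, annotations, threshold = 0.3,
                          smoothingEpochs = 15L, maxEpochs = 6000L,
                          cost = 1, tuneGamma = FALSE, seed = 1L) {
  stopifnot(is.list(records), is.list(annotations),
            length(records) == length(annotations))
  if (all(vapply(annotations, function(a) is.null(a) || nrow(a) == 0L,
                 logical(1))))
    stop("empty annotation list: training set must contain seizure epochs")
  feat <- list(); ovfr <- numeric(0); energies <- numeric(0)
  for (i in seq_along(records)) {
    prep <- preprocessRecord(records[[i]])
    ef <- epochFeatures(prep)
    feat[[i]] <- ef$features
    ovfr <- c(ovfr, epochOverlapFraction(ef$starts,
                                         annotations[[i]])[ef$epoch])
    energies <- c(energies, prep$energy[cbind(ef$epoch, ef$channel)])
  }
  X <- do.call(rbind, feat)
  # train on unambiguous epochs only: seizure epochs are those at least
  # half covered by a seizure; boundary epochs (partial overlap) are
  # excluded so their mixed content does not dilute either class
  keep <- stats::complete.cases(X) & (ovfr == 0 | ovfr >= 0.5)
  X <- X[keep, , drop = FALSE]
  lab <- ovfr[keep] >= 0.5
  if (length(unique(lab)) < 2L)
    stop("training set contains a single class only")
  set.seed(as.integer(seed))
  if (nrow(X) > maxEpochs) {
    pos <- which(lab); neg <- which(!lab)
    n_pos <- min(length(pos), maxEpochs %/% 2)
    n_neg <- min(length(neg), maxEpochs - n_pos)
    pick <- c(sample(pos, n_pos), sample(neg, n_neg))
    X <- X[pick, , drop = FALSE]; lab <- lab[pick]
  }
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd)
  scl[scl == 0] <- 1
  Z <- sweep(sweep(X, 2, ctr), 2, scl, "/")
  y <- factor(ifelse(lab, "seizure", "background"),
              levels = c("background", "seizure"))
  gam <- 1 / ncol(Z)
  if (tuneGamma) {
    grid <- gam * c(0.25, 1, 4)
    acc <- vapply(grid, function(g) {
      fit <- e1071::svm(Z, y, kernel = "radial", gamma = g, cost = cost,
                        cross = 3)
      fit$tot.accuracy
    }, numeric(1))
    gam <- grid[which.max(acc)]
    set.seed(as.integer(seed))
  }
  wts <- 1 / table(y)
  wts <- wts / sum(wts) * 2
  fit <- e1071::svm(Z, y, kernel = "radial", gamma = gam, cost = cost,
                    probability = TRUE, class.weights = wts)
  # artifact threshold: energy percentile of the training epochs, floored
  # above the observed seizure-epoch energies so ictal activity itself is
  # never masked as artifact
  e_thr <- stats::quantile(energies, 0.975, names = FALSE)
  e_sz <- energies[ovfr >= 0.5]
  if (length(e_sz)) e_thr <- max(e_thr, 1.5 * max(e_sz))
  new("DetectorModel", svm = fit, featureCenter = ctr, featureScale = scl,
      energyThreshold = e_thr,
      threshold = threshold, smoothingEpochs = as.numeric(smoothingEpochs),
      featureNames = epochFeatureNames())
}

# ---- probability trace and events --------------------------------------

# centered moving average with shrinking windows at the edges
movingAverage <- function(x, k) {
  if (k <= 1) return(x)
  half <- (k - 1) %/% 2
  n <- length(x)
  vapply(seq_len(n), function(i)
    mean(x[max(1, i - half):min(n, i + half)]), numeric(1))
}

#' Per-channel seizure probability trace
#'
#' Runs the classifier over every epoch and channel of a record, converts
#' SVM outputs into probabilities via the fitted sigmoid, smooths each
#' channel with a moving average, and keeps the per-epoch maximum across
#' channels together with its channel index (a single probability graph of
#' the channel of highest seizure probability).
#'
#' @param record an [EEGRecord-class] at 250/256 Hz.
#' @param model a [DetectorModel-class].
#' @return A list: `prob` (epochs x channels raw probabilities), `smoothed`
#'   (same shape), `maxProb` (per-epoch max of the smoothed trace),
#'   `maxChannel` (its channel index), `starts` (epoch start times, s),
#'   `channelLabels`, `epoch_s`, `hop_s`.
#' @export
probabilityTrace <- function(record, model) {
  prep <- preprocessRecord(record)
  ef <- epochFeatures(prep, energyThreshold = model@energyThreshold)
  n_ep <- length(ef$starts)
  n_ch <- max(ef$channel)
  p <- rep(0, length(ef$epoch))
  ok <- stats::complete.cases(ef$features)
  if (any(ok)) {
    Z <- sweep(sweep(ef$features[ok, , drop = FALSE], 2,
                     model@featureCenter), 2, model@featureScale, "/")
    pr <- stats::predict(model@svm, Z, probability = TRUE)
    p[ok] <- attr(pr, "probabilities")[, "seizure"]
  }
  prob <- matrix(0, n_ep, n_ch)
  prob[cbind(ef$epoch, ef$channel)] <- p
  sm <- apply(prob, 2, movingAverage, k = model@smoothingEpochs)
  sm <- matrix(sm, n_ep, n_ch)
  maxCh <- max.col(sm, ties.method = "first")
  list(prob = prob, smoothed = sm,
       maxProb = sm[cbind(seq_len(n_ep), maxCh)],
       maxChannel = maxCh, starts = ef$starts,
       channelLabels = channelLabels(record), epoch_s = 8, hop_s = 4)
}

#' Threshold a probability trace into detection events
#'
#' Maximal runs of epochs whose smoothed maximum-channel probability
#' exceeds the threshold become events; events separated by less than one
#' epoch hop merge. Each event reports its onset, duration, the modal
#' channel of highest probability and the peak probability.
#'
#' @param trace output of [probabilityTrace()].
#' @param threshold probability threshold in \{0, 0.1, ..., 1\} (adjustable
#'   in increments of 0.1).
#' @return data.frame: `onset_s`, `duration_s`, `channel`,
#'   `peak_probability` (zero rows when nothing crosses the threshold).
#' @export
detectEvents <- function(trace, threshold = 0.3) {
  if (length(threshold) != 1L ||
      !isTRUE(all.equal(threshold, round(threshold * 10) / 10)))
    stop("threshold must be one of 0, 0.1, ..., 1.0")
  act <- trace$maxProb > threshold
  empty <- data.frame(onset_s = numeric(0), duration_s = numeric(0),
                      channel = character(0), peak_probability = numeric(0))
  if (!any(act)) return(empty)
  r <- rle(act)
  ends <- cumsum(r$lengths)
  starts <- c(1L, ends[-length(ends)] + 1L)
  ev <- data.frame(i0 = starts[r$values], i1 = ends[r$values])
  # merge events whose covered-time gap is below one hop
  if (nrow(ev) > 1L) {
    keep <- ev[1, , drop = FALSE]
    for (i in 2:nrow(ev)) {
      gap_s <- (ev$i0[i] - 1) * trace$hop_s -
        ((keep$i1[nrow(keep)] - 1) * trace$hop_s + trace$epoch_s)
      if (gap_s < trace$hop_s) keep$i1[nrow(keep)] <- ev$i1[i]
      else keep <- rbind(keep, ev[i, ])
    }
    ev <- keep
  }
  out <- lapply(seq_len(nrow(ev)), function(j) {
    idx <- ev$i0[j]:ev$i1[j]
    ch <- trace$maxChannel[idx]
    modal <- as.integer(names(which.max(table(ch))))
    data.frame(
      onset_s = trace$starts[ev$i0[j]],
      duration_s = (ev$i1[j] - ev$i0[j]) * trace$hop_s + trace$epoch_s,
      channel = trace$channelLabels[modal],
      peak_probability = max(trace$maxProb[idx]),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
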