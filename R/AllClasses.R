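#' @import methods
NULL

#' EEGRecord: a multichannel EEG signal
#'
#' Container for a multichannel EEG recording in microvolts. The signal is
#' stored as a samples x channels numeric matrix together with the sampling
#' rate and the bipolar channel labels. Neonatal cot-side recordings use a
#' reduced 9-electrode adaptation of the 10-20 system displayed as 8 bipolar
#' derivations; see [neonatalMontage()].
#'
#' @slot signal numeric matrix, samples in rows, channels in columns, unit uV.
#' @slot samplingRate sampling frequency in Hz (250 or 256 for raw neonatal
#'   recordings; 32 after detector preprocessing).
#' @slot channelLabels character vector of bipolar derivation names, one per
#'   column of `signal`.
#'
#' @examples
#' m <- neonatalMontage()
#' rec <- generateBackground(backgroundSpec(1), duration_s = 10, montage = m,
#'                           seed = 1)
#' rec
#' nChannels(rec)
#' recordDuration(rec)
#' @export
setClass("EEGRecord",
  representation(
    signal = "matrix",
    samplingRate = "numeric",
    channelLabels = "character"
  )
)

setValidity("EEGRecord", function(object) {
  msg <- character()
  if (!is.numeric(object@signal))
    msg <- c(msg, "signal must be a numeric matrix")
  if (length(object@samplingRate) != 1L || object@samplingRate <= 0)
    msg <- c(msg, "samplingRate must be a single positive number")
  if (ncol(object@signal) != length(object@channelLabels))
    msg <- c(msg, "one channel label per signal column required")
  if (anyNA(object@signal))
    msg <- c(msg, "signal must not contain NA")
  if (length(msg)) msg else TRUE
})

#' Construct an EEGRecord
#'
#' @param signal samples x channels numeric matrix (uV).
#' @param samplingRate sampling frequency, Hz.
#' @param channelLabels character vector of channel names.
#' @return An [EEGRecord-class] object.
#' @export
EEGRecord <- function(signal, samplingRate, channelLabels = colnames(signal)) {
  signal <- as.matrix(signal)
  if (is.null(channelLabels))
    channelLabels <- paste0("ch", seq_len(ncol(signal)))
  colnames(signal) <- channelLabels
  new("EEGRecord", signal = signal, samplingRate = as.numeric(samplingRate),
      channelLabels = as.character(channelLabels))
}

#' @describeIn EEGRecord-class number of channels
#' @param object,x an `EEGRecord`
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))

#' @rdname EEGRecord-class
#' @export
setMethod("nChannels", "EEGRecord", function(x) ncol(x@signal))

#' @describeIn EEGRecord-class sampling rate in Hz
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))

#' @rdname EEGRecord-class
#' @export
setMethod("samplingRate", "EEGRecord", function(x) x@samplingRate)

#' @describeIn EEGRecord-class channel labels
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))

#' @rdname EEGRecord-class
#' @export
setMethod("channelLabels", "EEGRecord", function(x) x@channelLabels)

#' @describeIn EEGRecord-class the samples x channels signal matrix (uV)
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))

#' @rdname EEGRecord-class
#' @export
setMethod("signalMatrix", "EEGRecord", function(x) x@signal)

#' @describeIn EEGRecord-class record length in seconds
#' @export
setGeneric("recordDuration", function(x) standardGeneric("recordDuration"))

#' @rdname EEGRecord-class
#' @export
setMethod("recordDuration", "EEGRecord",
          function(x) nrow(x@signal) / x@samplingRate)

setMethod("show", "EEGRecord", function(object) {
  cat("EEGRecord:", ncol(object@signal), "channels x",
      nrow(object@signal), "samples @", object@samplingRate, "Hz (",
      sprintf("%.1f", recordDuration(object)), "s )\n")
  cat("  channels:", paste(object@channelLabels, collapse = ", "), "\n")
  rng <- range(object@signal)
  cat(sprintf("  amplitude range: %.1f .. %.1f uV\n", rng[1], rng[2]))
})

# extract a time window [from, to) in seconds as a samples x channels matrix
windowSamples <- function(record, from_s, to_s) {
  fs <- samplingRate(record)
  i0 <- max(1L, floor(from_s * fs) + 1L)
  i1 <- min(nrow(record@signal), ceiling(to_s * fs))
  if (i1 < i0) stop("requested window [", from_s, ", ", to_s,
                    ") lies outside the record")
  record@signal[i0:i1, , drop = FALSE]
}

#' DetectorModel: a trained seizure epoch classifier
#'
#' Holds the fitted support vector machine with its Platt sigmoid probability
#' calibration, the feature normalisation statistics estimated on the
#' training epochs, the artifact energy threshold, and the default decision
#' threshold applied to the smoothed probability trace.
#'
#' @slot svm fitted `e1071::svm` object (probability model included).
#' @slot featureCenter,featureScale named numeric vectors used to z-score
#'   epoch features before classification.
#' @slot energyThreshold epoch-energy artifact rejection threshold (uV^2).
#' @slot threshold default seizure probability threshold in \{0, 0.1, ..., 1\}.
#' @slot smoothingEpochs moving-average window length, in epochs.
#' @slot featureNames character vector of the features the model consumes.
#' @export
setClass("DetectorModel",
  representation(
    svm = "ANY",
    featureCenter = "numeric",
    featureScale = "numeric",
    energyThreshold = "numeric",
    threshold = "numeric",
    smoothingEpochs = "numeric",
    featureNames = "character"
  )
)

setValidity("DetectorModel", function(object) {
  msg <- character()
  th <- object@threshold
  if (length(th) != 1L || is.na(th) ||
      !isTRUE(all.equal(th, round(th * 10) / 10)) || th < 0 || th > 1)
    msg <- c(msg, "threshold must lie in {0, 0.1, ..., 1}")
  if (object@smoothingEpochs < 1)
    msg <- c(msg, "smoothingEpochs must be >= 1")
  if (length(msg)) msg else TRUE
})

setMethod("show", "DetectorModel", function(object) {
  cat("DetectorModel: SVM epoch classifier,", length(object@featureNames),
      "features/channel/epoch\n")
  cat("  default threshold:", object@threshold,
      "| smoothing:", object@smoothingEpochs, "epochs",
      "| artifact energy threshold:",
      format(object@energyThreshold, digits = 4), "\n")
})
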