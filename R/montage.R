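#' Neonatal reduced bipolar montage
#'
#' The standard neonatal long-term monitoring setup: nine scalp electrodes of
#' the 10-20 system adapted for neonates (F4, F3, T4, C4, Cz, C3, T3, O2, O1)
#' displayed as eight bipolar derivations. Eight channels is also the maximum
#' channel involvement a seizure can show in this scheme.
#'
#' @param samplingRate acquisition rate in Hz; neonatal video-EEG systems use
#'   250 or 256 Hz.
#' @return A list with elements `electrodes` (9 labels), `pairs` (8 x 2
#'   character matrix of ordered electrode pairs), `channels` (8 derivation
#'   labels such as "F4-C4") and `samplingRate`.
#' @examples
#' m <- neonatalMontage(256)
#' m$channels
#' @export
neonatalMontage <- function(samplingRate = 256) {
  pairs <- rbind(
    c("F4", "C4"), c("C4", "O2"), c("F3", "C3"), c("C3", "O1"),
    c("T4", "C4"), c("C4", "Cz"), c("Cz", "C3"), c("C3", "T3")
  )
  m <- list(
    electrodes = c("F4", "F3", "T4", "C4", "Cz", "C3", "T3", "O2", "O1"),
    pairs = pairs,
    channels = paste(pairs[, 1], pairs[, 2], sep = "-"),
    samplingRate = samplingRate
  )
  validateMontage(m)
  m
}

validateMontage <- function(m) {
  stopifnot(is.list(m), all(c("electrodes", "pairs", "channels",
                              "samplingRate") %in% names(m)))
  if (nrow(m$pairs) != 8L)
    stop("montage must define exactly 8 bipolar channels")
  if (!all(m$pairs %in% m$electrodes))
    stop("every bipolar pair member must be a montage electrode")
  if (!m$samplingRate %in% c(250, 256))
    stop("sampling rate must be 250 or 256 Hz, got ", m$samplingRate)
  invisible(m)
}
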