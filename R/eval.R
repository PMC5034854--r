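#' Match detector events against gold-standard seizures
#'
#' Event-based scoring: a gold seizure counts as detected when at least one
#' detection event overlaps it in time by at least `min_overlap_s` seconds
#' (a seizure split across several detections is counted once); detections
#' overlapping no gold seizure are false detections.
#'
#' @param gold data.frame of gold annotations (`onset_s`, `duration_s`).
#' @param detected data.frame of detection events (`onset_s`, `duration_s`).
#' @param min_overlap_s minimum temporal overlap, seconds.
#' @return A list: `detected_flags` (logical per gold seizure),
#'   `false_detections` (row indices into `detected`), `n_gold`,
#'   `n_detected`, `n_false`.
#' @examples
#' g <- data.frame(onset_s = 10, duration_s = 50)
#' d <- data.frame(onset_s = 30, duration_s = 20)
#' matchEvents(g, d)$detected_flags
#' @export
matchEvents <- function(gold, detected, min_overlap_s = 1) {
  n_g <- nrow(gold)
  flags <- logical(n_g)
  used <- logical(nrow(detected))
  if (n_g > 0L && nrow(detected) > 0L) {
    for (i in seq_len(n_g)) {
      a0 <- gold$onset_s[i]; a1 <- a0 + gold$duration_s[i]
      ov <- pmin(a1, detected$onset_s + detected$duration_s) -
        pmax(a0, detected$onset_s)
      hit <- ov >= min_overlap_s
      flags[i] <- any(hit)
      used <- used | hit
    }
  }
  list(detected_flags = flags,
       false_detections = which(!used),
       n_gold = n_g, n_detected = sum(flags), n_false = sum(!used))
}

#' Seizure detection rate
#'
#' Proportion of gold seizures detected; the per-subject summary measure
#' for detection performance.
#'
#' @param flags logical vector from [matchEvents()] (or a `matchEvents`
#'   result list).
#' @return proportion in \[0, 1\].
#' @export
detectionRate <- function(flags) {
  if (is.list(flags)) flags <- flags$detected_flags
  if (length(flags) == 0L)
    stop("detection rate undefined: no gold seizures")
  mean(flags)
}

#' Score one subject-period record
#'
#' @param gold gold annotations for the record.
#' @param detected detection events for the record.
#' @param record_hours record length in hours (for the false-detection
#'   rate).
#' @param subject,period identifiers carried into the result.
#' @return one-row data.frame: subject, period, n_gold, n_detected,
#'   detection_rate, false_detections, record_hours, fd_per_hour.
#' @export
evaluateDetections <- function(gold, detected, record_hours,
                               subject = NA, period = NA) {
  m <- matchEvents(gold, detected)
  data.frame(subject = subject, period = period,
             n_gold = m$n_gold, n_detected = m$n_detected,
             detection_rate = if (m$n_gold > 0) m$n_detected / m$n_gold
                              else NA_real_,
             false_detections = m$n_false,
             record_hours = record_hours,
             fd_per_hour = m$n_false / record_hours,
             stringsAsFactors = FALSE)
}
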