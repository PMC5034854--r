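# EDF (European Data Format) 16-bit read/write in base R. The format is an
# ASCII header (256 bytes + 256 per signal) followed by data records of
# little-endian 16-bit integers; one-second data records are used here.

padField <- function(x, width) {
  s <- substr(as.character(x), 1, width)
  paste0(s, strrep(" ", width - nchar(s)))
}

#' Write an EEG record to an EDF file
#'
#' Writes a 16-bit EDF file with one-second data records, channel labels
#' equal to the record's bipolar derivation names and physical unit uV.
#' The record is zero-padded to a whole number of seconds if needed.
#'
#' @param record an [EEGRecord-class] in uV.
#' @param path output file path.
#' @param physRange symmetric physical range in uV (clipping applies);
#'   with the default 2000 uV the quantisation step is about 0.06 uV.
#' @return `path`, invisibly.
#' @export
writeEDF <- function(record, path, physRange = 2000) {
  sig <- signalMatrix(record)
  if (nrow(sig) == 0L) stop("cannot write an empty record")
  fs <- samplingRate(record)
  if (fs != round(fs)) stop("sampling rate must be integral for EDF output")
  n_ch <- ncol(sig)
  n_rec <- ceiling(nrow(sig) / fs)
  if (nrow(sig) < n_rec * fs)
    sig <- rbind(sig, matrix(0, n_rec * fs - nrow(sig), n_ch))
  dmin <- -32768; dmax <- 32767
  pMin <- -physRange; pMax <- physRange
  clipped <- pmin(pmax(sig, pMin), pMax)
  dig <- round((clipped - pMin) / (pMax - pMin) * (dmax - dmin) + dmin)
  storage.mode(dig) <- "integer"
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    padField("0", 8),
    padField("X X X X", 80),
    padField("Startdate 01-JAN-2000 X X X", 80),
    padField("01.01.00", 8), padField("00.00.00", 8),
    padField(256 * (n_ch + 1), 8),
    padField("", 44),
    padField(n_rec, 8),
    padField("1", 8),
    padField(n_ch, 4),
    paste(vapply(channelLabels(record), padField, "", width = 16),
          collapse = ""),
    strrep(padField("simulated EEG", 80), n_ch),
    strrep(padField("uV", 8), n_ch),
    strrep(padField(pMin, 8), n_ch),
    strrep(padField(pMax, 8), n_ch),
    strrep(padField(dmin, 8), n_ch),
    strrep(padField(dmax, 8), n_ch),
    strrep(padField("BP 0.5-70 Hz", 80), n_ch),
    strrep(padField(fs, 8), n_ch),
    strrep(padField("", 32), n_ch)
  )
  writeChar(hdr, con, eos = NULL)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * fs + 1L):(r * fs)
    writeBin(as.integer(dig[idx, ]), con, size = 2L, endian = "little")
  }
  invisible(path)
}

readEDFHeader <- function(con) {
  rd <- function(k) readChar(con, k, useBytes = TRUE)
  h <- list(version = rd(8), patient = rd(80), recording = rd(80),
            startdate = rd(8), starttime = rd(8),
            header_bytes = as.integer(rd(8)), reserved = rd(44),
            n_records = as.integer(rd(8)), record_s = as.numeric(rd(8)),
            n_signals = as.integer(rd(4)))
  ns <- h$n_signals
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header: bad signal count")
  fld <- function(k) vapply(seq_len(ns), function(i) trimws(rd(k)), "")
  h$labels <- fld(16); h$transducer <- fld(80); h$unit <- fld(8)
  h$phys_min <- as.numeric(fld(8)); h$phys_max <- as.numeric(fld(8))
  h$dig_min <- as.numeric(fld(8)); h$dig_max <- as.numeric(fld(8))
  h$prefilter <- fld(80); h$samples_per_record <- as.integer(fld(8))
  h$sig_reserved <- fld(32)
  h
}

#' Read an EDF file into an EEGRecord
#'
#' Parses a 16-bit EDF file, converts digital values back to physical
#' units and returns the EEG channels. Channels whose physical dimension
#' is not microvolts (e.g. ECG or respiration traces recorded alongside
#' the EEG) are dropped; the remaining channels must share one sampling
#' rate.
#'
#' @param path EDF file path.
#' @return An [EEGRecord-class].
#' @export
readEDF <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  h <- tryCatch(readEDFHeader(con),
                error = function(e) stop("corrupt EDF header in ", path,
                                         ": ", conditionMessage(e)))
  if (is.na(h$n_records) || h$n_records < 1L)
    stop("corrupt EDF header: bad record count")
  keep <- grepl("uV|µV", h$unit)
  if (!any(keep))
    stop("unit mismatch: no microvolt channels found (units: ",
         paste(unique(h$unit), collapse = ", "), ")")
  fs <- unique(h$samples_per_record[keep] / h$record_s)
  if (length(fs) != 1L)
    stop("EEG channels disagree on sampling rate")
  per_rec <- sum(h$samples_per_record)
  raw <- readBin(con, "integer", n = h$n_records * per_rec, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < h$n_records * per_rec)
    stop("corrupt EDF: truncated data section")
  offs <- c(0L, cumsum(h$samples_per_record))
  sig <- matrix(0, h$n_records * max(h$samples_per_record[keep]), sum(keep))
  col <- 0L
  for (j in seq_len(h$n_signals)) {
    if (!keep[j]) next
    col <- col + 1L
    spr <- h$samples_per_record[j]
    gain <- (h$phys_max[j] - h$phys_min[j]) / (h$dig_max[j] - h$dig_min[j])
    for (r in seq_len(h$n_records)) {
      d <- raw[((r - 1L) * per_rec + offs[j] + 1L):
                 ((r - 1L) * per_rec + offs[j] + spr)]
      sig[((r - 1L) * spr + 1L):(r * spr), col] <-
        (d - h$dig_min[j]) * gain + h$phys_min[j]
    }
  }
  EEGRecord(sig, fs, h$labels[keep])
}
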