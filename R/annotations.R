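#' Write seizure annotations or detection events to a text file
#'
#' Tab-separated with a header row; onsets and durations are seconds from
#' record start, written to 2 decimal places. Detection-event columns
#' (`channel`, `peak_probability`) are included when present.
#'
#' @param events data.frame with at least `onset_s` and `duration_s`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAnnotations <- function(events, path) {
  stopifnot(all(c("onset_s", "duration_s") %in% names(events)))
  out <- events
  out$onset_s <- sprintf("%.2f", events$onset_s)
  out$duration_s <- sprintf("%.2f", events$duration_s)
  if ("peak_probability" %in% names(out))
    out$peak_probability <- sprintf("%.4f", events$peak_probability)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a seizure annotation / detection event file
#'
#' @param path tab-separated file with a header row; columns `onset_s`
#'   and `duration_s` required. Malformed rows raise an error naming the
#'   line; overlapping events produce a warning but are retained.
#' @return data.frame (zero rows for a header-only file).
#' @export
readAnnotations <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty annotation file: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("onset_s", "duration_s") %in% names(df)))
    stop("annotation file must have onset_s and duration_s columns")
  for (col in c("onset_s", "duration_s")) {
    v <- df[[col]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(v))
    if (length(bad))
      stop("malformed ", col, " in ", path, " at line ", bad[1] + 1L)
    df[[col]] <- v
  }
  if (nrow(df) > 1L) {
    # events only conflict within one record: group by subject/period when
    # those columns are present
    grp <- interaction(
      if ("subject" %in% names(df)) df$subject else 0,
      if ("period" %in% names(df)) df$period else 0, drop = TRUE)
    for (g in split(df, grp)) {
      if (nrow(g) < 2L) next
      o <- order(g$onset_s)
      ends <- g$onset_s[o] + g$duration_s[o]
      if (any(g$onset_s[o][-1] < ends[-length(ends)])) {
        warning("overlapping events in ", path, " (retained)")
        break
      }
    }
  }
  df
}

#' Read / write a run configuration
#'
#' YAML round-trip of the pipeline configuration: montage sampling rate,
#' simulation parameters (cohort size, drug effect, counts, record
#' length), detector hyperparameters (smoothing span, cost, artifact
#' percentile), decision threshold, statistics options and the master
#' seed.
#'
#' @param path YAML file path.
#' @return configuration list.
#' @export
readConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaultConfig(cfg)
}

#' @rdname readConfig
#' @param config configuration list to write.
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname readConfig
#' @param ... named overrides of the default configuration (or a single
#'   list).
#' @export
defaultConfig <- function(...) {
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1]]) && is.null(names(over)))
    over <- over[[1]]
  cfg <- list(
    sampling_rate = 256,
    n_subjects = 18,
    amplitude_scale = 0.435,
    channel_delta = 1,
    count_mean = 6, count_min = 1, count_max = 68,
    record_s = 1200,
    n_train_subjects = 4,
    threshold = 0.3,
    smoothing_epochs = 15,
    svm_cost = 1,
    artifact_percentile = 0.975,
    seed = 1
  )
  cfg[names(over)] <- over
  cfg
}
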