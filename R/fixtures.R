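#' Load the packaged per-subject cohort tables
#'
#' Two small tab-separated per-subject clinical summary tables (18 term
#' neonates) ship with the package: `cohort_counts` (per-patient aetiology, matched
#' pre/post seizure counts and phenobarbital doses, 18 rows) and
#' `subject_summaries` (per-baby median peak seizure amplitude and median
#' channels involved at seizure peak, pre and post phenobarbital, with
#' electroclinical-uncoupling labels carried as pass-through metadata).
#'
#' @param which "counts" or "summaries".
#' @return data.frame.
#' @export
loadCohortTable <- function(which = c("counts", "summaries")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   if (which == "counts") "cohort_counts.tsv"
                   else "subject_summaries.tsv",
                   package = "neoseize", mustWork = TRUE)
  df <- utils::read.delim(f, stringsAsFactors = FALSE)
  if (nrow(df) != 18L)
    stop("corrupt fixture table: expected 18 subjects")
  df
}

#' Recompute the group statistics from the per-subject tables
#'
#' The fixture analysis path: starting from the packaged per-baby
#' summaries (median peak seizure amplitude and median channels involved
#' at seizure peak, pre and post phenobarbital), recomputes the group
#' medians and interquartile ranges (weighted-average percentiles), the
#' percentage drop in median amplitude, Wilcoxon signed-rank p-values,
#' per-subject change counts, and the total matched seizure counts.
#'
#' @return A list with components `amplitude`, `channels` (each: medians,
#'   IQR bounds, p-value, change counts), `amplitude_drop_pct`,
#'   `matched_total` (named pre/post), and `table` (a tidy comparison
#'   data.frame).
#' @examples
#' rt <- reproduceTables()
#' rt$amplitude$post_median  # 53.5
#' @export
reproduceTables <- function() {
  counts <- loadCohortTable("counts")
  subj <- loadCohortTable("summaries")
  oneVar <- function(pre, post) {
    wt <- wilcoxonSignedRank(pre, post)
    cc <- perSubjectChangeCounts(pre, post)
    list(pre_median = stats::median(pre),
         pre_q1 = percentileWA(pre, 0.25),
         pre_q3 = percentileWA(pre, 0.75),
         post_median = stats::median(post),
         post_q1 = percentileWA(post, 0.25),
         post_q3 = percentileWA(post, 0.75),
         W = wt$W, z = wt$z, p_value = wt$p.value,
         n_reduced = cc$n_reduced, n_total = cc$n_total)
  }
  amp <- oneVar(subj$amp_pre_uV, subj$amp_post_uV)
  ch <- oneVar(subj$channels_peak_pre, subj$channels_peak_post)
  tab <- data.frame(
    variable = c("peak_amplitude_uV", "channels_peak"),
    pre_median = c(amp$pre_median, ch$pre_median),
    pre_iqr = c(sprintf("%.2f-%.2f", roundHalfUp(amp$pre_q1),
                        roundHalfUp(amp$pre_q3)),
                sprintf("%.2f-%.2f", roundHalfUp(ch$pre_q1),
                        roundHalfUp(ch$pre_q3))),
    post_median = c(amp$post_median, ch$post_median),
    post_iqr = c(sprintf("%.2f-%.2f", roundHalfUp(amp$post_q1),
                         roundHalfUp(amp$post_q3)),
                 sprintf("%.2f-%.2f", roundHalfUp(ch$post_q1),
                         roundHalfUp(ch$post_q3))),
    p_value = c(amp$p_value, ch$p_value),
    stringsAsFactors = FALSE)
  list(amplitude = amp, channels = ch,
       amplitude_drop_pct =
         100 * (amp$pre_median - amp$post_median) / amp$pre_median,
       matched_total = c(pre = sum(counts$n_pre), post = sum(counts$n_post)),
       table = tab)
}
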