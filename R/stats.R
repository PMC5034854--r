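#' Match pre/post seizure counts
#'
#' Post-treatment seizure numbers generally greatly exceed pre-treatment
#' numbers, so for paired statistics both periods are truncated to the
#' first `min(n_pre, n_post)` seizures in temporal order.
#'
#' @param pre_list,post_list data.frames (or lists) of per-seizure rows in
#'   temporal order, one per period.
#' @return A list: `pre`, `post` (truncated to the matched count `k`),
#'   `k`.
#' @examples
#' pre <- data.frame(onset_s = 1:5)
#' post <- data.frame(onset_s = 1:20)
#' matchCounts(pre, post)$k  # 5
#' @export
matchCounts <- function(pre_list, post_list) {
  n_pre <- if (is.data.frame(pre_list)) nrow(pre_list) else length(pre_list)
  n_post <- if (is.data.frame(post_list)) nrow(post_list)
            else length(post_list)
  if (n_pre == 0L || n_post == 0L)
    stop("subjects must have seizures in both periods (inclusion criterion)")
  k <- min(n_pre, n_post)
  takeFirst <- function(x, k) {
    if (is.data.frame(x)) x[seq_len(k), , drop = FALSE] else x[seq_len(k)]
  }
  list(pre = takeFirst(pre_list, k), post = takeFirst(post_list, k), k = k)
}

#' Per-subject summary of a seizure variable
#'
#' Reduces the per-seizure values of one subject and period to the summary
#' measure fixed for that variable: the median for peak amplitude,
#' duration, channel counts and frequency variability; the maximum for the
#' categorical rhythmicity and background scores; the proportion for
#' detection rate, discharge morphology and morphology change. Even-count
#' medians average the middle two values, so fractional channel counts are
#' legitimate summaries.
#'
#' @param values numeric (or logical, for proportions) per-seizure values.
#' @param variable variable name; one of the ten feature names or
#'   "detection_rate".
#' @return A list: `value`, `reducer`.
#' @export
summariseSeizures <- function(values, variable) {
  reducer <- summaryReducer(variable)
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("no non-missing values to summarise")
  v <- switch(reducer,
              median = stats::median(values),
              maximum = max(values),
              proportion = mean(as.logical(values)))
  list(value = v, reducer = reducer)
}

summaryReducer <- function(variable) {
  median_vars <- c("peak_amplitude_uV", "duration_s", "channels_onset",
                   "channels_peak", "frequency_variability_hz")
  max_vars <- c("rhythmicity_score", "background_score")
  prop_vars <- c("detection_rate", "morphology_changed",
                 "morphology_onset", "morphology_peak")
  if (variable %in% median_vars) "median"
  else if (variable %in% max_vars) "maximum"
  else if (variable %in% prop_vars) "proportion"
  else stop("unknown variable: ", variable)
}

#' Weighted-average percentile
#'
#' The percentile convention used for all reported interquartile ranges:
#' position `h = (n+1)p` on the sorted values, linearly interpolating
#' between the flanking order statistics (SPSS's default "weighted average"
#' definition, type 6 in R's taxonomy).
#'
#' @param values numeric vector (non-empty).
#' @param p probability in (0, 1).
#' @return the percentile value.
#' @examples
#' percentileWA(c(1, 2, 3, 10), 0.5)  # 2.5, the median
#' @export
percentileWA <- function(values, p) {
  if (!length(values)) stop("values must be non-empty")
  if (p <= 0 || p >= 1) stop("p must lie in (0, 1)")
  x <- sort(values)
  n <- length(x)
  h <- (n + 1) * p
  lo <- floor(h)
  if (lo < 1) return(x[1])
  if (lo >= n) return(x[n])
  x[lo] + (h - lo) * (x[lo + 1] - x[lo])
}

#' Round half away from zero
#'
#' Decimal rounding as statistical packages print it (0.125 -> 0.13),
#' unlike R's round-half-to-even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values.
#' @export
roundHalfUp <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Wilcoxon signed-rank test for paired pre/post summaries
#'
#' Paired two-sided Wilcoxon signed-rank test as run by standard
#' statistical packages on pre/post treatment comparisons: zero
#' differences are dropped, tied absolute differences get mid-ranks, and
#' the tie-corrected normal approximation gives the two-sided p-value.
#' An exact path enumerates all sign assignments (feasible for small n)
#' for validation of the asymptotic path.
#'
#' @param pre,post paired numeric vectors of equal length >= 2.
#' @param exact if `TRUE`, compute the p-value by full enumeration of the
#'   2^n sign assignments (n <= 16 enforced).
#' @return A list: `n` (non-zero pairs), `W` (sum of positive-difference
#'   ranks, for differences pre - post), `z`, `p.value`, `method`.
#' @examples
#' wilcoxonSignedRank(c(5, 7, 3, 9), c(2, 1, 4, 3))
#' @export
wilcoxonSignedRank <- function(pre, post, exact = FALSE) {
  stopifnot(length(pre) == length(post), length(pre) >= 2)
  d <- pre - post
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L)
    stop(errorCondition("all paired differences are zero",
                        class = c("degenerateComparison", "error")))
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  if (exact) {
    if (n > 16) stop("exact enumeration limited to n <= 16")
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- as.numeric(signs %*% r)
    p <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    z <- NA_real_
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    if (sig2 <= 0)
      stop(errorCondition("zero variance in signed ranks",
                          class = c("degenerateComparison", "error")))
    z <- (W - mu) / sqrt(sig2)
    p <- 2 * stats::pnorm(-abs(z))
    method <- "tie-corrected normal approximation"
  }
  list(n = n, W = W, z = z, p.value = min(p, 1), method = method)
}

#' Compare a pre/post cohort variable by variable
#'
#' Produces the group comparison table: for every variable, the group
#' median and interquartile range of the per-subject summaries in each
#' period (weighted-average percentiles), the Wilcoxon signed-rank
#' p-value, and a significance flag at p < 0.05 (two-sided).
#'
#' @param summaries data.frame with columns `subject`, `period`
#'   ("pre"/"post"), `variable`, `value` — one per-subject summary per row.
#' @return data.frame, one row per variable: medians, IQR bounds, p-value,
#'   significance flag, n.
#' @export
compareCohort <- function(summaries) {
  stopifnot(all(c("subject", "period", "variable", "value") %in%
                names(summaries)))
  out <- lapply(split(summaries, summaries$variable), function(sv) {
    w <- stats::reshape(sv[, c("subject", "period", "value")],
                        direction = "wide", idvar = "subject",
                        timevar = "period")
    if (!all(c("value.pre", "value.post") %in% names(w)) ||
        anyNA(w[, c("value.pre", "value.post")]))
      stop("subjects must be present in both periods for variable ",
           sv$variable[1])
    pre <- w$value.pre; post <- w$value.post
    p <- tryCatch(wilcoxonSignedRank(pre, post)$p.value,
                  degenerateComparison = function(e) 1)
    data.frame(
      variable = sv$variable[1],
      pre_median = stats::median(pre),
      pre_q1 = percentileWA(pre, 0.25), pre_q3 = percentileWA(pre, 0.75),
      post_median = stats::median(post),
      post_q1 = percentileWA(post, 0.25), post_q3 = percentileWA(post, 0.75),
      p_value = p, significant = p < 0.05, n = length(pre),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count subjects whose summary decreased after treatment
#'
#' Counts subjects with a strictly lower post-treatment summary; ties
#' count as not reduced.
#'
#' @param pre,post paired per-subject summary vectors.
#' @return A list: `n_reduced`, `n_total`.
#' @export
perSubjectChangeCounts <- function(pre, post) {
  stopifnot(length(pre) == length(post))
  list(n_reduced = sum(post < pre), n_total = length(pre))
}
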