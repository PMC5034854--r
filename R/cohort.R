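#' Derive a reproducible sub-seed
#'
#' Deterministic seed derivation that stays inside the 32-bit integer range
#' for any master seed: `(seed * 48271 + k) mod (2^31 - 1)`. Used to give
#' every subject, seizure and background its own RNG stream; exposed so
#' callers can re-render exactly the waveform a subject record contains.
#'
#' @param seed master integer seed.
#' @param k stream index.
#' @return derived integer seed.
#' @export
deriveSeed <- function(seed, k = 0) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(k)) %% 2147483647)
}

#' Seed of one rendered seizure within a subject simulation
#'
#' @param sim a `subjectSim`.
#' @param i seizure index within the period.
#' @return the integer seed [generateSubject()] uses for that seizure.
#' @export
seizureSeed <- function(sim, i) deriveSeed(sim$rng_seed, i)

# Truncated geometric seizure counts spanning the observed per-baby range.
drawSeizureCounts <- function(n, mean = 6, min = 1L, max = 68L) {
  p <- 1 / mean
  k <- integer(n)
  for (i in seq_len(n)) {
    repeat {
      v <- 1L + stats::rgeom(1L, p)
      if (v >= min && v <= max) { k[i] <- v; break }
    }
  }
  k
}

# Draw one ground-truth seizure specification. Frequencies are kept
# consistent with the drawn morphology band (rhythmic categories) or used as
# the discharge repetition rate (transient categories).
randomSeizureSpec <- function(onset_s, duration_s = NULL,
                              morph_probs = c(0.50, 0.15, 0.05, 0.12, 0.18),
                              p_change = 0.45,
                              amp_uV = NULL, subject_amp = 120) {
  if (is.null(duration_s))
    duration_s <- min(240, max(20, stats::rlnorm(1, log(103), 0.45)))
  m_on <- sample.int(5L, 1L, prob = morph_probs)
  m_pk <- if (stats::runif(1) < p_change)
    sample(setdiff(1:5, m_on), 1L) else m_on
  bandFreq <- function(m) switch(m, stats::runif(1, 1, 3.4),
                                 stats::runif(1, 4.2, 7.5),
                                 stats::runif(1, 8.2, 12.5),
                                 stats::runif(1, 0.8, 2),
                                 stats::runif(1, 0.8, 1.8))
  f0 <- bandFreq(m_on)
  f1 <- if (m_pk == m_on) f0 * stats::runif(1, 0.75, 1) else bandFreq(m_pk)
  f2 <- f1 * stats::runif(1, 0.6, 1)
  if (is.null(amp_uV))
    amp_uV <- max(30, subject_amp * stats::rlnorm(1, 0, 0.35))
  c_on <- sample.int(4L, 1L)
  c_pk <- min(8L, c_on + stats::rbinom(1L, 7L, 0.3))
  if (duration_s < 14) c_pk <- c_on
  seizureSpec(onset_s = onset_s, duration_s = duration_s,
              morphology_onset = m_on, morphology_peak = m_pk,
              freq_start = f0, freq_mid = f1, freq_end = f2,
              peak_amplitude_uV = amp_uV,
              channels_onset = c_on, channels_peak = c_pk,
              rhythmicity_jitter = stats::runif(1, 0.05, 0.40))
}

# Place n seizures sequentially with inter-seizure gaps; returns specs and
# the record length that accommodates them (or caps n to fit a fixed length).
placeSeizures <- function(n, record_s = NULL, lead_in = 40, gap = c(25, 60),
                          subject_amp = 120, max_dur = 240) {
  specs <- list()
  t <- lead_in + stats::runif(1, 0, gap[1])
  for (i in seq_len(n)) {
    s <- randomSeizureSpec(onset_s = t, subject_amp = subject_amp)
    if (s$duration_s > max_dur) s$duration_s <- max_dur
    if (!is.null(record_s) && t + s$duration_s + 20 > record_s) break
    specs[[length(specs) + 1L]] <- s
    t <- t + s$duration_s + stats::runif(1, gap[1], gap[2])
  }
  list(specs = specs,
       record_s = if (is.null(record_s)) ceiling(t + 20) else record_s)
}

#' Simulate the ground-truth description of one subject
#'
#' Draws background grade, per-period seizure specifications and record
#' lengths for one simulated neonate. In paired mode the post-treatment
#' seizures are the pre-treatment specifications transformed by the drug
#' effect (amplitude scaled, channel counts reduced), re-timed on the
#' post record.
#'
#' @param subject_id identifier.
#' @param n_seizures seizures per period (>= 1: only neonates with seizures
#'   in both periods enter the study design).
#' @param effect a [drugEffect()].
#' @param record_s fixed record length per period in seconds, or `NULL` to
#'   size each record to its seizures.
#' @param background_probs probabilities of background grades 1-4.
#' @param seed integer seed.
#' @return A list of class `subjectSim` with elements `subject_id`,
#'   `background`, `pre_seizures`, `post_seizures`, `drug_effect`,
#'   `record_s` (named pre/post) and `rng_seed`.
#' @examples
#' sim <- simulateSubject("b1", n_seizures = 2, seed = 5)
#' length(sim$pre_seizures)
#' @export
simulateSubject <- function(subject_id, n_seizures, effect = drugEffect(),
                            record_s = NULL,
                            background_probs = c(0.5, 0.25, 0.15, 0.10),
                            seed = 1L) {
  if (n_seizures < 1)
    stop("subjects must have at least one seizure in each period")
  set.seed(as.integer(seed))
  grade <- sample.int(4L, 1L, prob = background_probs)
  subject_amp <- max(45, stats::rlnorm(1, log(120), 0.6))
  pre <- placeSeizures(n_seizures, record_s, subject_amp = subject_amp)
  post_specs <- lapply(pre$specs, applyDrugEffect, effect = effect)
  # re-time post seizures on their own record
  t <- 40 + stats::runif(1, 0, 25)
  rec_post <- pre$record_s
  kept <- list()
  for (s in post_specs) {
    if (!is.null(record_s) && t + s$duration_s + 20 > record_s) break
    s$onset_s <- t
    kept[[length(kept) + 1L]] <- s
    t <- t + s$duration_s + stats::runif(1, 25, 60)
  }
  if (is.null(record_s)) rec_post <- ceiling(t + 20)
  # keep the periods matched if the fixed record length truncated one side
  k <- min(length(pre$specs), length(kept))
  structure(list(subject_id = subject_id,
                 background = backgroundSpec(grade),
                 pre_seizures = pre$specs[seq_len(k)],
                 post_seizures = kept[seq_len(k)],
                 drug_effect = effect,
                 record_s = c(pre = pre$record_s, post = rec_post),
                 rng_seed = as.integer(seed)),
            class = "subjectSim")
}

checkNonOverlapping <- function(specs) {
  if (length(specs) < 2) return(invisible(TRUE))
  on <- vapply(specs, `[[`, numeric(1), "onset_s")
  du <- vapply(specs, `[[`, numeric(1), "duration_s")
  o <- order(on)
  if (any(on[o][-1] < (on[o] + du[o])[-length(o)]))
    stop("seizure specifications overlap within a period")
  invisible(TRUE)
}

#' Render the pre/post records of one simulated subject
#'
#' Builds the two EEG records (background plus rendered seizures at their
#' specified onsets) and the matching gold-standard annotation table. The
#' post-period seizures already carry the drug effect from
#' [simulateSubject()]. Seizure waveform seeds are derived from the
#' subject seed and the seizure index, so an identity drug effect yields
#' identical pre and post waveforms.
#'
#' @param sim a `subjectSim` from [simulateSubject()].
#' @param montage a [neonatalMontage()].
#' @return A list: `pre`, `post` ([EEGRecord-class]s), `annotations`
#'   (data.frame: onset_s, duration_s, subject, period) and `truth`
#'   (data.frame of ground-truth spec values per seizure).
#' @export
generateSubject <- function(sim, montage = neonatalMontage()) {
  stopifnot(inherits(sim, "subjectSim"))
  checkNonOverlapping(sim$pre_seizures)
  checkNonOverlapping(sim$post_seizures)
  renderPeriod <- function(specs, dur, bg_seed) {
    rec <- generateBackground(sim$background, dur, montage, seed = bg_seed)
    sig <- rec@signal
    for (i in seq_along(specs)) {
      w <- renderSeizure(specs[[i]], montage, seed = seizureSeed(sim, i))
      i0 <- round(specs[[i]]$onset_s * montage$samplingRate) + 1L
      idx <- i0:(i0 + nrow(w$waveform) - 1L)
      sig[idx, ] <- sig[idx, ] + w$waveform
    }
    EEGRecord(sig, montage$samplingRate, montage$channels)
  }
  pre <- renderPeriod(sim$pre_seizures, sim$record_s["pre"],
                      deriveSeed(sim$rng_seed, 900001))
  post <- renderPeriod(sim$post_seizures, sim$record_s["post"],
                       deriveSeed(sim$rng_seed, 900002))
  ann <- rbind(annotationFrame(sim$pre_seizures, sim$subject_id, "pre"),
               annotationFrame(sim$post_seizures, sim$subject_id, "post"))
  list(pre = pre, post = post, annotations = ann, truth = specTable(sim))
}

annotationFrame <- function(specs, subject, period) {
  data.frame(
    onset_s = vapply(specs, `[[`, numeric(1), "onset_s"),
    duration_s = vapply(specs, `[[`, numeric(1), "duration_s"),
    subject = rep(as.character(subject), length(specs)),
    period = rep(period, length(specs)),
    stringsAsFactors = FALSE
  )
}

#' Ground-truth table of a subject simulation
#'
#' Flattens the per-seizure specifications of a `subjectSim` into a
#' data.frame (one row per seizure and period) for closure checks against
#' measured features.
#'
#' @param sim a `subjectSim`.
#' @return data.frame with the ground-truth value of every specification
#'   field plus `subject`, `period` and `seizure` index.
#' @export
specTable <- function(sim) {
  one <- function(specs, period) {
    if (!length(specs)) return(NULL)
    df <- do.call(rbind, lapply(specs, function(s)
      as.data.frame(unclass(s), stringsAsFactors = FALSE)))
    df$background_grade <- sim$background$grade
    df$subject <- as.character(sim$subject_id)
    df$period <- period
    df$seizure <- seq_len(nrow(df))
    df
  }
  rbind(one(sim$pre_seizures, "pre"), one(sim$post_seizures, "post"))
}

#' Generate a synthetic pre/post cohort
#'
#' Simulates `n_subjects` neonates, each with seizures before and after
#' treatment, with the drug effect applied to the post period. Seizure
#' counts per subject are drawn from a truncated geometric distribution
#' spanning the observed range. Optionally renders the EEG records and
#' writes one EDF file per subject and period plus a tab-separated
#' annotation file.
#'
#' @param n_subjects number of subjects (>= 1).
#' @param effect a [drugEffect()].
#' @param seed integer master seed; all subject seeds derive from it.
#' @param montage a [neonatalMontage()].
#' @param count_mean,count_min,count_max parameters of the truncated
#'   geometric seizure-count distribution.
#' @param record_s fixed per-period record length (seconds) or `NULL`.
#' @param render one of "specs" (ground truth only), "records" (also render
#'   the EEG).
#' @param outDir if non-`NULL`, write EDF + annotation files here.
#' @return A list: `sims` (list of `subjectSim`), `truth` (cohort
#'   ground-truth table), `annotations`, and when rendered `records` (a list
#'   per subject with `pre`/`post` [EEGRecord-class]s).
#' @examples
#' co <- generateCohort(2, seed = 11, render = "specs")
#' nrow(co$truth)
#' @export
generateCohort <- function(n_subjects, effect = drugEffect(), seed = 1L,
                           montage = neonatalMontage(),
                           count_mean = 6, count_min = 1L, count_max = 68L,
                           record_s = NULL,
                           render = c("specs", "records"),
                           outDir = NULL) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  render <- match.arg(render)
  set.seed(as.integer(seed))
  counts <- drawSeizureCounts(n_subjects, count_mean, count_min, count_max)
  sims <- lapply(seq_len(n_subjects), function(i)
    simulateSubject(sprintf("s%02d", i), counts[i], effect = effect,
                    record_s = record_s, seed = deriveSeed(seed, i)))
  truth <- do.call(rbind, lapply(sims, specTable))
  ann <- do.call(rbind, lapply(sims, function(s)
    rbind(annotationFrame(s$pre_seizures, s$subject_id, "pre"),
          annotationFrame(s$post_seizures, s$subject_id, "post"))))
  out <- list(sims = sims, truth = truth, annotations = ann,
              montage = montage)
  if (render == "records" || !is.null(outDir)) {
    recs <- lapply(sims, generateSubject, montage = montage)
    names(recs) <- vapply(sims, `[[`, character(1), "subject_id")
    out$records <- recs
  }
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (s in names(out$records)) {
      writeEDF(out$records[[s]]$pre, file.path(outDir,
               paste0(s, "_pre.edf")))
      writeEDF(out$records[[s]]$post, file.path(outDir,
               paste0(s, "_post.edf")))
      writeAnnotations(out$records[[s]]$annotations,
                       file.path(outDir, paste0(s, "_annotations.tsv")))
    }
  }
  out
}

#' Render one seizure into a short background record
#'
#' Convenience for closure checks and amplitude-recovery studies: builds a
#' record of `pad_pre + duration + pad_post` seconds of background with the
#' seizure rendered at `pad_pre`, optionally restricted to the seizure's
#' lead channel (cheap when only amplitude or frequency is measured).
#'
#' @param spec a [seizureSpec()] (its `onset_s` is ignored).
#' @param montage a [neonatalMontage()].
#' @param background a [backgroundSpec()].
#' @param seed integer seed.
#' @param pad_pre,pad_post background padding, seconds.
#' @param leadOnly if `TRUE`, return a single-channel record (the lead
#'   channel).
#' @return A list: `record` ([EEGRecord-class]), `annotation` (list with
#'   `onset_s`, `duration_s`), `render` (the [renderSeizure()] output).
#' @export
renderSeizureSnippet <- function(spec, montage = neonatalMontage(),
                                 background = backgroundSpec(1), seed = 1L,
                                 pad_pre = 15, pad_post = 10,
                                 leadOnly = FALSE) {
  stopifnot(inherits(spec, "seizureSpec"))
  dur <- pad_pre + spec$duration_s + pad_post
  rec <- generateBackground(background, dur, montage, seed = seed + 51L)
  w <- renderSeizure(spec, montage, seed = seed)
  sig <- rec@signal
  i0 <- round(pad_pre * montage$samplingRate) + 1L
  idx <- i0:(i0 + nrow(w$waveform) - 1L)
  sig[idx, ] <- sig[idx, ] + w$waveform
  if (leadOnly) sig <- sig[, w$lead_channel, drop = FALSE]
  list(record = EEGRecord(sig, montage$samplingRate,
                          if (leadOnly) montage$channels[w$lead_channel]
                          else montage$channels),
       annotation = list(onset_s = pad_pre, duration_s = spec$duration_s),
       render = w)
}
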