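test_that("cohorts are reproducible and respect the count range", {
  co1 <- generateCohort(5, seed = 17, render = "specs")
  co2 <- generateCohort(5, seed = 17, render = "specs")
  expect_identical(co1$truth, co2$truth)
  counts <- table(co1$annotations$subject, co1$annotations$period)
  expect_true(all(counts >= 1 & counts <= 68))
  # seizure-free subjects are excluded by design
  expect_error(simulateSubject("x", 0), "at least one")
  expect_error(generateCohort(0), ">= 1")
})

test_that("paired post specs equal pre specs transformed by the effect", {
  eff <- drugEffect(0.435, 1)
  co <- generateCohort(4, eff, seed = 23, render = "specs")
  for (sim in co$sims) {
    expect_equal(length(sim$pre_seizures), length(sim$post_seizures))
    for (i in seq_along(sim$pre_seizures)) {
      pre <- sim$pre_seizures[[i]]
      post <- sim$post_seizures[[i]]
      expect_equal(post$peak_amplitude_uV, pre$peak_amplitude_uV * 0.435)
      expect_equal(post$channels_peak, max(1L, pre$channels_peak - 1L))
      expect_equal(post$duration_s, pre$duration_s)
      expect_equal(post$freq_start, pre$freq_start)
    }
  }
  # the worked arithmetic: a 123 uV seizure scaled by 0.435
  s <- applyDrugEffect(seizureSpec(0, 60, peak_amplitude_uV = 123),
                       drugEffect(0.435, 0))
  expect_equal(s$peak_amplitude_uV, 53.505, tolerance = 1e-9)
})

test_that("measured features recover the generator's ground truth", {
  # a battery of seizures across morphologies and spreads
  m <- neonatalMontage()
  specs <- list(
    seizureSpec(0, 90, 1, 1, 2, 1.5, 1, 123, 1, 5, 0.05),
    seizureSpec(0, 70, 2, 2, 5, 4.5, 4.2, 150, 2, 4, 0.08),
    seizureSpec(0, 60, 3, 3, 9, 8.8, 8.4, 140, 2, 2, 0.05),
    seizureSpec(0, 80, 4, 4, 1.4, 1.2, 1, 170, 3, 6, 0.08),
    seizureSpec(0, 80, 5, 5, 1.2, 1.2, 1, 160, 2, 5, 0.08))
  for (k in seq_along(specs)) {
    sp <- specs[[k]]
    sp$onset_s <- 60
    g <- oneSeizureSubject(sp, seed = 30 + k)
    ann <- as.list(g$annotations[1, ])
    f <- extractFeatures(g$pre, ann)
    expect_lt(abs(f$peak_amplitude_uV - sp$peak_amplitude_uV) /
                sp$peak_amplitude_uV, 0.10)
    # onset windows sit at the envelope minimum; for sparse transient
    # morphologies the weakest channel there is below the SNR at which
    # exact counts are guaranteed, so one channel of slack is allowed
    if (sp$morphology_onset <= 3) {
      expect_equal(f$channels_onset, sp$channels_onset)
    } else {
      expect_lte(abs(f$channels_onset - sp$channels_onset), 1)
    }
    expect_equal(f$channels_peak, sp$channels_peak)
    expect_equal(f$duration_s, sp$duration_s, tolerance = 2)
    expect_equal(f$morphology_onset, sp$morphology_onset)
    expect_equal(f$morphology_peak, sp$morphology_peak)
    for (seg in c("start", "mid", "end")) {
      truth <- switch(seg, start = sp$freq_start, mid = sp$freq_mid,
                      end = sp$freq_end)
      expect_lt(abs(as.numeric(segmentFrequency(g$pre, ann, seg)) - truth),
                0.25)
    }
  }
})

test_that("a cohort's measured amplitude ratio recovers the drug effect", {
  scale <- 0.435
  co <- generateCohort(8, drugEffect(scale, 1), seed = 41, count_mean = 3,
                       render = "specs")
  med <- list(pre = numeric(0), post = numeric(0))
  for (sim in co$sims) {
    for (p in c("pre", "post")) {
      specs <- sim[[paste0(p, "_seizures")]]
      amps <- vapply(seq_along(specs), function(i) {
        # continuous (grade 1) background: the amplitude estimator is
        # validated under the background it is calibrated for; burst
        # suppression degrades graticule-style measurement generally
        sn <- renderSeizureSnippet(specs[[i]], background = backgroundSpec(1),
                                   seed = seizureSeed(sim, i),
                                   leadOnly = TRUE)
        peakAmplitude(sn$record, sn$annotation)
      }, numeric(1))
      med[[p]] <- c(med[[p]], median(amps))
    }
  }
  ratio <- median(med$post) / median(med$pre)
  expect_lt(abs(ratio - scale) / scale, 0.10)
})

test_that("morphology-change proportion equals the specified proportion", {
  co <- generateCohort(6, seed = 51, render = "specs")
  tr <- co$truth
  spec_prop <- mean(tr$morphology_onset != tr$morphology_peak)
  expect_equal(mean(morphologyChange(tr$morphology_onset,
                                     tr$morphology_peak)), spec_prop)
})
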