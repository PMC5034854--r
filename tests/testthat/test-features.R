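test_that("peak amplitude is unbiased on pure tones across the band", {
  for (f in c(0.5, 2, 6, 13)) {
    rec <- toneRecord(f, amp = 50)
    pp <- peakAmplitude(rec, list(onset_s = 0, duration_s = 30))
    expect_lt(abs(pp - 100) / 100, 0.01)
  }
})

test_that("flat and degenerate inputs are handled", {
  rec <- EEGRecord(matrix(0, 256 * 30, 8), 256, neonatalMontage()$channels)
  expect_equal(peakAmplitude(rec, list(onset_s = 0, duration_s = 30)), 0)
  expect_error(peakAmplitude(rec, list(onset_s = 25, duration_s = 20)),
               "outside")
  expect_error(extractFeatures(rec, list(onset_s = 5, duration_s = 0)),
               "duration")
})

test_that("segment frequency recovers tones and flags noise", {
  rec <- toneRecord(6)
  ann <- list(onset_s = 0, duration_s = 30)
  for (seg in c("start", "mid", "end")) {
    f <- segmentFrequency(rec, ann, seg)
    expect_lt(abs(as.numeric(f) - 6), 0.25)
    expect_false(attr(f, "low_confidence"))
  }
  set.seed(1)
  m <- neonatalMontage()
  noisy <- EEGRecord(matrix(rnorm(256 * 30 * 8), ncol = 8), 256, m$channels)
  fn <- segmentFrequency(noisy, ann, "mid")
  expect_true(attr(fn, "low_confidence"))
  flat <- EEGRecord(matrix(0, 256 * 30, 8), 256, m$channels)
  expect_error(segmentFrequency(flat, ann, "mid"),
               class = "noInvolvedChannel")
})

test_that("frequency variability is the sample SD of the three segments", {
  g <- oneSeizureSubject(seizureSpec(60, 90, freq_start = 2, freq_mid = 1.5,
                                     freq_end = 1, peak_amplitude_uV = 140,
                                     channels_onset = 2, channels_peak = 3,
                                     rhythmicity_jitter = 0.03))
  ann <- as.list(g$annotations[1, ])
  fv <- frequencyVariability(g$pre, ann)
  # sd(2, 1.5, 1) = 0.5; allow the per-segment measurement tolerance
  expect_lt(abs(fv - 0.5), 0.15)
  const <- oneSeizureSubject(seizureSpec(60, 90, freq_start = 2,
                                         freq_mid = 2, freq_end = 2,
                                         peak_amplitude_uV = 140,
                                         rhythmicity_jitter = 0.03))
  expect_lt(frequencyVariability(const$pre, as.list(const$annotations[1, ])),
            0.1)
})

test_that("morphology classification follows band and transient rules", {
  ann <- list(onset_s = 0, duration_s = 30)
  expect_equal(classifyMorphology(toneRecord(2), ann, "peak"), 1L)
  expect_equal(classifyMorphology(toneRecord(6), ann, "peak"), 2L)
  expect_equal(classifyMorphology(toneRecord(10), ann, "peak"), 3L)
  for (mo in 4:5) {
    g <- oneSeizureSubject(seizureSpec(60, 60, morphology_onset = mo,
                                       morphology_peak = mo,
                                       freq_start = 1.2, freq_mid = 1.2,
                                       freq_end = 1,
                                       peak_amplitude_uV = 180,
                                       channels_onset = 3, channels_peak = 4,
                                       rhythmicity_jitter = 0.08),
                           seed = 4 + mo)
    a <- as.list(g$annotations[1, ])
    expect_equal(classifyMorphology(g$pre, a, "onset"), mo)
    expect_equal(classifyMorphology(g$pre, a, "peak"), mo)
  }
  expect_false(morphologyChange(1, 1))
  expect_true(morphologyChange(1, 2))
  expect_error(morphologyChange(0, 2))
})

test_that("rhythmicity score maps injected jitter onto the 1-3 scale", {
  scores <- vapply(c(0.02, 0.25, 0.5), function(j) {
    g <- oneSeizureSubject(seizureSpec(60, 90, freq_start = 2, freq_mid = 2,
                                       freq_end = 2, peak_amplitude_uV = 150,
                                       channels_onset = 3, channels_peak = 3,
                                       rhythmicity_jitter = j), seed = 7)
    rhythmicityScore(g$pre, as.list(g$annotations[1, ]))
  }, integer(1))
  expect_equal(scores, c(3L, 2L, 1L))
  expect_equal(rhythmicityScore(toneRecord(2),
                                list(onset_s = 0, duration_s = 30)), 3L)
})

test_that("background grade is recovered from generated records", {
  m <- neonatalMontage()
  dummy <- list(onset_s = 200, duration_s = 1)
  for (grade in c(1L, 3L, 4L)) {
    rec <- generateBackground(backgroundSpec(grade), 420, m, seed = grade)
    expect_equal(backgroundScore(rec, dummy), grade)
  }
  short <- generateBackground(backgroundSpec(1), 120, m, seed = 1)
  expect_error(backgroundScore(short, list(onset_s = 50, duration_s = 10)),
               "insufficient")
})

test_that("channel involvement counts spread from onset to peak", {
  g <- oneSeizureSubject(seizureSpec(60, 90, peak_amplitude_uV = 150,
                                     channels_onset = 1, channels_peak = 5,
                                     freq_start = 2, freq_mid = 1.8,
                                     freq_end = 1.5,
                                     rhythmicity_jitter = 0.05))
  ann <- as.list(g$annotations[1, ])
  expect_equal(channelsInvolved(g$pre, ann, "onset"), 1L)
  expect_equal(channelsInvolved(g$pre, ann, "peak"), 5L)
  # background-only window scores zero
  bg <- generateBackground(backgroundSpec(1), 120, seed = 8)
  expect_equal(channelsInvolved(bg, list(onset_s = 60, duration_s = 30),
                                "peak"), 0L)
})

test_that("scaling the signal scales amplitude but not categories", {
  sp <- seizureSpec(60, 80, peak_amplitude_uV = 150, channels_onset = 2,
                    channels_peak = 4, freq_start = 2.5, freq_mid = 2,
                    freq_end = 1.6, rhythmicity_jitter = 0.1)
  g <- oneSeizureSubject(sp, seed = 12)
  ann <- as.list(g$annotations[1, ])
  rec2 <- EEGRecord(signalMatrix(g$pre) * 2, samplingRate(g$pre),
                    channelLabels(g$pre))
  f1 <- extractFeatures(g$pre, ann)
  f2 <- extractFeatures(rec2, ann)
  expect_equal(f2$peak_amplitude_uV / f1$peak_amplitude_uV, 2,
               tolerance = 0.05)
  for (col in c("morphology_onset", "morphology_peak", "rhythmicity_score",
                "channels_onset", "channels_peak"))
    expect_equal(f2[[col]], f1[[col]])
})

test_that("extractFeatures is deterministic and reports per-field errors", {
  g <- oneSeizureSubject(seizureSpec(60, 70, peak_amplitude_uV = 120),
                         seed = 21)
  ann <- as.list(g$annotations[1, ])
  f1 <- extractFeatures(g$pre, ann)
  f2 <- extractFeatures(g$pre, ann)
  expect_identical(f1, f2)
  expect_equal(f1$duration_s, ann$duration_s)
  expect_equal(f1$morphology_changed,
               f1$morphology_onset != f1$morphology_peak)
  # too-short record: background grading fails, other fields survive
  short <- oneSeizureSubject(seizureSpec(40, 60, peak_amplitude_uV = 120),
                             seed = 22, record_s = 150)
  fs <- extractFeatures(short$pre, as.list(short$annotations[1, ]))
  expect_true(is.na(fs$background_score))
  expect_false(is.na(fs$peak_amplitude_uV))
  expect_match(attr(fs, "errors")[["background"]], "insufficient")
})
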