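test_that("preprocessing resamples to 32 Hz with anti-alias attenuation", {
  m <- neonatalMontage(256)
  rec <- generateBackground(backgroundSpec(1), 60, m, seed = 1)
  prep <- preprocessRecord(rec)
  expect_equal(samplingRate(prep$record), 32)
  expect_equal(nrow(signalMatrix(prep$record)), 1920)
  # 14 Hz tone (above the 12.8 Hz cutoff) attenuated by >= 20 dB
  fs <- 256
  t <- seq_len(fs * 60) / fs
  tone <- EEGRecord(matrix(rep(50 * sin(2 * pi * 14 * t), 8), ncol = 8),
                    fs, m$channels)
  out <- preprocessRecord(tone)
  p_in <- mean(signalMatrix(tone)[, 1]^2)
  p_out <- mean(signalMatrix(out$record)[, 1]^2)
  expect_lt(10 * log10(p_out / p_in), -20)
  # 250 Hz input also lands exactly on the working rate
  rec250 <- generateBackground(backgroundSpec(1), 60, neonatalMontage(250),
                               seed = 2)
  expect_equal(nrow(signalMatrix(preprocessRecord(rec250)$record)), 1920)
  bad <- EEGRecord(matrix(0, 100, 8), 100, m$channels)
  expect_error(preprocessRecord(bad), "unsupported")
})

test_that("epoch grid has floor((T-8)/4)+1 epochs for varied lengths", {
  m <- neonatalMontage(256)
  for (T in c(8, 20, 61, 137)) {
    rec <- generateBackground(backgroundSpec(1), T, m, seed = 1)
    prep <- preprocessRecord(rec)
    expect_equal(length(prep$epochStarts), floor((T - 8) / 4) + 1)
  }
})

test_that("epoch features behave on analytic inputs", {
  fs <- 32
  zero <- singleEpochFeatures <- neoseize:::singleEpochFeatures
  f0 <- zero(numeric(256), fs)
  expect_equal(unname(f0[c("rms", "variance", "total_power")]), c(0, 0, 0))
  t <- seq_len(256) / fs
  f1 <- zero(3 * sin(2 * pi * 4 * t), fs)
  expect_equal(unname(f1["rms"]), 3 / sqrt(2), tolerance = 0.01)
  expect_equal(unname(f1["peak_frequency"]), 4, tolerance = 0.2)
  set.seed(2)
  fn <- zero(runif(256, -1, 1), fs)
  fc <- zero(sin(2 * pi * 1 * t), fs)
  expect_gt(fn["shannon_entropy"], fc["shannon_entropy"])
  expect_gt(fn["spectral_entropy"], fc["spectral_entropy"])
  expect_gt(fn["spectral_edge"], fc["spectral_edge"])
})

test_that("artifact epochs are masked out of the feature matrix", {
  m <- neonatalMontage(256)
  rec <- generateBackground(backgroundSpec(1), 60, m, seed = 3)
  sig <- signalMatrix(rec)
  sig[(20 * 256):(28 * 256), ] <- sig[(20 * 256):(28 * 256), ] + 1500
  prep <- preprocessRecord(EEGRecord(sig, 256, m$channels))
  ef <- epochFeatures(prep, energyThreshold = quantile(prep$energy, 0.9))
  expect_true(any(ef$masked))
  expect_true(all(is.na(ef$features[ef$masked, ])))
  expect_true(all(is.finite(ef$features[!ef$masked, ])))
})

test_that("training rejects degenerate sets and is seed-deterministic", {
  fx <- detectorFixture()
  expect_error(trainDetector(fx$records[1:2],
                             list(data.frame(), data.frame())),
               "empty annotation")
  bg <- generateBackground(backgroundSpec(1), 120, seed = 4)
  expect_error(
    trainDetector(list(bg),
                  list(data.frame(onset_s = 0, duration_s = 120))),
    "single class")
  m1 <- trainDetector(fx$records[1:2], fx$annotations[1:2], seed = 11)
  m2 <- trainDetector(fx$records[1:2], fx$annotations[1:2], seed = 11)
  expect_identical(m1@svm$coefs, m2@svm$coefs)
  expect_identical(m1@svm$probA, m2@svm$probA)
})

test_that("held-out epoch classification is accurate (AUC > 0.9)", {
  # per-record AUC: pooling across records mixes per-record operating
  # points (e.g. burst-suppression background vs low-amplitude seizures)
  # and no longer measures epoch discrimination
  fx <- detectorFixture()
  aucs <- vapply(7:12, function(i) {
    tr <- probabilityTrace(fx$records[[i]], fx$model)
    lab <- neoseize:::labelEpochs(tr$starts, fx$annotations[[i]])
    as.numeric(pROC::auc(pROC::roc(lab, apply(tr$prob, 1, max),
                                   quiet = TRUE)))
  }, numeric(1))
  expect_gt(mean(aucs), 0.9)
  expect_true(all(aucs > 0.8))
})

test_that("probability traces are proper probabilities and smoothing is sane", {
  fx <- detectorFixture()
  tr <- probabilityTrace(fx$records[[7]], fx$model)
  expect_true(all(tr$prob >= 0 & tr$prob <= 1))
  expect_true(all(tr$smoothed >= 0 & tr$smoothed <= 1))
  expect_equal(dim(tr$smoothed), dim(tr$prob))
  expect_equal(neoseize:::movingAverage(c(0.2, 0.9, 0.4), 1),
               c(0.2, 0.9, 0.4))
  expect_equal(neoseize:::movingAverage(rep(0.5, 20), 15), rep(0.5, 20))
})

test_that("event extraction thresholds, merges and stays monotone", {
  mkTrace <- function(p) list(maxProb = p,
                              maxChannel = rep(1L, length(p)),
                              starts = (seq_along(p) - 1) * 4,
                              channelLabels = "F4-C4",
                              epoch_s = 8, hop_s = 4)
  expect_equal(nrow(detectEvents(mkTrace(rep(0.99, 10)), 1.0)), 0)
  ev <- detectEvents(mkTrace(rep(0.5, 10)), 0.3)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$onset_s, 0)
  expect_equal(ev$duration_s, 9 * 4 + 8)
  expect_error(detectEvents(mkTrace(rep(0.5, 10)), 0.35), "0.1")
  coveredTime <- function(ev) sum(ev$duration_s)
  set.seed(42)
  for (rep in 1:20) {
    p <- pmin(1, pmax(0, cumsum(rnorm(100, 0, 0.15)) * 0.2 + 0.4))
    tr <- mkTrace(p)
    cov <- vapply(seq(0.1, 0.9, by = 0.2), function(th)
      coveredTime(detectEvents(tr, round(th, 1))), numeric(1))
    expect_true(all(diff(cov) <= 1e-9))
  }
})

test_that("pure background yields almost no detections at theta >= 0.5", {
  fx <- detectorFixture()
  hours <- 0
  fds <- 0
  for (k in 1:5) {
    bg <- generateBackground(backgroundSpec(1), 3600, seed = 600 + k)
    tr <- probabilityTrace(bg, fx$model)
    ev <- detectEvents(tr, 0.5)
    fds <- fds + nrow(ev)
    hours <- hours + 1
  }
  expect_lt(fds / hours, 1)
})
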