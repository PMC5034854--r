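# envelope in moving-RMS terms, averaged across channels
recordEnvelope <- function(rec, win_s = 0.5) {
  sig <- signalMatrix(rec)
  fs <- samplingRate(rec)
  k <- round(win_s * fs)
  sq <- apply(sig^2, 2, function(x)
    as.numeric(stats::filter(x, rep(1 / k, k), sides = 2)))
  rowMeans(sqrt(sq), na.rm = TRUE)
}

suppressedRuns <- function(env, fs, thr = 5) {
  ok <- !is.na(env)
  r <- rle(env[ok] < thr)
  r$lengths[r$values] / fs
}

test_that("grade 1 background is continuous (no suppression over 2 s)", {
  rec <- generateBackground(backgroundSpec(1), 60, seed = 11)
  runs <- suppressedRuns(recordEnvelope(rec), samplingRate(rec))
  expect_true(length(runs) == 0 || max(runs) < 2)
})

test_that("grades 2-4 produce inter-burst intervals in the grade's range", {
  m <- neonatalMontage()
  for (grade in 2:4) {
    rec <- generateBackground(backgroundSpec(grade), 420, m, seed = grade)
    ibis <- suppressedRuns(recordEnvelope(rec), m$samplingRate)
    ibis <- ibis[ibis >= 2]
    expect_gt(length(ibis), 0)
    med <- median(ibis)
    if (grade == 2) expect_lt(med, 10)
    if (grade == 3) expect_true(med >= 10 && med <= 60)
    if (grade == 4) expect_gt(med, 60)
  }
})

test_that("grade 4 inter-burst amplitude stays below 10 uV", {
  rec <- generateBackground(backgroundSpec(4), 420, seed = 9)
  env <- recordEnvelope(rec)
  supp <- env[!is.na(env) & env < 5]
  # peak amplitude of near-Gaussian activity ~ 2.8 x RMS envelope
  expect_lt(quantile(supp, 0.95) * 2.8, 10)
})

test_that("background generation is deterministic and band-limited", {
  a <- generateBackground(backgroundSpec(1), 30, seed = 4)
  b <- generateBackground(backgroundSpec(1), 30, seed = 4)
  expect_identical(signalMatrix(a), signalMatrix(b))
  # no power above the 70 Hz acquisition bandwidth (Hann window keeps
  # truncation leakage out of the measurement)
  x <- signalMatrix(a)[, 1]
  w <- 0.5 - 0.5 * cos(2 * pi * seq_along(x) / (length(x) + 1))
  sp <- Mod(fft(x * w))^2
  f <- (seq_along(sp) - 1) * samplingRate(a) / length(sp)
  hi <- sum(sp[f > 75 & f < 125])
  expect_lt(hi / sum(sp[f > 0.1 & f < 125]), 1e-6)
  expect_error(generateBackground(backgroundSpec(1), -5, seed = 1),
               "duration")
})
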