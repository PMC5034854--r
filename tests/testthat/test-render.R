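test_that("rendered envelope peaks mid-seizure at the specified amplitude", {
  sp <- seizureSpec(0, 90, peak_amplitude_uV = 100, freq_start = 2,
                    freq_mid = 2, freq_end = 2, channels_onset = 1,
                    channels_peak = 1, rhythmicity_jitter = 0)
  w <- renderSeizure(sp, seed = 2)
  fs <- w$fs
  mid <- w$waveform[(40 * fs):(50 * fs), w$lead_channel]
  expect_lt(abs(diff(range(mid)) - 100), 10)
  # edges are well below the peak
  edge <- w$waveform[seq_len(5 * fs), w$lead_channel]
  expect_lt(diff(range(edge)), 0.6 * diff(range(mid)))
})

test_that("channel involvement matches the ground truth at onset and mid-seizure", {
  sp <- seizureSpec(0, 90, peak_amplitude_uV = 120, channels_onset = 1,
                    channels_peak = 5)
  w <- renderSeizure(sp, seed = 7)
  fs <- w$fs
  active <- function(i0, i1) sum(apply(w$waveform[i0:i1, ], 2,
                                       function(x) any(x != 0)))
  expect_equal(active(1, 10 * fs - 1), 1)
  expect_equal(active(round(35 * fs), round(55 * fs)), 5)
  expect_length(w$onset_channels, 1)
  expect_length(w$peak_channels, 5)
})

test_that("dominant frequency follows the start-mid-end sweep", {
  sp <- seizureSpec(0, 100, freq_start = 2, freq_mid = 1.5, freq_end = 1,
                    peak_amplitude_uV = 100, channels_onset = 2,
                    channels_peak = 2, rhythmicity_jitter = 0.02)
  w <- renderSeizure(sp, seed = 5)
  fs <- w$fs
  # periodogram argmax oracle per 5 s window
  pgPeak <- function(x) {
    nfft <- 2^18
    sp <- Mod(fft(c(x - mean(x), numeric(nfft - length(x)))))^2
    f <- (seq_len(nfft / 2) - 1) * fs / nfft
    sel <- f >= 0.3 & f <= 15
    f[sel][which.max(sp[seq_len(nfft / 2)][sel])]
  }
  x <- w$waveform[, w$lead_channel]
  checks <- list(c(0, 5, 2), c(47.5, 52.5, 1.5), c(95, 100, 1))
  for (ck in checks) {
    seg <- x[(round(ck[1] * fs) + 1):round(ck[2] * fs)]
    expect_lt(abs(pgPeak(seg) - ck[3]), 0.25)
  }
})

test_that("renders are deterministic and identity effects reproduce them", {
  sp <- seizureSpec(0, 40, peak_amplitude_uV = 80)
  a <- renderSeizure(sp, seed = 9)
  b <- renderSeizure(sp, seed = 9)
  expect_identical(a$waveform, b$waveform)
  post <- applyDrugEffect(sp, drugEffect(1, 0))
  expect_identical(renderSeizure(post, seed = 9)$waveform, a$waveform)
  scaled <- applyDrugEffect(sp, drugEffect(0.5, 0))
  expect_equal(renderSeizure(scaled, seed = 9)$waveform, a$waveform / 2)
})

test_that("subject records reject overlapping seizures", {
  s1 <- seizureSpec(30, 60)
  s2 <- seizureSpec(50, 60)
  sim <- structure(list(subject_id = "x", background = backgroundSpec(1),
                        pre_seizures = list(s1, s2), post_seizures = list(),
                        drug_effect = drugEffect(),
                        record_s = c(pre = 200, post = 200), rng_seed = 1L),
                   class = "subjectSim")
  expect_error(generateSubject(sim), "overlap")
})
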