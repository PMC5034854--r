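# shared builders for synthetic fixtures; everything is generated in code

toneRecord <- function(freq, amp = 50, duration_s = 30, channel = 3L,
                       montage = neonatalMontage()) {
  fs <- montage$samplingRate
  t <- (seq_len(fs * duration_s)) / fs
  sig <- matrix(0, length(t), 8L)
  sig[, channel] <- amp * sin(2 * pi * freq * t)
  EEGRecord(sig, fs, montage$channels)
}

# one-seizure subject with grade-1 background and enough seizure-free
# signal for background grading
oneSeizureSubject <- function(spec, seed = 3L, record_s = 520,
                              effect = drugEffect(1, 0),
                              background = backgroundSpec(1)) {
  post <- applyDrugEffect(spec, effect)
  sim <- structure(list(subject_id = "t1", background = background,
                        pre_seizures = list(spec),
                        post_seizures = list(post),
                        drug_effect = effect,
                        record_s = c(pre = record_s, post = record_s),
                        rng_seed = as.integer(seed)),
                   class = "subjectSim")
  generateSubject(sim, neonatalMontage())
}

# small rendered cohort reused by the detector tests (train + test halves)
detectorFixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    co <- generateCohort(6, drugEffect(1, 0), seed = 5, count_mean = 3,
                         record_s = 600, render = "records")
    recs <- unlist(lapply(co$records, function(r) list(r$pre, r$post)),
                   recursive = FALSE)
    anns <- unlist(lapply(co$records, function(r) {
      a <- r$annotations
      list(a[a$period == "pre", ], a[a$period == "post", ])
    }), recursive = FALSE)
    model <- trainDetector(recs[1:6], anns[1:6], seed = 3)
    cache <<- list(records = recs, annotations = anns, model = model)
    cache
  }
})

# independent signed-rank oracle: brute-force enumeration of sign
# assignments on the ranked absolute differences
bruteForceSignedRank <- function(pre, post) {
  d <- pre - post
  d <- d[d != 0]
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  n <- length(d)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Ws <- as.numeric(signs %*% r)
  mu <- n * (n + 1) / 4
  list(W = W, p = mean(abs(Ws - mu) >= abs(W - mu) - 1e-9))
}
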