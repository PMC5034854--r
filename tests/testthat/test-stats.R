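test_that("seizure-count matching truncates to the smaller period", {
  pre <- data.frame(onset_s = seq(0, 400, by = 100))
  post <- data.frame(onset_s = seq(0, 1900, by = 100))
  mp <- matchCounts(pre, post)
  expect_equal(mp$k, 5)
  expect_equal(nrow(mp$post), 5)
  expect_equal(mp$post$onset_s, pre$onset_s)
  same <- matchCounts(data.frame(onset_s = 1:7), data.frame(onset_s = 1:7))
  expect_equal(same$k, 7)
  expect_error(matchCounts(data.frame(), data.frame(onset_s = 1)),
               "inclusion")
})

test_that("per-subject summaries use the variable's fixed reducer", {
  expect_equal(summariseSeizures(c(40, 60), "peak_amplitude_uV")$value, 50)
  expect_equal(summariseSeizures(c(1, 3, 2), "rhythmicity_score")$value, 3)
  expect_equal(summariseSeizures(c(3, 4, 4, 4), "channels_peak")$value, 4)
  expect_equal(summariseSeizures(c(3, 4, 4, 5), "channels_peak")$value, 4)
  expect_equal(summariseSeizures(c(3, 4), "channels_peak")$value, 3.5)
  expect_equal(summariseSeizures(c(TRUE, FALSE, TRUE, TRUE),
                                 "morphology_changed")$value, 0.75)
  expect_error(summariseSeizures(1:3, "no_such_variable"), "unknown")
  # brute-force median oracle on random vectors
  set.seed(3)
  for (rep in 1:20) {
    x <- sample(1:8, sample(1:9, 1), replace = TRUE)
    xs <- sort(x)
    n <- length(xs)
    oracle <- if (n %% 2 == 1) xs[(n + 1) / 2]
              else (xs[n / 2] + xs[n / 2 + 1]) / 2
    expect_equal(summariseSeizures(x, "channels_peak")$value, oracle)
  }
})

test_that("weighted-average percentile interpolates at (n+1)p", {
  expect_equal(percentileWA(c(1, 2, 3, 10), 0.5), 2.5)
  # p = 0.5 always equals the median
  set.seed(11)
  for (rep in 1:30) {
    x <- rnorm(sample(2:25, 1))
    expect_equal(percentileWA(x, 0.5), median(x))
  }
  expect_error(percentileWA(numeric(0), 0.5), "non-empty")
  expect_error(percentileWA(1:3, 1.2), "0, 1")
})

test_that("signed-rank test matches base R and the enumeration oracle", {
  set.seed(5)
  for (rep in 1:15) {
    n <- 8
    pre <- rnorm(n); post <- rnorm(n)
    ours <- wilcoxonSignedRank(pre, post)
    base_p <- wilcox.test(pre, post, paired = TRUE, exact = FALSE,
                          correct = FALSE)$p.value
    expect_equal(ours$p.value, base_p, tolerance = 1e-10)
    oracle <- bruteForceSignedRank(pre, post)
    expect_equal(ours$W, oracle$W)
    exact <- wilcoxonSignedRank(pre, post, exact = TRUE)
    expect_equal(exact$p.value, oracle$p)
  }
  expect_error(wilcoxonSignedRank(c(1, 2, 3), c(1, 2, 3)),
               class = "degenerateComparison")
})

test_that("asymptotic p agrees with enumeration up to the null granularity", {
  # the normal approximation cannot be closer to the exact p than the
  # discreteness of the signed-rank null allows: compare against the
  # largest point mass of |W - mu| under enumeration
  set.seed(9)
  for (n in c(10, 12, 16)) {
    for (rep in 1:5) {
      pre <- rnorm(n, mean = 0.4); post <- rnorm(n)
      a <- wilcoxonSignedRank(pre, post)
      e <- wilcoxonSignedRank(pre, post, exact = TRUE)
      expect_equal(a$W, e$W)
      d <- pre - post; d <- d[d != 0]; r <- rank(abs(d))
      signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
      Ws <- as.numeric(signs %*% r)
      mu <- length(d) * (length(d) + 1) / 4
      granularity <- max(table(round(abs(Ws - mu), 6))) / length(Ws)
      expect_lt(abs(a$p.value - e$p.value), granularity + 1e-9)
    }
  }
})

test_that("cohort comparison flags only real differences", {
  set.seed(13)
  subj <- sprintf("s%02d", 1:12)
  pre <- rlnorm(12, log(120), 0.4)
  sm <- rbind(
    data.frame(subject = subj, period = "pre",
               variable = "peak_amplitude_uV", value = pre),
    data.frame(subject = subj, period = "post",
               variable = "peak_amplitude_uV", value = pre * 0.4),
    data.frame(subject = subj, period = "pre",
               variable = "duration_s", value = 100 + rnorm(12)),
    data.frame(subject = subj, period = "post",
               variable = "duration_s", value = 100 + rnorm(12)))
  cmp <- compareCohort(sm)
  amp <- cmp[cmp$variable == "peak_amplitude_uV", ]
  expect_true(amp$significant)
  expect_equal(amp$pre_median, median(pre))
  # identical periods: degenerate comparison, never flagged
  sm2 <- rbind(
    data.frame(subject = subj, period = "pre", variable = "x", value = 1:12),
    data.frame(subject = subj, period = "post", variable = "x", value = 1:12))
  cmp2 <- compareCohort(sm2)
  expect_false(cmp2$significant)
  expect_equal(cmp2$p_value, 1)
  # mismatched subjects rejected
  bad <- sm[sm$subject != "s01" | sm$period != "post", ]
  expect_error(compareCohort(bad), "both periods")
})

test_that("change counts treat ties as not reduced", {
  cc <- perSubjectChangeCounts(c(5, 5, 7), c(4, 5, 8))
  expect_equal(cc$n_reduced, 1)
  expect_equal(cc$n_total, 3)
  expect_equal(perSubjectChangeCounts(1:4, 1:4)$n_reduced, 0)
})
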