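test_that("tap cleaning applies the 30-ms rule greedily", {
  expect_equal(cleanExtraTaps(c(0, 0.020, 0.375)), c(0, 0.375))
  expect_equal(cleanExtraTaps(numeric(0)), numeric(0))
  # sequential rule: 0.029 dropped, 0.058 kept relative to the retained 0
  expect_equal(cleanExtraTaps(c(0, 0.029, 0.058)), c(0, 0.058))

  set.seed(1)
  taps <- sort(runif(200, 0, 22.5))
  cleaned <- cleanExtraTaps(taps)
  expect_true(all(diff(cleaned) >= 0.030))
})

test_that("asynchrony correction removes the mean lead and flags outliers", {
  tones <- seq(0, by = 0.375, length.out = 10)
  ac <- asynchronyCorrect(tones - 0.030, tones)
  expect_equal(ac$meanAsynchrony, -0.030)
  expect_equal(ac$onsets, tones)
  expect_false(any(ac$excluded))

  taps <- c(tones[1:9] - 0.030, tones[10] + 0.170)
  ac2 <- asynchronyCorrect(taps, tones, meanAsynchrony = -0.030)
  expect_true(ac2$excluded[10])
  expect_equal(sum(ac2$excluded), 1)

  expect_equal(asynchronyCorrect(c(0.1, 0.3), c(0.14, 0.32))$meanAsynchrony,
               mean(c(-0.04, -0.02)))
})

test_that("ITI ratios follow tone-tap matching with cycle-wise exclusion", {
  cond <- fixtureConditions()
  sq <- buildSequence(cond[1, ], nCycles = 30)      # r = 0.5
  perfect <- c(eventTimes(sq), 22.5)
  res <- itiRatios(perfect, sq)
  expect_equal(res$nValid, 30)
  expect_equal(res$perCycle$ratio, rep(0.5, 30))
  expect_equal(res$meanRatio, 0.5)

  sq3 <- buildSequence(2/3, nCycles = 1, patternDur = 0.75)
  one <- itiRatios(c(0, 0.50, 0.75), sq3)
  expect_equal(one$meanRatio, 0.5 / 0.75)

  # missing middle tap: that cycle excluded, neighbors unaffected
  sq5 <- buildSequence(0.6, nCycles = 5, patternDur = 0.75)
  taps <- c(eventTimes(sq5), 5 * 0.75)
  taps <- taps[abs(taps - eventTimes(sq5)[6]) > 1e-9]  # drop cycle 3's 2nd tap
  res5 <- itiRatios(taps, sq5)
  expect_equal(res5$perCycle$excluded_reason[3], "unmatched_tone")
  expect_true(is.na(res5$perCycle$ratio[3]))
  expect_equal(res5$perCycle$ratio[-3], rep(0.6, 4))

  # invariance to a constant offset on all taps (post-correction shift)
  shifted <- itiRatios(perfect + 0.010, sq)
  expect_equal(shifted$perCycle$ratio, res$perCycle$ratio)
})

test_that("noiseless tapping reproduces the stimulus ratio in every condition", {
  cond <- fixtureConditions()
  for (i in c(1, 7, 13)) {
    sq <- buildSequence(cond[i, ], nCycles = 30)
    taps <- c(eventTimes(sq), 22.5)
    expect_equal(itiRatios(taps, sq)$meanRatio, cond$r[i], tolerance = 1e-12)
  }
})

test_that("sigmoid vs linear comparison behaves at both extremes", {
  cond <- fixtureConditions()
  x <- rep(cond$r, times = 6)
  grp <- rep(1:6, each = 13)

  # perfectly linear data: linear fit is exact, sigmoid does not win
  y <- x
  fit <- fitResponseCurves(x, y + rnorm(length(y), 0, 1e-4), grp)
  expect_gt(fit$linear$r2, 0.999)
  expect_gt(fit$comparisonP, 0.05)

  # step-like data: sigmoid wins the cross-validated comparison
  set.seed(8)
  ystep <- ifelse(x < 0.5625, 0.53, 0.63) + rnorm(length(x), 0, 0.004)
  fit2 <- fitResponseCurves(x, ystep, grp)
  expect_lt(fit2$comparisonP, 0.05)
  expect_gt(mean(fit2$sigmoid$cvR2), mean(fit2$linear$cvR2))
  expect_lt(abs(fit2$threshold - 0.5625), 0.01)
})

test_that("per-participant sigmoid fits recover a known threshold", {
  cond <- fixtureConditions()
  y <- 0.5 + (0.667 - 0.5) / (1 + exp(-60 * (cond$r - 0.56)))
  fit <- fitSigmoidParticipant(cond$r, y)
  expect_lt(abs(fit$threshold - 0.56), 0.005)
})

test_that("chi-square uniformity test uses 13 bins with df = 12", {
  cond <- fixtureConditions()
  centers <- cond$r
  uniform <- rep(centers, 10)
  res <- chi2Uniformity(uniform)
  expect_equal(res$chi2, 0)
  expect_equal(res$df, 12)
  expect_equal(res$p, 1)

  onebin <- rep(0.51, 130)
  res2 <- chi2Uniformity(onebin)
  # hand-computed: (130-10)^2/10 + 12 * (0-10)^2/10
  expect_equal(res2$chi2, 120^2 / 10 + 12 * 100 / 10)
  # out-of-range ratios count toward the nearest edge bin
  res3 <- chi2Uniformity(c(0.4, 0.9))
  expect_equal(res3$counts[1], 1)
  expect_equal(res3$counts[13], 1)
  expect_error(chi2Uniformity(numeric(0)), "ratios")
})

test_that("tap logs round-trip and feed the participant pipeline", {
  cond <- fixtureConditions()
  spec <- simulationSpec(warpStrength = 0, timingSd = 0, missRate = 0,
                         extraRate = 0, asynchronyMean = -0.03)
  taps <- simulateTapParticipant(spec, 1)
  path <- withr::local_tempfile(fileext = ".csv")
  writeTapLog(taps, path)
  back <- readTapLog(path)
  expect_equal(back$onset_s, taps$onset_s, tolerance = 1e-9)

  res <- participantITI(back, cond)
  expect_equal(res$meanAsynchrony, -0.03, tolerance = 1e-9)
  expect_equal(res$meanRatios, cond$r, tolerance = 1e-9)
})
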