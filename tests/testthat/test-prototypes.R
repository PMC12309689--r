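test_that("prototype sets span the ratio grid with analytic fingerprints", {
  set <- buildPrototypeSet()
  expect_length(set@ratios, 76)
  expect_equal(range(set@ratios), c(0.50, 0.84))
  expect_equal(ncol(set@magnitudes), 12)   # harmonics up to 16 Hz

  # isochronous template: zero magnitude at odd harmonics (period halves)
  small <- buildPrototypeSet(n = 5, rMin = 0.5, rMax = 0.84, fMaxHz = 8)
  odd <- small@frequencySet@harmonics %% 2 == 1
  expect_lt(max(small@magnitudes[1, odd]), 1e-12)
  expect_gt(min(small@magnitudes[1, !odd]), 0.001)

  expect_error(buildPrototypeSet(fs = 255), "integer number of samples")
})

test_that("fingerprints are invariant to circular time shifts", {
  fs <- 256; P <- 192; nCyc <- 10
  r <- 0.6
  d <- round(r * P)
  on1 <- as.vector(outer(c(0, d), (0:(nCyc - 1)) * P, "+")) / fs
  shift <- P / 2
  on2 <- ((as.vector(outer(c(0, d), (0:(nCyc - 1)) * P, "+")) + shift) %%
            (P * nCyc)) / fs
  fois <- harmonicFrequencies(0.75, 16, fs / (P * nCyc))
  m1 <- magnitudeSpectrum(fftSpectrum(impulseTrain(on1, fs, nCyc * 0.75)))[1, fois@bins]
  m2 <- magnitudeSpectrum(fftSpectrum(impulseTrain(sort(on2), fs, nCyc * 0.75)))[1, fois@bins]
  expect_equal(m1, m2, tolerance = 1e-12)
})

test_that("bootstrap distributions concentrate on the generating template", {
  set <- buildPrototypeSet(n = 39, rMin = 0.5, rMax = 0.84, fMaxHz = 16)

  # all participants exactly on one template: degenerate distribution
  target <- set@ratios[20]
  arr <- fingerprintArray(set, rep(set@realizedRatios[20], 3), 4)
  dist <- bootstrapBestPrototype(arr, set, nBoot = 50, seed = 1)
  expect_true(all(dist@bestRatios == target))

  # two identical participants: every resample is the same pool, so the
  # distribution is degenerate at one template per condition
  arr2 <- arr[, , 1:2, drop = FALSE]
  arr2[, , 2] <- arr2[, , 1]
  dist2 <- bootstrapBestPrototype(arr2, set, nBoot = 30, seed = 2)
  expect_equal(length(unique(as.vector(dist2@bestRatios))), 1)

  # noisy participants near 0.63: mode lands on the nearest grid template
  nearest <- set@ratios[which.min(abs(set@ratios - 0.63))]
  hits <- vapply(1:10, function(s) {
    arrN <- fingerprintArray(set, rep(0.63, 2), 12, noiseSd = 0.3, seed = s)
    d <- bootstrapBestPrototype(arrN, set, nBoot = 100, seed = s)
    md <- as.numeric(names(which.max(table(d@bestRatios))))
    abs(md - nearest) <= diff(set@ratios[1:2]) + 1e-9
  }, logical(1))
  expect_gte(sum(hits), 9)
})

test_that("in-out window index follows the width-weighted formula", {
  idx <- rhythmRSA:::.inOutIndex(c(rep(0.515, 800), rep(0.7, 200)),
                                 lo = 0.51, hi = 0.51 + 0.0139,
                                 widthIn = 0.0139, widthOut = 0.3261)
  expect_equal(idx, 800 / 0.0139 - 200 / 0.3261)
})

test_that("on-stimulus window test separates concentrated from displaced responses", {
  cond <- fixtureConditions()
  set <- buildPrototypeSet(n = 39, fMaxHz = 16)

  # responses concentrated on the stimulus ratio: index positive in all runs
  onArr <- fingerprintArray(set, cond$r, 8, noiseSd = 0.05, seed = 3)
  on <- onStimulusTest(onArr, set, conditionIndex = 7, conditions = cond,
                       nBoot = 150, nOuter = 300, seed = 4)
  expect_true(all(on$indexSamples > 0))
  expect_false(on$offStimulus)
  expect_equal(on$widthIn + on$widthOut, 0.34, tolerance = 1e-9)

  # responses displaced to 0.75: off-stimulus flagged
  offArr <- fingerprintArray(set, rep(0.75, 13), 8, noiseSd = 0.05, seed = 5)
  off <- onStimulusTest(offArr, set, conditionIndex = 7, conditions = cond,
                        nBoot = 150, nOuter = 300, seed = 6)
  expect_true(all(off$indexSamples < 0))
  expect_true(off$offStimulus)
})

test_that("pooled peak detection finds constructed density modes", {
  cond <- fixtureConditions()
  set <- buildPrototypeSet(n = 39, fMaxHz = 16)

  # single attractor at 0.63 for the big category, 0.53 for the small one
  ratios <- ifelse(cond$index <= 5, 0.53, 0.63)
  arr <- fingerprintArray(set, ratios, 10, noiseSd = 0.15, seed = 7)
  peaks <- pooledPeaks(arr, set, boundaryAfter = 5, conditions = cond,
                       nBoot = 150, nOuter = 300, seed = 8)
  sigBig <- peaks[peaks$category == "big" & peaks$pBonf < 0.05, ]
  expect_equal(nrow(sigBig), 1)
  expect_lt(abs(sigBig$peak - 0.63), 0.02)
  sigSmall <- peaks[peaks$category == "small" & peaks$pBonf < 0.05, ]
  expect_equal(nrow(sigSmall), 1)
  expect_lt(abs(sigSmall$peak - 0.53), 0.02)

  # two well-separated attractors inside one category: two significant peaks
  ratios2 <- rep(0.52, 13)
  ratios2[6:9] <- 0.60; ratios2[10:13] <- 0.78
  arr2 <- fingerprintArray(set, ratios2, 10, noiseSd = 0.1, seed = 9)
  peaks2 <- pooledPeaks(arr2, set, boundaryAfter = 5, conditions = cond,
                        nBoot = 150, nOuter = 300, seed = 10)
  sig2 <- peaks2[peaks2$category == "big" & peaks2$pBonf < 0.05, ]
  expect_equal(nrow(sig2), 2)
  expect_equal(sort(round(sig2$peak, 1)), c(0.6, 0.8), tolerance = 0.05)

  # flat (uniform) samples carry no density excess: the width-weighted
  # window-vs-flank index is centred on zero wherever the window sits
  set.seed(11)
  u <- runif(5000, 0.5, 0.84)
  step <- diff(cond$r[1:2])
  idxs <- vapply(seq(0.55, 0.79, by = 0.03), function(center)
    rhythmRSA:::.inOutIndexFlanks(u, center, step), numeric(1))
  # counts in window ~ 5000 * step / 0.34 ~ 200; index scale = count / step
  expect_lt(max(abs(idxs)) * step, 3 * sqrt(2 * 5000 * step / 0.34))
})

test_that("peak positions are stable across seeds for well-separated modes", {
  cond <- fixtureConditions()
  set <- buildPrototypeSet(n = 39, fMaxHz = 16)
  ratios <- ifelse(cond$index <= 5, 0.53, 0.63)
  arr <- fingerprintArray(set, ratios, 10, noiseSd = 0.15, seed = 13)
  step <- diff(set@ratios[1:2])
  pks <- vapply(1:3, function(s) {
    p <- pooledPeaks(arr, set, boundaryAfter = 5, conditions = cond,
                     nBoot = 120, nOuter = 10, seed = 100 + s)
    p$peak[p$category == "big"][which.max(p$index[p$category == "big"])]
  }, numeric(1))
  expect_lt(max(pks) - min(pks), step + 1e-9)
})

test_that("prototype distributions export as long CSV", {
  set <- buildPrototypeSet(n = 10, fMaxHz = 16)
  arr <- fingerprintArray(set, c(0.55, 0.65), 3)
  dist <- bootstrapBestPrototype(arr, set, nBoot = 20, seed = 1,
                                 conditionRatios = c(0.55, 0.65))
  path <- withr::local_tempfile(fileext = ".csv")
  writePrototypeDistribution(dist, path)
  back <- read.csv(path)
  expect_equal(nrow(back), 40)
  # membership up to text round-trip precision
  expect_lt(max(vapply(back$best_ratio, function(v)
    min(abs(v - set@ratios)), numeric(1))), 1e-9)
})
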