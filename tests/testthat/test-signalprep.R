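test_that("zero-phase Butterworth filtering matches the analytic response", {
  fs <- 256
  t <- (0:(fs * 30 - 1)) / fs
  dc <- new("ContinuousRecording", samples = matrix(1, 1, fs * 30), fs = fs,
            channelLabels = "dc", t0 = 0)
  dcOut <- samples(butterworthFilter(dc, "low", 4, 10))[1, ]
  mid <- (2 * fs):(28 * fs)           # away from filter edge transients
  expect_equal(dcOut[mid], rep(1, length(mid)), tolerance = 1e-6)

  ampAt <- function(f) {
    rec <- sineRecording(f, 1, fs = fs, dur = 30)
    y <- samples(butterworthFilter(rec, "low", 4, 10))[1, ]
    mid <- (5 * fs):(25 * fs)
    2 * abs(mean(y[mid] * exp(-2i * pi * f * t[mid])))
  }
  # two passes square the order-4 magnitude response: 1 / (1 + (f/fc)^8)
  expect_lt(abs(ampAt(20) - 1 / (1 + 2^8)), 0.15 / (1 + 2^8) + 1e-4)
  expect_lt(abs(ampAt(4/3) - 1), 0.01)

  expect_error(butterworthFilter(dc, "low", 4, 128), "Nyquist")
})

test_that("epoch segmentation produces exact chunks and honors t0", {
  fs <- 256
  rec <- sineRecording(4/3, 1, fs = fs, dur = 22.5)
  e <- segmentEpochs(rec, 0, 0.75, 30)
  expect_equal(nEpochs(e), 30)
  expect_equal(dim(epochArray(e)), c(30, 1, 192))

  expect_equal(nEpochs(segmentEpochs(rec, 0, 0.75, 0)), 0)
  expect_error(segmentEpochs(rec, 0, 0.75, 31), "insufficient")

  # pooling 6 trials of 30 cycles gives the 180 epochs per condition
  total <- sum(vapply(1:6, function(i) nEpochs(segmentEpochs(rec, 0, 0.75, 30)),
                      numeric(1)))
  expect_equal(total, 180)

  # t0 bookkeeping: a recording starting before onset addresses the same data
  rec2 <- initialize(rec, t0 = -1)
  e2 <- segmentEpochs(rec2, -1, 0.75, 10)
  expect_equal(epochArray(e2)[1, 1, ], samples(rec)[1, 1:192])

  # baseline-window flag subtracts the pre-epoch mean (force-channel use)
  const <- new("ContinuousRecording",
               samples = matrix(rep(c(5, 7), c(256, 512)), 1), fs = 256,
               channelLabels = "f", t0 = -1)
  eb <- segmentEpochs(const, 0, 1, 1, baselineWindow = c(-1, 0))
  expect_equal(as.vector(epochArray(eb)[1, 1, ]), rep(2, 256))
})

test_that("epoch demeaning is exact and idempotent", {
  a <- array(0, c(2, 1, 3))
  a[1, 1, ] <- c(1, 2, 3)
  a[2, 1, ] <- 5
  e <- new("EpochSet", epochs = a, fs = 4, epochDur = 0.75,
           channelLabels = "x")
  d <- demeanEpochs(e)
  expect_equal(as.vector(epochArray(d)[1, 1, ]), c(-1, 0, 1))
  expect_equal(as.vector(epochArray(d)[2, 1, ]), c(0, 0, 0))
  expect_equal(epochArray(demeanEpochs(d)), epochArray(d))

  set.seed(3)
  r <- new("EpochSet", epochs = array(rnorm(5 * 2 * 8), c(5, 2, 8)), fs = 8,
           epochDur = 1, channelLabels = c("a", "b"))
  m <- apply(epochArray(demeanEpochs(r)), c(1, 2), mean)
  expect_true(all(abs(m) < 1e-10))
})

test_that("epoch averaging recovers periodic cycles and suppresses noise", {
  fs <- 64
  rec <- sineRecording(4/3, 1, fs = fs, dur = 7.5)   # 10 cycles of 0.75 s
  avg <- averageEpochs(segmentEpochs(rec, 0, 0.75, 10))
  expect_equal(samples(avg)[1, ], samples(rec)[1, 1:48], tolerance = 1e-12)

  x <- samples(rec)[1, 1:48]
  e <- new("EpochSet", epochs = array(rep(rbind(x, -x), 1), c(2, 1, 48)),
           fs = fs, epochDur = 0.75, channelLabels = "s")
  e@epochs[1, 1, ] <- x; e@epochs[2, 1, ] <- -x
  expect_equal(max(abs(samples(averageEpochs(e)))), 0)

  expect_error(averageEpochs(new("EpochSet", epochs = array(0, c(0, 1, 48)),
                                 fs = fs, epochDur = 0.75,
                                 channelLabels = "s")), "empty")

  # Monte-Carlo: noise SD shrinks by sqrt(n) under averaging
  set.seed(11)
  n <- 64
  noise <- array(rnorm(n * 1 * 500), c(n, 1, 500))
  es <- new("EpochSet", epochs = noise, fs = 500, epochDur = 1,
            channelLabels = "n")
  ratio <- sd(samples(averageEpochs(es))) / sd(noise)
  expect_lt(abs(ratio - 1 / sqrt(n)), 0.3 / sqrt(n))
})

test_that("decimation divides the rate and warns without a low-pass stage", {
  fs <- 1024
  rec <- sineRecording(4/3, 1, fs = fs, dur = 3)
  expect_identical(downsampleRecording(rec, 1), rec)
  filt <- butterworthFilter(rec, "low", 4, 64)
  down <- downsampleRecording(filt, 4)
  expect_equal(samplingRate(down), 256)
  expect_equal(ncol(samples(down)), ncol(samples(rec)) / 4)
  expect_warning(downsampleRecording(rec, 4), "low-pass")
  expect_error(downsampleRecording(rec, 0), "'factor'")

  short <- initialize(filt, samples = filt@samples[, 1:192, drop = FALSE])
  expect_equal(ncol(samples(downsampleRecording(short, 4))), 48)
})

test_that("impulse trains place unit samples by rounding", {
  tr <- impulseTrain(c(0, 0.375, 0.75), fs = 256, durationS = 22.5)
  x <- samples(tr)[1, ]
  expect_equal(which(x == 1), c(0, 96, 192) + 1)
  expect_equal(sum(x), 3)

  expect_equal(sum(samples(impulseTrain(numeric(0), 256, 1))), 0)
  # collision: two onsets on one sample keep the value 1
  expect_equal(sum(samples(impulseTrain(c(0.1, 0.1001), 256, 1))), 1)
  expect_error(impulseTrain(c(-0.1), 256, 1), "onsetsS")
})

test_that("segment-then-average commutes with channel selection", {
  set.seed(9)
  rec <- new("ContinuousRecording", samples = matrix(rnorm(3 * 960), 3),
             fs = 64, channelLabels = c("a", "b", "c"), t0 = 0)
  left <- averageEpochs(segmentEpochs(selectChannels(rec, "b"), 0, 0.75, 20))
  right <- selectChannels(averageEpochs(segmentEpochs(rec, 0, 0.75, 20)), "b")
  expect_equal(samples(left), samples(right))
  expect_error(selectChannels(rec, "zz"), "unknown channel")
})
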