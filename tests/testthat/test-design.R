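test_that("condition continuum is linearly spaced with exact endpoints", {
  cond <- makeConditionContinuum(13, 0.5, 2/3, 0.75)
  expect_equal(nrow(cond), 13)
  expect_equal(cond$r[1], 0.5)
  expect_equal(cond$r[13], 2/3)
  expect_equal(cond$r[7], (0.5 + 2/3) / 2)   # continuum midpoint, ~0.5833
  expect_equal(cond$ioi1_s + cond$ioi2_s, rep(0.75, 13))
  expect_equal(cond$r, cond$ioi1_s / cond$pattern_s)

  two <- makeConditionContinuum(2, 0.5, 2/3)
  expect_equal(two$r, c(0.5, 2/3))

  # ratios strictly increasing and symmetric about the grid midpoint
  expect_true(all(diff(cond$r) > 0))
  expect_equal(cond$r + rev(cond$r), rep(0.5 + 2/3, 13))
})

test_that("invalid continuum parameters are rejected by name", {
  expect_error(makeConditionContinuum(1), "'n'")
  expect_error(makeConditionContinuum(13, rStart = 0), "'rStart'")
  expect_error(makeConditionContinuum(13, rEnd = 1), "'rEnd'")
  expect_error(makeConditionContinuum(13, rStart = 0.7, rEnd = 0.6), "'rStart'")
})

test_that("sequences loop the pattern seamlessly", {
  cond <- fixtureConditions()
  sq <- buildSequence(cond[1, ], nCycles = 30)
  expect_equal(recordingDuration(sq), 22.5)
  expect_length(eventTimes(sq), 60)
  # r = 0.5: events at every multiple of 0.375 s
  expect_equal(eventTimes(sq), seq(0, by = 0.375, length.out = 60))

  one <- buildSequence(2/3, nCycles = 1, patternDur = 0.75)
  expect_equal(eventTimes(one), c(0, 0.5))

  three <- buildSequence(0.6, nCycles = 3, patternDur = 0.75)
  expect_equal(eventTimes(three), c(0, 0.45, 0.75, 1.20, 1.50, 1.95))

  expect_error(buildSequence(0.5, nCycles = 0), "'nCycles'")
})

test_that("audio rendering places ramped tones and validates inputs", {
  tone <- toneSpec(300, 0.05, 0.01)
  sq <- buildSequence(0.5, nCycles = 2, patternDur = 0.75)
  audio <- renderAudio(sq, tone, fs = 44100)
  x <- samples(audio)[1, ]
  expect_length(x, round(1.5 * 44100))
  # per-tone footprint: 0.05 s x 44100 Hz = 2205 samples
  expect_equal(sum(abs(x[1:2205]) > 0), 2205 - 1)  # first ramp sample is 0
  expect_equal(max(abs(x)), 0.9)
  # linear onset ramp: samples one carrier period apart (147 samples = 1/300 s)
  # are phase-locked, so their ratio is the envelope ratio (t + 1/300) / t
  i1 <- 185; i2 <- i1 + 147           # ~4.2 and ~7.5 ms, both on the ramp
  expect_equal(x[i2] / x[i1], (i2 - 1) / (i1 - 1), tolerance = 1e-6)
  # on the plateau the phase-locked samples are equal
  j <- 600                            # ~13.6 ms, past the 10-ms ramp
  expect_equal(x[j + 147], x[j], tolerance = 1e-9)
  # zero outside tones
  expect_equal(x[(0.06 * 44100):(0.37 * 44100)], rep(0, length((0.06 * 44100):(0.37 * 44100))))

  empty <- new("StimulusSequence", conditionIndex = NA_integer_, r = 0.5,
               patternDur = 0.75, nCycles = 0L, eventTimes = numeric(0))
  silent <- renderAudio(empty, tone, fs = 44100)
  expect_equal(samples(silent), matrix(0, 1, 0), ignore_attr = TRUE)

  expect_error(renderAudio(sq, toneSpec(300, 0.4, 0.01), fs = 44100),
               "overlap")
  expect_error(renderAudio(sq, tone, fs = 500), "undersample")
})

test_that("acoustic RSM falls off linearly and respects symmetries", {
  cond <- fixtureConditions()
  rsm <- acousticRSM(cond)
  m <- similarityMatrix(rsm)
  expect_equal(rsmKind(rsm), "one-minus-absdiff")
  expect_equal(unname(diag(m)), rep(1, 13))
  expect_equal(m[1, 13], 1 - 1/6)
  # Toeplitz with linear falloff = grid spacing per step
  step <- (2/3 - 0.5) / 12
  for (d in 1:12)
    expect_equal(unique(round(m[row(m) - col(m) == d], 12)),
                 round(1 - d * step, 12))
  # persymmetric: invariant under reversal of the condition order
  rev <- acousticRSM(cond[13:1, ])
  expect_equal(similarityMatrix(rev), m[13:1, 13:1], ignore_attr = TRUE)
})

test_that("categorical model family enumerates admissible boundaries", {
  expect_length(categoricalModelSet(13, 2), 10)
  expect_length(categoricalModelSet(4, 2), 1)
  expect_length(categoricalModelSet(5, 2), 2)
  expect_error(categoricalModelSet(3, 2), "nConditions")

  # counting law n - 2 minSpan + 1, checked exhaustively for n <= 8
  for (n in 4:8)
    expect_length(categoricalModelSet(n, 2), n - 3)

  # block structure: exactly two all-ones diagonal blocks
  for (mod in categoricalModelSet(6, 2)) {
    m <- similarityMatrix(mod)
    b <- boundaryAfter(mod)
    expect_true(all(m[1:b, 1:b] == 1))
    expect_true(all(m[(b + 1):6, (b + 1):6] == 1))
    expect_true(all(m[1:b, (b + 1):6] == 0))
    expect_equal(m, t(m))
  }
})

test_that("boundary ratios are midpoints between flanking conditions", {
  cond <- fixtureConditions()
  models <- fixtureModels()
  expect_equal(boundaryRatio(models[["5"]], cond), (cond$r[5] + cond$r[6]) / 2)
  expect_equal(round(boundaryRatio(5, cond), 4), 0.5625)
  expect_equal(round(boundaryRatio(4, cond), 4), 0.5486)
  two <- makeConditionContinuum(2, 0.5, 2/3)
  expect_equal(boundaryRatio(1, two), mean(two$r))
})

test_that("condition designs round-trip through JSON", {
  cond <- fixtureConditions()
  path <- withr::local_tempfile(fileext = ".json")
  writeDesign(cond, 30, path)
  back <- readDesign(path)
  expect_equal(back$conditions$r, cond$r)
  expect_equal(back$nCycles, 30)
})
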