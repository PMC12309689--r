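# Shared fixtures, all generated in code.

fixtureConditions <- function(n = 13) makeConditionContinuum(n = n)

fixtureModels <- function(n = 13) categoricalModelSet(n)

fixtureAcoustic <- function(n = 13) acousticRSM(fixtureConditions(n))

# A recording holding a single sinusoid (or sum of sinusoids).
sineRecording <- function(freqs, amps, fs = 256, dur = 22.5, phase = 0) {
  t <- (seq_len(round(dur * fs)) - 1) / fs
  x <- rowSums(vapply(seq_along(freqs), function(i)
    amps[i] * sin(2 * pi * freqs[i] * t + phase), numeric(length(t))))
  new("ContinuousRecording", samples = matrix(x, 1), fs = fs,
      channelLabels = "sig", t0 = 0)
}

# Band-limited periodic cycle signals whose spectral feature vectors are
# mean-zero, so the Pearson feature RSM coincides exactly with the Pearson
# time-course RSM (Plancherel identity plus vanishing feature means).
bandLimitedCycles <- function(nCond = 13, P = 192, seed = 1) {
  K <- P / 2 - 1
  t <- (seq_len(P) - 1) / P
  withr::with_seed(seed, {
    vapply(seq_len(nCond), function(i) {
      a <- stats::rnorm(K)
      b <- stats::rnorm(K)
      b[K] <- sum(a) - sum(b[-K])     # forces sum(re) + sum(im) = 0
      rowSums(vapply(seq_len(K), function(k)
        a[k] * cos(2 * pi * k * t) + b[k] * sin(2 * pi * k * t),
        numeric(P)))
    }, numeric(P))
  })
}

# Per-participant condition-mean produced ratios through the full tapping
# pipeline; returns an nParticipants x nConditions matrix.
tapStudyMeanRatios <- function(spec, nParticipants, seedBase = 1000) {
  conditions <- spec@conditions
  t(vapply(seq_len(nParticipants), function(p) {
    taps <- simulateTapParticipant(spec, seedBase + p)
    participantITI(taps, conditions, nCycles = spec@nCycles)$meanRatios
  }, numeric(nrow(conditions))))
}

# Scalar (one-minus-absdiff) RSMs from a ratio matrix.
ratioRSMs <- function(ratioMat) {
  lapply(seq_len(nrow(ratioMat)), function(p) rsmFromScalars(ratioMat[p, ]))
}

# Synthetic noise-corrected fingerprint array concentrated on one template
# ratio per condition (plus optional Gaussian noise), for prototype tests.
fingerprintArray <- function(set, condRatios, nParticipants, noiseSd = 0,
                             seed = 1) {
  k <- set@frequencySet@harmonics
  withr::with_seed(seed, {
    arr <- array(0, c(length(k), length(condRatios), nParticipants))
    for (ci in seq_along(condRatios)) {
      base <- 2 * abs(cos(pi * k * condRatios[ci]))
      for (p in seq_len(nParticipants))
        arr[, ci, p] <- base + stats::rnorm(length(k), 0, noiseSd)
    }
    arr
  })
}
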