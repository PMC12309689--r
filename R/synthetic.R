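#' Specification of a synthetic rhythm-categorization study
#'
#' Bundles the stimulus design and the generative parameters for synthetic
#' tapping and EEG-like data with known categorical ground truth. Defaults
#' are fixed at the study conditions the package targets: 13 conditions from
#' 0.50 to 2/3 (750-ms pattern, 30 cycles), 18 participants, 3 tapping / 6
#' EEG trials per condition, category boundary after condition 5 (boundary
#' ratio 0.5625) with attractors at 0.53 and 0.63, 10-ms tap jitter, -30-ms
#' mean anticipation, 2% missed and 1% extra taps, 256-Hz sampling, 64
#' channels, a gamma response kernel peaking at 100 ms, and 1/f plus
#' alpha-band noise scaled so grand-average harmonic z-scores land around
#' 5-15.
#'
#' @param conditions condition continuum (default [makeConditionContinuum()]).
#' @param nCycles cycles per trial (default 30).
#' @param boundaryAfter true category split (default 5).
#' @param protoSmall,protoBig attractor ratios (defaults 0.53, 0.63).
#' @param warpStrength attractor pull in `[0, 1]` (default 0.8).
#' @param timingSd per-tap jitter SD in seconds (default 0.010).
#' @param asynchronyMean constant tap lead in seconds (default -0.030).
#' @param missRate,extraRate tap corruption rates (defaults 0.02, 0.01).
#' @param nTrials tapping trials per condition (default 3).
#' @param nTrialsEEG EEG trials per condition (default 6).
#' @param fs sampling rate (default 256).
#' @param nChannels EEG channel count (default 64).
#' @param kernelPeak,kernelShape gamma kernel peak latency (s) and shape
#'   (defaults 0.1, 3).
#' @param noiseScale additive-noise scale (default 3).
#' @param noiseExponent 1/f exponent (default 1).
#' @param alphaPower relative 8-12-Hz noise power (default 1).
#' @param nParticipants cohort size (default 18).
#' @return a [SimulationSpec].
#' @export
simulationSpec <- function(conditions = makeConditionContinuum(),
                           nCycles = 30, boundaryAfter = 5,
                           protoSmall = 0.53, protoBig = 0.63,
                           warpStrength = 0.8, timingSd = 0.010,
                           asynchronyMean = -0.030, missRate = 0.02,
                           extraRate = 0.01, nTrials = 3, nTrialsEEG = 6,
                           fs = 256, nChannels = 64, kernelPeak = 0.1,
                           kernelShape = 3, noiseScale = 3,
                           noiseExponent = 1, alphaPower = 1,
                           nParticipants = 18) {
  new("SimulationSpec", conditions = conditions,
      nCycles = as.integer(nCycles), boundaryAfter = as.integer(boundaryAfter),
      protoSmall = protoSmall, protoBig = protoBig,
      warpStrength = warpStrength, timingSd = timingSd,
      asynchronyMean = asynchronyMean, missRate = missRate,
      extraRate = extraRate, nTrials = as.integer(nTrials),
      nTrialsEEG = as.integer(nTrialsEEG), fs = fs,
      nChannels = as.integer(nChannels), kernelPeak = kernelPeak,
      kernelShape = kernelShape, noiseScale = noiseScale,
      noiseExponent = noiseExponent, alphaPower = alphaPower,
      nParticipants = as.integer(nParticipants))
}

# Ratio actually produced in a condition: stimulus ratio pulled toward the
# category attractor.
.producedRatio <- function(spec, conditionIndex) {
  r <- spec@conditions$r[conditionIndex]
  attractor <- if (conditionIndex <= spec@boundaryAfter) spec@protoSmall
               else spec@protoBig
  (1 - spec@warpStrength) * r + spec@warpStrength * attractor
}

#' Simulate one participant's tapping responses
#'
#' Per condition and trial, taps are placed at the event grid of the
#' produced (attractor-warped) ratio: a tap at every cycle onset plus one at
#' the produced first-interval offset, and a continuation tap at the loop
#' boundary. Each tap receives the participant's constant anticipation and
#' Gaussian jitter; taps are deleted with probability `missRate`, spurious
#' taps are injected at rate `extraRate` per produced tap, and onsets
#' outside the sequence are dropped.
#'
#' @param spec a [SimulationSpec].
#' @param participantSeed per-participant RNG seed.
#' @return tap-log data frame (`condition`, `trial`, `onset_s`) covering all
#'   conditions and trials.
#' @export
simulateTapParticipant <- function(spec, participantSeed = NULL) {
  stopifnot(is(spec, "SimulationSpec"))
  withSeed(participantSeed, {
    T <- spec@conditions$pattern_s[1]
    dur <- spec@nCycles * T
    rows <- list()
    for (ci in seq_len(nrow(spec@conditions))) {
      rProd <- .producedRatio(spec, ci)
      for (tr in seq_len(spec@nTrials)) {
        k <- seq_len(spec@nCycles) - 1
        grid <- sort(c(k * T, (k + rProd) * T, spec@nCycles * T))
        on <- grid + spec@asynchronyMean +
          stats::rnorm(length(grid), 0, spec@timingSd)
        on <- on[stats::runif(length(on)) >= spec@missRate]
        nExtra <- stats::rpois(1, spec@extraRate * length(grid))
        if (nExtra > 0) on <- c(on, stats::runif(nExtra, 0, dur))
        on <- sort(on[on >= 0 & on <= dur])
        if (length(on))
          rows[[length(rows) + 1L]] <-
            data.frame(condition = ci, trial = tr, onset_s = on)
      }
    }
    do.call(rbind, rows)
  })
}

# 1/f-shaped Gaussian noise via spectral shaping (zero-mean, unit SD).
.pinkNoise <- function(n, exponent) {
  half <- floor(n / 2)
  f <- seq_len(half)
  amp <- f^(-exponent / 2)
  phase <- stats::runif(half, 0, 2 * pi)
  X <- complex(modulus = amp * stats::rnorm(half, 1, 0.2), argument = phase)
  spec <- complex(real = numeric(n))
  spec[1 + f] <- X
  spec[1 + n - f[f < n - f]] <- Conj(X[f < n - f])
  x <- Re(stats::fft(spec, inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) numeric(n) else (x - mean(x)) / s
}

# Band-limited (8-12 Hz) Gaussian noise emulating the alpha rhythm.
.alphaNoise <- function(n, fs) {
  half <- floor(n / 2)
  f <- seq_len(half) * fs / n
  amp <- exp(-((f - 10)^2) / (2 * 1^2))
  phase <- stats::runif(half, 0, 2 * pi)
  X <- complex(modulus = amp, argument = phase)
  spec <- complex(real = numeric(n))
  idx <- seq_len(half)
  spec[1 + idx] <- X
  spec[1 + n - idx[idx < n - idx]] <- Conj(X[idx < n - idx])
  x <- Re(stats::fft(spec, inverse = TRUE))
  s <- stats::sd(x)
  if (s == 0) numeric(n) else (x - mean(x)) / s
}

# Circular convolution via the FFT; keeps a periodic drive exactly periodic
# (the steady-state regime the frequency-tagging analysis assumes).
.circularConvolve <- function(x, kern) {
  n <- length(x)
  kp <- numeric(n)
  kp[seq_along(kern)] <- kern
  Re(stats::fft(stats::fft(x) * stats::fft(kp), inverse = TRUE)) / n
}

# Gamma-shaped impulse-response kernel, peak-normalized.
.responseKernel <- function(fs, peakS, shape, lengthS = 0.5) {
  t <- seq(0, lengthS, by = 1 / fs)
  scale <- peakS / (shape - 1)  # mode of the gamma density at peakS
  k <- t^(shape - 1) * exp(-t / scale)
  k / max(k)
}

#' Standard 64-channel label set
#'
#' 10-20-style labels for the simulated montage; the first nine are the
#' frontocentral pool used for channel-averaged analyses.
#'
#' @param n number of channels (default 64).
#' @return character vector of labels.
#' @export
standardChannelLabels <- function(n = 64) {
  base <- c("F1", "Fz", "F2", "FC1", "FCz", "FC2", "C1", "Cz", "C2",
            "Fp1", "Fpz", "Fp2", "AF7", "AF3", "AFz", "AF4", "AF8",
            "F7", "F5", "F3", "F4", "F6", "F8", "FT7", "FC5", "FC3",
            "FC4", "FC6", "FT8", "T7", "C5", "C3", "C4", "C6", "T8",
            "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
            "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
            "PO7", "PO3", "POz", "PO4", "PO8", "O1", "Oz", "O2",
            "P9", "P10", "Iz")
  if (n <= length(base)) base[seq_len(n)]
  else c(base, sprintf("EX%d", seq_len(n - length(base))))
}

#' Frontocentral channel pool
#'
#' The nine frontocentral channels conventionally used to summarize auditory
#' rhythm-tracking EEG responses.
#'
#' @return character vector of nine labels.
#' @export
frontocentralPool <- function() {
  c("F1", "Fz", "F2", "FC1", "FCz", "FC2", "C1", "Cz", "C2")
}

#' Simulate one participant's EEG-like responses
#'
#' Per condition, the produced-ratio impulse train is convolved with a
#' gamma-shaped response kernel, scaled per channel by a frontocentral-
#' maximal topography gain, and buried in 1/f plus alpha-band noise drawn
#' independently per trial and channel. Trials are averaged per condition
#' (the form every downstream analysis consumes) unless `averageTrials` is
#' `FALSE`.
#'
#' @param spec a [SimulationSpec].
#' @param participantSeed per-participant RNG seed.
#' @param nChannels,nTrials,fs optional scaled-down overrides of the spec.
#' @param averageTrials return the trial average per condition (default) or
#'   a list of single-trial recordings.
#' @return list over conditions of [ContinuousRecording]s.
#' @export
simulateEEGParticipant <- function(spec, participantSeed = NULL,
                                   nChannels = spec@nChannels,
                                   nTrials = spec@nTrialsEEG, fs = spec@fs,
                                   averageTrials = TRUE) {
  stopifnot(is(spec, "SimulationSpec"))
  withSeed(participantSeed, {
    T <- spec@conditions$pattern_s[1]
    dur <- spec@nCycles * T
    n <- round(dur * fs)
    labs <- standardChannelLabels(nChannels)
    gains <- ifelse(labs %in% frontocentralPool(), 1, 0.4)
    kern <- .responseKernel(fs, spec@kernelPeak, spec@kernelShape)
    lapply(seq_len(nrow(spec@conditions)), function(ci) {
      rProd <- .producedRatio(spec, ci)
      k <- seq_len(spec@nCycles) - 1
      onsets <- sort(c(k * T, (k + rProd) * T))
      tr <- impulseTrain(onsets, fs = fs, durationS = dur)
      resp <- .circularConvolve(tr@samples[1, ], kern)
      trials <- lapply(seq_len(nTrials), function(j) {
        noise <- vapply(seq_len(nChannels), function(ch)
          spec@noiseScale * (.pinkNoise(n, spec@noiseExponent) +
                             spec@alphaPower * .alphaNoise(n, fs)),
          numeric(n))
        t(noise) + outer(gains, resp)
      })
      avg <- if (averageTrials) Reduce(`+`, trials) / nTrials else NULL
      if (averageTrials)
        new("ContinuousRecording", samples = avg, fs = fs,
            channelLabels = labs, t0 = 0,
            processingLog = sprintf("synthetic EEG, condition %d, average of %d trials",
                                    ci, nTrials))
      else lapply(trials, function(m)
        new("ContinuousRecording", samples = m, fs = fs,
            channelLabels = labs, t0 = 0,
            processingLog = sprintf("synthetic EEG, condition %d, single trial", ci)))
    })
  })
}

#' Simulate a null (non-categorical) participant
#'
#' Identical to the categorical generators but with the attractor pull
#' forced to zero, so responses track the stimulus ratios exactly (up to
#' noise); used for type-I-error calibration.
#'
#' @param spec a [SimulationSpec].
#' @param participantSeed per-participant RNG seed.
#' @param what `"tap"` or `"eeg"`.
#' @param ... passed to the underlying generator.
#' @return as the corresponding generator.
#' @export
simulateNullParticipant <- function(spec, participantSeed = NULL,
                                    what = c("tap", "eeg"), ...) {
  what <- match.arg(what)
  nullSpec <- initialize(spec, warpStrength = 0)
  if (what == "tap") simulateTapParticipant(nullSpec, participantSeed, ...)
  else simulateEEGParticipant(nullSpec, participantSeed, ...)
}
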