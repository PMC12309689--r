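#' @import methods
#' @importFrom stats fft cor sd median quantile rnorm runif rbinom rpois
#'   pchisq pt lm coef predict density approx wilcox.test complete.cases
#'   setNames
#' @importFrom utils read.table write.table modifyList
NULL

.almostEqual <- function(a, b, tol = 1e-9) all(abs(a - b) <= tol, na.rm = TRUE)

#' Multichannel continuous recording
#'
#' Container for a regularly sampled multichannel signal (EEG, tapping force,
#' audio, impulse trains). Rows are channels, columns are samples. `t0` is the
#' time of the first sample relative to stimulus-sequence onset, so epoch
#' segmentation can address absolute times. `processingLog` accumulates a
#' human-readable trace of the conditioning steps applied (filtering,
#' downsampling, ...), which downstream steps consult, e.g. to warn when
#' decimating a signal that was never low-pass filtered.
#'
#' @slot samples numeric matrix, channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels one label per channel.
#' @slot t0 time of the first sample in seconds relative to sequence onset.
#' @slot processingLog character vector of applied operations.
#' @exportClass ContinuousRecording
setClass("ContinuousRecording",
  representation(samples = "matrix", fs = "numeric",
                 channelLabels = "character", t0 = "numeric",
                 processingLog = "character"),
  prototype(t0 = 0, processingLog = character(0)),
  validity = function(object) {
    msg <- character(0)
    if (length(object@fs) != 1L || !is.finite(object@fs) || object@fs <= 0)
      msg <- c(msg, "'fs' must be a single positive number")
    if (!all(is.finite(object@samples)))
      msg <- c(msg, "all samples must be finite")
    if (length(object@channelLabels) != nrow(object@samples))
      msg <- c(msg, "channel label count must equal channel count")
    if (length(msg)) msg else TRUE
  })

#' Set of fixed-length signal epochs
#'
#' @slot epochs numeric array, n_epochs x channels x samples.
#' @slot fs sampling rate in Hz.
#' @slot epochDur epoch duration in seconds.
#' @slot channelLabels one label per channel.
#' @exportClass EpochSet
setClass("EpochSet",
  representation(epochs = "array", fs = "numeric", epochDur = "numeric",
                 channelLabels = "character"),
  validity = function(object) {
    d <- dim(object@epochs)
    if (length(d) != 3L)
      return("'epochs' must be a 3-d array (epochs x channels x samples)")
    if (d[1] > 0 && d[3] != round(object@epochDur * object@fs))
      return("epoch length must equal round(epochDur * fs) samples")
    if (length(object@channelLabels) != d[2])
      return("channel label count must equal channel count")
    TRUE
  })

#' Complex Fourier spectrum of a (trial-averaged) signal
#'
#' Stores the full discrete Fourier transform per channel, normalized by the
#' number of samples so a unit-amplitude cosine at an exact bin has magnitude
#' 0.5 in each of its two conjugate bins. Bin spacing is `fs / nSamples`;
#' column `k` holds frequency `(k - 1) * df` Hz.
#'
#' @slot coefficients complex matrix, channels x nSamples.
#' @slot fs sampling rate of the source signal in Hz.
#' @slot nSamples length of the source signal.
#' @slot channelLabels one label per channel.
#' @exportClass ComplexSpectrum
setClass("ComplexSpectrum",
  representation(coefficients = "matrix", fs = "numeric",
                 nSamples = "integer", channelLabels = "character"),
  validity = function(object) {
    if (!is.complex(object@coefficients))
      return("'coefficients' must be complex")
    if (ncol(object@coefficients) != object@nSamples)
      return("'coefficients' must have nSamples columns")
    if (length(object@channelLabels) != nrow(object@coefficients))
      return("channel label count must equal channel count")
    TRUE
  })

#' Harmonics of a pattern repetition rate mapped onto spectrum bins
#'
#' @slot f0 pattern repetition rate in Hz.
#' @slot harmonics integer multipliers (1, 2, ...).
#' @slot freqs harmonic frequencies in Hz.
#' @slot bins 1-based column indices into a [ComplexSpectrum] coefficient
#'   matrix.
#' @exportClass FrequencySet
setClass("FrequencySet",
  representation(f0 = "numeric", harmonics = "integer", freqs = "numeric",
                 bins = "integer"),
  validity = function(object) {
    if (length(object@freqs) != length(object@harmonics) ||
        length(object@bins) != length(object@harmonics))
      return("'harmonics', 'freqs' and 'bins' must have equal length")
    if (length(object@harmonics) &&
        !.almostEqual(object@freqs, object@harmonics * object@f0, 1e-9))
      return("freqs must equal harmonics * f0")
    TRUE
  })

#' Representational similarity matrix
#'
#' Condition-by-condition similarity, the central object of the analysis.
#' `kind` records how entries were computed: `"correlation"` (Pearson of
#' feature vectors or time courses), `"one-minus-absdiff"` (1 - |difference|
#' of a scalar summary, as used for stimulus ratios and mean intertap-interval
#' ratios), or `"binary"` (theoretical categorical models). Correlation and
#' one-minus-absdiff matrices have a unit diagonal by construction.
#'
#' @slot matrix numeric similarity matrix (NA allowed off-diagonal for
#'   undefined correlations).
#' @slot kind one of `"correlation"`, `"one-minus-absdiff"`, `"binary"`.
#' @slot labels condition labels.
#' @exportClass RSM
setClass("RSM",
  representation(matrix = "matrix", kind = "character",
                 labels = "character"),
  validity = function(object) {
    m <- object@matrix
    if (nrow(m) != ncol(m)) return("matrix must be square")
    if (!object@kind %in% c("correlation", "one-minus-absdiff", "binary"))
      return("unknown RSM kind")
    if (length(object@labels) != nrow(m))
      return("label count must match matrix dimension")
    if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9, check.attributes = FALSE)))
      return("matrix must be symmetric")
    if (object@kind != "binary" && nrow(m) &&
        !.almostEqual(diag(m), rep(1, nrow(m))))
      return("diagonal must be 1 for correlation / one-minus-absdiff kinds")
    if (object@kind == "correlation" && any(abs(m) > 1 + 1e-9, na.rm = TRUE))
      return("correlation entries must lie in [-1, 1]")
    TRUE
  })

#' Two-category theoretical model RSM
#'
#' Binary similarity model in which conditions `1..boundaryAfter` form the
#' first category and the remainder the second; entries are 1 iff both
#' conditions fall on the same side of the boundary.
#'
#' @slot boundaryAfter index of the last condition in the first category.
#' @exportClass CategoricalModelRSM
setClass("CategoricalModelRSM", contains = "RSM",
  representation(boundaryAfter = "integer"),
  validity = function(object) {
    n <- nrow(object@matrix)
    b <- object@boundaryAfter
    if (object@kind != "binary") return("categorical models must be binary")
    if (b < 2L || b > n - 2L)
      return("each category must span at least 2 conditions")
    member <- rep(1:2, c(b, n - b))
    expect <- outer(member, member, "==") * 1
    if (!identical(unname(object@matrix), expect))
      return("matrix must be the block-diagonal model implied by the boundary")
    TRUE
  })

#' Auditory stimulus sequence of a two-interval rhythm
#'
#' @slot conditionIndex 1-based index on the condition continuum (NA if free).
#' @slot r first-interval ratio IOI1 / pattern duration.
#' @slot patternDur pattern duration in seconds.
#' @slot nCycles number of seamless pattern repetitions.
#' @slot eventTimes tone-onset times in seconds (2 per cycle).
#' @exportClass StimulusSequence
setClass("StimulusSequence",
  representation(conditionIndex = "integer", r = "numeric",
                 patternDur = "numeric", nCycles = "integer",
                 eventTimes = "numeric"),
  validity = function(object) {
    if (object@r <= 0 || object@r >= 1) return("'r' must lie in (0, 1)")
    if (length(object@eventTimes) != 2L * object@nCycles)
      return("a sequence must contain exactly 2 events per cycle")
    if (is.unsorted(object@eventTimes, strictly = TRUE))
      return("event times must be strictly increasing")
    TRUE
  })

#' Set of two-interval impulse-train prototypes
#'
#' Templates span a grid of first-interval ratios; each is a two-impulse-per-
#' cycle train whose magnitude fingerprint at the frequencies of interest is
#' precomputed. `realizedRatios` are the ratios after rounding the second
#' impulse onto the sample grid (the analytic magnitude of a template is
#' `2 |cos(pi k r_realized)|` per cycle at harmonic `k`).
#'
#' @slot ratios nominal template ratios (equally spaced grid).
#' @slot realizedRatios ratios realized on the sample grid.
#' @slot patternDur,nCycles,fs construction parameters.
#' @slot frequencySet the [FrequencySet] of the fingerprints.
#' @slot magnitudes matrix, templates x frequencies of interest.
#' @exportClass PrototypeSet
setClass("PrototypeSet",
  representation(ratios = "numeric", realizedRatios = "numeric",
                 patternDur = "numeric", nCycles = "integer", fs = "numeric",
                 frequencySet = "FrequencySet", magnitudes = "matrix"),
  validity = function(object) {
    if (is.unsorted(object@ratios, strictly = TRUE))
      return("template ratios must be strictly increasing")
    if (any(object@ratios <= 0 | object@ratios >= 1))
      return("template ratios must lie in (0, 1)")
    if (nrow(object@magnitudes) != length(object@ratios))
      return("one magnitude row per template required")
    if (ncol(object@magnitudes) != length(object@frequencySet@harmonics))
      return("magnitude columns must match the frequency set")
    TRUE
  })

#' Bootstrap distribution of maximally correlated prototypes
#'
#' @slot bestRatios matrix, bootstrap iterations x conditions, each entry the
#'   grid ratio of the template maximally correlated with the resampled
#'   grand-average magnitude fingerprint (NA where undefined).
#' @slot conditionRatios stimulus ratio per condition column.
#' @slot templateRatios the prototype grid the entries are drawn from.
#' @slot nBoot number of bootstrap iterations.
#' @slot seed RNG seed used (NA if none).
#' @exportClass PrototypeDistribution
setClass("PrototypeDistribution",
  representation(bestRatios = "matrix", conditionRatios = "numeric",
                 templateRatios = "numeric", nBoot = "integer",
                 seed = "integer"),
  validity = function(object) {
    if (nrow(object@bestRatios) != object@nBoot)
      return("one row per bootstrap iteration required")
    if (ncol(object@bestRatios) != length(object@conditionRatios))
      return("one column per condition required")
    v <- object@bestRatios[!is.na(object@bestRatios)]
    if (length(v) && !all(v %in% object@templateRatios))
      return("stored ratios must be members of the template grid")
    TRUE
  })

#' Specification of a synthetic tapping / EEG study
#'
#' Defaults reproduce the study conditions the package targets: a 13-condition
#' continuum from 0.50 to 2/3 with a 750-ms pattern looped 30 times, 18
#' participants, 3 tapping trials and 6 EEG-like trials per condition, a
#' category boundary after condition 5 and category attractors at ratios 0.53
#' and 0.63. See `simulationSpec()`.
#'
#' @slot conditions condition continuum data frame.
#' @slot nCycles pattern repetitions per trial.
#' @slot boundaryAfter true category split (last condition of category 1).
#' @slot protoSmall,protoBig attractor ratios of the two categories.
#' @slot warpStrength 0-1 mixing of the stimulus ratio toward the attractor.
#' @slot timingSd per-tap Gaussian jitter SD in seconds.
#' @slot asynchronyMean constant tap-tone asynchrony in seconds (negative =
#'   anticipation).
#' @slot missRate,extraRate per-tap deletion / insertion probabilities.
#' @slot nTrials tapping trials per condition.
#' @slot nTrialsEEG EEG trials per condition.
#' @slot fs sampling rate of simulated continuous signals.
#' @slot nChannels number of EEG channels.
#' @slot kernelPeak,kernelShape gamma response-kernel peak latency (s) and
#'   shape parameter.
#' @slot noiseScale overall additive-noise scale relative to the response.
#' @slot noiseExponent 1/f noise exponent.
#' @slot alphaPower relative power of the 8-12-Hz noise component.
#' @slot nParticipants default cohort size.
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(conditions = "data.frame", nCycles = "integer",
                 boundaryAfter = "integer", protoSmall = "numeric",
                 protoBig = "numeric", warpStrength = "numeric",
                 timingSd = "numeric", asynchronyMean = "numeric",
                 missRate = "numeric", extraRate = "numeric",
                 nTrials = "integer", nTrialsEEG = "integer", fs = "numeric",
                 nChannels = "integer", kernelPeak = "numeric",
                 kernelShape = "numeric", noiseScale = "numeric",
                 noiseExponent = "numeric", alphaPower = "numeric",
                 nParticipants = "integer"),
  validity = function(object) {
    msg <- character(0)
    inunit <- function(x) length(x) == 1 && x >= 0 && x <= 1
    if (!inunit(object@warpStrength))
      msg <- c(msg, "'warpStrength' must lie in [0, 1]")
    if (!inunit(object@missRate) || !inunit(object@extraRate))
      msg <- c(msg, "miss/extra rates must lie in [0, 1]")
    if (object@timingSd < 0) msg <- c(msg, "'timingSd' must be >= 0")
    b <- object@boundaryAfter; n <- nrow(object@conditions)
    if (b < 1L || b >= n) msg <- c(msg, "'boundaryAfter' must split the grid")
    if (length(msg)) msg else TRUE
  })
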