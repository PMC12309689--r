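#' Accessor generics
#'
#' Small family of accessors used across the package's S4 containers:
#' `samples()` returns the channels-by-samples matrix of a recording,
#' `samplingRate()` the sampling rate in Hz, `channelLabels()` the channel
#' names, `nChannels()` the channel count, `recordingDuration()` the length in
#' seconds, `similarityMatrix()` the numeric matrix of an [RSM],
#' `rsmKind()` its kind, `boundaryAfter()` the category split of a
#' [CategoricalModelRSM], `eventTimes()` the tone onsets of a
#' [StimulusSequence], and `frequencies()` the harmonic frequencies of a
#' [FrequencySet].
#'
#' @param x an object of the documented class.
#' @return See the individual accessor descriptions.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("samples", function(x) standardGeneric("samples"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))
#' @rdname accessors
#' @export
setGeneric("similarityMatrix", function(x) standardGeneric("similarityMatrix"))
#' @rdname accessors
#' @export
setGeneric("rsmKind", function(x) standardGeneric("rsmKind"))
#' @rdname accessors
#' @export
setGeneric("boundaryAfter", function(x) standardGeneric("boundaryAfter"))
#' @rdname accessors
#' @export
setGeneric("eventTimes", function(x) standardGeneric("eventTimes"))
#' @rdname accessors
#' @export
setGeneric("frequencies", function(x) standardGeneric("frequencies"))

#' @rdname accessors
setMethod("samples", "ContinuousRecording", function(x) x@samples)
#' @rdname accessors
setMethod("samplingRate", "ContinuousRecording", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "ContinuousRecording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("nChannels", "ContinuousRecording", function(x) nrow(x@samples))
#' @rdname accessors
setMethod("recordingDuration", "ContinuousRecording",
          function(x) ncol(x@samples) / x@fs)

#' @rdname accessors
setMethod("samplingRate", "EpochSet", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "EpochSet", function(x) x@channelLabels)
#' @rdname accessors
setMethod("nChannels", "EpochSet", function(x) dim(x@epochs)[2])

#' @rdname accessors
setMethod("samplingRate", "ComplexSpectrum", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "ComplexSpectrum", function(x) x@channelLabels)
#' @rdname accessors
setMethod("nChannels", "ComplexSpectrum", function(x) nrow(x@coefficients))

#' @rdname accessors
setMethod("similarityMatrix", "RSM", function(x) {
  m <- x@matrix
  dimnames(m) <- list(x@labels, x@labels)
  m
})
#' @rdname accessors
setMethod("rsmKind", "RSM", function(x) x@kind)
#' @rdname accessors
setMethod("boundaryAfter", "CategoricalModelRSM", function(x) x@boundaryAfter)
#' @rdname accessors
setMethod("eventTimes", "StimulusSequence", function(x) x@eventTimes)
#' @rdname accessors
setMethod("recordingDuration", "StimulusSequence",
          function(x) x@nCycles * x@patternDur)
#' @rdname accessors
setMethod("frequencies", "FrequencySet", function(x) x@freqs)

#' Number of epochs in an EpochSet
#' @param x an [EpochSet].
#' @return integer count.
#' @export
nEpochs <- function(x) {
  stopifnot(is(x, "EpochSet"))
  dim(x@epochs)[1]
}

#' Epoch array of an EpochSet
#' @param x an [EpochSet].
#' @return numeric array, epochs x channels x samples.
#' @export
epochArray <- function(x) {
  stopifnot(is(x, "EpochSet"))
  x@epochs
}

#' Frequency-bin spacing of a spectrum
#' @param x a [ComplexSpectrum].
#' @return bin spacing `fs / nSamples` in Hz.
#' @export
binSpacing <- function(x) {
  stopifnot(is(x, "ComplexSpectrum"))
  x@fs / x@nSamples
}

setMethod("show", "ContinuousRecording", function(object) {
  cat(sprintf("ContinuousRecording: %d channel(s) x %d samples @ %g Hz (%.3f s, t0 = %g s)\n",
              nrow(object@samples), ncol(object@samples), object@fs,
              ncol(object@samples) / object@fs, object@t0))
  if (length(object@processingLog))
    cat("  processing:", paste(object@processingLog, collapse = "; "), "\n")
})

setMethod("show", "EpochSet", function(object) {
  d <- dim(object@epochs)
  cat(sprintf("EpochSet: %d epoch(s) x %d channel(s) x %d samples (%g s @ %g Hz)\n",
              d[1], d[2], d[3], object@epochDur, object@fs))
})

setMethod("show", "ComplexSpectrum", function(object) {
  cat(sprintf("ComplexSpectrum: %d channel(s), %d bins, df = %.4g Hz\n",
              nrow(object@coefficients), object@nSamples,
              object@fs / object@nSamples))
})

setMethod("show", "FrequencySet", function(object) {
  cat(sprintf("FrequencySet: f0 = %.4g Hz, %d harmonic(s)%s\n",
              object@f0, length(object@harmonics),
              if (length(object@harmonics))
                sprintf(" (%.3g-%.3g Hz)", min(object@freqs), max(object@freqs))
              else ""))
})

setMethod("show", "RSM", function(object) {
  cat(sprintf("RSM (%s): %d x %d conditions\n", object@kind,
              nrow(object@matrix), ncol(object@matrix)))
})

setMethod("show", "CategoricalModelRSM", function(object) {
  cat(sprintf("CategoricalModelRSM: %d conditions, boundary after condition %d\n",
              nrow(object@matrix), object@boundaryAfter))
})

setMethod("show", "StimulusSequence", function(object) {
  cat(sprintf("StimulusSequence: r = %.4f, pattern %g s x %d cycles (%g s, %d events)\n",
              object@r, object@patternDur, object@nCycles,
              object@nCycles * object@patternDur, length(object@eventTimes)))
})

setMethod("show", "PrototypeSet", function(object) {
  cat(sprintf("PrototypeSet: %d templates, ratios %.2f-%.2f, %d frequencies of interest\n",
              length(object@ratios), min(object@ratios), max(object@ratios),
              ncol(object@magnitudes)))
})

setMethod("show", "PrototypeDistribution", function(object) {
  cat(sprintf("PrototypeDistribution: %d bootstrap iterations x %d condition(s)\n",
              object@nBoot, ncol(object@bestRatios)))
})

setMethod("show", "SimulationSpec", function(object) {
  cat(sprintf(paste0("SimulationSpec: %d conditions x %d cycles, boundary after %d,",
                     " attractors {%.2f, %.2f}, warp %.2f\n"),
              nrow(object@conditions), object@nCycles, object@boundaryAfter,
              object@protoSmall, object@protoBig, object@warpStrength))
})
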