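#' Zero-phase Butterworth filtering
#'
#' Designs a Butterworth low- or high-pass filter and applies it forward and
#' backward (`signal::filtfilt`), so the output has no group delay and the
#' effective amplitude response is the squared magnitude of the single-pass
#' filter. Zero-phase application matters downstream: representational
#' similarity of complex Fourier coefficients must not be distorted by a
#' frequency-dependent phase shift.
#'
#' @param rec a [ContinuousRecording].
#' @param kind `"low"` or `"high"`.
#' @param order filter order (default 4).
#' @param cutoffHz cutoff frequency in Hz, strictly below Nyquist.
#' @return the filtered [ContinuousRecording] (same length; processing log
#'   extended).
#' @export
butterworthFilter <- function(rec, kind = c("low", "high"), order = 4,
                              cutoffHz) {
  stopifnot(is(rec, "ContinuousRecording"))
  kind <- match.arg(kind)
  .assertCount(order, "order", min = 1)
  .assertScalar(cutoffHz, "cutoffHz", min = 0)
  if (cutoffHz <= 0 || cutoffHz >= rec@fs / 2)
    stop(sprintf("'cutoffHz' must lie in (0, Nyquist = %g Hz)", rec@fs / 2))
  flt <- signal::butter(order, cutoffHz / (rec@fs / 2),
                        type = if (kind == "low") "low" else "high")
  out <- t(apply(rec@samples, 1, function(ch) signal::filtfilt(flt, ch)))
  if (nrow(rec@samples) == 1L) out <- matrix(out, nrow = 1)
  initialize(rec, samples = out,
             processingLog = c(rec@processingLog,
                               sprintf("butterworth %s-pass order %d @ %g Hz (zero-phase)",
                                       kind, order, cutoffHz)))
}

#' Segment a recording into contiguous fixed-length epochs
#'
#' Cuts `nEpochs` successive non-overlapping chunks of `epochDur` seconds
#' starting at absolute time `startS` (relative to sequence onset, honoring
#' the recording's `t0`). The sample index of epoch `k` starts at
#' `round((startS + k * epochDur - t0) * fs)`. An optional baseline window
#' (in seconds relative to each epoch onset, e.g. `c(-1, 0)` for the second
#' preceding the epoch) has its per-channel mean subtracted from the epoch,
#' as used for tapping-force baseline correction.
#'
#' @param rec a [ContinuousRecording].
#' @param startS absolute start time of the first epoch in seconds.
#' @param epochDur epoch duration in seconds.
#' @param nEpochs number of epochs.
#' @param baselineWindow optional `c(from, to)` in seconds relative to each
#'   epoch onset; `NULL` (default) skips baseline correction.
#' @return an [EpochSet].
#' @export
segmentEpochs <- function(rec, startS, epochDur, nEpochs,
                          baselineWindow = NULL) {
  stopifnot(is(rec, "ContinuousRecording"))
  .assertScalar(startS, "startS")
  .assertScalar(epochDur, "epochDur", min = 0)
  .assertCount(nEpochs, "nEpochs", min = 0)
  nsamp <- round(epochDur * rec@fs)
  total <- ncol(rec@samples)
  nch <- nrow(rec@samples)
  epochs <- array(0, dim = c(nEpochs, nch, nsamp))
  for (k in seq_len(nEpochs)) {
    i0 <- round((startS + (k - 1) * epochDur - rec@t0) * rec@fs) + 1
    i1 <- i0 + nsamp - 1
    if (i0 < 1 || i1 > total)
      stop(sprintf("insufficient data: epoch %d needs samples %d..%d of %d",
                   k, i0, i1, total))
    chunk <- rec@samples[, i0:i1, drop = FALSE]
    if (!is.null(baselineWindow)) {
      b0 <- i0 + round(baselineWindow[1] * rec@fs)
      b1 <- i0 + round(baselineWindow[2] * rec@fs) - 1
      if (b0 < 1 || b1 > total || b1 < b0)
        stop(sprintf("baseline window of epoch %d (samples %d..%d) outside the recording",
                     k, b0, b1))
      chunk <- chunk - rowMeans(rec@samples[, b0:b1, drop = FALSE])
    }
    epochs[k, , ] <- chunk
  }
  new("EpochSet", epochs = epochs, fs = rec@fs, epochDur = epochDur,
      channelLabels = rec@channelLabels)
}

#' Remove the within-epoch mean
#'
#' Subtracts from every time point of each epoch/channel the average amplitude
#' over that epoch, correcting for slow offsets. Idempotent.
#'
#' @param e an [EpochSet].
#' @return the demeaned [EpochSet].
#' @export
demeanEpochs <- function(e) {
  stopifnot(is(e, "EpochSet"))
  a <- e@epochs
  m <- apply(a, c(1, 2), mean)
  initialize(e, epochs = a - as.vector(m))  # recycles over 3rd dim
}

#' Average epochs pointwise
#'
#' Arithmetic mean across epochs per channel and time point. For a strictly
#' periodic signal segmented at its period this returns any single cycle
#' exactly; for signal plus independent noise the noise SD shrinks by the
#' square root of the epoch count.
#'
#' @param e an [EpochSet] with at least one epoch.
#' @return a [ContinuousRecording] holding the average epoch (`t0 = 0`).
#' @export
averageEpochs <- function(e) {
  stopifnot(is(e, "EpochSet"))
  if (nEpochs(e) < 1) stop("cannot average an empty epoch set")
  avg <- apply(e@epochs, c(2, 3), mean)
  if (is.null(dim(avg))) avg <- matrix(avg, nrow = nChannels(e))
  new("ContinuousRecording", samples = avg, fs = e@fs,
      channelLabels = e@channelLabels, t0 = 0,
      processingLog = sprintf("average of %d epochs", nEpochs(e)))
}

#' Downsample a recording by decimation
#'
#' Retains every `factor`-th sample and divides the sampling rate by
#' `factor`. No anti-alias filter is applied here; a warning is emitted when
#' the processing log shows no prior low-pass stage, since the caller is
#' responsible for band-limiting below the new Nyquist.
#'
#' @param rec a [ContinuousRecording].
#' @param factor integer decimation factor (>= 1).
#' @return the decimated [ContinuousRecording].
#' @export
downsampleRecording <- function(rec, factor) {
  stopifnot(is(rec, "ContinuousRecording"))
  .assertCount(factor, "factor", min = 1)
  if (factor == 1L) return(rec)
  if (!any(grepl("low-pass", rec@processingLog, fixed = TRUE)))
    warning("decimating a recording with no low-pass stage in its processing log")
  keep <- seq(1, ncol(rec@samples), by = factor)
  initialize(rec, samples = rec@samples[, keep, drop = FALSE],
             fs = rec@fs / factor,
             processingLog = c(rec@processingLog,
                               sprintf("decimated by %d to %g Hz",
                                       factor, rec@fs / factor)))
}

#' Unit impulse train from onset times
#'
#' One-channel signal of `duration` seconds at `fs` Hz with the sample at
#' `round(onset * fs)` set to 1 for every onset and 0 elsewhere. Two onsets
#' rounding to the same sample keep the value 1 (the representation marks
#' event presence, not multiplicity).
#'
#' @param onsetsS onset times in seconds, all within `[0, duration)`.
#' @param fs sampling rate in Hz.
#' @param durationS signal duration in seconds.
#' @param label channel label (default `"impulse"`).
#' @return a one-channel [ContinuousRecording].
#' @export
impulseTrain <- function(onsetsS, fs, durationS, label = "impulse") {
  .assertScalar(fs, "fs", min = 0)
  .assertScalar(durationS, "durationS", min = 0)
  n <- round(durationS * fs)
  if (length(onsetsS) && (any(onsetsS < 0) || any(onsetsS >= durationS)))
    stop("'onsetsS' must lie within [0, durationS)")
  x <- numeric(n)
  idx <- round(onsetsS * fs) + 1
  idx <- idx[idx >= 1 & idx <= n]
  x[idx] <- 1
  new("ContinuousRecording", samples = matrix(x, nrow = 1), fs = fs,
      channelLabels = label, t0 = 0,
      processingLog = sprintf("impulse train (%d onsets)", length(onsetsS)))
}

#' Select channels of a recording or epoch set
#'
#' @param x a [ContinuousRecording] or [EpochSet].
#' @param channels labels (or indices) to keep.
#' @return object of the same class restricted to the channels, in the
#'   requested order.
#' @export
selectChannels <- function(x, channels) {
  labs <- channelLabels(x)
  idx <- if (is.numeric(channels)) as.integer(channels)
         else match(channels, labs)
  if (anyNA(idx) || any(idx < 1) || any(idx > length(labs)))
    stop("unknown channel(s): ",
         paste(setdiff(as.character(channels), labs), collapse = ", "))
  if (is(x, "ContinuousRecording"))
    initialize(x, samples = x@samples[idx, , drop = FALSE],
               channelLabels = labs[idx])
  else if (is(x, "EpochSet"))
    initialize(x, epochs = x@epochs[, idx, , drop = FALSE],
               channelLabels = labs[idx])
  else stop("'x' must be a ContinuousRecording or EpochSet")
}

#' Average a recording across channels
#'
#' @param rec a [ContinuousRecording].
#' @param channels optional channel pool (labels); default all.
#' @param label label of the pooled channel.
#' @return a one-channel [ContinuousRecording] holding the channel mean.
#' @export
poolChannels <- function(rec, channels = NULL, label = "pool") {
  stopifnot(is(rec, "ContinuousRecording"))
  if (!is.null(channels)) rec <- selectChannels(rec, channels)
  initialize(rec, samples = matrix(colMeans(rec@samples), nrow = 1),
             channelLabels = label,
             processingLog = c(rec@processingLog,
                               sprintf("pooled %d channels", nChannels(rec))))
}
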