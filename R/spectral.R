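#' Discrete Fourier spectrum of a signal
#'
#' Plain FFT, no windowing: the analysis rests on stimulus sequences spanning
#' an exact integer number of pattern cycles, so responses at the pattern
#' repetition rate and harmonics fall on exact bins with zero leakage.
#' Coefficients are divided by the signal length, so a unit-amplitude cosine
#' at an exact bin has magnitude 0.5 in each conjugate bin (the convention is
#' immaterial for correlations and z-scores but is asserted by tests).
#'
#' @param x a [ContinuousRecording], or a channels-by-samples matrix / plain
#'   vector combined with `fs`.
#' @param fs sampling rate in Hz (taken from `x` when it is a recording).
#' @return a [ComplexSpectrum].
#' @export
fftSpectrum <- function(x, fs = NULL) {
  if (is(x, "ContinuousRecording")) {
    fs <- x@fs
    labs <- x@channelLabels
    m <- x@samples
  } else {
    if (is.null(fs)) stop("'fs' is required when 'x' is not a recording")
    m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
    labs <- rownames(m)
    if (is.null(labs)) labs <- paste0("ch", seq_len(nrow(m)))
  }
  n <- ncol(m)
  if (n < 2) stop("signal must contain at least 2 samples")
  coef <- t(apply(m, 1, stats::fft)) / n
  if (nrow(m) == 1L) coef <- matrix(coef, nrow = 1)
  new("ComplexSpectrum", coefficients = coef, fs = fs,
      nSamples = as.integer(n), channelLabels = labs)
}

#' Magnitude spectrum
#'
#' @param spec a [ComplexSpectrum].
#' @return numeric matrix of magnitudes, channels x bins.
#' @export
magnitudeSpectrum <- function(spec) {
  stopifnot(is(spec, "ComplexSpectrum"))
  abs(spec@coefficients)
}

#' Average a complex spectrum across channels
#'
#' Complex (coefficient-wise) mean, equivalent to computing the spectrum of
#' the channel-averaged time course; used for frontocentral channel pools.
#'
#' @param spec a [ComplexSpectrum].
#' @param channels optional channel labels to pool; default all.
#' @param label label of the pooled channel.
#' @return a one-channel [ComplexSpectrum].
#' @export
poolSpectrum <- function(spec, channels = NULL, label = "pool") {
  stopifnot(is(spec, "ComplexSpectrum"))
  coef <- spec@coefficients
  if (!is.null(channels)) {
    idx <- match(channels, spec@channelLabels)
    if (anyNA(idx))
      stop("unknown channel(s): ",
           paste(channels[is.na(idx)], collapse = ", "))
    coef <- coef[idx, , drop = FALSE]
  }
  new("ComplexSpectrum",
      coefficients = matrix(colMeans(coef), nrow = 1), fs = spec@fs,
      nSamples = spec@nSamples, channelLabels = label)
}

#' Harmonics of a pattern repetition rate as frequencies of interest
#'
#' Returns harmonics `k = 1 .. floor(fMax * patternDur)` of
#' `f0 = 1 / patternDur` together with their bin indices in a spectrum of
#' resolution `dfHz`. Every harmonic must land on an exact bin (within
#' `1e-6 * df`), which holds whenever the analyzed signal spans an integer
#' number of pattern cycles; a non-integer mapping is rejected.
#'
#' @param patternDur pattern duration in seconds.
#' @param fMaxHz highest frequency of interest (>= `1 / patternDur`);
#'   8 Hz retains the first six harmonics of a 750-ms pattern, 16 Hz twelve.
#' @param dfHz spectral resolution (bin spacing) in Hz, e.g.
#'   [binSpacing()] of the target spectrum.
#' @return a [FrequencySet].
#' @export
harmonicFrequencies <- function(patternDur, fMaxHz, dfHz) {
  .assertScalar(patternDur, "patternDur", min = 0)
  .assertScalar(fMaxHz, "fMaxHz")
  .assertScalar(dfHz, "dfHz", min = 0)
  if (patternDur <= 0) stop("'patternDur' must be positive")
  f0 <- 1 / patternDur
  if (fMaxHz < f0) stop("'fMaxHz' must be at least 1 / patternDur")
  k <- seq_len(floor(fMaxHz * patternDur + 1e-9))
  freqs <- k * f0
  binsReal <- freqs / dfHz
  bins <- round(binsReal)
  if (any(abs(binsReal - bins) > 1e-6 * pmax(1, binsReal)))
    stop("harmonics do not map onto exact bins at 'dfHz': analyze an integer number of cycles")
  new("FrequencySet", f0 = f0, harmonics = as.integer(k), freqs = freqs,
      bins = as.integer(bins + 1L))
}

.flankOffsets <- function(nFlank, skip) {
  c(-(skip + nFlank):-(skip + 1), (skip + 1):(skip + nFlank))
}

#' Signal-to-noise z-score of a spectral bin
#'
#' Compares the magnitude at `bin` against a local noise baseline formed by
#' `nFlank` bins on each side, skipping the `skip` immediately adjacent bins
#' to guard against residual leakage (defaults: 8 baseline bins, 4 per side,
#' 1 skipped). `z = (x - mean(baseline)) / SD(baseline)` with the sample SD
#' (n - 1 denominator); `sdType = "population"` selects the n denominator.
#' A zero-SD baseline yields `NA` with a warning (the statistic is undefined,
#' not infinite). With the default threshold, `z > 3.09` corresponds to a
#' one-tailed P < 0.001 for signal exceeding noise.
#'
#' @param mag numeric magnitude spectrum (vector over bins).
#' @param bin 1-based index of the tested bin.
#' @param nFlank baseline bins per side (default 4).
#' @param skip adjacent bins skipped per side (default 1).
#' @param sdType `"sample"` (default) or `"population"`.
#' @return the z value, or `NA` when the baseline SD is zero.
#' @export
snrZscore <- function(mag, bin, nFlank = 4, skip = 1,
                      sdType = c("sample", "population")) {
  sdType <- match.arg(sdType)
  .assertCount(bin, "bin", min = 1)
  off <- .flankOffsets(nFlank, skip)
  if (bin + min(off) < 1 || bin + max(off) > length(mag))
    stop(sprintf("bin %d lacks %d + %d valid neighbors on each side",
                 bin, nFlank, skip))
  bl <- mag[bin + off]
  s <- stats::sd(bl)
  if (sdType == "population") s <- s * sqrt((length(bl) - 1) / length(bl))
  if (!is.finite(s) || s == 0) {
    warning(sprintf("baseline SD at bin %d is zero: z-score undefined", bin))
    return(NA_real_)
  }
  (mag[bin] - mean(bl)) / s
}

#' z-scores at all frequencies of interest
#'
#' @param mag magnitude spectrum vector (typically a grand average across
#'   participants, conditions and channels).
#' @param fois a [FrequencySet].
#' @inheritParams snrZscore
#' @return named numeric vector, one z per harmonic.
#' @export
foiZscores <- function(mag, fois, nFlank = 4, skip = 1,
                       sdType = c("sample", "population")) {
  stopifnot(is(fois, "FrequencySet"))
  sdType <- match.arg(sdType)
  z <- vapply(fois@bins, function(b)
    snrZscore(mag, b, nFlank = nFlank, skip = skip, sdType = sdType),
    numeric(1))
  names(z) <- fois@harmonics
  z
}

#' Truncate a frequency set to the leading run of significant harmonics
#'
#' Keeps harmonics `1..m` where `m` is the last index of the unbroken run of
#' `z > zCrit` starting at the first harmonic; returns an empty set when the
#' first harmonic is not significant (the caller decides how to proceed).
#'
#' @param fois a [FrequencySet].
#' @param z z-scores ordered by harmonic number (e.g. [foiZscores()]).
#' @param zCrit significance threshold (default 3.09, one-tailed P < 0.001).
#' @return the truncated [FrequencySet].
#' @export
consecutiveSignificant <- function(fois, z, zCrit = 3.09) {
  stopifnot(is(fois, "FrequencySet"), length(z) == length(fois@harmonics))
  sig <- !is.na(z) & z > zCrit
  m <- if (!length(sig) || !sig[1]) 0L else {
    run <- which(!sig)
    if (!length(run)) length(sig) else run[1] - 1L
  }
  keep <- seq_len(m)
  new("FrequencySet", f0 = fois@f0, harmonics = fois@harmonics[keep],
      freqs = fois@freqs[keep], bins = fois@bins[keep])
}

#' Concatenated real/imaginary feature vector at frequencies of interest
#'
#' Fixed deterministic layout: frequency-major, real before imaginary,
#' channels innermost — for each harmonic, the real coefficients of all
#' requested channels, then the imaginary ones. Length is
#' `n_foi * 2 * n_channels` (e.g. 6 harmonics x 64 channels -> 768).
#'
#' @param spec a [ComplexSpectrum].
#' @param fois a [FrequencySet] whose bins all lie inside the spectrum.
#' @param channels channel labels to include (default all, in stored order).
#' @return numeric feature vector with a `"layout"` attribute describing the
#'   ordering.
#' @export
featureVector <- function(spec, fois, channels = NULL) {
  stopifnot(is(spec, "ComplexSpectrum"), is(fois, "FrequencySet"))
  if (is.null(channels)) channels <- spec@channelLabels
  idx <- match(channels, spec@channelLabels)
  if (anyNA(idx))
    stop("unknown channel(s): ", paste(channels[is.na(idx)], collapse = ", "))
  if (any(fois@bins < 1 | fois@bins > spec@nSamples))
    stop("frequency set contains bins outside the spectrum")
  coef <- spec@coefficients[idx, fois@bins, drop = FALSE]
  v <- as.vector(apply(coef, 2, function(col) c(Re(col), Im(col))))
  structure(v, layout = "foi-major; re before im; channels innermost")
}

#' Noise-corrected magnitudes at frequencies of interest
#'
#' Subtracts from the magnitude at each frequency of interest the local noise
#' baseline, approximated as the mean magnitude of the same surrounding bins
#' used by [snrZscore()]. Values may be negative; they are not clipped.
#'
#' @param mag magnitude spectrum vector.
#' @param fois a [FrequencySet].
#' @inheritParams snrZscore
#' @return named numeric vector of corrected magnitudes, one per harmonic.
#' @export
noiseCorrectedMagnitudes <- function(mag, fois, nFlank = 4, skip = 1) {
  stopifnot(is(fois, "FrequencySet"))
  off <- .flankOffsets(nFlank, skip)
  v <- vapply(fois@bins, function(b) {
    if (b + min(off) < 1 || b + max(off) > length(mag))
      stop(sprintf("bin %d lacks %d + %d valid neighbors on each side",
                   b, nFlank, skip))
    mag[b] - mean(mag[b + off])
  }, numeric(1))
  names(v) <- fois@harmonics
  v
}

#' Export a spectrum as a delimited table
#'
#' Long-format table with columns frequency, channel, re, im, magnitude.
#'
#' @param spec a [ComplexSpectrum].
#' @param path output file (tab-separated).
#' @param fMaxHz optional upper frequency limit for the export.
#' @return the path, invisibly.
#' @export
writeSpectrumTable <- function(spec, path, fMaxHz = NULL) {
  stopifnot(is(spec, "ComplexSpectrum"))
  df <- binSpacing(spec)
  bins <- seq_len(floor(spec@nSamples / 2) + 1)
  if (!is.null(fMaxHz)) bins <- bins[(bins - 1) * df <= fMaxHz]
  out <- do.call(rbind, lapply(seq_len(nChannels(spec)), function(ch) {
    co <- spec@coefficients[ch, bins]
    data.frame(frequency = (bins - 1) * df,
               channel = spec@channelLabels[ch],
               re = Re(co), im = Im(co), magnitude = abs(co))
  }))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
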