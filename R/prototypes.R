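#' Build a set of two-interval impulse-train prototypes
#'
#' Creates `n` templates with first-interval ratios equally spaced between
#' `rMin` and `rMax` inclusive (defaults: 76 templates spanning 0.50-0.84).
#' Each template is a two-impulse-per-cycle unit impulse train with the same
#' pattern duration and cycle count as the stimuli; its temporal structure is
#' summarized by the magnitude fingerprint at the frequencies of interest.
#' The second impulse is rounded onto the sample grid; the realized ratios
#' are stored alongside the nominal grid, and the analytic per-cycle
#' magnitude of template `r` at harmonic `k` is `2 |cos(pi k r_realized)|`
#' (times the FFT normalization).
#'
#' @param n number of templates (default 76).
#' @param rMin,rMax ratio grid endpoints (defaults 0.50 and 0.84).
#' @param patternDur pattern duration in seconds (default 0.75).
#' @param nCycles pattern repetitions (default 30).
#' @param fs sampling rate used to realize the trains (default 256 Hz;
#'   `patternDur * fs` must be an integer number of samples).
#' @param fMaxHz highest harmonic retained (default 16 Hz; use 8 Hz for EEG
#'   fingerprints).
#' @return a [PrototypeSet].
#' @export
buildPrototypeSet <- function(n = 76, rMin = 0.50, rMax = 0.84,
                              patternDur = 0.75, nCycles = 30, fs = 256,
                              fMaxHz = 16) {
  .assertCount(n, "n", min = 2)
  .assertScalar(rMin, "rMin"); .assertScalar(rMax, "rMax")
  if (rMin <= 0 || rMax >= 1 || rMin >= rMax)
    stop("need 0 < rMin < rMax < 1")
  P <- patternDur * fs
  if (abs(P - round(P)) > 1e-9)
    stop("'fs' must realize the pattern as an integer number of samples")
  P <- round(P)
  ratios <- seq(rMin, rMax, length.out = n)
  d <- round(ratios * P)
  if (any(d <= 0) || any(d >= P))
    stop(sprintf("impulse collision at fs = %g Hz: template impulses share a sample", fs))
  nSamp <- P * nCycles
  fois <- harmonicFrequencies(patternDur, fMaxHz, dfHz = fs / nSamp)
  mags <- t(vapply(d, function(dk) {
    onsets <- as.vector(outer(c(0, dk), (seq_len(nCycles) - 1) * P, "+")) / fs
    tr <- impulseTrain(onsets, fs = fs, durationS = nCycles * patternDur)
    magnitudeSpectrum(fftSpectrum(tr))[1, fois@bins]
  }, numeric(length(fois@bins))))
  new("PrototypeSet", ratios = ratios, realizedRatios = d / P,
      patternDur = patternDur, nCycles = as.integer(nCycles), fs = fs,
      frequencySet = fois, magnitudes = mags)
}

#' Noise-corrected magnitude fingerprints per participant and condition
#'
#' Applies [noiseCorrectedMagnitudes()] to each column of a bins x conditions
#' x participants magnitude array. Because the correction is linear in the
#' spectrum, averaging corrected fingerprints across a participant resample
#' equals correcting the resampled grand-average spectrum, which the
#' bootstrap engine exploits.
#'
#' @param mags numeric array, spectrum bins x conditions x participants (or a
#'   bins x conditions matrix for a single participant).
#' @param fois the [FrequencySet] of the fingerprints.
#' @inheritParams snrZscore
#' @return array, frequencies of interest x conditions x participants.
#' @export
foiMagnitudeArray <- function(mags, fois, nFlank = 4, skip = 1) {
  if (length(dim(mags)) == 2) dim(mags) <- c(dim(mags), 1)
  stopifnot(length(dim(mags)) == 3)
  out <- array(NA_real_, c(length(fois@bins), dim(mags)[2], dim(mags)[3]))
  for (p in seq_len(dim(mags)[3])) for (ci in seq_len(dim(mags)[2]))
    out[, ci, p] <- noiseCorrectedMagnitudes(mags[, ci, p], fois,
                                             nFlank = nFlank, skip = skip)
  out
}

# Standardized template fingerprints: centered unit-norm columns (nfoi x nT).
.standardizeTemplates <- function(set) {
  Tm <- t(set@magnitudes)
  Ts <- sweep(Tm, 2, colMeans(Tm))
  nrm <- sqrt(colSums(Ts^2))
  nrm[nrm == 0] <- NA_real_
  sweep(Ts, 2, nrm, "/")
}

# Resample-count matrix: nP x nDraw, column j holding how often each
# participant appears in bootstrap draw j.
.drawWeights <- function(nP, nDraw) {
  idx <- sample.int(nP, nDraw * nP, replace = TRUE)
  matrix(tabulate(idx + (rep(seq_len(nDraw), each = nP) - 1L) * nP,
                  nbins = nP * nDraw), nP, nDraw)
}

# Best-template index per draw for one condition. C: nfoi x nP corrected
# fingerprints; Ts: standardized templates; W: nP x nDraw counts.
.bestForDraws <- function(C, Ts, W) {
  M <- C %*% W
  Ms <- sweep(M, 2, colMeans(M))
  nrm <- sqrt(colSums(Ms^2))
  undef <- nrm == 0
  nrm[undef] <- 1
  corr <- crossprod(Ts, sweep(Ms, 2, nrm, "/"))
  best <- max.col(t(corr), ties.method = "first")
  best[undef] <- NA_integer_
  best
}

#' Bootstrap distribution of maximally correlated prototypes
#'
#' Each iteration resamples participants with replacement (the same resample
#' for all conditions), averages their noise-corrected magnitude
#' fingerprints, Pearson-correlates the grand-average fingerprint with every
#' template's fingerprint, and stores the ratio of the maximally correlated
#' template per condition. Iterations whose resampled fingerprint is constant
#' are stored as `NA` (counted, not dropped silently).
#'
#' @param corrected array from [foiMagnitudeArray()], frequencies x
#'   conditions x participants (>= 2 participants).
#' @param set a [PrototypeSet] with a matching frequency layout.
#' @param nBoot bootstrap iterations (default 1000).
#' @param seed RNG seed.
#' @param conditionRatios stimulus ratio per condition column (optional,
#'   stored for window tests).
#' @return a [PrototypeDistribution].
#' @export
bootstrapBestPrototype <- function(corrected, set, nBoot = 1000, seed = NULL,
                                   conditionRatios = NULL) {
  stopifnot(is(set, "PrototypeSet"), length(dim(corrected)) == 3)
  if (dim(corrected)[1] != length(set@frequencySet@harmonics))
    stop("fingerprint layout of 'corrected' does not match the prototype set")
  nP <- dim(corrected)[3]
  if (nP < 2) stop("need at least 2 participants")
  nCond <- dim(corrected)[2]
  if (is.null(conditionRatios)) conditionRatios <- rep(NA_real_, nCond)
  Ts <- .standardizeTemplates(set)
  best <- withSeed(seed, {
    W <- .drawWeights(nP, nBoot)
    vapply(seq_len(nCond), function(ci)
      set@ratios[.bestForDraws(corrected[, ci, , drop = TRUE], Ts, W)],
      numeric(nBoot))
  })
  if (is.null(dim(best))) best <- matrix(best, nrow = nBoot)
  new("PrototypeDistribution", bestRatios = best,
      conditionRatios = conditionRatios, templateRatios = set@ratios,
      nBoot = as.integer(nBoot),
      seed = if (is.null(seed)) NA_integer_ else as.integer(seed))
}

# Width-weighted in-out index of samples relative to a window.
.inOutIndex <- function(samples, lo, hi, widthIn, widthOut) {
  s <- samples[!is.na(samples)]
  nIn <- sum(s >= lo & s <= hi)
  nIn / widthIn - (length(s) - nIn) / widthOut
}

#' On-stimulus window test for one condition
#'
#' Tests whether the bootstrap distribution of maximally correlated
#' prototypes concentrates in a narrow window centered on the stimulus
#' ratio. The window runs from the midpoint to the preceding condition to
#' the midpoint to the following one (edge conditions use the symmetric
#' half-step); the in-out index is the in-window count minus the out-window
#' count, each divided by the ratio span it covers, so a positive index
#' marks on-stimulus concentration. The full bootstrap is re-run `nOuter`
#' times; `p` is the add-one proportion of runs with a non-negative index, so
#' a small `p` (Bonferroni-corrected by the number of conditions) flags the
#' response as off-stimulus.
#'
#' @inheritParams bootstrapBestPrototype
#' @param conditionIndex which condition column to test.
#' @param conditions the stimulus continuum data frame.
#' @param nOuter outer repetitions of the bootstrap (default 500).
#' @param nBoot inner bootstrap iterations per run (default 1000).
#' @return list with `center`, `widthIn`, `widthOut`, `indexSamples`
#'   (one index per outer run), `p`, `pBonf`, `offStimulus`.
#' @export
onStimulusTest <- function(corrected, set, conditionIndex, conditions,
                           nBoot = 1000, nOuter = 500, seed = NULL) {
  stopifnot(is(set, "PrototypeSet"))
  rGrid <- conditions$r
  ci <- .assertCount(conditionIndex, "conditionIndex", min = 1)
  if (ci > length(rGrid)) stop("'conditionIndex' outside the continuum")
  step <- mean(diff(rGrid))
  lo <- if (ci > 1) (rGrid[ci - 1] + rGrid[ci]) / 2 else rGrid[ci] - step / 2
  hi <- if (ci < length(rGrid)) (rGrid[ci] + rGrid[ci + 1]) / 2
        else rGrid[ci] + step / 2
  widthIn <- hi - lo
  widthOut <- (max(set@ratios) - min(set@ratios)) - widthIn
  nP <- dim(corrected)[3]
  Ts <- .standardizeTemplates(set)
  C <- corrected[, ci, , drop = TRUE]
  idx <- withSeed(seed, {
    chunk <- max(1L, min(nOuter, floor(5e5 / nBoot)))
    out <- numeric(nOuter)
    done <- 0L
    while (done < nOuter) {
      k <- min(chunk, nOuter - done)
      W <- .drawWeights(nP, k * nBoot)
      best <- set@ratios[.bestForDraws(C, Ts, W)]
      dim(best) <- c(nBoot, k)
      out[done + seq_len(k)] <- apply(best, 2, .inOutIndex,
                                      lo = lo, hi = hi,
                                      widthIn = widthIn, widthOut = widthOut)
      done <- done + k
    }
    out
  })
  p <- (sum(idx >= 0) + 1) / (nOuter + 1)
  pB <- bonferroniCorrect(p, length(rGrid))
  list(center = rGrid[ci], widthIn = widthIn, widthOut = widthOut,
       indexSamples = idx, p = p, pBonf = pB, offStimulus = pB < 0.05)
}

#' Category-pooled prototype peaks and their significance
#'
#' Splits the conditions at the category boundary, pools each category's
#' bootstrap best-prototype ratios, and estimates the pooled density with a
#' Gaussian kernel (Silverman's rule-of-thumb bandwidth) on a fixed grid
#' over the template range. Peaks are local maxima exceeding
#' `minPeakFrac` x the mean grid density. Each peak is tested with a window
#' of one condition-grid step centered on it against flanking regions of
#' half that width on each side, using the width-weighted in-out index; `p`
#' is the add-one proportion of `nOuter` fresh bootstrap runs with index
#' <= 0, Bonferroni-corrected by the total number of peaks tested.
#'
#' @inheritParams onStimulusTest
#' @param boundaryAfter category split (last condition of the first
#'   category).
#' @param minPeakFrac peak height threshold as a fraction of the mean
#'   density (default 0.1).
#' @return data frame with columns `category`, `peak`, `index`, `p`,
#'   `pBonf`, `bandwidth`.
#' @export
pooledPeaks <- function(corrected, set, boundaryAfter, conditions,
                        nBoot = 1000, nOuter = 500, seed = NULL,
                        minPeakFrac = 0.1) {
  stopifnot(is(set, "PrototypeSet"))
  n <- nrow(conditions)
  b <- .assertCount(boundaryAfter, "boundaryAfter", min = 1)
  if (b >= n) stop("'boundaryAfter' must leave both categories non-empty")
  cats <- list(small = seq_len(b), big = seq(b + 1, n))
  step <- mean(diff(conditions$r))
  base <- bootstrapBestPrototype(corrected, set, nBoot = nBoot,
                                 seed = childSeed(seed, 0),
                                 conditionRatios = conditions$r)
  # fresh pooled samples per outer run, chunked over all conditions at once
  nP <- dim(corrected)[3]
  Ts <- .standardizeTemplates(set)
  outerBest <- withSeed(childSeed(seed, 1), {
    lapply(seq_len(nOuter), function(i) {
      W <- .drawWeights(nP, nBoot)
      vapply(seq_len(n), function(ci)
        set@ratios[.bestForDraws(corrected[, ci, , drop = TRUE], Ts, W)],
        numeric(nBoot))
    })
  })
  rows <- list()
  for (cat in names(cats)) {
    pooled <- as.vector(base@bestRatios[, cats[[cat]]])
    pooled <- pooled[!is.na(pooled)]
    if (!length(pooled)) stop(sprintf("category '%s' has no pooled samples", cat))
    dens <- stats::density(pooled, bw = "nrd0", from = min(set@ratios),
                           to = max(set@ratios), n = 512)
    pk <- pracma::findpeaks(dens$y, minpeakheight = minPeakFrac * mean(dens$y))
    if (is.null(pk)) next
    for (j in seq_len(nrow(pk))) {
      center <- dens$x[pk[j, 2]]
      lo <- center - step / 2; hi <- center + step / 2
      obs <- .inOutIndexFlanks(pooled, center, step)
      idxs <- vapply(outerBest, function(bm) {
        s <- as.vector(bm[, cats[[cat]]])
        .inOutIndexFlanks(s[!is.na(s)], center, step)
      }, numeric(1))
      p <- (sum(idxs <= 0) + 1) / (nOuter + 1)
      rows[[length(rows) + 1L]] <- data.frame(
        category = cat, peak = center, index = obs, p = p,
        bandwidth = dens$bw)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(category = character(0), peak = numeric(0),
                      index = numeric(0), p = numeric(0),
                      pBonf = numeric(0), bandwidth = numeric(0)))
  out$pBonf <- bonferroniCorrect(out$p, nrow(out))
  out[, c("category", "peak", "index", "p", "pBonf", "bandwidth")]
}

# In-out index of a peak window against its directly flanking regions
# (each flank half the window width, so in and out spans are equal).
.inOutIndexFlanks <- function(samples, center, width) {
  lo <- center - width / 2; hi <- center + width / 2
  nIn <- sum(samples >= lo & samples <= hi)
  nOut <- sum((samples >= lo - width / 2 & samples < lo) |
              (samples > hi & samples <= hi + width / 2))
  nIn / width - nOut / width
}

#' Export a prototype distribution as CSV
#'
#' Long format: condition, iteration, best_ratio.
#'
#' @param dist a [PrototypeDistribution].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writePrototypeDistribution <- function(dist, path) {
  stopifnot(is(dist, "PrototypeDistribution"))
  long <- data.frame(
    condition = rep(seq_len(ncol(dist@bestRatios)), each = dist@nBoot),
    iteration = rep(seq_len(dist@nBoot), ncol(dist@bestRatios)),
    best_ratio = as.vector(dist@bestRatios))
  utils::write.table(long, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
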