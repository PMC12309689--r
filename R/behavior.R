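#' Remove accidental extra taps
#'
#' Scans sorted onsets left to right and drops any tap closer than `minGap`
#' to the previously retained tap, so retention is greedy: in a chain of
#' near-coincident taps the first survives and later ones are judged against
#' it.
#'
#' @param onsetsS sorted tap-onset times in seconds.
#' @param minGap minimum inter-tap gap in seconds (default 0.030).
#' @return the cleaned onset vector; all successive gaps are >= `minGap`.
#' @export
cleanExtraTaps <- function(onsetsS, minGap = 0.030) {
  if (!length(onsetsS)) return(onsetsS)
  if (is.unsorted(onsetsS)) stop("'onsetsS' must be sorted")
  keep <- logical(length(onsetsS))
  keep[1] <- TRUE
  last <- onsetsS[1]
  for (i in seq_along(onsetsS)[-1]) {
    if (onsetsS[i] - last >= minGap) {
      keep[i] <- TRUE
      last <- onsetsS[i]
    }
  }
  onsetsS[keep]
}

.nearestTone <- function(onsets, tones) {
  vapply(onsets, function(o) tones[which.min(abs(tones - o))], numeric(1))
}

#' Mean tap-tone asynchrony across trials
#'
#' Asynchrony of a tap is its onset minus the nearest tone onset; humans
#' typically anticipate the tone, giving negative values. The participant
#' mean is computed across all supplied trials and conditions, as required
#' before asynchrony correction.
#'
#' @param trials list of trials, each a list with elements `onsets` (tap
#'   times) and `tones` (tone times), both in seconds.
#' @return mean asynchrony in seconds.
#' @export
meanTapAsynchrony <- function(trials) {
  asyn <- unlist(lapply(trials, function(tr) {
    if (!length(tr$onsets)) return(numeric(0))
    tr$onsets - .nearestTone(tr$onsets, tr$tones)
  }))
  if (!length(asyn)) stop("no taps available to estimate the mean asynchrony")
  mean(asyn)
}

#' Asynchrony-correct tap onsets and flag outliers
#'
#' Subtracts the participant's mean tap-tone asynchrony from every onset and
#' flags taps whose residual asynchrony to the nearest tone exceeds
#' `maxResid` (default 80 ms, i.e. less than half the smallest stimulus
#' interonset interval) as excluded.
#'
#' @param onsetsS tap onsets of one trial, seconds.
#' @param toneTimes tone onsets of the trial, seconds.
#' @param maxResid exclusion threshold on |residual asynchrony|, seconds.
#' @param meanAsynchrony the participant-level mean asynchrony; when `NULL`
#'   it is estimated from this trial alone (supply the cross-trial value from
#'   [meanTapAsynchrony()] for the standard pipeline).
#' @return list with `onsets` (corrected times), `excluded` (logical flags),
#'   `meanAsynchrony` (the value subtracted).
#' @export
asynchronyCorrect <- function(onsetsS, toneTimes, maxResid = 0.080,
                              meanAsynchrony = NULL) {
  if (!length(onsetsS)) stop("no taps to correct")
  if (!length(toneTimes)) stop("no tone times supplied")
  if (is.null(meanAsynchrony))
    meanAsynchrony <- mean(onsetsS - .nearestTone(onsetsS, toneTimes))
  corrected <- onsetsS - meanAsynchrony
  resid <- corrected - .nearestTone(corrected, toneTimes)
  list(onsets = corrected, excluded = abs(resid) > maxResid,
       meanAsynchrony = meanAsynchrony)
}

#' Per-cycle intertap-interval ratios of a synchronization trial
#'
#' For every repetition of the rhythmic pattern, the cycle's two tones plus
#' the first tone of the directly following repetition are each matched with
#' the closest asynchrony-corrected tap; then `ITI1 = tap2 - tap1`,
#' `ITI2 = tap3 - tap2` and the ratio is `ITI1 / (ITI1 + ITI2)`. A cycle is
#' excluded (recorded, never raised) when any tone lacks an exclusive nearest
#' tap: if one tap is nearest to two tones, the pairing with the smaller
#' asynchrony wins and the losing tone is unmatched. The loop boundary at
#' `nCycles * patternDur` — the onset the next pattern would have — serves as
#' matching target for the final cycle, so all repetitions are scoreable.
#'
#' @param onsetsS cleaned, asynchrony-corrected tap onsets (excluded taps
#'   already removed), seconds.
#' @param sequence the [StimulusSequence] that paced the trial.
#' @return list with `perCycle` (data frame: cycle, ratio, excluded_reason),
#'   `meanRatio` (mean over valid cycles), `nValid`.
#' @export
itiRatios <- function(onsetsS, sequence) {
  stopifnot(is(sequence, "StimulusSequence"))
  n <- sequence@nCycles
  tones <- c(sequence@eventTimes, n * sequence@patternDur)
  taps <- sort(onsetsS)
  match_of <- rep(NA_integer_, length(tones))
  if (length(taps)) {
    nearest <- vapply(tones, function(t) which.min(abs(taps - t)), integer(1))
    dist <- abs(taps[nearest] - tones)
    # exclusive-nearest resolution: smaller asynchrony wins a contested tap
    for (tapIdx in unique(nearest)) {
      claimants <- which(nearest == tapIdx)
      winner <- claimants[which.min(dist[claimants])]
      match_of[winner] <- tapIdx
    }
  }
  cycle <- seq_len(n)
  ratio <- rep(NA_real_, n)
  reason <- rep(NA_character_, n)
  for (k in cycle) {
    ti <- c(2 * k - 1, 2 * k, 2 * k + 1)   # tone indices incl. next cycle's first
    mi <- match_of[ti]
    if (anyNA(mi)) { reason[k] <- "unmatched_tone"; next }
    t3 <- taps[mi]
    iti1 <- t3[2] - t3[1]
    iti2 <- t3[3] - t3[2]
    if (iti1 <= 0 || iti2 <= 0) { reason[k] <- "nonmonotonic_taps"; next }
    ratio[k] <- iti1 / (iti1 + iti2)
  }
  valid <- !is.na(ratio)
  list(perCycle = data.frame(cycle = cycle, ratio = ratio,
                             excluded_reason = reason),
       meanRatio = if (any(valid)) mean(ratio[valid]) else NA_real_,
       nValid = sum(valid))
}

.sigmoid4p <- function(x, a, b, k, x0) a + (b - a) / (1 + exp(-k * (x - x0)))

.fitSigmoid <- function(x, y) {
  lo <- min(y); hi <- max(y)
  starts <- lapply(c(10, 30, 60, 120, 240), function(k0)
    list(a = lo, b = hi, k = k0, x0 = stats::median(x)))
  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(y ~ a + (b - a) / (1 + exp(-k * (x - x0))),
                        start = st, control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::residuals(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best))
    stop("sigmoid fit failed to converge from all deterministic starts")
  best$fit
}

.heldOutR2 <- function(yObs, yHat) {
  ssTot <- sum((yObs - mean(yObs))^2)
  if (ssTot == 0) return(NA_real_)
  1 - sum((yObs - yHat)^2) / ssTot
}

#' Sigmoid versus linear characterization of produced interval ratios
#'
#' Fits a 4-parameter logistic
#' `y = a + (b - a) / (1 + exp(-k (x - x0)))` (free asymptotes; threshold is
#' the inflection `x0`) and a straight line to mean produced ratios pooled
#' across participants, both by least squares. Out-of-sample performance is
#' assessed by leave-one-participant-out cross-validation (per-fold held-out
#' R^2 against the held-out participant's data), and the two models are
#' compared with a Wilcoxon rank-sum test on the two sets of per-fold R^2. A
#' categorical (step-like) mapping favors the sigmoid; a faithful
#' reproduction of the stimulus ratios favors neither.
#'
#' @param x stimulus first-interval ratios, one per observation.
#' @param y mean produced intertap-interval ratios, matching `x`.
#' @param groups participant identifier per observation (>= 3 participants,
#'   each contributing all conditions).
#' @return list with elements `sigmoid` and `linear` (each: `kind`, `params`,
#'   `r2`, `cvR2` per fold), `threshold` (sigmoid `x0`), `comparisonP`.
#' @export
fitResponseCurves <- function(x, y, groups) {
  stopifnot(length(x) == length(y), length(groups) == length(x))
  ids <- unique(groups)
  if (length(ids) < 3) stop("'groups' must contain at least 3 participants")
  sig <- .fitSigmoid(x, y)
  lin <- stats::lm(y ~ x)
  r2of <- function(yhat) .heldOutR2(y, yhat)
  cvS <- cvL <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    hold <- groups == id
    sfit <- .fitSigmoid(x[!hold], y[!hold])
    lfit <- stats::lm(y ~ x, subset = !hold)
    cvS[as.character(id)] <-
      .heldOutR2(y[hold], stats::predict(sfit, list(x = x[hold])))
    cvL[as.character(id)] <-
      .heldOutR2(y[hold], stats::predict(lfit, data.frame(x = x[hold])))
  }
  cmp <- suppressWarnings(stats::wilcox.test(cvS, cvL))
  ps <- coef(sig)
  list(sigmoid = list(kind = "sigmoid", params = ps,
                      r2 = r2of(stats::predict(sig)), cvR2 = cvS),
       linear = list(kind = "linear", params = coef(lin),
                     r2 = summary(lin)$r.squared, cvR2 = cvL),
       threshold = unname(ps["x0"]),
       comparisonP = cmp$p.value)
}

#' Fit the 4-parameter logistic to one participant's ratios
#'
#' Same model and deterministic multi-start as [fitResponseCurves()], for
#' per-participant threshold estimates.
#'
#' @param x stimulus ratios.
#' @param y produced ratios.
#' @return list with `params` and `threshold` (`x0`).
#' @export
fitSigmoidParticipant <- function(x, y) {
  fit <- .fitSigmoid(x, y)
  ps <- coef(fit)
  list(params = ps, threshold = unname(ps["x0"]))
}

#' Chi-square test of uniformity of produced interval ratios
#'
#' Bins pooled produced ratios into `nBins` equal bins spanning `range`
#' (ratios outside the range count toward the nearest edge bin) and compares
#' observed counts against the uniform expectation `n / nBins`;
#' `df = nBins - 1`. A significant statistic indicates clustering of produced
#' ratios, e.g. around category prototypes.
#'
#' @param ratios pooled produced ratios.
#' @param nBins number of bins (default 13, one per stimulus condition).
#' @param range `c(min, max)` of the stimulus ratio range (default
#'   `c(0.5, 2/3)`).
#' @return list with `chi2`, `df`, `p`, `counts`.
#' @export
chi2Uniformity <- function(ratios, nBins = 13, range = c(0.5, 2/3)) {
  if (!length(ratios)) stop("'ratios' must contain at least one value")
  .assertCount(nBins, "nBins", min = 2)
  breaks <- seq(range[1], range[2], length.out = nBins + 1)
  bin <- findInterval(ratios, breaks, rightmost.closed = TRUE)
  bin <- pmin(pmax(bin, 1L), nBins)  # edge-clamp out-of-range ratios
  counts <- tabulate(bin, nbins = nBins)
  expected <- length(ratios) / nBins
  chi2 <- sum((counts - expected)^2 / expected)
  df <- nBins - 1
  list(chi2 = chi2, df = df,
       p = stats::pchisq(chi2, df, lower.tail = FALSE), counts = counts)
}

#' Read / write tap logs
#'
#' Delimited text with columns `participant` (optional on read), `condition`,
#' `trial`, `onset_s`.
#'
#' @param path file path.
#' @return `readTapLog`: data frame of tap onsets.
#' @export
readTapLog <- function(path) {
  d <- utils::read.table(path, header = TRUE, sep = ",")
  need <- c("condition", "trial", "onset_s")
  if (!all(need %in% names(d)))
    stop("tap log must contain columns: ", paste(need, collapse = ", "))
  d
}

#' @rdname readTapLog
#' @param taps data frame with the tap-log columns.
#' @export
writeTapLog <- function(taps, path) {
  utils::write.table(taps, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full intertap-interval pipeline for one participant
#'
#' Cleaning (30-ms rule), participant-level mean-asynchrony correction,
#' removal of taps with residual asynchrony beyond 80 ms, per-cycle ratio
#' extraction, and averaging across a condition's cycles and trials.
#'
#' @param taps tap-log data frame (`condition`, `trial`, `onset_s`).
#' @param conditions the condition continuum.
#' @param nCycles pattern repetitions per trial.
#' @param minGap,maxResid cleaning parameters, see [cleanExtraTaps()] and
#'   [asynchronyCorrect()].
#' @return list with `meanRatios` (one per condition), `cycles` (long data
#'   frame with per-cycle ratios and exclusion reasons), `meanAsynchrony`.
#' @export
participantITI <- function(taps, conditions, nCycles = 30, minGap = 0.030,
                           maxResid = 0.080) {
  seqs <- lapply(seq_len(nrow(conditions)), function(i)
    buildSequence(conditions[i, ], nCycles = nCycles))
  trials <- list()
  for (ci in unique(taps$condition)) for (tr in unique(taps$trial[taps$condition == ci])) {
    on <- sort(taps$onset_s[taps$condition == ci & taps$trial == tr])
    trials[[length(trials) + 1L]] <- list(
      condition = ci, trial = tr,
      onsets = cleanExtraTaps(on, minGap = minGap),
      # the loop boundary acts as the next pattern's first tone
      tones = c(eventTimes(seqs[[ci]]), nCycles * conditions$pattern_s[1]))
  }
  mAsyn <- meanTapAsynchrony(trials)
  rows <- list()
  for (tr in trials) {
    if (!length(tr$onsets)) next
    ac <- asynchronyCorrect(tr$onsets, tr$tones, maxResid = maxResid,
                            meanAsynchrony = mAsyn)
    res <- itiRatios(ac$onsets[!ac$excluded], seqs[[tr$condition]])
    pc <- res$perCycle
    pc$condition <- tr$condition
    pc$trial <- tr$trial
    rows[[length(rows) + 1L]] <- pc
  }
  cycles <- do.call(rbind, rows)
  meanRatios <- vapply(seq_len(nrow(conditions)), function(ci) {
    v <- cycles$ratio[cycles$condition == ci]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
  list(meanRatios = meanRatios, cycles = cycles, meanAsynchrony = mAsyn)
}
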