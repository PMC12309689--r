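#' Construct a continuum of two-interval rhythm conditions
#'
#' Builds `n` rhythm conditions whose first-interval ratios
#' `r = IOI1 / (IOI1 + IOI2)` are linearly spaced between `rStart` and `rEnd`
#' inclusive. The defaults reproduce the 13-condition continuum from isochrony
#' (1:1, r = 0.50) to a long-short 2:1 pattern (r = 2/3) with a 750-ms pattern.
#'
#' @param n number of conditions (>= 2).
#' @param rStart,rEnd first and last ratio, `0 < rStart < rEnd < 1`.
#' @param patternDur pattern duration in seconds.
#' @return data frame with columns `index`, `r`, `pattern_s`, `ioi1_s`,
#'   `ioi2_s`, one row per condition.
#' @examples
#' cond <- makeConditionContinuum()
#' cond$r[7]   # continuum midpoint, approximately 0.5833
#' @export
makeConditionContinuum <- function(n = 13, rStart = 0.5, rEnd = 2/3,
                                   patternDur = 0.75) {
  .assertCount(n, "n", min = 2)
  .assertScalar(rStart, "rStart")
  .assertScalar(rEnd, "rEnd")
  .assertScalar(patternDur, "patternDur", min = 0)
  if (rStart <= 0 || rStart >= 1)
    stop("'rStart' must lie strictly within (0, 1)")
  if (rEnd <= 0 || rEnd >= 1)
    stop("'rEnd' must lie strictly within (0, 1)")
  if (rStart >= rEnd) stop("'rStart' must be smaller than 'rEnd'")
  if (patternDur <= 0) stop("'patternDur' must be positive")
  r <- seq(rStart, rEnd, length.out = n)
  data.frame(index = seq_len(n), r = r, pattern_s = patternDur,
             ioi1_s = r * patternDur, ioi2_s = (1 - r) * patternDur)
}

#' Build a seamlessly looped stimulus sequence
#'
#' Loops a two-interval pattern `nCycles` times: cycle `k` (0-based) carries
#' tones at `k * patternDur` and `k * patternDur + r * patternDur`, so the
#' first tone of each cycle doubles as the (virtual) third tone of the
#' previous one.
#'
#' @param condition a single row of [makeConditionContinuum()], or a ratio in
#'   (0, 1) combined with `patternDur`.
#' @param nCycles number of pattern repetitions (>= 1).
#' @param patternDur pattern duration in seconds; ignored when `condition` is
#'   a continuum row.
#' @return a [StimulusSequence].
#' @examples
#' sq <- buildSequence(makeConditionContinuum()[1, ], nCycles = 30)
#' recordingDuration(sq)  # 22.5 s
#' @export
buildSequence <- function(condition, nCycles = 30, patternDur = 0.75) {
  .assertCount(nCycles, "nCycles", min = 1)
  if (is.data.frame(condition)) {
    if (nrow(condition) != 1L)
      stop("'condition' must be a single continuum row")
    r <- condition$r
    patternDur <- condition$pattern_s
    idx <- as.integer(condition$index)
  } else {
    .assertScalar(condition, "condition")
    r <- condition
    idx <- NA_integer_
  }
  if (r <= 0 || r >= 1) stop("'condition' ratio must lie in (0, 1)")
  k <- seq_len(nCycles) - 1
  events <- as.vector(rbind(k * patternDur, (k + r) * patternDur))
  new("StimulusSequence", conditionIndex = idx, r = r,
      patternDur = patternDur, nCycles = as.integer(nCycles),
      eventTimes = events)
}

#' Pure-tone specification
#'
#' @param carrierHz carrier frequency in Hz (default 300).
#' @param durS tone duration in seconds (default 0.05).
#' @param rampS linear onset/offset ramp duration in seconds (default 0.01);
#'   the two ramps may not exceed the tone duration.
#' @return a list with class `"toneSpec"`.
#' @export
toneSpec <- function(carrierHz = 300, durS = 0.05, rampS = 0.01) {
  .assertScalar(carrierHz, "carrierHz")
  .assertScalar(durS, "durS", min = 0)
  .assertScalar(rampS, "rampS", min = 0)
  if (carrierHz <= 0) stop("'carrierHz' must be positive")
  if (2 * rampS > durS) stop("'rampS': 2 * rampS must not exceed durS")
  structure(list(carrierHz = carrierHz, durS = durS, rampS = rampS),
            class = "toneSpec")
}

#' Render a stimulus sequence as audio
#'
#' Places an identical ramped pure tone at every event time of the sequence;
#' the signal is zero elsewhere and peak-normalized to `peak` full scale.
#'
#' @param sequence a [StimulusSequence].
#' @param tone a [toneSpec()].
#' @param fs audio sampling rate in Hz; must satisfy `fs >= 2 * carrierHz`.
#' @param peak peak amplitude after normalization (default 0.9).
#' @return a one-channel [ContinuousRecording].
#' @export
renderAudio <- function(sequence, tone = toneSpec(), fs = 44100, peak = 0.9) {
  stopifnot(is(sequence, "StimulusSequence"), inherits(tone, "toneSpec"))
  .assertScalar(fs, "fs", min = 0)
  if (fs < 2 * tone$carrierHz)
    stop("'fs' undersamples the carrier: need fs >= 2 * carrierHz")
  ev <- sequence@eventTimes
  if (length(ev) > 1 && min(diff(ev)) < tone$durS)
    stop("overlapping tones: tone duration exceeds the smallest interonset interval")
  n <- round(recordingDuration(sequence) * fs)
  x <- numeric(n)
  nt <- round(tone$durS * fs)
  if (length(ev) && nt > 0) {
    tt <- (seq_len(nt) - 1) / fs
    env <- pmin(1, tt / tone$rampS, (tone$durS - 1 / fs - tt) / tone$rampS)
    env <- pmax(env, 0)
    wave <- sin(2 * pi * tone$carrierHz * tt) * env
    for (e in ev) {
      i0 <- round(e * fs) + 1
      i1 <- min(i0 + nt - 1, n)
      x[i0:i1] <- x[i0:i1] + wave[seq_len(i1 - i0 + 1)]
    }
    pk <- max(abs(x))
    if (pk > 0) x <- x * (peak / pk)
  }
  new("ContinuousRecording", samples = matrix(x, nrow = 1), fs = fs,
      channelLabels = "audio", t0 = 0,
      processingLog = sprintf("rendered audio (%g Hz carrier)", tone$carrierHz))
}

#' Acoustic similarity matrix of a condition continuum
#'
#' Entry (i, j) is `1 - |r_i - r_j|`: similarity falls off linearly with the
#' distance between the stimulus first-interval ratios, reflecting the equal
#' spacing of the continuum.
#'
#' @param conditions a continuum from [makeConditionContinuum()].
#' @return an [RSM] of kind `"one-minus-absdiff"`.
#' @export
acousticRSM <- function(conditions) {
  if (!is.data.frame(conditions) || nrow(conditions) < 2)
    stop("'conditions' must contain at least 2 conditions")
  rsmFromScalars(conditions$r, labels = as.character(conditions$index))
}

#' Family of two-category theoretical model RSMs
#'
#' One binary model per admissible boundary position: conditions up to the
#' boundary form one category, the rest the other, and similarity is 1 within
#' and 0 across categories. Boundaries leaving a category with fewer than
#' `minSpan` conditions are excluded (such models cannot test within-category
#' generalization), so a 13-condition continuum yields 10 models.
#'
#' @param nConditions number of conditions on the continuum.
#' @param minSpan minimum category span (default 2).
#' @return list of [CategoricalModelRSM], named by boundary position.
#' @examples
#' length(categoricalModelSet(13))  # 10
#' @export
categoricalModelSet <- function(nConditions = 13, minSpan = 2) {
  .assertCount(nConditions, "nConditions", min = 2)
  .assertCount(minSpan, "minSpan", min = 1)
  if (nConditions < 2 * minSpan)
    stop("'nConditions' must be at least 2 * minSpan")
  boundaries <- seq(minSpan, nConditions - minSpan)
  models <- lapply(boundaries, function(b) {
    member <- rep(1:2, c(b, nConditions - b))
    m <- outer(member, member, "==") * 1
    new("CategoricalModelRSM", matrix = m, kind = "binary",
        labels = as.character(seq_len(nConditions)),
        boundaryAfter = as.integer(b))
  })
  names(models) <- as.character(boundaries)
  models
}

#' Boundary position of a categorical model on the ratio scale
#'
#' The boundary ratio is the midpoint between the ratio of the last condition
#' of the first category and the ratio of the first condition of the second.
#'
#' @param model a [CategoricalModelRSM], or a boundary index.
#' @param conditions the condition continuum the model refers to.
#' @return boundary ratio (unitless).
#' @export
boundaryRatio <- function(model, conditions) {
  b <- if (is(model, "CategoricalModelRSM")) model@boundaryAfter
       else .assertCount(model, "model", min = 1)
  if (b < 1 || b >= nrow(conditions))
    stop("'model' boundary does not fit the condition list")
  (conditions$r[b] + conditions$r[b + 1]) / 2
}

#' Serialize a condition design to JSON
#'
#' @param conditions condition continuum.
#' @param nCycles pattern repetitions per trial.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeDesign <- function(conditions, nCycles, path) {
  jsonlite::write_json(list(
    n_conditions = nrow(conditions),
    pattern_s = conditions$pattern_s[1],
    n_cycles = nCycles,
    conditions = conditions), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a condition design written by [writeDesign()]
#' @param path JSON file.
#' @return list with elements `conditions` (data frame) and `nCycles`.
#' @export
readDesign <- function(path) {
  d <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(conditions = as.data.frame(d$conditions), nCycles = d$n_cycles)
}
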