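#' Default analysis configuration
#'
#' Named list of pipeline settings mirroring the study conditions: 13
#' conditions, frequencies of interest up to 8 Hz for EEG and 16 Hz for
#' tapping, 5000 individual / 10000 group permutation iterations, Bonferroni
#' over the 10 categorical models, 1000-iteration prototype bootstrap with
#' 500 outer repetitions, and the nine-channel frontocentral pool. Override
#' entries via `modifyList` semantics in [runPipeline()] or a YAML file.
#'
#' @return named list of settings.
#' @export
defaultPipelineConfig <- function() {
  list(
    dataset = NULL, out = NULL, seed = 1L,
    fMaxTapHz = 16, fMaxEEGHz = 8, zCrit = 3.09,
    channelPool = "all",                  # "all" or "frontocentral"
    nIterIndividual = 5000, nIterGroup = 10000,
    nBootPrototype = 1000, nOuterPrototype = 500,
    nBootMedian = 10000, bonferroniM = 10,
    doPrototypes = FALSE, doEEG = TRUE)
}

#' Read a YAML pipeline configuration
#'
#' Entries omitted from the file keep their [defaultPipelineConfig()] value.
#'
#' @param path YAML file.
#' @return named configuration list.
#' @export
readPipelineConfig <- function(path) {
  utils::modifyList(defaultPipelineConfig(), yaml::read_yaml(path))
}

#' Simulate a complete dataset directory
#'
#' Writes a design JSON, per-participant tap logs (CSV), and optionally
#' per-participant, per-condition trial-averaged EEG-like recordings
#' (BrainVision), in the layout [runPipeline()] consumes.
#'
#' @param spec a [SimulationSpec].
#' @param dir output directory (created).
#' @param seed study-level seed; participant seeds are derived from it.
#' @param what `"tap"`, `"eeg"` or `"both"`.
#' @param nChannels,nTrialsEEG scaled-down EEG overrides (defaults from the
#'   spec).
#' @return the directory, invisibly.
#' @export
simulateDataset <- function(spec, dir, seed = 1, what = c("tap", "both", "eeg"),
                            nChannels = spec@nChannels,
                            nTrialsEEG = spec@nTrialsEEG) {
  what <- match.arg(what)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeDesign(spec@conditions, spec@nCycles, file.path(dir, "design.json"))
  if (what %in% c("tap", "both")) {
    dir.create(file.path(dir, "tap"), showWarnings = FALSE)
    for (p in seq_len(spec@nParticipants)) {
      taps <- simulateTapParticipant(spec, childSeed(seed, p))
      writeTapLog(taps, file.path(dir, "tap", sprintf("participant_%02d.csv", p)))
    }
  }
  if (what %in% c("eeg", "both")) {
    dir.create(file.path(dir, "eeg"), showWarnings = FALSE)
    for (p in seq_len(spec@nParticipants)) {
      recs <- simulateEEGParticipant(spec, childSeed(seed, 10000 + p),
                                     nChannels = nChannels,
                                     nTrials = nTrialsEEG)
      for (ci in seq_along(recs))
        bvWrite(recs[[ci]],
                file.path(dir, "eeg", sprintf("p%02d_c%02d.vhdr", p, ci)))
    }
  }
  invisible(dir)
}

# Trial-averaged tap-onset impulse trains per condition for one participant.
.tapOnsetSpectra <- function(taps, conditions, nCycles, fs = 256) {
  T <- conditions$pattern_s[1]
  dur <- nCycles * T
  lapply(seq_len(nrow(conditions)), function(ci) {
    sub <- taps[taps$condition == ci, ]
    trials <- unique(sub$trial)
    trains <- lapply(trials, function(tr)
      samples(impulseTrain(sub$onset_s[sub$trial == tr & sub$onset_s < dur],
                           fs = fs, durationS = dur))[1, ])
    avg <- Reduce(`+`, trains) / length(trains)
    fftSpectrum(avg, fs = fs)
  })
}

# Frequencies of interest: harmonics up to fMax, truncated to the leading run
# of significant grand-average z-scores; falls back to the full set (with a
# warning) when even the first harmonic fails the criterion.
.selectFois <- function(grandMag, patternDur, fMaxHz, dfHz, zCrit) {
  fois <- harmonicFrequencies(patternDur, fMaxHz, dfHz)
  z <- foiZscores(grandMag, fois)
  sel <- consecutiveSignificant(fois, z, zCrit)
  if (!length(sel@harmonics)) {
    warning("first harmonic not significant in the grand average; keeping all harmonics")
    sel <- fois
  }
  list(fois = sel, z = z)
}

#' Run the end-to-end analysis pipeline
#'
#' Consumes a dataset directory (`design.json`, `tap/participant_*.csv`,
#' optionally `eeg/p*_c*.vhdr`), executes the behavioral intertap-interval
#' analysis, frequency-domain RSA of tap-onset signals (and of EEG when
#' present), group-level permutation inference against the categorical model
#' family, boundary estimation with a bootstrap CI, and optionally the
#' prototype analysis; writes `results.json`, RSM CSV files and a Markdown
#' report into the output directory. Every stochastic step derives its seed
#' from `config$seed` and the report logs exclusion counts.
#'
#' @param config a configuration list (see [defaultPipelineConfig()]), or the
#'   path of a YAML file; `dataset` and `out` entries are required.
#' @return the results list, invisibly (also serialized as JSON).
#' @export
runPipeline <- function(config) {
  if (is.character(config)) config <- readPipelineConfig(config)
  config <- utils::modifyList(defaultPipelineConfig(), config)
  if (is.null(config$dataset) || !dir.exists(config$dataset))
    stop("config$dataset must name an existing dataset directory, got: ",
         if (is.null(config$dataset)) "NULL" else config$dataset)
  if (is.null(config$out)) stop("config$out must name an output directory")
  dir.create(config$out, recursive = TRUE, showWarnings = FALSE)
  designPath <- file.path(config$dataset, "design.json")
  if (!file.exists(designPath)) stop("missing design file: ", designPath)
  design <- readDesign(designPath)
  conditions <- design$conditions
  nCycles <- design$nCycles
  acoustic <- acousticRSM(conditions)
  models <- categoricalModelSet(nrow(conditions))
  results <- list(config = config[setdiff(names(config), c("dataset", "out"))],
                  design = list(nConditions = nrow(conditions),
                                patternS = conditions$pattern_s[1],
                                nCycles = nCycles))

  tapFiles <- sort(list.files(file.path(config$dataset, "tap"),
                              pattern = "\\.csv$", full.names = TRUE))
  if (!length(tapFiles)) stop("no tap logs under ", file.path(config$dataset, "tap"))
  tapLogs <- lapply(tapFiles, readTapLog)
  nP <- length(tapLogs)

  ## --- behavioral ITI analysis -------------------------------------------
  itis <- lapply(tapLogs, participantITI, conditions = conditions,
                 nCycles = nCycles)
  meanRatioMat <- do.call(rbind, lapply(itis, `[[`, "meanRatios"))
  itiRSMs <- lapply(seq_len(nP), function(p)
    rsmFromScalars(meanRatioMat[p, ], labels = conditions$index))
  itiGroup <- permutationTestGroup(itiRSMs, models, acoustic,
                                   nIter = config$nIterGroup,
                                   seed = childSeed(config$seed, 1))
  itiBounds <- vapply(itiGroup$perParticipant$bestBoundary, boundaryRatio,
                      numeric(1), conditions = conditions)
  itiCI <- bootstrapMedianCI(itiBounds, nBoot = config$nBootMedian,
                             seed = childSeed(config$seed, 2))
  pooled <- data.frame(
    x = rep(conditions$r, each = nP),
    y = as.vector(meanRatioMat),
    participant = rep(seq_len(nP), times = nrow(conditions)))
  pooled <- pooled[is.finite(pooled$y), ]
  curves <- fitResponseCurves(pooled$x, pooled$y, pooled$participant)
  allRatios <- unlist(lapply(itis, function(ii)
    ii$cycles$ratio[!is.na(ii$cycles$ratio)]))
  chi2 <- chi2Uniformity(allRatios, nBins = nrow(conditions),
                         range = range(conditions$r))
  results$behavior <- list(
    groupRho = itiGroup$observed,
    groupP = itiGroup$p,
    groupPBonf = bonferroniCorrect(itiGroup$p, config$bonferroniM),
    boundaryMedianRatio = itiCI$median,
    boundaryCI = c(itiCI$ciLow, itiCI$ciHigh),
    sigmoidThreshold = curves$threshold,
    sigmoidVsLinearP = curves$comparisonP,
    chi2 = chi2$chi2, chi2Df = chi2$df, chi2P = chi2$p,
    nValidCycles = vapply(itis, function(ii) sum(!is.na(ii$cycles$ratio)),
                          numeric(1)),
    meanAsynchrony = vapply(itis, `[[`, numeric(1), "meanAsynchrony"))

  ## --- tap-onset fRSA -----------------------------------------------------
  tapSpectra <- lapply(tapLogs, .tapOnsetSpectra, conditions = conditions,
                       nCycles = nCycles)
  grandMag <- Reduce(`+`, lapply(tapSpectra, function(sp)
    Reduce(`+`, lapply(sp, function(s) magnitudeSpectrum(s)[1, ])) /
      length(sp))) / nP
  selTap <- .selectFois(grandMag, conditions$pattern_s[1], config$fMaxTapHz,
                        tapSpectra[[1]][[1]]@fs / tapSpectra[[1]][[1]]@nSamples,
                        config$zCrit)
  tapRSMs <- lapply(tapSpectra, function(sp)
    rsmFromFeatures(vapply(sp, featureVector, fois = selTap$fois,
                           FUN.VALUE = numeric(length(selTap$fois@bins) * 2)),
                    labels = conditions$index))
  tapGroup <- permutationTestGroup(tapRSMs, models, acoustic,
                                   nIter = config$nIterGroup,
                                   seed = childSeed(config$seed, 3))
  tapVsITI <- compareRSMsGroup(tapRSMs, itiRSMs, acoustic,
                               nIter = config$nIterGroup,
                               seed = childSeed(config$seed, 4))
  results$tapOnset <- list(
    fois = selTap$fois@freqs, foiZ = selTap$z,
    groupRho = tapGroup$observed, groupP = tapGroup$p,
    groupPBonf = bonferroniCorrect(tapGroup$p, config$bonferroniM),
    boundaryMedianRatio = stats::median(
      vapply(tapGroup$perParticipant$bestBoundary, boundaryRatio, numeric(1),
             conditions = conditions)),
    vsITIrho = tapVsITI$rho, vsITIp = tapVsITI$p)

  ## --- EEG fRSA (optional) ------------------------------------------------
  eegFiles <- sort(list.files(file.path(config$dataset, "eeg"),
                              pattern = "\\.vhdr$", full.names = TRUE))
  if (isTRUE(config$doEEG) && length(eegFiles)) {
    pid <- sub("^p(\\d+)_c\\d+\\.vhdr$", "\\1", basename(eegFiles))
    eegSpectra <- lapply(unique(pid), function(p) {
      files <- eegFiles[pid == p]
      lapply(files, function(f) fftSpectrum(bvRead(f)))
    })
    grandEEG <- Reduce(`+`, lapply(eegSpectra, function(sp)
      Reduce(`+`, lapply(sp, function(s) colMeans(magnitudeSpectrum(s)))) /
        length(sp))) / length(eegSpectra)
    selEEG <- .selectFois(grandEEG, conditions$pattern_s[1], config$fMaxEEGHz,
                          eegSpectra[[1]][[1]]@fs / eegSpectra[[1]][[1]]@nSamples,
                          config$zCrit)
    pool <- if (identical(config$channelPool, "frontocentral"))
      frontocentralPool() else NULL
    eegRSMs <- lapply(eegSpectra, function(sp) {
      feats <- vapply(sp, function(s) {
        s2 <- if (is.null(pool)) s else poolSpectrum(s, pool)
        featureVector(s2, selEEG$fois)
      }, FUN.VALUE = numeric(length(selEEG$fois@bins) * 2 *
                               (if (is.null(pool)) nChannels(sp[[1]]) else 1)))
      rsmFromFeatures(feats, labels = conditions$index)
    })
    eegGroup <- permutationTestGroup(eegRSMs, models, acoustic,
                                     nIter = config$nIterGroup,
                                     seed = childSeed(config$seed, 5))
    results$eeg <- list(
      fois = selEEG$fois@freqs, foiZ = selEEG$z,
      groupRho = eegGroup$observed, groupP = eegGroup$p,
      groupPBonf = bonferroniCorrect(eegGroup$p, config$bonferroniM),
      boundaryMedianRatio = stats::median(
        vapply(eegGroup$perParticipant$bestBoundary, boundaryRatio,
               numeric(1), conditions = conditions)))
    for (p in seq_along(eegRSMs))
      writeRSM(eegRSMs[[p]], file.path(config$out, sprintf("rsm_eeg_p%02d.csv", p)))
  }

  ## --- prototype analysis (optional) --------------------------------------
  if (isTRUE(config$doPrototypes)) {
    protoSet <- buildPrototypeSet(fMaxHz = config$fMaxTapHz,
                                  patternDur = conditions$pattern_s[1],
                                  nCycles = nCycles)
    nBins <- tapSpectra[[1]][[1]]@nSamples
    mags <- array(0, c(nBins, nrow(conditions), nP))
    for (p in seq_len(nP)) for (ci in seq_len(nrow(conditions)))
      mags[, ci, p] <- magnitudeSpectrum(tapSpectra[[p]][[ci]])[1, ]
    corrected <- foiMagnitudeArray(mags, protoSet@frequencySet)
    dist <- bootstrapBestPrototype(corrected, protoSet,
                                   nBoot = config$nBootPrototype,
                                   seed = childSeed(config$seed, 6),
                                   conditionRatios = conditions$r)
    medBoundary <- stats::median(tapGroup$perParticipant$bestBoundary)
    peaks <- pooledPeaks(corrected, protoSet,
                         boundaryAfter = max(2, min(nrow(conditions) - 2,
                                                    round(medBoundary))),
                         conditions = conditions,
                         nBoot = config$nBootPrototype,
                         nOuter = config$nOuterPrototype,
                         seed = childSeed(config$seed, 7))
    writePrototypeDistribution(dist, file.path(config$out, "prototype_distribution.csv"))
    utils::write.table(peaks, file.path(config$out, "prototype_peaks.csv"),
                       sep = ",", row.names = FALSE, quote = FALSE)
    results$prototypes <- list(peaks = peaks)
  }

  ## --- outputs ------------------------------------------------------------
  for (p in seq_len(nP)) {
    writeRSM(itiRSMs[[p]], file.path(config$out, sprintf("rsm_iti_p%02d.csv", p)))
    writeRSM(tapRSMs[[p]], file.path(config$out, sprintf("rsm_taponset_p%02d.csv", p)))
  }
  jsonlite::write_json(results, file.path(config$out, "results.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  writeLines(.pipelineReport(results), file.path(config$out, "report.md"))
  invisible(results)
}

.pipelineReport <- function(res) {
  fmt <- function(x) formatC(x, digits = 4, format = "g")
  out <- c("# Rhythm categorization analysis report", "",
           sprintf("Design: %d conditions, %g-s pattern, %d cycles.",
                   res$design$nConditions, res$design$patternS,
                   res$design$nCycles), "",
           "## Behavioral (intertap-interval) analysis",
           sprintf("- group categorical rho = %s (P = %s, Bonferroni P = %s)",
                   fmt(res$behavior$groupRho), fmt(res$behavior$groupP),
                   fmt(res$behavior$groupPBonf)),
           sprintf("- median boundary ratio = %s [%s, %s]",
                   fmt(res$behavior$boundaryMedianRatio),
                   fmt(res$behavior$boundaryCI[1]),
                   fmt(res$behavior$boundaryCI[2])),
           sprintf("- sigmoid threshold = %s; sigmoid vs linear P = %s",
                   fmt(res$behavior$sigmoidThreshold),
                   fmt(res$behavior$sigmoidVsLinearP)),
           sprintf("- chi-square(%d) = %s, P = %s", res$behavior$chi2Df,
                   fmt(res$behavior$chi2), fmt(res$behavior$chi2P)),
           sprintf("- valid cycles per participant: %s",
                   paste(res$behavior$nValidCycles, collapse = ", ")), "",
           "## Tap-onset fRSA",
           sprintf("- frequencies of interest: %s Hz",
                   paste(fmt(res$tapOnset$fois), collapse = ", ")),
           sprintf("- group categorical rho = %s (Bonferroni P = %s)",
                   fmt(res$tapOnset$groupRho), fmt(res$tapOnset$groupPBonf)),
           sprintf("- tap-onset vs ITI RSM rho = %s (P = %s)",
                   fmt(res$tapOnset$vsITIrho), fmt(res$tapOnset$vsITIp)))
  if (!is.null(res$eeg))
    out <- c(out, "", "## EEG fRSA",
             sprintf("- group categorical rho = %s (Bonferroni P = %s)",
                     fmt(res$eeg$groupRho), fmt(res$eeg$groupPBonf)),
             sprintf("- median boundary ratio = %s",
                     fmt(res$eeg$boundaryMedianRatio)))
  if (!is.null(res$prototypes))
    out <- c(out, "", "## Prototype peaks",
             utils::capture.output(print(res$prototypes$peaks)))
  out
}
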