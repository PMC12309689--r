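#' Spearman partial correlation of two triangle vectors given a covariate
#'
#' Rank-transforms `x`, `y` and `cov` (average ranks for ties), residualizes
#' the ranks of `x` and `y` on the ranks of `cov` by ordinary least squares
#' (with intercept), and Pearson-correlates the residuals. Pairs with missing
#' values in any vector are excluded pairwise before ranking. Zero-variance
#' residuals make the statistic undefined (`NA`, with a warning).
#'
#' @param x,y lower-triangle vectors of the two similarity matrices.
#' @param cov lower-triangle vector of the covariate matrix (e.g. the
#'   acoustic RSM).
#' @return the partial Spearman rho.
#' @export
spearmanPartial <- function(x, y, cov) {
  stopifnot(length(x) == length(y), length(cov) == length(x))
  ok <- stats::complete.cases(x, y, cov)
  if (sum(ok) < 4) stop("need at least 4 complete pairs")
  rx <- rank(x[ok]); ry <- rank(y[ok]); rc <- rank(cov[ok])
  ex <- stats::lm.fit(cbind(1, rc), rx)$residuals
  ey <- stats::lm.fit(cbind(1, rc), ry)$residuals
  tol <- 1e-10 * length(rx)
  if (stats::sd(ex) < tol || stats::sd(ey) < tol) {
    warning("zero-variance residuals: partial correlation undefined")
    return(NA_real_)
  }
  stats::cor(ex, ey)
}

# Precomputed engine for repeatedly correlating (shuffled) response triangles
# with a fixed model set, partialing out a fixed covariate. Returns closures:
#   $rhos(ranksOfResponse) -> rho per model (vector)
#   $ranks(x)              -> rank transform to feed $rhos
# Ranks of a shuffled vector are the same shuffle of the ranks, so permutation
# loops rank once and permute the rank vector.
.partialEngine <- function(modelTris, covTri) {
  n <- length(covTri)
  Z <- cbind(1, rank(covTri))
  ZtZi <- solve(crossprod(Z))
  resid <- function(r) r - Z %*% (ZtZi %*% crossprod(Z, r))
  tol <- 1e-10 * n
  M <- vapply(modelTris, function(m) {
    e <- resid(rank(m))
    nrm <- sqrt(sum(e^2))
    if (nrm < tol) rep(NA_real_, n) else as.vector(e / nrm)
  }, numeric(n))
  list(
    ranks = function(x) rank(x),
    rhos = function(rx) {
      e <- resid(rx)
      nrm <- sqrt(sum(e^2))
      if (nrm < tol) return(rep(NA_real_, ncol(M)))
      as.vector(crossprod(M, e)) / nrm
    })
}

.modelTriangles <- function(models) lapply(models, lowerTriangle)

.tieBreakBest <- function(rhos, boundaries, nConditions) {
  best <- which(rhos == max(rhos, na.rm = TRUE))
  if (length(best) > 1) {
    center <- (nConditions + 1) / 2
    d <- abs(boundaries[best] + 0.5 - center)
    best <- best[order(d, boundaries[best])]
    message(sprintf("tie among best-fitting models; choosing boundary %d (nearest continuum center)",
                    boundaries[best[1]]))
  }
  best[1]
}

#' Fit the categorical model family to a response RSM
#'
#' Computes the partial Spearman correlation between the response RSM and
#' each two-category model RSM while partialing out the acoustic RSM, and
#' selects the best-fitting model (highest rho; ties broken toward the
#' boundary nearest the continuum center, logged via `message`).
#'
#' @param response the response [RSM].
#' @param models list of [CategoricalModelRSM] from [categoricalModelSet()].
#' @param acoustic the acoustic [RSM] covariate.
#' @return list with `rhoPerModel` (named by boundary), `bestModel`
#'   (boundary index), `bestRho`.
#' @export
fitCategoricalModels <- function(response, models, acoustic) {
  stopifnot(is(response, "RSM"), is(acoustic, "RSM"))
  tri <- lowerTriangle(response)
  boundaries <- vapply(models, boundaryAfter, integer(1))
  n <- nrow(response@matrix)
  ok <- !is.na(tri)
  eng <- .partialEngine(lapply(.modelTriangles(models), `[`, ok),
                        lowerTriangle(acoustic)[ok])
  rhos <- eng$rhos(eng$ranks(tri[ok]))
  names(rhos) <- names(models)
  bi <- .tieBreakBest(rhos, boundaries, n)
  list(rhoPerModel = rhos, bestModel = unname(boundaries[bi]),
       bestRho = unname(rhos[bi]))
}

.permNull <- function(engine, rxObs, nIter) {
  vapply(seq_len(nIter), function(i)
    max(engine$rhos(sample(rxObs)), na.rm = TRUE), numeric(1))
}

#' Individual-level permutation test of categorical structure
#'
#' The observed statistic is the best-fitting model's partial rho. The null
#' distribution shuffles the entries of the response RSM's lower triangle
#' (`nIter` times), refits all models against each shuffle and stores the
#' maximum rho; `p = (count(null >= observed) + 1) / (nIter + 1)`.
#'
#' @param response the response [RSM].
#' @param models the categorical model family.
#' @param acoustic the acoustic covariate [RSM].
#' @param nIter permutation iterations (default 5000).
#' @param seed RNG seed (`NULL` leaves the stream untouched).
#' @return list with `p`, `observed` (best rho), `bestModel`, `null`
#'   (list: `values`, `nIter`, `seed`).
#' @export
permutationTestIndividual <- function(response, models, acoustic,
                                      nIter = 5000, seed = NULL) {
  fit <- fitCategoricalModels(response, models, acoustic)
  tri <- lowerTriangle(response)
  ok <- !is.na(tri)
  eng <- .partialEngine(lapply(.modelTriangles(models), `[`, ok),
                        lowerTriangle(acoustic)[ok])
  rx <- eng$ranks(tri[ok])
  null <- withSeed(seed, .permNull(eng, rx, nIter))
  list(p = (sum(null >= fit$bestRho) + 1) / (nIter + 1),
       observed = fit$bestRho, bestModel = fit$bestModel,
       null = list(values = null, nIter = as.integer(nIter),
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Group-level permutation test of categorical structure
#'
#' The observed statistic is the mean over participants of each participant's
#' best-model partial rho (so the group statistic equals the mean of the
#' individual observed statistics exactly). Each null iteration shuffles
#' every participant's response triangle independently, refits, and stores
#' the mean best rho.
#'
#' @param responses list of per-participant response [RSM]s.
#' @param models,acoustic as in [permutationTestIndividual()].
#' @param nIter permutation iterations (default 10000).
#' @param seed RNG seed.
#' @return list with `p`, `observed` (group mean rho), `perParticipant`
#'   (best rho and boundary per participant), `null`.
#' @export
permutationTestGroup <- function(responses, models, acoustic, nIter = 10000,
                                 seed = NULL) {
  if (length(responses) < 1) stop("need at least one participant")
  covTri <- lowerTriangle(acoustic)
  modelTris <- .modelTriangles(models)
  boundaries <- vapply(models, boundaryAfter, integer(1))
  n <- nrow(acoustic@matrix)
  fits <- lapply(responses, function(r) {
    tri <- lowerTriangle(r)
    ok <- !is.na(tri)
    eng <- .partialEngine(lapply(modelTris, `[`, ok), covTri[ok])
    rx <- eng$ranks(tri[ok])
    rhos <- eng$rhos(rx)
    bi <- .tieBreakBest(rhos, boundaries, n)
    list(eng = eng, rx = rx, best = unname(rhos[bi]),
         boundary = unname(boundaries[bi]))
  })
  observed <- mean(vapply(fits, `[[`, numeric(1), "best"))
  null <- withSeed(seed, vapply(seq_len(nIter), function(i)
    mean(vapply(fits, function(f)
      max(f$eng$rhos(sample(f$rx)), na.rm = TRUE), numeric(1))),
    numeric(1)))
  list(p = (sum(null >= observed) + 1) / (nIter + 1), observed = observed,
       perParticipant = data.frame(
         participant = seq_along(fits),
         bestRho = vapply(fits, `[[`, numeric(1), "best"),
         bestBoundary = vapply(fits, `[[`, integer(1), "boundary")),
       null = list(values = null, nIter = as.integer(nIter),
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Bonferroni correction
#'
#' @param p p value(s) in (0, 1].
#' @param m number of comparisons (default 10, the categorical model count).
#' @return `min(1, p * m)`, vectorized.
#' @export
bonferroniCorrect <- function(p, m = 10) pmin(1, p * m)

#' Percentile bootstrap CI of a median over participants
#'
#' Resamples participants with replacement `nBoot` times, storing the median
#' of each resample; the CI is the percentile interval of the stored medians.
#'
#' @param values one value per participant (e.g. boundary ratios).
#' @param nBoot bootstrap iterations (default 10000).
#' @param seed RNG seed.
#' @param level confidence level (default 0.95).
#' @return list with `median`, `ciLow`, `ciHigh`.
#' @export
bootstrapMedianCI <- function(values, nBoot = 10000, seed = NULL,
                              level = 0.95) {
  if (length(values) < 2) stop("need at least 2 values")
  meds <- withSeed(seed, vapply(seq_len(nBoot), function(i)
    stats::median(sample(values, replace = TRUE)), numeric(1)))
  qs <- stats::quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        names = FALSE, type = 7)
  list(median = stats::median(values), ciLow = qs[1], ciHigh = qs[2])
}

#' Compare two RSMs beyond the stimulus-driven structure
#'
#' Partial Spearman correlation between the lower triangles of two response
#' RSMs with the acoustic RSM as covariate; significance by permutation,
#' shuffling the first RSM's triangle.
#'
#' @param a,b the two [RSM]s.
#' @param acoustic covariate [RSM].
#' @param nIter permutation iterations (default 5000).
#' @param seed RNG seed.
#' @return list with `rho`, `p`, `null`.
#' @export
compareRSMs <- function(a, b, acoustic, nIter = 5000, seed = NULL) {
  ta <- lowerTriangle(a); tb <- lowerTriangle(b)
  tc <- lowerTriangle(acoustic)
  ok <- stats::complete.cases(ta, tb, tc)
  eng <- .partialEngine(list(tb[ok]), tc[ok])
  rx <- eng$ranks(ta[ok])
  rho <- eng$rhos(rx)[1]
  null <- withSeed(seed, vapply(seq_len(nIter), function(i)
    eng$rhos(sample(rx))[1], numeric(1)))
  list(rho = rho, p = (sum(null >= rho) + 1) / (nIter + 1),
       null = list(values = null, nIter = as.integer(nIter),
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

#' Group-level RSM comparison
#'
#' Per-participant partial rhos between paired RSMs are averaged; the null
#' shuffles every participant's first triangle independently per iteration.
#'
#' @param as,bs lists of per-participant [RSM]s, paired by position.
#' @param acoustic covariate [RSM].
#' @param nIter permutation iterations (default 10000).
#' @param seed RNG seed.
#' @return list with `rho` (group mean), `perParticipant`, `p`, `null`.
#' @export
compareRSMsGroup <- function(as, bs, acoustic, nIter = 10000, seed = NULL) {
  stopifnot(length(as) == length(bs))
  tc <- lowerTriangle(acoustic)
  parts <- lapply(seq_along(as), function(i) {
    ta <- lowerTriangle(as[[i]]); tb <- lowerTriangle(bs[[i]])
    ok <- stats::complete.cases(ta, tb, tc)
    eng <- .partialEngine(list(tb[ok]), tc[ok])
    rx <- eng$ranks(ta[ok])
    list(eng = eng, rx = rx, rho = eng$rhos(rx)[1])
  })
  rhos <- vapply(parts, `[[`, numeric(1), "rho")
  observed <- mean(rhos)
  null <- withSeed(seed, vapply(seq_len(nIter), function(i)
    mean(vapply(parts, function(p) p$eng$rhos(sample(p$rx))[1], numeric(1))),
    numeric(1)))
  list(rho = observed, perParticipant = rhos,
       p = (sum(null >= observed) + 1) / (nIter + 1),
       null = list(values = null, nIter = as.integer(nIter),
                   seed = if (is.null(seed)) NA_integer_ else as.integer(seed)))
}

.clipRho <- function(r) {
  if (any(abs(r) >= 1)) {
    warning("correlation(s) of magnitude 1 clipped before Fisher transform")
    r <- pmin(pmax(r, -(1 - 1e-12)), 1 - 1e-12)
  }
  r
}

#' Similarity of model-fit profiles between two response kinds
#'
#' The per-model correlation profiles (e.g. 10 rhos across boundary
#' positions) of two response kinds are Fisher-transformed and Pearson-
#' correlated; the resulting `r` is itself Fisher-transformed for group
#' testing.
#'
#' @param profileA,profileB equal-length vectors of correlation coefficients.
#' @return list with `r` and `fisherZ`.
#' @seealso [profileSimilarityGroupTest()]
#' @export
modelProfileSimilarity <- function(profileA, profileB) {
  stopifnot(length(profileA) == length(profileB))
  r <- stats::cor(atanh(.clipRho(profileA)), atanh(.clipRho(profileB)))
  list(r = r, fisherZ = atanh(.clipRho(r)))
}

#' Group test of profile similarity
#'
#' One-sample t test of per-participant Fisher-z profile correlations
#' against zero.
#'
#' @param rs per-participant profile correlations (raw `r` values).
#' @return list with `meanR`, `t`, `df`, `p`.
#' @export
profileSimilarityGroupTest <- function(rs) {
  z <- atanh(.clipRho(rs))
  tt <- tTests(z)
  list(meanR = mean(rs), t = tt$t, df = tt$df, p = tt$p)
}

#' One-sample and paired t tests with degenerate-case handling
#'
#' Standard two-sided t statistic: one-sample against zero when `b` is
#' `NULL`, otherwise paired. A zero-variance difference is handled
#' explicitly: identical pairs give `t = 0`, `p = 1` (by convention, logged
#' via `message`); a constant nonzero difference gives an infinite statistic
#' with `p = 0`.
#'
#' @param a sample (or first member of pairs).
#' @param b optional second member of pairs.
#' @return list with `t`, `df`, `p`.
#' @export
tTests <- function(a, b = NULL) {
  d <- if (is.null(b)) a else {
    stopifnot(length(a) == length(b))
    a - b
  }
  n <- length(d)
  if (n < 2) stop("need at least 2 observations")
  s <- stats::sd(d)
  if (s == 0) {
    if (mean(d) == 0) {
      message("zero difference with zero variance: p = 1 by convention")
      return(list(t = 0, df = n - 1, p = 1))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, df = n - 1, p = 2 * stats::pt(-abs(t), n - 1))
}
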