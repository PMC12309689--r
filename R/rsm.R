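#' Representational similarity from feature vectors
#'
#' Pearson-correlates equal-length feature vectors across all pairs of
#' conditions. A zero-variance vector leaves its pairwise entries undefined
#' (`NA`, reported with a warning); downstream rank correlations exclude such
#' pairs pairwise.
#'
#' @param features a numeric matrix with one column per condition (features
#'   in rows), or a list of equal-length numeric vectors.
#' @param labels condition labels; defaults to column names or indices.
#' @return an [RSM] of kind `"correlation"`.
#' @export
rsmFromFeatures <- function(features, labels = NULL) {
  if (is.list(features)) {
    len <- lengths(features)
    if (length(unique(len)) != 1L)
      stop("all feature vectors must have equal length")
    features <- do.call(cbind, features)
  }
  if (!is.matrix(features) || ncol(features) < 2)
    stop("'features' must provide at least 2 conditions")
  if (is.null(labels))
    labels <- colnames(features)
  if (is.null(labels)) labels <- as.character(seq_len(ncol(features)))
  sds <- apply(features, 2, stats::sd)
  flat <- sds == 0 | !is.finite(sds)
  m <- suppressWarnings(stats::cor(features))
  if (any(flat)) {
    warning(sprintf("%d condition(s) with zero feature variance: entries undefined",
                    sum(flat)))
    m[flat, ] <- NA_real_
    m[, flat] <- NA_real_
  }
  diag(m) <- 1
  m[!flat, !flat] <- (m[!flat, !flat] + t(m[!flat, !flat])) / 2
  new("RSM", matrix = unname(m), kind = "correlation",
      labels = as.character(labels))
}

#' Representational similarity from one scalar per condition
#'
#' Entry (i, j) is `1 - |v_i - v_j|`, the similarity form used for stimulus
#' interval ratios and for mean produced intertap-interval ratios.
#'
#' @param values one number per condition.
#' @param labels condition labels.
#' @return an [RSM] of kind `"one-minus-absdiff"`.
#' @export
rsmFromScalars <- function(values, labels = NULL) {
  if (length(values) < 2) stop("'values' must contain at least 2 conditions")
  if (is.null(labels)) labels <- names(values)
  if (is.null(labels)) labels <- as.character(seq_along(values))
  m <- 1 - abs(outer(values, values, "-"))
  new("RSM", matrix = unname(m), kind = "one-minus-absdiff",
      labels = as.character(labels))
}

#' Representational similarity from average response time courses
#'
#' Pearson-correlates the demeaned per-condition average cycle (channel-pooled
#' epoch averages) across all pairs of conditions. For noiseless periodic
#' signals containing only harmonics below Nyquist this is equivalent (by
#' Plancherel's theorem) to [rsmFromFeatures()] on the full harmonic set,
#' exactly so when the spectral feature vectors are mean-centered.
#'
#' @param timecourses numeric matrix, samples x conditions, or a list of
#'   equal-length vectors (one average cycle per condition).
#' @param labels condition labels.
#' @return an [RSM] of kind `"correlation"`.
#' @export
rsmFromTimecourses <- function(timecourses, labels = NULL) {
  if (is.list(timecourses)) {
    len <- lengths(timecourses)
    if (length(unique(len)) != 1L) stop("all epochs must have equal length")
    timecourses <- do.call(cbind, timecourses)
  }
  tc <- sweep(timecourses, 2, colMeans(timecourses))
  rsmFromFeatures(tc, labels = labels)
}

#' Lower-triangle vector of a similarity matrix
#'
#' Strictly-below-diagonal entries in column-major order (the project-wide
#' fixed ordering, so permutation shuffles are reproducible across modules);
#' length `n (n - 1) / 2`. Asymmetry beyond `1e-9` is rejected.
#'
#' @param x an [RSM] or a square numeric matrix.
#' @return numeric vector of the strict lower triangle.
#' @seealso [rsmFromTriangle()] for the inverse.
#' @export
lowerTriangle <- function(x) {
  m <- if (is(x, "RSM")) x@matrix else x
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("'x' must be square")
  if (!isTRUE(all.equal(m, t(m), tolerance = 1e-9, check.attributes = FALSE)))
    stop("'x' is asymmetric beyond tolerance 1e-9")
  m[lower.tri(m)]
}

#' Rebuild a symmetric matrix from its lower-triangle vector
#'
#' Inverse of [lowerTriangle()] (column-major strict lower triangle).
#'
#' @param v triangle vector of length `n (n - 1) / 2`.
#' @param diagValue diagonal fill (default 1).
#' @return symmetric numeric matrix.
#' @export
rsmFromTriangle <- function(v, diagValue = 1) {
  n <- (1 + sqrt(1 + 8 * length(v))) / 2
  if (abs(n - round(n)) > 1e-9)
    stop("'v' length is not a triangular number")
  n <- round(n)
  m <- matrix(diagValue, n, n)
  m[lower.tri(m)] <- v
  m[upper.tri(m)] <- t(m)[upper.tri(m)]
  m
}

#' Write / read an RSM as CSV
#'
#' Plain CSV with condition labels as header and row names.
#'
#' @param rsm an [RSM].
#' @param path file path.
#' @return `writeRSM` the path invisibly; `readRSM` an [RSM].
#' @export
writeRSM <- function(rsm, path) {
  stopifnot(is(rsm, "RSM"))
  m <- similarityMatrix(rsm)
  utils::write.table(cbind(condition = rownames(m), as.data.frame(m)),
                     path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeRSM
#' @param kind RSM kind to stamp on the object read back.
#' @export
readRSM <- function(path, kind = "correlation") {
  d <- utils::read.table(path, sep = ",", header = TRUE, check.names = FALSE)
  labs <- as.character(d[[1]])
  m <- as.matrix(d[, -1, drop = FALSE])
  m <- (m + t(m)) / 2  # float round-trip symmetrization
  new("RSM", matrix = unname(m), kind = kind, labels = labs)
}
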