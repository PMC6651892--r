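.supportedMetrics <- c("euclidean", "manhattan", "spearman", "hamming")

#' Distance between two feature vectors
#'
#' Dissimilarity metrics used for biometric matching. All work in distance
#' space: identical vectors (identical rank profiles, for Spearman) score 0,
#' and the verification decision accepts a probe when its distance to the
#' claimed gallery falls below the threshold.
#'
#' * `euclidean`, `manhattan`: the standard L2 / L1 distances.
#' * `spearman`: `1 - rho`, where `rho` is the Spearman rank correlation
#'   (midranks for ties); range \[0, 2\], requires dimension >= 2 and
#'   non-constant vectors.
#' * `hamming`: fraction of coordinates that differ.
#'
#' @param u,v Numeric vectors of equal dimension.
#' @param metric One of `"euclidean"`, `"manhattan"`, `"spearman"`,
#'   `"hamming"`.
#' @return A single non-negative number.
#' @examples
#' featureDistance(c(0, 0), c(3, 4), "euclidean")  # 5
#' featureDistance(1:3, 3:1, "spearman")           # 2 (rho = -1)
#' @export
featureDistance <- function(u, v, metric = .supportedMetrics) {
  metric <- match.arg(metric)
  if (length(u) != length(v))
    .stopf("dimensionError", "vectors differ in dimension (%d vs %d)",
           length(u), length(v))
  M <- rbind(u, v)
  as.numeric(indexedDistances(M, 1L, 2L, metric))
}

## Midranks row-wise; errors if any row is rank-constant (spearman undefined).
.rankRows <- function(M) {
  if (ncol(M) < 2L)
    .stopf("dimensionError", "spearman distance needs dimension >= 2")
  R <- t(apply(M, 1L, rank, ties.method = "average"))
  v <- apply(R, 1L, stats::var)
  if (any(v == 0))
    .stopf("undefinedCorrelationError",
           "constant vector: spearman correlation undefined")
  R
}

## Standardized midranks so that tcrossprod/(d-1) gives Spearman rho.
.zRankRows <- function(M) {
  R <- .rankRows(M)
  mu <- rowMeans(R)
  s <- sqrt(apply(R, 1L, stats::var))
  (R - mu) / s
}

#' Row-indexed pair distances
#'
#' Vectorized distances between `M[i[k], ]` and `M[j[k], ]` for each `k`;
#' the workhorse behind pair scoring.
#'
#' @param M Numeric matrix, samples in rows.
#' @param i,j Integer row indices of equal length.
#' @param metric Metric name as in [featureDistance()].
#' @return Numeric vector of length `length(i)`.
#' @export
indexedDistances <- function(M, i, j, metric = .supportedMetrics) {
  metric <- match.arg(metric)
  M <- as.matrix(M)
  switch(metric,
    euclidean = {
      D <- M[i, , drop = FALSE] - M[j, , drop = FALSE]
      sqrt(rowSums(D * D))
    },
    manhattan = rowSums(abs(M[i, , drop = FALSE] - M[j, , drop = FALSE])),
    hamming = rowMeans(M[i, , drop = FALSE] != M[j, , drop = FALSE]),
    spearman = {
      Z <- .zRankRows(M)
      1 - rowSums(Z[i, , drop = FALSE] * Z[j, , drop = FALSE]) / (ncol(M) - 1L)
    })
}

#' All cross-pair distances between two sample sets
#'
#' @param A,B Numeric matrices with samples in rows and a common feature
#'   dimension; `B = NULL` means `A` against itself.
#' @param metric Metric name as in [featureDistance()].
#' @return `nrow(A) x nrow(B)` matrix of distances.
#' @export
pairwiseDistances <- function(A, B = NULL, metric = .supportedMetrics) {
  metric <- match.arg(metric)
  A <- as.matrix(A)
  B <- if (is.null(B)) A else as.matrix(B)
  if (ncol(A) != ncol(B))
    .stopf("dimensionError", "feature dimensions differ (%d vs %d)",
           ncol(A), ncol(B))
  switch(metric,
    euclidean = {
      G <- tcrossprod(A, B)
      d2 <- outer(rowSums(A * A), rowSums(B * B), `+`) - 2 * G
      sqrt(pmax(d2, 0))
    },
    manhattan = {
      D <- matrix(0, nrow(A), nrow(B))
      for (k in seq_len(ncol(A)))
        D <- D + abs(outer(A[, k], B[, k], `-`))
      D
    },
    hamming = {
      D <- matrix(0, nrow(A), nrow(B))
      for (k in seq_len(ncol(A)))
        D <- D + outer(A[, k], B[, k], `!=`)
      D / ncol(A)
    },
    spearman = {
      n <- nrow(A)
      Z <- .zRankRows(rbind(A, B))
      1 - tcrossprod(Z[seq_len(n), , drop = FALSE],
                     Z[-seq_len(n), , drop = FALSE]) / (ncol(A) - 1L)
    })
}

#' Min-max score normalization per modality
#'
#' Maps each modality's scores onto \[0, 1\] by an affine transform computed
#' over the union of that modality's genuine and impostor scores for the
#' current evaluation run. Order-preserving within each modality; required
#' before score-level fusion because the raw distance scales of different
#' modalities (and metrics) are not commensurable.
#'
#' @param scores A named list of numeric vectors (one per modality), or a
#'   single numeric vector.
#' @return Object of the same shape with each modality mapped to \[0, 1\].
#' @examples
#' normalizeScores(list(ecg = c(2, 4, 6)))  # 0, 0.5, 1
#' @export
normalizeScores <- function(scores) {
  one <- function(x) {
    rng <- range(x)
    if (!is.finite(diff(rng)) || diff(rng) == 0)
      .stopf("degenerateNormalizationError",
             "constant scores cannot be min-max normalized")
    (x - rng[1L]) / (rng[2L] - rng[1L])
  }
  if (is.numeric(scores)) return(one(scores))
  lapply(scores, one)
}

#' Score-level fusion
#'
#' Combines per-modality normalized scores for the same sample pair with one
#' of the elementary rules: `sum`, `min`, or `mult` (product). Applied after
#' per-modality matching; feature-level concatenation is handled by
#' [fuseFeatures()] instead.
#'
#' @param scores Numeric vector of m >= 2 per-modality scores for one pair,
#'   or an n x m matrix (one row per pair, one column per modality).
#' @param rule `"sum"`, `"min"`, or `"mult"`.
#' @return A single fused score, or a vector of n fused scores.
#' @examples
#' fuseScores(c(0.2, 0.3, 0.1), "sum")   # 0.6
#' fuseScores(c(0.2, 0.3, 0.1), "mult")  # 0.006
#' @export
fuseScores <- function(scores, rule = c("sum", "min", "mult")) {
  if (identical(rule, "concat") ||
      (length(rule) == 1L && rule == "concat"))
    .stopf("wrongLevelError",
           "concat is feature-level fusion; use fuseFeatures()")
  rule <- match.arg(rule)
  if (is.matrix(scores)) {
    if (ncol(scores) < 2L)
      .stopf("dimensionError", "score fusion needs >= 2 modalities")
    cols <- lapply(seq_len(ncol(scores)), function(k) scores[, k])
  } else {
    if (length(scores) < 2L)
      .stopf("dimensionError", "score fusion needs >= 2 modalities")
    cols <- as.list(scores)
  }
  out <- switch(rule,
    sum = Reduce(`+`, cols),
    min = do.call(pmin, cols),
    mult = Reduce(`*`, cols))
  unname(out)
}

#' Per-dimension min-max scaling statistics from training data
#'
#' @param train Numeric matrix of training-session feature vectors (samples
#'   in rows) for one modality.
#' @return List with per-dimension `min` and `max` vectors, to pass to
#'   [fuseFeatures()].
#' @export
featureScaling <- function(train) {
  train <- as.matrix(train)
  list(min = apply(train, 2L, min), max = apply(train, 2L, max))
}

## Affine per-dimension scaling of a sample matrix; dimensions with zero
## training range carry no information and are mapped to 0.
.scaleFeatureMatrix <- function(M, scaling) {
  rng <- scaling$max - scaling$min
  out <- sweep(M, 2L, scaling$min, `-`)
  out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), `/`)
  out[, rng == 0] <- 0
  out
}

#' Feature-level fusion by concatenation
#'
#' Concatenates one feature vector per modality, in declared modality order,
#' into a single n+m-dimensional vector. Each modality's dimensions are
#' min-max scaled with training-session statistics first, so no modality
#' dominates the concatenated distance purely through its numeric range.
#'
#' @param vectors Named list of numeric vectors, one per modality, in the
#'   declared modality order.
#' @param scalings Optional named list of [featureScaling()] results,
#'   parallel to `vectors`; `NULL` skips scaling.
#' @return A single concatenated numeric vector.
#' @examples
#' fuseFeatures(list(a = c(1, 2), b = c(3, 4)))  # c(1, 2, 3, 4)
#' @export
fuseFeatures <- function(vectors, scalings = NULL) {
  if (any(vapply(vectors, is.null, TRUE)))
    .stopf("integrityError", "missing modality vector in feature fusion")
  pieces <- lapply(seq_along(vectors), function(k) {
    v <- as.numeric(vectors[[k]])
    if (length(v) < 1L)
      .stopf("integrityError", "empty modality vector in feature fusion")
    if (!is.null(scalings)) {
      sc <- scalings[[k]]
      rng <- sc$max - sc$min
      v <- ifelse(rng > 0, (v - sc$min) / rng, 0)
    }
    v
  })
  unlist(pieces, use.names = FALSE)
}

#' Verification decision for one probe against a claimed identity
#'
#' Open-set verification: the probe is accepted as genuine when its minimum
#' distance to the claimed identity's gallery vectors lies strictly below
#' the threshold, otherwise it is rejected as an impostor. This is the
#' dissimilarity analogue of thresholding a similarity score from above.
#'
#' @param probe Numeric feature vector.
#' @param gallery Numeric matrix of the claimed identity's gallery vectors
#'   (one per row), non-empty.
#' @param threshold Decision threshold `t >= 0`; `t = 0` rejects everything.
#' @param metric Metric name as in [featureDistance()].
#' @return `"genuine"` or `"impostor"`.
#' @export
verify <- function(probe, gallery, threshold,
                   metric = .supportedMetrics) {
  metric <- match.arg(metric)
  gallery <- as.matrix(gallery)
  if (nrow(gallery) == 0L)
    .stopf("integrityError", "empty gallery for claimed identity")
  d <- min(pairwiseDistances(matrix(probe, nrow = 1L), gallery, metric))
  if (d < threshold) "genuine" else "impostor"
}
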