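#' Construct a ScoreSet
#'
#' @param genuine,impostor Numeric score vectors (distance convention:
#'   genuine pairs score low).
#' @param scenario,method Free-form descriptors.
#' @return A validated [ScoreSet-class].
#' @export
ScoreSet <- function(genuine, impostor, scenario = "unspecified",
                     method = "unspecified") {
  new("ScoreSet", genuine = as.numeric(genuine),
      impostor = as.numeric(impostor),
      scenario = as.character(scenario), method = as.character(method))
}

setMethod("show", "ScoreSet", function(object) {
  cat(sprintf("ScoreSet [%s / %s]: %d genuine, %d impostor scores\n",
              object@scenario, object@method,
              length(object@genuine), length(object@impostor)))
  cat(sprintf("  genuine  mean %.4g sd %.4g\n", mean(object@genuine),
              sd(object@genuine)))
  cat(sprintf("  impostor mean %.4g sd %.4g\n", mean(object@impostor),
              sd(object@impostor)))
})

## Sessions of a chimeric dataset in build order (first = train/gallery).
.cdsSessions <- function(cds) unique(cds@samples$session_id)

## All unordered index pairs of 1..n as two integer vectors.
.allPairs <- function(n) {
  if (n < 2L) return(list(i = integer(), j = integer()))
  i <- rep.int(seq_len(n - 1L), (n - 1L):1L)
  j <- sequence((n - 1L):1L, from = 2L:n)
  list(i = i, j = j)
}

#' Enumerate genuine and impostor sample pairs for a scenario
#'
#' * `train_intra` / `test_intra`: all unordered pairs of chimeric samples
#'   within the training / test session (a one-against-all comparison).
#' * `inter`: the full cross-product of test-session (probe) against
#'   training-session (gallery) samples, so every pair mixes sessions.
#'
#' A pair is genuine iff both samples belong to the same chimeric
#' individual. Optional limits draw a seeded uniform subsample of each
#' class of pairs.
#'
#' @param cds A [ChimericDataset-class].
#' @param scenario `"train_intra"`, `"test_intra"`, or `"inter"`.
#' @param limits Optional `c(genuine = n1, impostor = n2)` pair-count caps.
#' @param seed Seed for the subsampling (required when `limits` given).
#' @return A `data.frame` with columns `i`, `j` (row indices into the
#'   dataset's sample manifest) and `genuine`; scenario kept as an
#'   attribute.
#' @export
enumeratePairs <- function(cds, scenario = c("train_intra", "test_intra",
                                             "inter"),
                           limits = NULL, seed = NULL) {
  scenario <- match.arg(scenario)
  sessions <- .cdsSessions(cds)
  if (scenario != "train_intra" && length(sessions) < 2L)
    .stopf("integrityError",
           "scenario '%s' needs a second (test) session", scenario)
  smp <- cds@samples
  if (scenario == "inter") {
    probe <- which(smp$session_id != sessions[1L])
    gallery <- which(smp$session_id == sessions[1L])
    i <- rep(probe, each = length(gallery))
    j <- rep.int(gallery, length(probe))
  } else {
    sess <- if (scenario == "train_intra") sessions[1L] else sessions[2L]
    rows <- which(smp$session_id == sess)
    if (length(rows) < 2L)
      .stopf("integrityError", "session '%s' has < 2 samples", sess)
    p <- .allPairs(length(rows))
    i <- rows[p$i]; j <- rows[p$j]
  }
  genuine <- smp$chimeric_id[i] == smp$chimeric_id[j]
  man <- data.frame(i = i, j = j, genuine = genuine)
  if (!is.null(limits)) {
    if (is.null(seed))
      .stopf("integrityError", "pair subsampling requires a seed")
    lims <- c(genuine = Inf, impostor = Inf)
    lims[names(limits)] <- limits
    keep <- withSeed(seed, {
      g <- which(man$genuine); im <- which(!man$genuine)
      c(if (length(g) > lims[["genuine"]])
          sample(g, lims[["genuine"]]) else g,
        if (length(im) > lims[["impostor"]])
          sample(im, lims[["impostor"]]) else im)
    })
    man <- man[sort(keep), , drop = FALSE]
    rownames(man) <- NULL
  }
  attr(man, "scenario") <- scenario
  man
}

#' Score a pair manifest under a matching method
#'
#' Computes the dissimilarity score of every enumerated pair. For
#' score-level methods the per-modality distances are computed with each
#' modality's metric, min-max normalized over the manifest's pairs, and
#' fused with the chosen rule. For the feature-level `concat` method each
#' modality's features are min-max scaled with training-session statistics,
#' concatenated, and matched with a single metric. Unimodal scoring (one
#' modality, `fusion = NULL`) returns that modality's normalized distances.
#'
#' @param manifest Pair manifest from [enumeratePairs()].
#' @param cds The [ChimericDataset-class] the manifest refers to.
#' @param modalities Named list of source [ModalityDataset-class]s to use,
#'   in declared fusion order.
#' @param metrics Metric name(s): one per modality (recycled if single).
#' @param fusion `NULL` (unimodal), `"sum"`, `"min"`, `"mult"`, or
#'   `"concat"`.
#' @param concatMetric Metric for the concatenated vectors (default
#'   euclidean).
#' @return A [ScoreSet-class].
#' @export
scorePairs <- function(manifest, cds, modalities, metrics = "euclidean",
                       fusion = NULL, concatMetric = "euclidean") {
  stopifnot(length(modalities) >= 1L)
  mods <- vapply(modalities, modalityId, "")
  names(modalities) <- mods
  metrics <- setNames(rep_len(metrics, length(mods)), mods)
  if (is.null(fusion) && length(mods) > 1L)
    .stopf("integrityError", "multiple modalities require a fusion rule")
  if (!is.null(fusion) && fusion != "concat" && length(mods) < 2L)
    .stopf("integrityError", "score fusion needs >= 2 modalities")
  i <- manifest$i; j <- manifest$j
  feats <- lapply(modalities, chimericFeatures, cds = cds)
  if (identical(fusion, "concat")) {
    sessions <- .cdsSessions(cds)
    trainRows <- which(cds@samples$session_id == sessions[1L])
    scaled <- lapply(feats, function(F)
      .scaleFeatureMatrix(F, featureScaling(F[trainRows, , drop = FALSE])))
    C <- do.call(cbind, scaled)
    scores <- normalizeScores(indexedDistances(C, i, j, concatMetric))
  } else {
    perMod <- vapply(mods, function(m)
      indexedDistances(feats[[m]], i, j, metrics[[m]]),
      numeric(length(i)))
    perMod <- matrix(perMod, ncol = length(mods),
                     dimnames = list(NULL, mods))
    norm <- vapply(mods, function(m) normalizeScores(perMod[, m]),
                   numeric(length(i)))
    norm <- matrix(norm, ncol = length(mods))
    scores <- if (is.null(fusion)) norm[, 1L] else fuseScores(norm, fusion)
  }
  methodName <- if (is.null(fusion)) mods else
    paste0(paste(mods, collapse = "+"), ":", fusion)
  ScoreSet(genuine = scores[manifest$genuine],
           impostor = scores[!manifest$genuine],
           scenario = attr(manifest, "scenario") %||% "unspecified",
           method = methodName)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @rdname decidability
#' @export
setMethod("decidability", "ScoreSet", function(scores) {
  g <- scores@genuine; im <- scores@impostor
  if (length(g) < 2L || length(im) < 2L)
    .stopf("insufficientSamplesError",
           "decidability needs >= 2 scores per class")
  sI <- sd(g); sE <- sd(im)
  num <- abs(mean(im) - mean(g))
  den <- sqrt((sI^2 + sE^2) / 2)
  if (den == 0) {
    if (num == 0)
      .stopf("undefinedDecidabilityError",
             "identical constant score distributions: decidability undefined")
    return(Inf)
  }
  num / den
})

#' @rdname detCurve
#' @export
setMethod("detCurve", "ScoreSet", function(scores) {
  g <- scores@genuine; im <- scores@impostor
  thr <- c(-Inf, sort(unique(c(g, im))), Inf)
  sg <- sort(g); si <- sort(im)
  ## number of scores strictly below each threshold
  nBelow <- function(sorted, t) findInterval(t, sorted, left.open = TRUE)
  far <- nBelow(si, thr) / length(im)
  frr <- 1 - nBelow(sg, thr) / length(g)
  data.frame(threshold = thr, far = far, frr = frr)
})

.eerFromCurve <- function(curve) {
  d <- curve$far - curve$frr
  k <- which(d >= 0)[1L]
  if (is.na(k))
    .stopf("integrityError", "malformed DET curve: no FAR/FRR crossing")
  if (d[k] == 0) return(curve$far[k])
  a <- -d[k - 1L] / (d[k] - d[k - 1L])
  curve$far[k - 1L] + a * (curve$far[k] - curve$far[k - 1L])
}

#' @rdname equalErrorRate
#' @export
setMethod("equalErrorRate", "ScoreSet", function(scores)
  .eerFromCurve(detCurve(scores)))

#' @rdname equalErrorRate
#' @export
setMethod("equalErrorRate", "data.frame", function(scores)
  .eerFromCurve(scores))
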