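#' Construct a ZooConfig
#'
#' @param goatPercentile Goat selection percentile (default 70): individuals
#'   whose intra-class dispersion ranks above this percentile become goat
#'   candidates.
#' @param lambPercentile Lamb selection percentile (default 30): individuals
#'   whose mean inter-class distance ranks in the lower tail up to this
#'   percentile become lamb candidates.
#' @param finalFraction Fraction of valid individuals finally labeled per
#'   minority category (default 0.10).
#' @param metric Distance metric for the labeling statistics.
#' @param seed Integer seed for the selection permutations.
#' @return A validated [ZooConfig-class].
#' @export
zooConfig <- function(goatPercentile = 70, lambPercentile = 30,
                      finalFraction = 0.10, metric = "euclidean",
                      seed = 1L) {
  new("ZooConfig", goatPercentile = as.numeric(goatPercentile),
      lambPercentile = as.numeric(lambPercentile),
      finalFraction = as.numeric(finalFraction),
      metric = as.character(metric), seed = as.integer(seed))
}

#' Fractional percentile rank index
#'
#' The index of the p-th percentile in a population of N ranked individuals,
#' \eqn{index = p/100 \times N + 1/2}, returned exactly, without rounding.
#' Goat candidates are the ranks strictly above the goat-percentile index;
#' lamb candidates are the ranks up to the round-half-up of the
#' lamb-percentile index.
#'
#' @param p Percentile in \[0, 100\].
#' @param N Number of individuals (>= 1).
#' @return The fractional 1-based rank index.
#' @examples
#' percentileIndex(70, 56)  # 39.7
#' percentileIndex(30, 10)  # 3.5
#' @export
percentileIndex <- function(p, N) {
  if (length(N) != 1L || is.na(N) || N < 1L)
    .stopf("emptyPopulationError", "percentile index needs N >= 1")
  stopifnot(p >= 0, p <= 100)
  p / 100 * N + 0.5
}

#' Individuals with at least one sample in every session
#'
#' Individuals missing any session cannot supply both gallery and probe data
#' and are discarded before labeling.
#'
#' @param dataset A [ModalityDataset-class].
#' @return Sorted character vector of valid individual ids.
#' @export
filterValidIndividuals <- function(dataset) {
  info <- sampleInfo(dataset)
  sessions <- sessionOrder(dataset)
  ids <- individualIds(dataset)
  present <- vapply(ids, function(id) {
    have <- unique(info$session_id[info$individual_id == id])
    all(sessions %in% have)
  }, TRUE)
  valid <- ids[present]
  if (length(valid) == 0L)
    .stopf("emptyPopulationError",
           "no individual has samples in every session")
  valid
}

## Training session = first session of the declared order.
.trainingSession <- function(dataset) sessionOrder(dataset)[1L]

#' Intra-class dispersion of one individual
#'
#' Mean pairwise distance over all unordered pairs of the individual's
#' training-session samples. High dispersion marks goat-like (hard to match)
#' individuals.
#'
#' @param dataset A [ModalityDataset-class].
#' @param individualId Individual to assess.
#' @param metric Metric name as in [featureDistance()].
#' @return Non-negative number.
#' @export
intraClassDispersion <- function(dataset, individualId,
                                 metric = .supportedMetrics) {
  metric <- match.arg(metric)
  M <- .individualSession(dataset, individualId, .trainingSession(dataset))
  n <- nrow(M)
  if (n < 2L)
    .stopf("insufficientSamplesError",
           "individual '%s' has < 2 training samples", individualId)
  D <- pairwiseDistances(M, metric = metric)
  mean(D[upper.tri(D)])
}

#' Mean inter-class distance of one individual (one-against-all)
#'
#' Mean distance between each of the individual's training-session samples
#' and every training-session sample of every other individual. Low values
#' mark lamb-like (easily imitated) individuals.
#'
#' @inheritParams intraClassDispersion
#' @param others Ids to compare against; defaults to all other individuals.
#' @return Non-negative number.
#' @export
meanInterClassDistance <- function(dataset, individualId,
                                   metric = .supportedMetrics,
                                   others = NULL) {
  metric <- match.arg(metric)
  if (is.null(others))
    others <- setdiff(individualIds(dataset), individualId)
  others <- setdiff(others, individualId)
  if (length(others) == 0L)
    .stopf("insufficientPopulationError",
           "inter-class distance needs >= 2 individuals")
  sess <- .trainingSession(dataset)
  own <- .individualSession(dataset, individualId, sess)
  rest <- do.call(rbind, lapply(others, .individualSession,
                                mds = dataset, session = sess))
  if (nrow(rest) == 0L)
    .stopf("insufficientPopulationError",
           "no training samples among other individuals")
  mean(pairwiseDistances(own, rest, metric))
}

## Both labeling statistics for all ids from a single training-session
## distance matrix (quadratic, but computed once per modality).
.labelingStats <- function(dataset, ids, metric) {
  sess <- .trainingSession(dataset)
  mats <- lapply(ids, .individualSession, mds = dataset, session = sess)
  counts <- vapply(mats, nrow, 0L)
  if (any(counts < 2L))
    .stopf("insufficientSamplesError",
           "individuals with < 2 training samples: %s",
           paste(head(ids[counts < 2L], 5L), collapse = ", "))
  M <- do.call(rbind, mats)
  who <- rep(seq_along(ids), counts)
  D <- pairwiseDistances(M, metric = metric)
  disp <- sep <- setNames(numeric(length(ids)), ids)
  for (k in seq_along(ids)) {
    own <- which(who == k)
    Dk <- D[own, own, drop = FALSE]
    disp[k] <- mean(Dk[upper.tri(Dk)])
    sep[k] <- mean(D[own, who != k, drop = FALSE])
  }
  list(dispersion = disp, separation = sep)
}

#' Goat candidates from intra-class dispersions
#'
#' Ids are sorted ascending by dispersion (ties broken by id); the
#' candidates are those whose rank lies strictly above the fractional
#' [percentileIndex()] of the goat percentile.
#'
#' @param dispersions Named numeric vector, individual id to intra-class
#'   dispersion.
#' @param cfg A [ZooConfig-class].
#' @return `data.frame` with columns `id`, `statistic`, in ascending rank
#'   order.
#' @export
identifyGoats <- function(dispersions, cfg = zooConfig()) {
  stopifnot(length(dispersions) > 0L, !is.null(names(dispersions)))
  N <- length(dispersions)
  idx <- percentileIndex(cfg@goatPercentile, N)
  ord <- .orderByStat(dispersions, names(dispersions))
  keep <- ord[which(seq_len(N) > idx)]
  data.frame(id = names(dispersions)[keep],
             statistic = unname(dispersions[keep]),
             stringsAsFactors = FALSE)
}

#' Lamb candidates from mean inter-class distances
#'
#' Ids are sorted ascending by separation (ties broken by id); the
#' candidates are those with rank at most the round-half-up of the
#' fractional [percentileIndex()] of the lamb percentile.
#'
#' @param separations Named numeric vector, individual id to mean
#'   inter-class distance.
#' @param cfg A [ZooConfig-class].
#' @return `data.frame` with columns `id`, `statistic`, in ascending rank
#'   order.
#' @export
identifyLambs <- function(separations, cfg = zooConfig()) {
  stopifnot(length(separations) > 0L, !is.null(names(separations)))
  N <- length(separations)
  k <- roundHalfUp(percentileIndex(cfg@lambPercentile, N))
  ord <- .orderByStat(separations, names(separations))
  keep <- ord[seq_len(min(k, N))]
  data.frame(id = names(separations)[keep],
             statistic = unname(separations[keep]),
             stringsAsFactors = FALSE)
}

#' Final sheep/goat/lamb labels from the candidate lists
#'
#' Ids appearing in both candidate lists are resolved in favor of goat. For
#' each minority category a seeded random permutation of its candidates is
#' drawn and the first `roundHalfUp(finalFraction * N)` ids (capped at the
#' candidate count) receive the label; every other valid individual is a
#' sheep. Fails if sheep are not the strict majority afterwards.
#'
#' @param goatCands,lambCands Candidate `data.frame`s from [identifyGoats()]
#'   / [identifyLambs()].
#' @param validIds All valid individual ids.
#' @param cfg A [ZooConfig-class]; `cfg@seed` drives the permutations.
#' @param discarded Ids discarded for missing sessions (recorded only).
#' @return A [ZooLabelMap-class].
#' @export
finalizeLabels <- function(goatCands, lambCands, validIds,
                           cfg = zooConfig(), discarded = character()) {
  stopifnot(all(goatCands$id %in% validIds), all(lambCands$id %in% validIds))
  N <- length(validIds)
  target <- roundHalfUp(cfg@finalFraction * N)
  lambPool <- lambCands[!(lambCands$id %in% goatCands$id), , drop = FALSE]
  seeds <- spawnSeeds(cfg@seed, c("goat_selection", "lamb_selection"))
  pick <- function(ids, seed) {
    if (length(ids) == 0L) return(character())
    perm <- withSeed(seed, sample(ids))
    perm[seq_len(min(target, length(perm)))]
  }
  goats <- pick(goatCands$id, seeds[["goat_selection"]])
  lambs <- pick(lambPool$id, seeds[["lamb_selection"]])
  labels <- setNames(rep("sheep", N), validIds)
  labels[goats] <- "goat"
  labels[lambs] <- "lamb"
  tab <- table(factor(labels, levels = c("sheep", "goat", "lamb")))
  if (tab[["sheep"]] <= tab[["goat"]] || tab[["sheep"]] <= tab[["lamb"]])
    .stopf("constraintViolationError",
           "sheep must be the strict majority (got %d sheep, %d goats, %d lambs)",
           tab[["sheep"]], tab[["goat"]], tab[["lamb"]])
  new("ZooLabelMap", labels = labels, goatCandidates = goatCands,
      lambCandidates = lambPool, discarded = as.character(discarded),
      seed = cfg@seed)
}

#' Label the individuals of a modality as sheep, goats, or lambs
#'
#' Full Doddington-Zoo labeling of one modality: discard individuals missing
#' a session, compute intra-class dispersion and mean inter-class distance
#' on training-session data, select goat and lamb candidates by the
#' configured percentiles, and finalize a seeded selection with everyone
#' else labeled sheep.
#'
#' @param dataset A [ModalityDataset-class].
#' @param cfg A [ZooConfig-class].
#' @return A [ZooLabelMap-class].
#' @examples
#' cfg <- syntheticConfig(nIndividuals = 20, seed = 7L)
#' md <- generateSuite(cfg)[[1]]
#' zooLabel(md, zooConfig(seed = 1L))
#' @export
zooLabel <- function(dataset, cfg = zooConfig()) {
  valid <- filterValidIndividuals(dataset)
  discarded <- setdiff(individualIds(dataset), valid)
  stats <- .labelingStats(dataset, valid, cfg@metric)
  goatCands <- identifyGoats(stats$dispersion, cfg)
  lambCands <- identifyLambs(stats$separation, cfg)
  finalizeLabels(goatCands, lambCands, valid, cfg, discarded = discarded)
}

#' @rdname ZooLabelMap
#' @export
setMethod("zooLabels", "ZooLabelMap", function(x) x@labels)

setMethod("show", "ZooLabelMap", function(object) {
  tab <- table(factor(object@labels, levels = c("sheep", "goat", "lamb")))
  cat(sprintf("ZooLabelMap: %d sheep, %d goats, %d lambs (%d discarded), seed %d\n",
              tab[["sheep"]], tab[["goat"]], tab[["lamb"]],
              length(object@discarded), object@seed))
})

#' Reconcile labels for modalities sharing the same individuals
#'
#' When several modalities come from the same source individuals, each
#' chimeric individual must carry one label across all modalities. Ids
#' labeled identically in every map keep that label. If a minority category
#' then falls short of its target count, the divergently-labeled ids are
#' pooled, permuted with the configured seed, and the first ones fill the
#' category; everything else is sheep.
#'
#' @param maps List of [ZooLabelMap-class] objects over the same id set.
#' @param cfg A [ZooConfig-class]; target counts use `cfg@finalFraction`,
#'   fills use `cfg@seed`.
#' @return A single [ZooLabelMap-class].
#' @export
reconcileSharedLabels <- function(maps, cfg = zooConfig()) {
  stopifnot(length(maps) >= 2L)
  ids <- sort(names(zooLabels(maps[[1L]])))
  for (m in maps[-1L])
    if (!identical(sort(names(zooLabels(m))), ids))
      .stopf("integrityError",
             "label maps cover different individual sets")
  L <- vapply(maps, function(m) zooLabels(m)[ids], character(length(ids)))
  agree <- apply(L, 1L, function(r) length(unique(r)) == 1L)
  labels <- setNames(rep("sheep", length(ids)), ids)
  labels[agree] <- L[agree, 1L]
  N <- length(ids)
  target <- roundHalfUp(cfg@finalFraction * N)
  divergent <- ids[!agree]
  seeds <- spawnSeeds(cfg@seed, c("reconcile_goat", "reconcile_lamb"))
  for (animal in c("goat", "lamb")) {
    have <- sum(labels == animal)
    if (have < target && length(divergent) > 0L) {
      sd_ <- seeds[[paste0("reconcile_", animal)]]
      perm <- withSeed(sd_, sample(divergent))
      fill <- perm[seq_len(min(target - have, length(perm)))]
      labels[fill] <- animal
      divergent <- setdiff(divergent, fill)
    }
  }
  empty <- data.frame(id = character(), statistic = numeric(),
                      stringsAsFactors = FALSE)
  new("ZooLabelMap", labels = labels, goatCandidates = empty,
      lambCandidates = empty, discarded = character(), seed = cfg@seed)
}
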