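#' Cap per-category counts across modalities
#'
#' The number of chimeric individuals of each menagerie category is limited
#' by the modality with the fewest individuals of that category: combining a
#' modality labeled (10 goats, 10 lambs, 80 sheep) with one labeled
#' (5 goats, 5 lambs, 400 sheep) yields caps of 5 goats, 5 lambs, 80 sheep.
#' A label absent from some modality caps at 0.
#'
#' @param counts List (one element per modality) of named label-to-count
#'   vectors.
#' @return Named integer vector, label to capped count.
#' @examples
#' capCategoryCounts(list(c(goat = 10, lamb = 10, sheep = 80),
#'                        c(goat = 5, lamb = 5, sheep = 400)))
#' @export
capCategoryCounts <- function(counts) {
  if (length(counts) == 0L)
    .stopf("integrityError", "no modalities supplied")
  labels <- unique(unlist(lapply(counts, names)))
  if (is.null(labels))
    .stopf("integrityError", "category counts must be named by label")
  caps <- vapply(labels, function(lb) {
    min(vapply(counts, function(cc) {
      v <- cc[lb]
      if (is.na(v)) 0L else as.integer(v)
    }, 0L))
  }, 0L)
  setNames(caps, labels)
}

#' Assign source individuals to chimeric individuals
#'
#' For each label, each modality's individuals carrying that label are put
#' through a seeded random permutation and the first `cap` of them are
#' paired positionally, one per modality, into label-homogeneous chimeric
#' individuals. Each source individual feeds at most one chimeric
#' individual (injective per modality); unselected individuals are unused.
#'
#' @param labelMaps Named list (by modality id) of [ZooLabelMap-class]s.
#' @param caps Named integer vector from [capCategoryCounts()].
#' @param seed Integer seed for the permutations.
#' @return `data.frame` with columns `chimeric_id`, `label`, `modality_id`,
#'   `individual_id`.
#' @export
assignIndividuals <- function(labelMaps, caps, seed) {
  stopifnot(length(labelMaps) >= 1L, !is.null(names(labelMaps)))
  mods <- names(labelMaps)
  labels <- names(caps)[caps > 0L]
  stages <- as.vector(outer(labels, mods, paste, sep = "."))
  seeds <- spawnSeeds(seed, stages)
  out <- list()
  for (lb in labels) {
    cap <- caps[[lb]]
    picked <- lapply(mods, function(m) {
      ids <- names(zooLabels(labelMaps[[m]]))[zooLabels(labelMaps[[m]]) == lb]
      if (length(ids) < cap)
        .stopf("integrityError",
               "cap %d exceeds the %d '%s' individuals of modality '%s'",
               cap, length(ids), lb, m)
      withSeed(seeds[[paste(lb, m, sep = ".")]], sample(ids))[seq_len(cap)]
    })
    cid <- sprintf("%s_%03d", lb, seq_len(cap))
    out[[lb]] <- data.frame(
      chimeric_id = rep(cid, times = length(mods)),
      label = lb,
      modality_id = rep(mods, each = cap),
      individual_id = unlist(picked),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Pair source samples sequentially into chimeric samples
#'
#' Within each session, the k-th sample of every modality (ordered by sample
#' index) forms the k-th chimeric sample; the number of chimeric samples per
#' session is the minimum sample count among the source individuals in that
#' session. Pairing within sessions keeps inter-session evaluation
#' meaningful: training-session samples pair with training, test with test.
#'
#' @param sampleLists Named list (by modality id), each a named list (by
#'   session id) of ordered integer sample indices for the source
#'   individual.
#' @param sessionOrder Session order to emit; defaults to the session order
#'   of the first modality's list.
#' @return `data.frame` with columns `ord` (global 1-based chimeric-sample
#'   ordinal), `session_id`, `modality_id`, `sample_index`.
#' @examples
#' pairSamples(list(m1 = list(s1 = 1:5), m2 = list(s1 = 1:3)))  # 3 samples
#' @export
pairSamples <- function(sampleLists, sessionOrder = NULL) {
  stopifnot(length(sampleLists) >= 1L, !is.null(names(sampleLists)))
  if (is.null(sessionOrder)) sessionOrder <- names(sampleLists[[1L]])
  for (m in names(sampleLists))
    if (!setequal(names(sampleLists[[m]]), sessionOrder))
      .stopf("integrityError",
             "modality '%s' does not cover sessions %s", m,
             paste(sessionOrder, collapse = ", "))
  rows <- list()
  ordBase <- 0L
  for (sess in sessionOrder) {
    counts <- vapply(sampleLists, function(sl) length(sl[[sess]]), 0L)
    if (any(counts == 0L))
      .stopf("insufficientSamplesError",
             "a source individual has no samples in session '%s'", sess)
    ms <- min(counts)
    for (m in names(sampleLists)) {
      rows[[length(rows) + 1L]] <- data.frame(
        ord = ordBase + seq_len(ms),
        session_id = sess,
        modality_id = m,
        sample_index = as.integer(sampleLists[[m]][[sess]][seq_len(ms)]),
        stringsAsFactors = FALSE)
    }
    ordBase <- ordBase + ms
  }
  res <- do.call(rbind, rows)
  res <- res[order(res$ord, res$modality_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Build a chimeric multimodal dataset
#'
#' Orchestrates the full construction: label each modality (unless label
#' maps are supplied), cap the per-category counts at the scarcest modality,
#' assign label-homogeneous source individuals injectively, and pair their
#' samples per session. Every random stage draws its seed deterministically
#' from the master seed, and the complete outcome is recorded in the
#' attached [BuildRecipe-class], so the build is a pure function of
#' (inputs, seed).
#'
#' @param modalities List of >= 2 [ModalityDataset-class]s with identical
#'   session orders.
#' @param cfg A [ZooConfig-class] used for labeling.
#' @param seed Integer master seed.
#' @param labelMaps Optional named list (by modality id) of precomputed
#'   [ZooLabelMap-class]s; when supplied, labeling is skipped.
#' @return A [ChimericDataset-class].
#' @examples
#' suite <- generateSuite(syntheticConfig(nIndividuals = 15, seed = 3L))
#' cds <- buildChimericDataset(suite, seed = 11L)
#' labelCounts(cds)
#' @export
buildChimericDataset <- function(modalities, cfg = zooConfig(), seed = 1L,
                                 labelMaps = NULL) {
  if (length(modalities) < 2L)
    .stopf("integrityError", "a chimeric build needs >= 2 modalities")
  mods <- vapply(modalities, modalityId, "")
  if (anyDuplicated(mods) > 0L)
    .stopf("integrityError", "duplicate modality ids")
  names(modalities) <- mods
  sessions <- sessionOrder(modalities[[1L]])
  for (m in modalities)
    if (!identical(sessionOrder(m), sessions))
      .stopf("integrityError",
             "all modalities must declare the same session order")
  stageNames <- c(paste0("label_", mods), "assignment")
  seeds <- spawnSeeds(seed, stageNames)
  if (is.null(labelMaps)) {
    labelMaps <- lapply(mods, function(m) {
      mcfg <- cfg
      mcfg@seed <- seeds[[paste0("label_", m)]]
      zooLabel(modalities[[m]], mcfg)
    })
    names(labelMaps) <- mods
  } else {
    stopifnot(setequal(names(labelMaps), mods))
    labelMaps <- labelMaps[mods]
  }
  counts <- lapply(labelMaps, function(lm)
    table(factor(zooLabels(lm), levels = c("sheep", "goat", "lamb"))))
  caps <- capCategoryCounts(lapply(counts, function(tt)
    setNames(as.integer(tt), names(tt))))
  ia <- assignIndividuals(labelMaps, caps, seeds[["assignment"]])
  labelAssign <- setNames(ia$label[!duplicated(ia$chimeric_id)],
                          ia$chimeric_id[!duplicated(ia$chimeric_id)])
  pairing <- lapply(unique(ia$chimeric_id), function(cid) {
    rowsc <- ia[ia$chimeric_id == cid, ]
    sampleLists <- setNames(lapply(seq_len(nrow(rowsc)), function(r) {
      cd <- sampleInfo(modalities[[rowsc$modality_id[r]]])
      sel <- cd[cd$individual_id == rowsc$individual_id[r], ]
      setNames(lapply(sessions, function(ss)
        sort(sel$sample_index[sel$session_id == ss])), sessions)
    }), rowsc$modality_id)
    sp <- pairSamples(sampleLists, sessionOrder = sessions)
    sp$chimeric_id <- cid
    sp
  })
  samplePairing <- do.call(rbind, pairing)
  samplePairing <- samplePairing[, c("chimeric_id", "ord", "session_id",
                                     "modality_id", "sample_index")]
  recipe <- BuildRecipe(
    masterSeed = seed, stageSeeds = seeds,
    individualAssignments = ia[, c("chimeric_id", "modality_id",
                                   "individual_id")],
    labelAssignments = labelAssign,
    samplePairing = samplePairing)
  .chimericFromRecipe(recipe)
}

#' @rdname ChimericDataset
#' @export
setMethod("chimericIds", "ChimericDataset", function(x)
  x@individuals$chimeric_id)

#' @rdname ChimericDataset
#' @export
setMethod("labelCounts", "ChimericDataset", function(x) {
  tab <- table(factor(x@individuals$label,
                      levels = c("sheep", "goat", "lamb")))
  setNames(as.integer(tab), names(tab))
})

#' @rdname ChimericDataset
#' @export
setMethod("buildRecipe", "ChimericDataset", function(x) x@recipe)

#' @rdname ChimericDataset
#' @export
setMethod("zooLabels", "ChimericDataset", function(x)
  setNames(x@individuals$label, x@individuals$chimeric_id))

setMethod("show", "ChimericDataset", function(object) {
  lc <- labelCounts(object)
  cat(sprintf("ChimericDataset: %d individuals (%s), %d samples, %d modalities\n",
              nrow(object@individuals),
              paste(sprintf("%d %s", lc, names(lc)), collapse = ", "),
              nrow(object@samples),
              length(unique(object@sources$modality_id))))
  cat(sprintf("master seed %d\n", object@recipe@masterSeed))
})

setMethod("show", "BuildRecipe", function(object) {
  cat(sprintf("BuildRecipe: master seed %d, %d stage seeds, %d chimeric individuals\n",
              object@masterSeed, length(object@stageSeeds),
              length(object@labelAssignments)))
})

#' Per-modality feature matrix of the chimeric samples
#'
#' Resolves the sample references of a chimeric dataset against one source
#' modality and returns the feature vectors aligned with the rows of the
#' dataset's sample manifest.
#'
#' @param cds A [ChimericDataset-class].
#' @param modality The referenced [ModalityDataset-class].
#' @return Numeric matrix, one row per chimeric sample.
#' @export
chimericFeatures <- function(cds, modality) {
  m <- modalityId(modality)
  refs <- cds@sampleRefs[cds@sampleRefs$modality_id == m, , drop = FALSE]
  if (nrow(refs) == 0L)
    .stopf("integrityError", "chimeric dataset has no references to '%s'", m)
  cd <- sampleInfo(modality)
  key <- paste(cd$individual_id, cd$session_id, cd$sample_index, sep = "\r")
  want <- paste(refs$individual_id, refs$session_id, refs$sample_index,
                sep = "\r")
  pos <- match(want, key)
  if (anyNA(pos))
    .stopf("integrityError",
           "referenced samples missing from modality '%s'", m)
  fm <- featureMatrix(modality)[pos, , drop = FALSE]
  out <- matrix(NA_real_, nrow(cds@samples), ncol(fm))
  out[refs$row, ] <- fm
  out
}
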