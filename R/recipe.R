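#' Construct a BuildRecipe
#'
#' Normally produced by [buildChimericDataset()]; exposed so that recipes can
#' be assembled or edited programmatically.
#'
#' @param masterSeed Integer master seed.
#' @param stageSeeds Named integer vector of stage seeds.
#' @param individualAssignments `data.frame` with columns `chimeric_id`,
#'   `modality_id`, `individual_id`.
#' @param labelAssignments Named character vector, chimeric id to label.
#' @param samplePairing `data.frame` with columns `chimeric_id`, `ord`,
#'   `session_id`, `modality_id`, `sample_index`.
#' @return A validated [BuildRecipe-class].
#' @export
BuildRecipe <- function(masterSeed, stageSeeds, individualAssignments,
                        labelAssignments, samplePairing) {
  new("BuildRecipe",
      masterSeed = as.integer(masterSeed),
      stageSeeds = setNames(as.integer(stageSeeds), names(stageSeeds)),
      individualAssignments = .asRecipeDf(individualAssignments,
        c("chimeric_id", "modality_id", "individual_id")),
      labelAssignments = setNames(as.character(labelAssignments),
                                  names(labelAssignments)),
      samplePairing = .asRecipeDf(samplePairing,
        c("chimeric_id", "ord", "session_id", "modality_id", "sample_index")))
}

.asRecipeDf <- function(df, cols) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(cols, colnames(df))
  if (length(missing) > 0L)
    .stopf("integrityError", "recipe table lacks columns: %s",
           paste(missing, collapse = ", "))
  df <- df[, cols, drop = FALSE]
  for (cc in intersect(c("ord", "sample_index"), cols))
    df[[cc]] <- as.integer(df[[cc]])
  for (cc in setdiff(cols, c("ord", "sample_index")))
    df[[cc]] <- as.character(df[[cc]])
  rownames(df) <- NULL
  df
}

#' Write / read a build recipe
#'
#' Recipes are serialized as human-readable JSON so that the seeds and the
#' outcome of every random stage of a build can be audited and shared;
#' `writeRecipe` followed by `readRecipe` is the identity.
#'
#' @param recipe A [BuildRecipe-class].
#' @param path Output (input) path.
#' @return `writeRecipe`: invisibly, `path`. `readRecipe`: the recipe.
#' @export
writeRecipe <- function(recipe, path) {
  stopifnot(is(recipe, "BuildRecipe"))
  if (anyNA(recipe@stageSeeds))
    .stopf("integrityError", "recipe has a missing stage seed")
  cids <- unique(recipe@individualAssignments$chimeric_id)
  uncovered <- setdiff(cids, names(recipe@labelAssignments))
  if (length(uncovered) > 0L)
    .stopf("integrityError", "chimeric ids without a label: %s",
           paste(head(uncovered, 5L), collapse = ", "))
  payload <- list(
    master_seed = recipe@masterSeed,
    stage_seeds = as.list(recipe@stageSeeds),
    individual_assignments = recipe@individualAssignments,
    label_assignments = as.list(recipe@labelAssignments),
    sample_pairing = recipe@samplePairing)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRecipe
#' @export
readRecipe <- function(path) {
  if (!file.exists(path))
    .stopf("integrityError", "recipe file not found: %s", path)
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("master_seed", "stage_seeds", "individual_assignments",
            "label_assignments", "sample_pairing")
  missing <- setdiff(need, names(p))
  if (length(missing) > 0L)
    .stopf("integrityError", "recipe file lacks fields: %s",
           paste(missing, collapse = ", "))
  BuildRecipe(masterSeed = p$master_seed,
              stageSeeds = unlist(p$stage_seeds),
              individualAssignments = p$individual_assignments,
              labelAssignments = unlist(p$label_assignments),
              samplePairing = p$sample_pairing)
}

#' Replay a build recipe against the original source modalities
#'
#' Reconstructs the chimeric dataset recorded in a recipe, checking that
#' every referenced source sample exists in the supplied modalities. The
#' result is identical to the dataset the original build produced.
#'
#' @param recipe A [BuildRecipe-class].
#' @param modalities List of [ModalityDataset-class] objects covering every
#'   modality the recipe references.
#' @return A [ChimericDataset-class].
#' @export
replayRecipe <- function(recipe, modalities) {
  stopifnot(is(recipe, "BuildRecipe"))
  byId <- setNames(modalities, vapply(modalities, modalityId, ""))
  sp <- recipe@samplePairing
  unknown <- setdiff(unique(sp$modality_id), names(byId))
  if (length(unknown) > 0L)
    .stopf("integrityError", "recipe references unknown modalities: %s",
           paste(unknown, collapse = ", "))
  ia <- recipe@individualAssignments
  srcOf <- setNames(ia$individual_id,
                    paste(ia$chimeric_id, ia$modality_id, sep = "\r"))
  ## verify every referenced sample exists
  for (m in names(byId)) {
    spm <- sp[sp$modality_id == m, ]
    if (nrow(spm) == 0L) next
    cd <- SummarizedExperiment::colData(byId[[m]])
    have <- paste(cd$individual_id, cd$session_id, cd$sample_index, sep = "\r")
    want <- paste(srcOf[paste(spm$chimeric_id, m, sep = "\r")],
                  spm$session_id, spm$sample_index, sep = "\r")
    if (!all(want %in% have))
      .stopf("integrityError",
             "recipe references samples absent from modality '%s'", m)
  }
  .chimericFromRecipe(recipe)
}

## Assemble the ChimericDataset object purely from recipe tables.
.chimericFromRecipe <- function(recipe) {
  ia <- recipe@individualAssignments
  la <- recipe@labelAssignments
  sp <- recipe@samplePairing
  cids <- unique(ia$chimeric_id)
  individuals <- data.frame(chimeric_id = cids,
                            label = unname(la[cids]),
                            stringsAsFactors = FALSE)
  srcOf <- setNames(ia$individual_id,
                    paste(ia$chimeric_id, ia$modality_id, sep = "\r"))
  skey <- paste(sp$chimeric_id, sp$ord, sep = "\r")
  uk <- !duplicated(skey)
  samples <- data.frame(chimeric_id = sp$chimeric_id[uk],
                        session_id = sp$session_id[uk],
                        ord = sp$ord[uk], stringsAsFactors = FALSE)
  ord <- order(match(samples$chimeric_id, cids), samples$ord)
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL
  rowOf <- setNames(seq_len(nrow(samples)),
                    paste(samples$chimeric_id, samples$ord, sep = "\r"))
  sampleRefs <- data.frame(
    row = unname(rowOf[skey]),
    modality_id = sp$modality_id,
    individual_id = unname(srcOf[paste(sp$chimeric_id, sp$modality_id,
                                       sep = "\r")]),
    session_id = sp$session_id,
    sample_index = sp$sample_index, stringsAsFactors = FALSE)
  sampleRefs <- sampleRefs[order(sampleRefs$row, sampleRefs$modality_id), ,
                           drop = FALSE]
  rownames(sampleRefs) <- NULL
  new("ChimericDataset", individuals = individuals,
      sources = ia, samples = samples, sampleRefs = sampleRefs,
      recipe = recipe)
}
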