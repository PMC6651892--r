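#' ModalityDataset: feature-vector samples for one biometric modality
#'
#' A `ModalityDataset` holds the fixed-length feature vectors extracted from
#' one biometric modality (e.g. ECG beats, periocular embeddings, face
#' embeddings), together with the per-sample metadata the chimeric-dataset
#' protocol needs: which individual each sample belongs to, which acquisition
#' session it was captured in, and a dense per-(individual, session) sample
#' index. It extends [SummarizedExperiment::SummarizedExperiment] with the
#' feature matrix as the single `"features"` assay (feature dimensions in
#' rows, samples in columns) and the metadata as `colData`.
#'
#' Sessions are ordered by an explicit declared list (`sessionOrder`), never
#' by lexicographic sort; the first session is the training/gallery session,
#' the remaining sessions are test/probe sessions.
#'
#' @slot modalityId Single string naming the modality.
#' @slot sessionOrder Character vector giving the declared session order.
#'
#' @seealso [ModalityDataset()], [readFeatureTable()]
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @exportClass ModalityDataset
setClass("ModalityDataset",
  contains = "SummarizedExperiment",
  slots = c(modalityId = "character", sessionOrder = "character")
)

setValidity("ModalityDataset", function(object) {
  cd <- SummarizedExperiment::colData(object)
  need <- c("individual_id", "session_id", "sample_index")
  if (!all(need %in% colnames(cd)))
    return(sprintf("colData must contain %s", paste(need, collapse = ", ")))
  if (length(object@modalityId) != 1L || !nzchar(object@modalityId))
    return("modalityId must be a single non-empty string")
  if (length(object@sessionOrder) < 1L ||
      anyDuplicated(object@sessionOrder) > 0L)
    return("sessionOrder must be a non-empty set of distinct session ids")
  if (!all(cd$session_id %in% object@sessionOrder))
    return("all session_id values must appear in sessionOrder")
  key <- paste(cd$individual_id, cd$session_id, cd$sample_index, sep = "\r")
  if (anyDuplicated(key) > 0L)
    return("(individual_id, session_id, sample_index) must be unique")
  if (length(unique(cd$individual_id)) < 2L)
    return("a modality needs at least 2 individuals")
  if (nrow(object) < 1L)
    return("feature dimension must be positive")
  TRUE
})

#' ZooConfig: parameters of the Doddington-Zoo labeling stage
#'
#' Holds the selection percentiles and the final per-category fraction used
#' to label the individuals of a modality as sheep, goats, or lambs. Goats
#' are the individuals whose intra-class dispersion ranks above the
#' `goatPercentile` (default 70th) percentile; lamb candidates are those
#' whose mean one-against-all inter-class distance ranks at or below the
#' `lambPercentile` (default 30th) percentile. From each candidate pool a
#' seeded random permutation retains a `finalFraction` (default 10%) of the
#' valid individuals; everyone else is a sheep.
#'
#' @slot goatPercentile Percentage in (0, 100); default 70.
#' @slot lambPercentile Percentage in (0, 100), below `goatPercentile`;
#'   default 30.
#' @slot finalFraction Proportion in (0, 0.5) of valid individuals kept per
#'   minority category; default 0.10.
#' @slot metric Distance metric name (see [featureDistance()]).
#' @slot seed Integer seed for the candidate permutations.
#'
#' @seealso [zooConfig()], [zooLabel()]
#' @exportClass ZooConfig
setClass("ZooConfig", slots = c(
  goatPercentile = "numeric", lambPercentile = "numeric",
  finalFraction = "numeric", metric = "character", seed = "integer"
))

setValidity("ZooConfig", function(object) {
  pg <- object@goatPercentile; pl <- object@lambPercentile
  if (!(pl > 0 && pg > pl && pg < 100))
    return("need 0 < lambPercentile < goatPercentile < 100")
  f <- object@finalFraction
  if (!(f > 0 && f < 0.5)) return("finalFraction must lie in (0, 0.5)")
  if (!object@metric %in% .supportedMetrics)
    return(sprintf("metric must be one of %s",
                   paste(.supportedMetrics, collapse = ", ")))
  TRUE
})

#' ZooLabelMap: menagerie labels for the individuals of one modality
#'
#' The result of the zoo-labeling stage: one label (sheep/goat/lamb) per
#' valid individual, plus the ordered candidate lists with their statistics,
#' the individuals discarded for missing a session, and the seed used for the
#' final selection permutations.
#'
#' @slot labels Named character vector, individual id to label.
#' @slot goatCandidates `data.frame` with columns `id`, `statistic`
#'   (intra-class dispersion), in candidate rank order.
#' @slot lambCandidates `data.frame` with columns `id`, `statistic`
#'   (mean inter-class distance), in candidate rank order.
#' @slot discarded Ids removed for lacking a sample in some session.
#' @slot seed Integer seed used for the final selection.
#'
#' @seealso [zooLabel()], [finalizeLabels()]
#' @exportClass ZooLabelMap
setClass("ZooLabelMap", slots = c(
  labels = "character", goatCandidates = "data.frame",
  lambCandidates = "data.frame", discarded = "character", seed = "integer"
))

setValidity("ZooLabelMap", function(object) {
  lv <- object@labels
  if (is.null(names(lv)) || anyDuplicated(names(lv)) > 0L)
    return("labels must be uniquely named by individual id")
  if (!all(lv %in% c("sheep", "goat", "lamb")))
    return("labels must be sheep, goat, or lamb")
  tab <- table(factor(lv, levels = c("sheep", "goat", "lamb")))
  if (tab[["sheep"]] <= tab[["goat"]] || tab[["sheep"]] <= tab[["lamb"]])
    return("sheep must strictly outnumber goats and lambs")
  TRUE
})

#' BuildRecipe: everything needed to replay a chimeric build
#'
#' A chimeric dataset build is a guided stochastic process; the recipe stores
#' the master seed, the per-stage seeds derived from it, and the concrete
#' outcome of every random stage (which source individual feeds each chimeric
#' individual, which label each received, and exactly which source samples
#' were paired), so that the identical dataset can be reconstructed, shared
#' and audited. Recipes serialize losslessly to JSON via [writeRecipe()].
#'
#' @slot masterSeed Integer master seed of the build.
#' @slot stageSeeds Named integer vector of per-stage seeds.
#' @slot individualAssignments `data.frame` with columns `chimeric_id`,
#'   `modality_id`, `individual_id`.
#' @slot labelAssignments Named character vector, chimeric id to label.
#' @slot samplePairing `data.frame` with columns `chimeric_id`, `ord`,
#'   `session_id`, `modality_id`, `sample_index`.
#'
#' @seealso [buildChimericDataset()], [writeRecipe()], [replayRecipe()]
#' @exportClass BuildRecipe
setClass("BuildRecipe", slots = c(
  masterSeed = "integer", stageSeeds = "integer",
  individualAssignments = "data.frame", labelAssignments = "character",
  samplePairing = "data.frame"
))

setValidity("BuildRecipe", function(object) {
  if (length(object@stageSeeds) == 0L || is.null(names(object@stageSeeds)))
    return("stageSeeds must be a non-empty named integer vector")
  ia <- object@individualAssignments
  if (!all(c("chimeric_id", "modality_id", "individual_id") %in% colnames(ia)))
    return("individualAssignments needs chimeric_id, modality_id, individual_id")
  cids <- unique(ia$chimeric_id)
  if (length(cids) > 0L &&
      !all(cids %in% names(object@labelAssignments)))
    return("every chimeric id must have a label assignment")
  TRUE
})

#' ChimericDataset: assembled chimeric individuals across modalities
#'
#' Chimeric individuals pair one real source individual per modality, all
#' sharing the same Doddington-Zoo label; their samples pair the k-th sample
#' of every modality within each session. The dataset records the
#' individuals, their per-modality sources, the sample manifest, the label
#' counts, and the [BuildRecipe-class] that reproduces the build.
#'
#' @slot individuals `data.frame` with columns `chimeric_id`, `label`.
#' @slot sources `data.frame` with columns `chimeric_id`, `modality_id`,
#'   `individual_id` (injective per modality).
#' @slot samples `data.frame`, one row per chimeric sample: `chimeric_id`,
#'   `session_id`, `ord` (1-based ordinal within the session).
#' @slot sampleRefs `data.frame`, one row per (chimeric sample, modality):
#'   `row` (index into `samples`), `modality_id`, `individual_id`,
#'   `session_id`, `sample_index`.
#' @slot recipe The [BuildRecipe-class] of this build.
#'
#' @seealso [buildChimericDataset()], [chimericFeatures()]
#' @exportClass ChimericDataset
setClass("ChimericDataset", slots = c(
  individuals = "data.frame", sources = "data.frame",
  samples = "data.frame", sampleRefs = "data.frame", recipe = "BuildRecipe"
))

setValidity("ChimericDataset", function(object) {
  ind <- object@individuals
  if (!all(c("chimeric_id", "label") %in% colnames(ind)))
    return("individuals needs chimeric_id and label columns")
  if (anyDuplicated(ind$chimeric_id) > 0L)
    return("chimeric ids must be unique")
  src <- object@sources
  for (m in unique(src$modality_id)) {
    sm <- src[src$modality_id == m, ]
    if (anyDuplicated(sm$individual_id) > 0L)
      return(sprintf("source individuals reused within modality %s", m))
  }
  if (!all(object@samples$chimeric_id %in% ind$chimeric_id))
    return("sample manifest references unknown chimeric ids")
  TRUE
})

#' ScoreSet: genuine and impostor dissimilarity scores
#'
#' The matcher output for one scenario and one method: the genuine
#' (intra-class) and impostor (inter-class) dissimilarity scores, from which
#' decidability, the DET curve and the equal error rate are computed. Scores
#' follow the distance convention throughout: genuine pairs score low.
#'
#' @slot genuine Numeric vector of genuine-pair scores (non-empty).
#' @slot impostor Numeric vector of impostor-pair scores (non-empty).
#' @slot scenario Scenario label (`train_intra`, `test_intra`, `inter`, or
#'   free-form).
#' @slot method Method descriptor (modalities and fusion rule).
#'
#' @seealso [ScoreSet()], [decidability()], [detCurve()], [equalErrorRate()]
#' @exportClass ScoreSet
setClass("ScoreSet", slots = c(
  genuine = "numeric", impostor = "numeric",
  scenario = "character", method = "character"
))

setValidity("ScoreSet", function(object) {
  if (length(object@genuine) == 0L || length(object@impostor) == 0L)
    return("both genuine and impostor score sets must be non-empty")
  if (anyNA(object@genuine) || anyNA(object@impostor))
    return("scores must not contain NA")
  TRUE
})

#' ExperimentReport: aggregated results of the repeated protocol
#'
#' Per method and per scenario, the mean and standard deviation of
#' decidability and EER over the repeated seeded runs, plus the raw per-run
#' values and the seeds that reproduce them.
#'
#' @slot summary `data.frame`: `method`, `scenario`, `decidability_mean`,
#'   `decidability_sd`, `eer_mean`, `eer_sd`.
#' @slot runs `data.frame`: `run`, `seed`, `method`, `scenario`,
#'   `decidability`, `eer`.
#' @slot nRuns Number of runs.
#' @slot masterSeed Master seed of the whole protocol.
#' @slot runSeeds Integer vector of per-run seeds (all distinct).
#'
#' @seealso [runProtocol()], [compareMethods()]
#' @exportClass ExperimentReport
setClass("ExperimentReport", slots = c(
  summary = "data.frame", runs = "data.frame", nRuns = "integer",
  masterSeed = "integer", runSeeds = "integer"
))

setValidity("ExperimentReport", function(object) {
  if (object@nRuns < 2L) return("nRuns must be at least 2")
  if (length(object@runSeeds) != object@nRuns)
    return("one seed per run required")
  if (anyDuplicated(object@runSeeds) > 0L)
    return("run seeds must be distinct")
  TRUE
})
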