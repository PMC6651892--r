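#' @rdname ModalityDataset
#' @param object,x An object.
#' @export
setGeneric("modalityId", function(x) standardGeneric("modalityId"))

#' @rdname ModalityDataset
#' @export
setGeneric("sessionOrder", function(x) standardGeneric("sessionOrder"))

#' @rdname ModalityDataset
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname ModalityDataset
#' @export
setGeneric("individualIds", function(x) standardGeneric("individualIds"))

#' @rdname ModalityDataset
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname ModalityDataset
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))

#' @rdname ModalityDataset
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))

#' @rdname ZooLabelMap
#' @param x An object carrying menagerie labels.
#' @export
setGeneric("zooLabels", function(x) standardGeneric("zooLabels"))

#' @rdname ChimericDataset
#' @param x A [ChimericDataset-class].
#' @export
setGeneric("chimericIds", function(x) standardGeneric("chimericIds"))

#' @rdname ChimericDataset
#' @export
setGeneric("labelCounts", function(x) standardGeneric("labelCounts"))

#' @rdname ChimericDataset
#' @export
setGeneric("buildRecipe", function(x) standardGeneric("buildRecipe"))

#' Decidability of a genuine/impostor score separation
#'
#' Decidability (d') measures how far apart the genuine (intra-class) and
#' impostor (inter-class) score distributions lie:
#' \deqn{d' = \frac{|\mu_E - \mu_I|}{\sqrt{(\sigma_I^2 + \sigma_E^2)/2}}}
#' where \eqn{\mu_I, \sigma_I} are the sample mean and standard deviation of
#' the genuine scores and \eqn{\mu_E, \sigma_E} those of the impostor scores.
#' It is invariant under common affine rescaling of all scores.
#'
#' @param scores A [ScoreSet-class].
#' @return A single non-negative number.
#' @examples
#' s <- ScoreSet(genuine = rnorm(100, 1), impostor = rnorm(100, 3))
#' decidability(s)
#' @export
setGeneric("decidability", function(scores) standardGeneric("decidability"))

#' Detection Error Trade-off curve
#'
#' Sweeps a decision threshold over all distinct scores (plus infinite
#' sentinels) and records the false acceptance rate (fraction of impostor
#' scores strictly below the threshold) and false rejection rate (fraction
#' of genuine scores at or above it), under the distance convention where a
#' probe is accepted when its score falls below the threshold.
#'
#' @param scores A [ScoreSet-class].
#' @return A `data.frame` with columns `threshold`, `far`, `frr`, ordered by
#'   increasing threshold; `far` is non-decreasing and `frr` non-increasing,
#'   with endpoints (far = 0, frr = 1) and (far = 1, frr = 0).
#' @seealso [equalErrorRate()]
#' @export
setGeneric("detCurve", function(scores) standardGeneric("detCurve"))

#' Equal Error Rate
#'
#' The operating point of the DET curve where the false acceptance rate
#' equals the false rejection rate, located by linear interpolation between
#' the adjacent thresholds where FAR - FRR changes sign. EER is invariant
#' under any strictly monotone transform applied to all scores.
#'
#' @param scores A [ScoreSet-class], or a DET-curve `data.frame` as returned
#'   by [detCurve()].
#' @return A rate in \[0, 1\].
#' @examples
#' s <- ScoreSet(genuine = rnorm(500, 0), impostor = rnorm(500, 2))
#' equalErrorRate(s)   # near pnorm(-1) for unit-variance classes 2 apart
#' @export
setGeneric("equalErrorRate", function(scores) standardGeneric("equalErrorRate"))
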