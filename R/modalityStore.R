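#' Construct a ModalityDataset
#'
#' @param features Numeric matrix of feature vectors, one sample per row,
#'   `d` columns.
#' @param individual Character vector of individual ids, one per sample.
#' @param session Character vector of session ids, one per sample.
#' @param sampleIndex Integer vector of per-(individual, session) sample
#'   indices. If `NULL`, dense 1-based indices are assigned in input order.
#' @param modalityId Single string naming the modality.
#' @param sessionOrder Declared session order; defaults to the order of first
#'   appearance in `session`.
#' @return A validated [ModalityDataset-class].
#' @examples
#' f <- matrix(rnorm(12), nrow = 4)
#' md <- ModalityDataset(f, individual = c("a", "a", "b", "b"),
#'                       session = c("s1", "s2", "s1", "s2"),
#'                       modalityId = "toy")
#' nIndividuals(md)
#' @export
ModalityDataset <- function(features, individual, session, sampleIndex = NULL,
                            modalityId, sessionOrder = NULL) {
  features <- as.matrix(features)
  if (nrow(features) == 0L)
    .stopf("emptyInputError", "no samples supplied for modality '%s'",
           modalityId)
  storage.mode(features) <- "double"
  n <- nrow(features)
  individual <- as.character(individual)
  session <- as.character(session)
  if (length(session) == 1L) session <- rep(session, n)
  if (length(individual) != n || length(session) != n)
    .stopf("integrityError", "metadata length does not match sample count")
  if (is.null(sessionOrder)) sessionOrder <- unique(session)
  if (is.null(sampleIndex)) {
    key <- paste(individual, session, sep = "\r")
    sampleIndex <- stats::ave(seq_len(n), key, FUN = seq_along)
  }
  sampleIndex <- as.integer(sampleIndex)
  key <- paste(individual, session, sampleIndex, sep = "\r")
  if (anyDuplicated(key) > 0L)
    .stopf("integrityError",
           "duplicate (individual, session, sample) key in modality '%s'",
           modalityId)
  cd <- S4Vectors::DataFrame(individual_id = individual,
                             session_id = session,
                             sample_index = sampleIndex)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(features)), colData = cd)
  colnames(se) <- key
  new("ModalityDataset", se, modalityId = as.character(modalityId),
      sessionOrder = as.character(sessionOrder))
}

#' Read a delimited per-modality feature table
#'
#' The expected layout is a header row with `individual`, `session`,
#' `sample` columns followed by the feature columns `f1..fd`; fields are
#' comma-separated by default, tab-separated tables are accepted. Row order
#' never affects downstream results.
#'
#' @param path Path to the feature table.
#' @param modalityId Modality name to attach.
#' @param sessionOrder Declared session order; defaults to order of first
#'   appearance (after sorting rows by individual, session, sample this is
#'   deterministic regardless of input row order).
#' @param sep Field separator; `NULL` (default) auto-detects comma vs tab
#'   from the header line.
#' @return A validated [ModalityDataset-class].
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, modalityId, sessionOrder = NULL,
                             sep = NULL) {
  if (!file.exists(path))
    .stopf("integrityError", "feature table not found: %s", path)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L || !nzchar(header))
    .stopf("emptyInputError", "empty feature table: %s", path)
  if (is.null(sep))
    sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  tab <- tryCatch(
    read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
               colClasses = NA, check.names = FALSE),
    error = function(e)
      .stopf("dimensionError", "ragged or malformed feature table: %s",
             conditionMessage(e)))
  if (nrow(tab) == 0L)
    .stopf("emptyInputError", "feature table has no data rows: %s", path)
  need <- c("individual", "session", "sample")
  if (!all(need %in% colnames(tab)))
    .stopf("integrityError", "header must declare columns %s",
           paste(need, collapse = ", "))
  fcols <- setdiff(colnames(tab), need)
  if (length(fcols) == 0L)
    .stopf("dimensionError", "no feature columns found")
  feats <- as.matrix(tab[, fcols, drop = FALSE])
  if (!is.numeric(feats) || anyNA(feats))
    .stopf("dimensionError",
           "non-numeric or missing feature values (ragged rows?)")
  ## canonical row order: parse is insensitive to input row permutation
  ord <- order(tab$individual, tab$session, tab$sample, method = "radix")
  ModalityDataset(feats[ord, , drop = FALSE],
                  individual = tab$individual[ord],
                  session = tab$session[ord],
                  sampleIndex = tab$sample[ord],
                  modalityId = modalityId, sessionOrder = sessionOrder)
}

#' Write a ModalityDataset as a delimited feature table
#'
#' @param x A [ModalityDataset-class].
#' @param path Output path.
#' @param sep Field separator (default comma).
#' @return Invisibly, `path`.
#' @export
writeFeatureTable <- function(x, path, sep = ",") {
  info <- sampleInfo(x)
  feats <- featureMatrix(x)
  colnames(feats) <- paste0("f", seq_len(ncol(feats)))
  out <- data.frame(individual = info$individual_id,
                    session = info$session_id,
                    sample = info$sample_index,
                    feats, check.names = FALSE)
  write.table(out, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname ModalityDataset
#' @export
setMethod("modalityId", "ModalityDataset", function(x) x@modalityId)

#' @rdname ModalityDataset
#' @export
setMethod("sessionOrder", "ModalityDataset", function(x) x@sessionOrder)

#' @rdname ModalityDataset
#' @export
setMethod("featureDim", "ModalityDataset", function(x) nrow(x))

#' @rdname ModalityDataset
#' @export
setMethod("individualIds", "ModalityDataset", function(x)
  sort(unique(SummarizedExperiment::colData(x)$individual_id)))

#' @rdname ModalityDataset
#' @export
setMethod("nIndividuals", "ModalityDataset", function(x)
  length(individualIds(x)))

#' @rdname ModalityDataset
#' @export
setMethod("sampleInfo", "ModalityDataset", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @rdname ModalityDataset
#' @export
setMethod("featureMatrix", "ModalityDataset", function(x)
  t(SummarizedExperiment::assay(x, "features")))

setMethod("show", "ModalityDataset", function(object) {
  cat(sprintf("ModalityDataset '%s': %d samples x %d features, %d individuals\n",
              object@modalityId, ncol(object), nrow(object),
              nIndividuals(object)))
  cat("sessions:", paste(object@sessionOrder, collapse = " < "), "\n")
})

## Feature vectors of one individual in one session, rows ordered by
## sample_index. Returns a matrix (possibly 0-row).
.individualSession <- function(mds, individual, session) {
  cd <- SummarizedExperiment::colData(mds)
  sel <- which(cd$individual_id == individual & cd$session_id == session)
  sel <- sel[order(cd$sample_index[sel])]
  fm <- t(SummarizedExperiment::assay(mds, "features"))[sel, , drop = FALSE]
  attr(fm, "sample_index") <- cd$sample_index[sel]
  fm
}

## Per-individual sample counts in one session for all given individuals.
.sessionCounts <- function(mds, individuals, session) {
  cd <- SummarizedExperiment::colData(mds)
  sel <- cd$session_id == session & cd$individual_id %in% individuals
  tab <- table(factor(cd$individual_id[sel], levels = individuals))
  setNames(as.integer(tab), individuals)
}
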