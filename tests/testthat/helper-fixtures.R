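## Fixture builders shared across test files. Everything is generated in
## code; no stored data.

## A tiny handmade modality: nInd individuals x sessions, k samples each,
## deterministic features unless noise() supplied.
makeModality <- function(nInd = 3L, k = 2L, d = 3L,
                         sessions = c("s1", "s2"),
                         modalityId = "toy", seed = 1L) {
  set.seed(seed)
  ids <- sprintf("p%02d", seq_len(nInd))
  rows <- expand.grid(sample = seq_len(k), session = sessions,
                      individual = ids, stringsAsFactors = FALSE)
  feats <- matrix(rnorm(nrow(rows) * d), ncol = d)
  ModalityDataset(feats, individual = rows$individual,
                  session = rows$session, sampleIndex = rows$sample,
                  modalityId = modalityId, sessionOrder = sessions)
}

## A small synthetic suite for builder/eval tests.
smallSuite <- function(n = c(12L, 14L, 16L), d = 4L, seed = 1L) {
  specs <- lapply(seq_along(n), function(k)
    list(modalityId = paste0("m", k), dim = d, nIndividuals = n[k]))
  generateSuite(syntheticConfig(nIndividuals = n[1L], modalities = specs,
                                seed = seed))
}

## Brute-force distance between two vectors, independent of the package's
## vectorized paths.
refDistance <- function(u, v, metric) {
  switch(metric,
    euclidean = sqrt(sum((u - v)^2)),
    manhattan = sum(abs(u - v)),
    hamming = mean(u != v),
    spearman = 1 - cor(rank(u), rank(v)))
}

## Exhaustive labeling statistics by double loops over training samples.
refLabelingStats <- function(mds, ids, metric) {
  sess <- sessionOrder(mds)[1L]
  info <- sampleInfo(mds)
  fm <- featureMatrix(mds)
  rowsOf <- function(id) {
    sel <- which(info$individual_id == id & info$session_id == sess)
    sel[order(info$sample_index[sel])]
  }
  disp <- sep <- setNames(numeric(length(ids)), ids)
  for (id in ids) {
    own <- rowsOf(id)
    ds <- c()
    for (a in seq_along(own)) for (b in seq_along(own)) if (a < b)
      ds <- c(ds, refDistance(fm[own[a], ], fm[own[b], ], metric))
    disp[id] <- mean(ds)
    xs <- c()
    for (other in setdiff(ids, id)) for (o in rowsOf(other)) for (a in own)
      xs <- c(xs, refDistance(fm[a, ], fm[o, ], metric))
    sep[id] <- mean(xs)
  }
  list(dispersion = disp, separation = sep)
}

## Independent candidate-selection oracle: naive rank arithmetic.
refGoatCandidates <- function(dispersions, p = 70) {
  N <- length(dispersions)
  idx <- p / 100 * N + 0.5
  ord <- order(dispersions, names(dispersions))
  names(dispersions)[ord][seq_len(N) > idx]
}

refLambCandidates <- function(separations, p = 30) {
  N <- length(separations)
  k <- floor(p / 100 * N + 0.5 + 0.5)
  ord <- order(separations, names(separations))
  head(names(separations)[ord], min(k, N))
}
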