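test_that("category caps take the minimum across modalities", {
  caps <- capCategoryCounts(list(c(goat = 10, lamb = 10, sheep = 80),
                                 c(goat = 5, lamb = 5, sheep = 400)))
  expect_equal(caps, c(goat = 5L, lamb = 5L, sheep = 80L))

  same <- c(goat = 3, lamb = 4, sheep = 20)
  expect_equal(capCategoryCounts(list(same, same)),
               c(goat = 3L, lamb = 4L, sheep = 20L))

  missing <- capCategoryCounts(list(c(goat = 2, sheep = 10),
                                    c(goat = 1, lamb = 3, sheep = 10)))
  expect_equal(missing[["lamb"]], 0L)
  expect_error(capCategoryCounts(list()), class = "integrityError")
})

test_that("individual assignment is label-homogeneous and injective", {
  mk <- function(labels, ids) new("ZooLabelMap",
    labels = setNames(labels, ids),
    goatCandidates = data.frame(id = character(), statistic = numeric()),
    lambCandidates = data.frame(id = character(), statistic = numeric()),
    discarded = character(), seed = 1L)
  idsA <- sprintf("a%02d", 1:8); idsB <- sprintf("b%02d", 1:9)
  labsA <- c("goat", "lamb", rep("sheep", 6))
  labsB <- c("goat", "goat", "lamb", rep("sheep", 6))
  maps <- list(m1 = mk(labsA, idsA), m2 = mk(labsB, idsB))
  caps <- c(goat = 1L, lamb = 1L, sheep = 2L)
  ia <- assignIndividuals(maps, caps, seed = 5L)
  expect_identical(length(unique(ia$chimeric_id)), 4L)
  ## label homogeneity: each chimeric id's sources carry its label
  for (cid in unique(ia$chimeric_id)) {
    sub <- ia[ia$chimeric_id == cid, ]
    for (r in seq_len(nrow(sub))) {
      lm <- maps[[sub$modality_id[r]]]
      expect_identical(unname(zooLabels(lm)[sub$individual_id[r]]),
                       sub$label[r])
    }
  }
  ## injectivity per modality across many seeds; determinism; variability
  assigns <- lapply(1:20, function(s) assignIndividuals(maps, caps, s))
  for (a in assigns)
    for (m in c("m1", "m2"))
      expect_identical(anyDuplicated(a$individual_id[a$modality_id == m]),
                       0L)
  expect_identical(assignIndividuals(maps, caps, 5L), ia)
  expect_true(any(!vapply(assigns, identical, TRUE, assigns[[1L]])))

  expect_error(assignIndividuals(maps, c(goat = 2L, lamb = 1L, sheep = 2L),
                                 seed = 1L),
               class = "integrityError")
})

test_that("sample pairing takes the per-session minimum sequentially", {
  sp <- pairSamples(list(m1 = list(s1 = 1:5), m2 = list(s1 = 1:3),
                         m3 = list(s1 = 1:4)))
  expect_identical(max(sp$ord), 3L)
  expect_identical(sp$sample_index[sp$modality_id == "m1"], 1:3)

  eq <- pairSamples(list(m1 = list(s1 = 1:4), m2 = list(s1 = 1:4)))
  expect_identical(max(eq$ord), 4L)
  expect_identical(eq$sample_index[eq$modality_id == "m2"], eq$ord[eq$modality_id == "m2"])

  two <- pairSamples(list(m1 = list(s1 = 1:4, s2 = 1:3),
                          m2 = list(s1 = 1:2, s2 = 1:3)))
  expect_identical(max(two$ord), 5L)  # min(4,2) + min(3,3)
  expect_identical(unique(two$session_id[two$ord <= 2]), "s1")

  expect_error(pairSamples(list(m1 = list(s1 = 1:3, s2 = integer()),
                                m2 = list(s1 = 1:2, s2 = 1:2))),
               class = "insufficientSamplesError")
  expect_error(pairSamples(list(m1 = list(s1 = 1:3), m2 = list(sX = 1:3))),
               class = "integrityError")
})

test_that("the build is capped by the scarcest modality", {
  specs <- lapply(seq_along(c(60L, 56L, 70L)), function(k)
    list(modalityId = paste0("m", k), dim = 6L,
         nIndividuals = c(60L, 56L, 70L)[k]))
  suite <- generateSuite(syntheticConfig(modalities = specs, seed = 2L))
  cds <- buildChimericDataset(suite, seed = 31L)
  expect_identical(length(chimericIds(cds)), 56L)
  expect_identical(sum(labelCounts(cds)), 56L)

  expect_error(buildChimericDataset(suite[1], seed = 1L),
               class = "integrityError")
})

test_that("build invariants hold across seeds", {
  suite <- smallSuite(n = c(10L, 12L, 14L), seed = 6L)
  infos <- lapply(suite, sampleInfo)
  violations <- character()
  for (seed in 1:12) {
    cds <- buildChimericDataset(suite, seed = seed)
    ## per-category counts equal caps derived from that run's labeling
    lmaps <- list()
    stageSeeds <- buildRecipe(cds)@stageSeeds
    for (m in names(suite)) {
      cfg <- zooConfig()
      cfg@seed <- stageSeeds[[paste0("label_", m)]]
      lmaps[[m]] <- zooLabel(suite[[m]], cfg)
    }
    caps <- capCategoryCounts(lapply(lmaps, function(m)
      table(zooLabels(m))))
    if (!isTRUE(all.equal(labelCounts(cds)[names(caps)], caps)))
      violations <- c(violations, sprintf("seed %d: counts != caps", seed))
    ## label homogeneity against the per-run maps
    src <- cds@sources
    labOf <- zooLabels(cds)
    srcLab <- vapply(seq_len(nrow(src)), function(r)
      unname(zooLabels(lmaps[[src$modality_id[r]]])[src$individual_id[r]]),
      "")
    if (!all(srcLab == labOf[src$chimeric_id]))
      violations <- c(violations, sprintf("seed %d: label mix", seed))
    ## no sample reuse: referenced source samples are unique per modality
    refs <- cds@sampleRefs
    key <- paste(refs$modality_id, refs$individual_id, refs$session_id,
                 refs$sample_index)
    if (anyDuplicated(key) > 0L)
      violations <- c(violations, sprintf("seed %d: sample reuse", seed))
    ## per-chimeric per-session sample count = min across sources
    smp <- cds@samples
    got <- table(smp$chimeric_id, smp$session_id)
    for (cid in chimericIds(cds)) {
      srcs <- src[src$chimeric_id == cid, ]
      for (ss in c("s1", "s2")) {
        avail <- vapply(seq_len(nrow(srcs)), function(r) {
          info <- infos[[srcs$modality_id[r]]]
          sum(info$individual_id == srcs$individual_id[r] &
                info$session_id == ss)
        }, 0L)
        if (got[cid, ss] != min(avail))
          violations <- c(violations,
                          sprintf("seed %d: %s/%s sample count", seed, cid, ss))
      }
    }
  }
  expect_identical(violations, character())
})

test_that("the build is a pure function of inputs and seed", {
  suite <- smallSuite(n = c(10L, 11L), seed = 8L)
  a <- buildChimericDataset(suite, seed = 77L)
  b <- buildChimericDataset(suite, seed = 77L)
  expect_equal(a@individuals, b@individuals)
  expect_equal(a@sources, b@sources)
  expect_equal(a@samples, b@samples)
  expect_equal(a@sampleRefs, b@sampleRefs)
  expect_identical(buildRecipe(a)@stageSeeds, buildRecipe(b)@stageSeeds)
})
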