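#' Default method grid: every unimodal method plus all-modality fusions
#'
#' @param modalityIds Character vector of modality ids.
#' @param fusions Fusion rules for the all-modality methods.
#' @return List of method specs (`list(modalities, fusion)`), named.
#' @export
defaultMethods <- function(modalityIds, fusions = "sum") {
  uni <- lapply(modalityIds, function(m) list(modalities = m, fusion = NULL))
  names(uni) <- modalityIds
  fus <- lapply(fusions, function(r)
    list(modalities = modalityIds, fusion = r))
  names(fus) <- paste0(paste(modalityIds, collapse = "+"), ":", fusions)
  c(uni, fus)
}

#' Run the repeated seeded evaluation protocol
#'
#' Because the chimeric dataset construction is a guided stochastic
#' process, every evaluation repeats the whole pipeline: each run draws a
#' fresh seed from the master seed, rebuilds the chimeric dataset (new zoo
#' selection permutations, new individual assignment), scores every
#' configured method in every scenario, and records decidability and EER.
#' The report aggregates mean and standard deviation over the runs
#' (30 by default) and keeps the per-run values and seeds.
#'
#' @param modalities Named list of source [ModalityDataset-class]s (fixed
#'   across runs).
#' @param methods List of method specs (`list(modalities, fusion)`);
#'   default: [defaultMethods()] with sum-rule fusion of all modalities.
#' @param cfg A [ZooConfig-class] for the labeling stage.
#' @param nRuns Number of repetitions (>= 2, default 30).
#' @param masterSeed Integer master seed; the per-run seeds derive from it.
#' @param metrics Named per-modality metric vector (or one name for all).
#' @param pairLimits Optional `c(genuine=, impostor=)` caps passed to
#'   [enumeratePairs()].
#' @param scenarios Scenarios to evaluate.
#' @return An [ExperimentReport-class].
#' @export
runProtocol <- function(modalities, methods = NULL, cfg = zooConfig(),
                        nRuns = 30L, masterSeed = 1L,
                        metrics = "euclidean", pairLimits = NULL,
                        scenarios = c("train_intra", "test_intra", "inter")) {
  if (nRuns < 2L)
    .stopf("validationError", "nRuns must be at least 2")
  mods <- vapply(modalities, modalityId, "")
  names(modalities) <- mods
  metrics <- if (length(metrics) == 1L && is.null(names(metrics)))
    setNames(rep(metrics, length(mods)), mods) else metrics
  if (is.null(methods)) methods <- defaultMethods(mods)
  if (is.null(names(methods)))
    names(methods) <- vapply(methods, function(ms)
      if (is.null(ms$fusion)) ms$modalities[1L] else
        paste0(paste(ms$modalities, collapse = "+"), ":", ms$fusion), "")
  runSeeds <- spawnSeeds(masterSeed, paste0("run_", seq_len(nRuns)))
  rows <- vector("list", nRuns)
  for (r in seq_len(nRuns)) {
    rows[[r]] <- tryCatch(
      .oneRun(modalities, methods, cfg, runSeeds[[r]], metrics,
              pairLimits, scenarios, r),
      error = function(e) stop(sprintf(
        "protocol run %d (seed %d) failed: %s",
        r, runSeeds[[r]], conditionMessage(e)), call. = FALSE))
  }
  runs <- do.call(rbind, rows)
  rownames(runs) <- NULL
  agg <- stats::aggregate(
    cbind(decidability, eer) ~ method + scenario, data = runs,
    FUN = function(x) c(mean = mean(x), sd = sd(x)))
  summary <- data.frame(
    method = agg$method, scenario = agg$scenario,
    decidability_mean = agg$decidability[, "mean"],
    decidability_sd = agg$decidability[, "sd"],
    eer_mean = agg$eer[, "mean"], eer_sd = agg$eer[, "sd"],
    stringsAsFactors = FALSE)
  new("ExperimentReport", summary = summary, runs = runs,
      nRuns = as.integer(nRuns), masterSeed = as.integer(masterSeed),
      runSeeds = unname(runSeeds))
}

.oneRun <- function(modalities, methods, cfg, runSeed, metrics,
                    pairLimits, scenarios, runIdx) {
  seeds <- spawnSeeds(runSeed, c("build", "pairs"))
  cds <- buildChimericDataset(modalities, cfg, seed = seeds[["build"]])
  res <- list()
  for (sc in scenarios) {
    man <- enumeratePairs(cds, sc, limits = pairLimits,
                          seed = seeds[["pairs"]])
    for (mn in names(methods)) {
      ms <- methods[[mn]]
      ss <- scorePairs(man, cds, modalities[ms$modalities],
                       metrics = metrics[ms$modalities],
                       fusion = ms$fusion)
      res[[length(res) + 1L]] <- data.frame(
        run = runIdx, seed = runSeed, method = mn, scenario = sc,
        decidability = decidability(ss), eer = equalErrorRate(ss),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, res)
}

setMethod("show", "ExperimentReport", function(object) {
  cat(sprintf("ExperimentReport: %d runs, master seed %d\n",
              object@nRuns, object@masterSeed))
  print(object@summary, digits = 4)
})

#' Per-run results and summary accessors
#'
#' @param report An [ExperimentReport-class].
#' @return `reportSummary`: the per-method/scenario mean and sd table;
#'   `reportRuns`: the per-run raw values.
#' @export
reportSummary <- function(report) report@summary

#' @rdname reportSummary
#' @export
reportRuns <- function(report) report@runs

#' Compare every method against the best one per scenario
#'
#' For each scenario the method with the lowest mean EER is taken as the
#' reference, and every method's per-run EER vector is compared against it
#' with Welch's two-sample t-test. Methods whose p-value is at or above
#' `alpha` are flagged as statistically equivalent to the best.
#'
#' @param report An [ExperimentReport-class] with >= 2 methods.
#' @param alpha Significance level (default 0.05).
#' @return `data.frame` with columns `scenario`, `method`, `eer_mean`,
#'   `best`, `t`, `p`, `equivalent_to_best`.
#' @export
compareMethods <- function(report, alpha = 0.05) {
  runs <- report@runs
  methods <- unique(runs$method)
  if (length(methods) < 2L)
    .stopf("integrityError", "method comparison needs >= 2 methods")
  cnt <- table(runs$method, runs$scenario)
  if (length(unique(as.vector(cnt))) != 1L)
    .stopf("integrityError", "unequal run counts across methods")
  out <- list()
  for (sc in unique(runs$scenario)) {
    sub <- runs[runs$scenario == sc, ]
    means <- tapply(sub$eer, sub$method, mean)
    best <- names(means)[which.min(means)]
    x <- sub$eer[sub$method == best]
    for (mn in names(means)) {
      y <- sub$eer[sub$method == mn]
      if (isTRUE(all.equal(x, y)) || (sd(x) == 0 && sd(y) == 0)) {
        tt <- list(statistic = if (mean(x) == mean(y)) 0 else Inf,
                   p.value = if (mean(x) == mean(y)) 1 else 0)
      } else {
        ht <- t.test(y, x, var.equal = FALSE)
        tt <- list(statistic = unname(ht$statistic), p.value = ht$p.value)
      }
      out[[length(out) + 1L]] <- data.frame(
        scenario = sc, method = mn, eer_mean = unname(means[mn]),
        best = best, t = tt$statistic, p = tt$p.value,
        equivalent_to_best = tt$p.value >= alpha,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
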