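#' Configuration of the synthetic multi-session feature generator
#'
#' The generator emulates per-modality biometric embedding tables with a
#' controllable Doddington-Zoo structure, so the whole chimeric protocol can
#' be exercised without external biometric data. Each individual gets a
#' spherical-Gaussian class center (scale `sigmaBetween`); each session adds
#' an individual-by-session drift offset (scale `sigmaDrift`, the source of
#' inter-session hardness); each sample adds within-class noise (scale
#' `sigmaWithin`). Planted goats have their within-class noise inflated by
#' `goatMultiplier`; planted lambs have their center shrunk toward the
#' origin (the population mean) by `lambShrink`, lowering their
#' one-against-all separation.
#'
#' @param nIndividuals Default number of individuals per modality.
#' @param modalities List of per-modality specs: `list(modalityId, dim,
#'   sigmaBetween, sigmaWithin, sigmaDrift, nIndividuals)`; missing fields
#'   fall back to the defaults below. Default: three 16-dimensional
#'   modalities with `sigmaBetween = 1`, `sigmaWithin = 0.5`,
#'   `sigmaDrift = 0.3`.
#' @param goatFraction,lambFraction Fractions of individuals planted as
#'   goats / lambs (default 0.10 each; must sum below 0.5).
#' @param goatMultiplier Within-class noise multiplier for planted goats
#'   (> 1, default 2: goats are markedly harder to match but remain better
#'   than chance — larger values push goat genuine scores past the impostor
#'   distribution).
#' @param lambShrink Center shrink factor for planted lambs (in (0,1),
#'   default 0.5).
#' @param samplesRange Integer range of per-(individual, session) sample
#'   counts, minimum >= 2 (default 3..6).
#' @param sessions Ordered session ids (default two sessions).
#' @param mode `"independent"` (separate individual pools per modality) or
#'   `"shared"` (one pool, identical ids and planted labels across
#'   modalities).
#' @param seed Integer seed.
#' @return A validated configuration list of class `SyntheticConfig`.
#' @export
syntheticConfig <- function(nIndividuals = 50,
                            modalities = NULL,
                            goatFraction = 0.10, lambFraction = 0.10,
                            goatMultiplier = 2, lambShrink = 0.5,
                            samplesRange = c(3L, 6L),
                            sessions = c("s1", "s2"),
                            mode = c("independent", "shared"),
                            seed = 1L) {
  mode <- match.arg(mode)
  if (is.null(modalities))
    modalities <- lapply(c("m1", "m2", "m3"), function(m) list(modalityId = m))
  defaults <- list(dim = 16L, sigmaBetween = 1, sigmaWithin = 0.5,
                   sigmaDrift = 0.3, nIndividuals = nIndividuals)
  modalities <- lapply(modalities, function(sp) {
    for (f in names(defaults)) if (is.null(sp[[f]])) sp[[f]] <- defaults[[f]]
    sp
  })
  cfg <- list(nIndividuals = as.integer(nIndividuals),
              modalities = modalities,
              goatFraction = goatFraction, lambFraction = lambFraction,
              goatMultiplier = goatMultiplier, lambShrink = lambShrink,
              samplesRange = as.integer(samplesRange),
              sessions = as.character(sessions),
              mode = mode, seed = as.integer(seed))
  .validateSyntheticConfig(cfg)
  class(cfg) <- "SyntheticConfig"
  cfg
}

.validateSyntheticConfig <- function(cfg) {
  ok <- function(cond, msg) if (!cond) .stopf("validationError", msg)
  ok(cfg$goatFraction + cfg$lambFraction < 0.5,
     "goat and lamb fractions must sum below 0.5")
  ok(cfg$goatFraction >= 0 && cfg$lambFraction >= 0,
     "fractions must be non-negative")
  ok(cfg$goatMultiplier > 1, "goatMultiplier must exceed 1")
  ok(cfg$lambShrink > 0 && cfg$lambShrink < 1,
     "lambShrink must lie in (0, 1)")
  ok(length(cfg$samplesRange) == 2L && cfg$samplesRange[1L] >= 2L &&
       cfg$samplesRange[2L] >= cfg$samplesRange[1L],
     "samplesRange must be (min >= 2, max >= min)")
  ok(length(cfg$sessions) >= 1L, "need at least one session")
  ok(length(cfg$modalities) >= 1L, "need at least one modality spec")
  for (sp in cfg$modalities) {
    ok(!is.null(sp$modalityId), "every modality spec needs a modalityId")
    ok(sp$dim >= 1L, "feature dimension must be positive")
    ok(sp$sigmaBetween > 0 && sp$sigmaWithin > 0 && sp$sigmaDrift >= 0,
       "sigmas must be positive (sigmaDrift may be 0)")
    ok(sp$nIndividuals >= 2L, "need at least 2 individuals")
  }
  invisible(cfg)
}

## Planted menagerie labels for n individuals under one seed.
.plantLabels <- function(ids, goatFraction, lambFraction, seed) {
  n <- length(ids)
  nG <- roundHalfUp(goatFraction * n)
  nL <- roundHalfUp(lambFraction * n)
  labels <- setNames(rep("sheep", n), ids)
  perm <- withSeed(seed, sample(ids))
  if (nG > 0L) labels[perm[seq_len(nG)]] <- "goat"
  if (nL > 0L) labels[perm[nG + seq_len(nL)]] <- "lamb"
  labels
}

#' Generate one synthetic modality
#'
#' @param cfg A [syntheticConfig()].
#' @param spec One entry of `cfg$modalities`.
#' @param plantedLabels Named character vector id -> planted label
#'   (`sheep`/`goat`/`lamb`), one per individual.
#' @param seed Integer seed for this modality's draws.
#' @return A [ModalityDataset-class].
#' @export
generateModality <- function(cfg, spec, plantedLabels, seed) {
  .validateSyntheticConfig(unclass(cfg))
  ids <- names(plantedLabels)
  n <- length(ids)
  d <- as.integer(spec$dim)
  withSeed(seed, {
    centers <- matrix(rnorm(n * d, sd = spec$sigmaBetween), n, d)
    shrink <- ifelse(plantedLabels == "lamb", cfg$lambShrink, 1)
    centers <- centers * shrink
    noiseSd <- ifelse(plantedLabels == "goat",
                      spec$sigmaWithin * cfg$goatMultiplier,
                      spec$sigmaWithin)
    rows <- list()
    for (jj in seq_len(n)) {
      for (ss in cfg$sessions) {
        drift <- rnorm(d, sd = spec$sigmaDrift)
        k <- sample(cfg$samplesRange[1L]:cfg$samplesRange[2L], 1L)
        noise <- matrix(rnorm(k * d, sd = noiseSd[jj]), k, d)
        feats <- sweep(noise, 2L, centers[jj, ] + drift, `+`)
        rows[[length(rows) + 1L]] <- list(
          feats = feats, individual = rep(ids[jj], k),
          session = rep(ss, k), sample = seq_len(k))
      }
    }
    ModalityDataset(
      features = do.call(rbind, lapply(rows, `[[`, "feats")),
      individual = unlist(lapply(rows, `[[`, "individual")),
      session = unlist(lapply(rows, `[[`, "session")),
      sampleIndex = unlist(lapply(rows, `[[`, "sample")),
      modalityId = spec$modalityId, sessionOrder = cfg$sessions)
  })
}

#' Generate a full synthetic multi-modality suite
#'
#' In `"independent"` mode each modality draws its own individual pool and
#' its own planted labels (modalities from unrelated source datasets); in
#' `"shared"` mode all modalities share one id set and one planted labeling
#' (modalities captured from the same people).
#'
#' @param cfg A [syntheticConfig()].
#' @param seed Master seed; defaults to `cfg$seed`.
#' @return Named list of [ModalityDataset-class]s with a
#'   `"plantedLabels"` attribute (named list per modality).
#' @examples
#' suite <- generateSuite(syntheticConfig(nIndividuals = 12, seed = 5L))
#' vapply(suite, nIndividuals, 0L)
#' @export
generateSuite <- function(cfg, seed = cfg$seed) {
  .validateSyntheticConfig(unclass(cfg))
  mods <- vapply(cfg$modalities, `[[`, "", "modalityId")
  seeds <- spawnSeeds(seed, c(paste0("plant_", mods),
                              paste0("features_", mods), "plant_shared"))
  planted <- list()
  out <- list()
  for (k in seq_along(cfg$modalities)) {
    sp <- cfg$modalities[[k]]
    ids <- sprintf("i%03d", seq_len(sp$nIndividuals))
    plantSeed <- if (cfg$mode == "shared") seeds[["plant_shared"]]
                 else seeds[[paste0("plant_", sp$modalityId)]]
    pl <- .plantLabels(ids, cfg$goatFraction, cfg$lambFraction, plantSeed)
    planted[[sp$modalityId]] <- pl
    out[[sp$modalityId]] <- generateModality(
      cfg, sp, pl, seeds[[paste0("features_", sp$modalityId)]])
  }
  if (cfg$mode == "shared") {
    ns <- vapply(cfg$modalities, `[[`, 0L, "nIndividuals")
    if (length(unique(ns)) != 1L)
      .stopf("validationError",
             "shared mode requires equal nIndividuals across modalities")
  }
  attr(out, "plantedLabels") <- planted
  out
}
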