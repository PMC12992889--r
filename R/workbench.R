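#' Compute per-case, per-scheme lung features for a phantom cohort
#'
#' The feature front-end of the experiment harness: each case is
#' materialized, both lungs are layered by the threshold descent, the
#' requested masking schemes are combined, the standardized MIP views are
#' rendered and encoded with the frozen encoder. Because the encoder is
#' frozen this is lossless to cache; with a `cacheDir` each case's features
#' are stored once (keyed by a content hash of the cohort configuration and
#' the case) and reruns are served from disk.
#'
#' @param cohort a [generateCohort()] result.
#' @param schemes character vector of scheme names (see [maskingSchemes()]).
#' @param views view table (default [makeViewSet()]).
#' @param window HU display window, c(level, width).
#' @param encoder encoder identifier.
#' @param outSize MIP image side in pixels.
#' @param rayStepMM ray sampling step (mm) passed to the renderer.
#' @param cacheDir optional directory for cached per-case features.
#' @param verbose print progress.
#' @return named list of feature sets, one per scheme; each is a list with
#'   `cases` (data.frame case_id, label) and `feat[[case_id]]$left/right`.
#' @export
cohortFeatures <- function(cohort, schemes = names(maskingSchemes()),
                           views = makeViewSet(), window = c(200, 700),
                           encoder = "projection", outSize = 224L,
                           rayStepMM = NULL, cacheDir = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(cohort, "PhantomCohort"),
            all(schemes %in% names(maskingSchemes())))
  enc <- getEncoder(encoder)
  key0 <- rlang::hash(list(cohort$cases, cohort$base, cohort$signal,
                           cohort$seed, cohort$closingRadiusMM, cohort$huStep,
                           views, window, enc$name, outSize, rayStepMM))
  feat <- lapply(schemes, function(s) list())
  names(feat) <- schemes
  for (i in seq_len(nrow(cohort$cases))) {
    id <- cohort$cases$case_id[i]
    cacheFile <- if (!is.null(cacheDir))
      file.path(cacheDir, paste0("feat-", rlang::hash(list(key0, id)), ".rds"))
    caseFeat <- NULL
    if (!is.null(cacheFile) && file.exists(cacheFile))
      caseFeat <- readRDS(cacheFile)
    if (is.null(caseFeat) || !all(schemes %in% names(caseFeat))) {
      if (verbose) message("features: ", id)
      cs <- materializeCase(cohort, i)
      caseFeat <- list()
      for (side in c("left", "right")) {
        lay <- computeLayers(cs$volume, cs$masks, side,
                             cohort$closingRadiusMM, cohort$huStep)
        ini <- maskArray(cs$masks, side, "initial")
        full <- maskArray(cs$masks, side, "full")
        for (s in schemes) {
          region <- combineLayers(lay, s, initial = ini)
          # frame on the full lung so all schemes share one geometry
          mips <- renderMIPSet(cs$volume, region, views, window, outSize,
                               scheme = s, side = side,
                               rayStepMM = rayStepMM, frameMask = full)
          caseFeat[[s]][[side]] <- enc$fn(mips@images)
        }
      }
      if (!is.null(cacheFile)) {
        dir.create(dirname(cacheFile), recursive = TRUE, showWarnings = FALSE)
        saveRDS(caseFeat, cacheFile)
      }
    }
    for (s in schemes) feat[[s]][[id]] <- caseFeat[[s]]
  }
  lapply(schemes, function(s)
    list(cases = cohort$cases[, c("case_id", "label")], feat = feat[[s]])) |>
    stats::setNames(schemes)
}

#' Full experiment configuration
#'
#' Bundles everything the end-to-end runner needs: one labeled cohort per
#' classification task, the masking schemes, the CV design, the training
#' protocol and the projection settings. One master seed deterministically
#' derives every other seed. The default scheme list enumerates all eleven
#' masking schemes, so two tasks yield 22 experiments.
#'
#' @param cohorts named list of [generateCohort()] results, one per task.
#' @param schemes scheme names (default: all eleven).
#' @param cv a [cvDesign()].
#' @param train a [trainConfig()].
#' @param views view table.
#' @param window HU window.
#' @param encoder encoder identifier.
#' @param outDir output/cache directory (created on demand).
#' @param masterSeed master seed; cv and training seeds derive from it.
#' @param rayStepMM renderer ray step.
#' @return list of class "ExperimentConfig" with a stable `hash`.
#' @export
experimentConfig <- function(cohorts, schemes = names(maskingSchemes()),
                             cv = cvDesign(), train = trainConfig(),
                             views = makeViewSet(), window = c(200, 700),
                             encoder = "projection", outDir = tempfile("pulmo"),
                             masterSeed = 1L, rayStepMM = NULL) {
  stopifnot(is.list(cohorts), length(names(cohorts)) == length(cohorts))
  cv$seed <- deriveSeed(masterSeed, "cv")
  cfg <- list(cohorts = cohorts, schemes = schemes, cv = cv, train = train,
              views = views, window = window, encoder = encoder,
              outDir = outDir, masterSeed = as.integer(masterSeed),
              rayStepMM = rayStepMM)
  cfg$hash <- rlang::hash(cfg[setdiff(names(cfg), "outDir")])
  structure(cfg, class = "ExperimentConfig")
}

#' Enumerate the (task, scheme) experiments of a configuration
#'
#' @param cfg an [experimentConfig()].
#' @return data.frame (task, scheme), one row per experiment.
#' @export
enumerateExperiments <- function(cfg) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  expand.grid(task = names(cfg$cohorts), scheme = cfg$schemes,
              stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
}

#' Run every experiment of a configuration
#'
#' For each task and masking scheme, computes (or loads from cache) the
#' cohort features and runs the grouped repeated cross-validation, then
#' compares all schemes of each task against the reference scheme. Cached
#' intermediates are keyed by content hashes; a pre-existing output
#' directory written under a different configuration hash is refused unless
#' `force = TRUE`. Rerunning with an identical configuration reuses every
#' cached feature and reproduces the result bundle exactly.
#'
#' @param cfg an [experimentConfig()].
#' @param reference reference scheme for comparisons (default "full"; only
#'   used when it is among `cfg$schemes`).
#' @param force overwrite an output directory with a different config hash.
#' @param verbose print progress.
#' @return list: `results[[task]][[scheme]]` ([ExperimentResult-class]),
#'   `comparisons[[task]]` (from [compareSchemes()], when possible),
#'   `experiments` (the enumeration), `config_hash`.
#' @export
runAll <- function(cfg, reference = "full", force = FALSE, verbose = FALSE) {
  stopifnot(inherits(cfg, "ExperimentConfig"))
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  manifest <- file.path(cfg$outDir, "manifest.json")
  if (file.exists(manifest)) {
    prev <- jsonlite::read_json(manifest)
    if (!identical(prev$config_hash, cfg$hash) && !force)
      stop("output directory holds results for a different configuration ",
           "hash; pass force = TRUE to overwrite")
  }
  jsonlite::write_json(list(config_hash = cfg$hash,
                            master_seed = cfg$masterSeed,
                            schemes = cfg$schemes,
                            tasks = names(cfg$cohorts),
                            cv = unclass(cfg$cv),
                            epochs = cfg$train$epochs),
                       manifest, auto_unbox = TRUE, pretty = TRUE)

  results <- list()
  comparisons <- list()
  for (task in names(cfg$cohorts)) {
    fs <- cohortFeatures(cfg$cohorts[[task]], cfg$schemes, cfg$views,
                         cfg$window, cfg$encoder,
                         rayStepMM = cfg$rayStepMM,
                         cacheDir = file.path(cfg$outDir, "cache"),
                         verbose = verbose)
    results[[task]] <- list()
    for (s in cfg$schemes) {
      if (verbose) message("experiment: ", task, " / ", s)
      results[[task]][[s]] <- runExperiment(fs[[s]], cfg$cv, cfg$train,
                                            scheme = s, task = task)
    }
    if (reference %in% cfg$schemes && length(cfg$schemes) >= 2L) {
      comparisons[[task]] <- compareSchemes(results[[task]], reference)
      utils::write.csv(comparisons[[task]]$table,
                       file.path(cfg$outDir, paste0("summary-", task, ".csv")),
                       row.names = FALSE)
    }
    # summary CSV per task (scheme, shuffle, auroc)
    rows <- do.call(rbind, lapply(cfg$schemes, function(s)
      data.frame(task = task, scheme = s,
                 shuffle = seq_along(aurocPerShuffle(results[[task]][[s]])),
                 auroc = aurocPerShuffle(results[[task]][[s]]))))
    utils::write.csv(rows, file.path(cfg$outDir,
                                     paste0("auroc-", task, ".csv")),
                     row.names = FALSE)
  }
  list(results = results, comparisons = comparisons,
       experiments = enumerateExperiments(cfg), config_hash = cfg$hash)
}
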