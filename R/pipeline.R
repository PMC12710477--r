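## Config-driven pipeline: simulate -> pretrain -> metatrain -> evaluate,
## with per-stage checkpoints, resume, and a run manifest.

configDefaults <- function() {
  list(
    stages = c("simulate", "pretrain", "metatrain", "evaluate"),
    seed = 1L,
    ablation = "none",
    zeroShot = FALSE,
    world = list(),        # syntheticWorldConfig overrides
    model = list(),        # modelConfig overrides
    training = list(pretrainEpochs = 30L, episodes = 300L, N = 5L, K = 10L,
                    Q = 10L, alpha = 0.1, beta = 1e-3, dropout = 0.1,
                    lr = 1e-3, metaOptimizer = "adam"),
    evaluation = list(nTasks = 30L, repeats = 20L, mode = "fewshot",
                      threshold = 0),
    testFraction = 0.2)
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) config, rejects unknown keys, validates value
#' ranges, and fills defaults. The completed config is echoed into the run
#' manifest.
#'
#' @param path config file path, or a named list to validate directly.
#' @return validated config list.
#' @export
loadConfig <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg)) cfg <- list()
  defaults <- configDefaults()

  unknown <- setdiff(names(cfg), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (grp in c("training", "evaluation")) {
    extra <- setdiff(names(cfg[[grp]]), names(defaults[[grp]]))
    if (length(extra))
      stop("unknown config key(s) in '", grp, "': ",
           paste(extra, collapse = ", "))
    defaults[[grp]][names(cfg[[grp]])] <- cfg[[grp]]
  }
  scalars <- setdiff(names(cfg), c("training", "evaluation"))
  defaults[scalars] <- cfg[scalars]
  cfg <- defaults

  badStage <- setdiff(cfg$stages, c("simulate", "pretrain", "metatrain",
                                    "evaluate"))
  if (length(badStage))
    stop("unknown stage(s): ", paste(badStage, collapse = ", "))
  tr <- cfg$training
  assertCount(tr$K, "training$K")
  assertCount(tr$Q, "training$Q")
  assertCount(tr$N, "training$N")
  assertCount(tr$pretrainEpochs, "training$pretrainEpochs", min = 0L)
  assertCount(tr$episodes, "training$episodes", min = 0L)
  assertNumber(tr$alpha, "training$alpha", 0, strict = TRUE)
  assertNumber(tr$beta, "training$beta", 0, strict = TRUE)
  if (tr$dropout < 0 || tr$dropout >= 1)
    stop("training$dropout must be in [0, 1)")
  if (!cfg$ablation %in% c("none", "no_ml", "no_ft", "no_so", "no_pt"))
    stop("unknown ablation: ", cfg$ablation)
  if (cfg$testFraction <= 0 || cfg$testFraction >= 1)
    stop("testFraction must be strictly between 0 and 1")
  cfg
}

md5OrNA <- function(path) {
  if (file.exists(path)) unname(tools::md5sum(path)) else NA_character_
}

#' Run the staged pipeline
#'
#' Executes the requested stage sequence with checkpoints between stages.
#' With `resume = TRUE`, a stage whose checkpoint already exists (and
#' hash-matches the manifest) is skipped and its artifact reused; a missing
#' prerequisite checkpoint is an error naming the stage that must run first.
#'
#' @param config path to a config file, or a config list (validated either
#'   way via [loadConfig()]).
#' @param outDir output directory for checkpoints, reports and the manifest.
#' @param resume reuse existing stage checkpoints.
#' @return the run manifest (list), invisibly written to
#'   `outDir/manifest.json`.
#' @export
runPipeline <- function(config, outDir, resume = FALSE) {
  cfg <- loadConfig(config)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(world = file.path(outDir, "world.rds"),
                pretrained = file.path(outDir, "model_pretrained.rds"),
                meta = file.path(outDir, "model_meta.rds"),
                report = file.path(outDir, "evaluation.tsv"),
                manifest = file.path(outDir, "manifest.json"))
  manifestPath <- paths$manifest
  oldManifest <- if (resume && file.exists(manifestPath))
    jsonlite::read_json(manifestPath, simplifyVector = TRUE) else NULL
  canReuse <- function(key) {
    resume && file.exists(paths[[key]]) && !is.null(oldManifest) &&
      identical(unname(oldManifest$checkpoints[[key]]), md5OrNA(paths[[key]]))
  }
  events <- list()
  note <- function(stage, action) {
    events[[length(events) + 1L]] <<- list(stage = stage, action = action,
                                           time = format(Sys.time()))
  }

  tr <- cfg$training
  worldCfg <- do.call(syntheticWorldConfig,
                      c(cfg$world, list(seed = cfg$seed)[
                        !("seed" %in% names(cfg$world))]))
  world <- NULL; split <- NULL; entities <- NULL
  needWorld <- function() {
    if (is.null(world)) {
      if (!file.exists(paths$world))
        stop("stage requires the 'simulate' checkpoint; run 'simulate' first")
      world <<- readRDS(paths$world)
    }
    split <<- splitRandom(names(world@profiles),
                          fraction = 1 - cfg$testFraction, seed = cfg$seed)
    entities <<- buildEntityCache(world@drugs, world@profiles)
  }

  if ("simulate" %in% cfg$stages) {
    if (canReuse("world")) {
      note("simulate", "reused checkpoint")
    } else {
      world <- generateWorld(worldCfg)
      writeWorld(world, file.path(outDir, "data"))
      saveRDS(world, paths$world)
      note("simulate", "ran")
    }
  }

  newModel <- function() {
    mc <- do.call(modelConfig, cfg$model)
    newSynergyModel(mc, seed = cfg$seed, alpha = tr$alpha, beta = tr$beta,
                    dropout = tr$dropout, ablation = cfg$ablation)
  }

  if ("pretrain" %in% cfg$stages && cfg$ablation != "no_pt") {
    if (canReuse("pretrained")) {
      note("pretrain", "reused checkpoint")
    } else {
      needWorld()
      model <- newModel()
      trainSamples <- world@samples[world@samples$cellLine %in%
                                      metaTrainCells(split), , drop = FALSE]
      model <- pretrain(model, trainSamples, entities,
                        epochs = tr$pretrainEpochs, seed = cfg$seed,
                        lr = tr$lr)
      saveModel(model, paths$pretrained)
      note("pretrain", "ran")
    }
  }

  if ("metatrain" %in% cfg$stages && cfg$ablation != "no_ml") {
    if (canReuse("meta")) {
      note("metatrain", "reused checkpoint")
    } else {
      needWorld()
      model <- if (cfg$ablation == "no_pt") newModel() else {
        if (!file.exists(paths$pretrained))
          stop("stage 'metatrain' requires the 'pretrain' checkpoint; ",
               "run 'pretrain' first")
        loadModel(paths$pretrained)
      }
      trainSamples <- world@samples[world@samples$cellLine %in%
                                      metaTrainCells(split), , drop = FALSE]
      model <- metaTrain(model, trainSamples, entities,
                         episodes = tr$episodes, N = tr$N, K = tr$K,
                         Q = tr$Q, seed = cfg$seed,
                         zeroShot = isTRUE(cfg$zeroShot),
                         optimizer = tr$metaOptimizer)
      saveModel(model, paths$meta)
      note("metatrain", "ran")
    }
  }

  if ("evaluate" %in% cfg$stages) {
    needWorld()
    modelPath <- if (cfg$ablation == "no_ml") paths$pretrained else
      paths$meta
    if (!file.exists(modelPath))
      stop("stage 'evaluate' requires the '",
           if (cfg$ablation == "no_ml") "pretrain" else "metatrain",
           "' checkpoint; run it first")
    model <- loadModel(modelPath)
    ev <- cfg$evaluation
    mode <- if (isTRUE(cfg$zeroShot) || cfg$ablation == "no_ft")
      "zeroshot" else ev$mode
    report <- evaluateFewShot(model, world@samples, entities, split,
                              K = tr$K, Q = tr$Q, nTasks = ev$nTasks,
                              repeats = ev$repeats, seed = cfg$seed,
                              mode = mode, threshold = ev$threshold)
    utils::write.table(report$perRepeat, paths$report, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(list(mean = as.list(report$mean),
                              sd = as.list(report$sd)),
                         file.path(outDir, "evaluation_summary.json"),
                         auto_unbox = TRUE, digits = NA)
    note("evaluate", "ran")
  }

  manifest <- list(
    package = as.character(utils::packageVersion("FewShotSynergy")),
    created = format(Sys.time()),
    config = cfg,
    seeds = list(root = cfg$seed,
                 substreams = lapply(c("init", "pretrain", "episode", "eval",
                                       "world", "split"),
                                     function(s) deriveSeed(cfg$seed, s))),
    checkpoints = lapply(paths[c("world", "pretrained", "meta")], md5OrNA),
    events = events)
  jsonlite::write_json(manifest, manifestPath, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
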