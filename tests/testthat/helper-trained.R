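## Trained benchmark artifacts shared by the heavier study-level tests.
## Built lazily once per test run; every build is fully seeded.

.benchCache <- new.env(parent = emptyenv())

benchCached <- function(key, builder) {
  if (!exists(key, envir = .benchCache))
    assign(key, builder(), envir = .benchCache)
  get(key, envir = .benchCache)
}

## Study conditions of the meta-learning-benefit / ablation world:
## strong shared structure (0.8), 15 cell lines, 40 drugs.
benchCfg <- function() benchmarkConfig(seed = 11L)

benchWorld <- function() {
  benchCached("worldA", function()
    generateWorld(syntheticWorldConfig(nDrugs = 40L, nCellLines = 15L,
                                       samplesPerCellLine = 60L,
                                       sharedWeight = 0.8, seed = 11L)))
}

benchSplit <- function() {
  benchCached("splitA", function()
    splitRandom(names(benchWorld()@profiles), fraction = 0.8, seed = 11L))
}

benchEntities <- function() {
  benchCached("entitiesA", function() {
    w <- benchWorld()
    FewShotSynergy:::buildEntityCache(w@drugs, w@profiles)
  })
}

benchModel <- function(variant = "none") {
  benchCached(paste0("model_", variant), function()
    trainVariant(benchWorld(), benchSplit(), benchCfg(), variant))
}

benchRandomModel <- function() {
  benchCached("model_random", function() {
    cfg <- benchCfg()
    newSynergyModel(cfg$model, seed = 999L, alpha = cfg$alpha,
                    beta = cfg$beta, dropout = cfg$dropout)
  })
}

benchEval <- function(modelKey, mode = "fewshot") {
  benchCached(paste0("eval_", modelKey, "_", mode), function() {
    cfg <- benchCfg()
    model <- switch(modelKey,
                    random = benchRandomModel(),
                    benchModel(modelKey))
    evaluateFewShot(model, benchWorld()@samples, benchEntities(),
                    benchSplit(), K = cfg$K, Q = cfg$Q,
                    nTasks = cfg$evalTasks, repeats = cfg$evalRepeats,
                    seed = cfg$seed, mode = mode)
  })
}

## Wide-dispersion world for the per-cell-line error analysis: enough test
## lines for a powered correlation, and observation noise strong enough
## that each line's irreducible error scales with its dispersion.
dispersionWorld <- function() {
  benchCached("worldB", function()
    generateWorld(syntheticWorldConfig(nDrugs = 30L, nCellLines = 36L,
                                       samplesPerCellLine = 60L,
                                       sharedWeight = 0.8, noiseSd = 0.5,
                                       dispersionRange = c(0.25, 4),
                                       seed = 13L)))
}

dispersionSplit <- function() {
  benchCached("splitB", function()
    splitRandom(names(dispersionWorld()@profiles), fraction = 0.5,
                seed = 13L))
}

dispersionModel <- function() {
  benchCached("modelB", function() {
    cfg <- benchmarkConfig(seed = 13L, pretrainEpochs = 15L,
                           episodes = 120L)
    trainVariant(dispersionWorld(), dispersionSplit(), cfg, "none")
  })
}
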