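## A micro world shared by the evaluation-harness tests.
evalWorld <- function() {
  cachedFixture("evalWorld", function() {
    generateWorld(syntheticWorldConfig(nDrugs = 10L, nCellLines = 6L,
                                       samplesPerCellLine = 20L,
                                       sharedWeight = 0.8, noiseSd = 0.05,
                                       seed = 71L))
  })
}

evalModelAndSplit <- function() {
  cachedFixture("evalModelSplit", function() {
    world <- evalWorld()
    split <- splitRandom(names(world@profiles), fraction = 2 / 3, seed = 71)
    m <- tinyModel(seed = 71, alpha = 0.01)
    list(model = m, split = split,
         entities = FewShotSynergy:::buildEntityCache(world@drugs,
                                                      world@profiles))
  })
}

test_that("few-shot evaluation is reproducible and well-formed", {
  ms <- evalModelAndSplit()
  world <- evalWorld()
  r1 <- evaluateFewShot(ms$model, world@samples, ms$entities, ms$split,
                        K = 5, Q = 5, nTasks = 4, repeats = 3, seed = 9)
  r2 <- evaluateFewShot(ms$model, world@samples, ms$entities, ms$split,
                        K = 5, Q = 5, nTasks = 4, repeats = 3, seed = 9)
  expect_identical(r1$perRepeat, r2$perRepeat)
  expect_equal(nrow(r1$perRepeat), 3)
  expect_true(all(c("mse", "scc", "r2", "auc", "aupr") %in%
                    names(r1$perRepeat)))
  expect_true(all(r1$perRepeat$mse >= 0))
})

test_that("evaluation never leaks query data into adaptation state", {
  ms <- evalModelAndSplit()
  world <- evalWorld()
  snapE <- ms$model@thetaE
  snapP <- ms$model@thetaP
  invisible(evaluateFewShot(ms$model, world@samples, ms$entities, ms$split,
                            K = 5, Q = 5, nTasks = 3, repeats = 2, seed = 4))
  # the shared initialization is restored bit-identically between tasks
  expect_identical(ms$model@thetaE, snapE)
  expect_identical(ms$model@thetaP, snapP)
})

test_that("a model that reproduces the task scores achieves zero MSE", {
  ms <- evalModelAndSplit()
  world <- evalWorld()
  task <- FewShotSynergy:::sampleTask(world@samples,
                                      metaTestCells(ms$split)[1], 5, 5,
                                      seed = 3)
  task@support$score <- predictScores(ms$model, supportSet(task),
                                      ms$entities)
  task@query$score <- predictScores(ms$model, querySet(task), ms$entities)
  ft <- fineTune(ms$model, task, ms$entities)
  expect_equal(ft$queryMse, 0, tolerance = 1e-12)
})

test_that("per-cell-line analysis yields one row per included line", {
  ms <- evalModelAndSplit()
  world <- evalWorld()
  res <- perCellLineAnalysis(ms$model, world@samples, ms$entities, ms$split,
                             K = 5, Q = 5, nTasksPerLine = 3, seed = 2)
  expect_equal(nrow(res$table), length(metaTestCells(ms$split)))
  expect_setequal(res$table$cellLine, metaTestCells(ms$split))
  expect_true(all(res$table$dispersion > 0))
})

test_that("degenerate constant scores flag the correlation as undefined", {
  ms <- evalModelAndSplit()
  world <- evalWorld()
  flat <- world@samples
  flat$score <- 0
  m0 <- ms$model
  m0@thetaP$headW2[] <- 0
  m0@thetaP$headb2 <- 0
  res <- perCellLineAnalysis(m0, flat, ms$entities, ms$split, K = 5, Q = 5,
                             nTasksPerLine = 2, seed = 2)
  expect_true(is.na(res$correlation))
  expect_true(all(res$table$mse == 0))
})

test_that("lines with too few samples are excluded and reported", {
  ms <- evalModelAndSplit()
  world <- evalWorld()
  short <- metaTestCells(ms$split)[1]
  idx <- which(world@samples$cellLine == short)
  cut <- world@samples[-idx[-(1:3)], , drop = FALSE]  # keep only 3 samples
  res <- perCellLineAnalysis(ms$model, cut, ms$entities, ms$split, K = 5,
                             Q = 5, nTasksPerLine = 2, seed = 2)
  expect_true(short %in% res$excluded)
  expect_false(short %in% res$table$cellLine)
})

test_that("ablation orchestration validates variants and runs the full model", {
  world <- evalWorld()
  cfg <- benchmarkConfig(model = tinyModelConfig(), pretrainEpochs = 2L,
                         episodes = 2L, N = 2L, K = 4L, Q = 4L,
                         evalTasks = 3L, evalRepeats = 2L,
                         testFraction = 1 / 3, seed = 71L)
  expect_error(runAblation(world, variants = "bogus", cfg = cfg), "unknown")
  out <- runAblation(world, variants = character(0), cfg = cfg)
  expect_equal(out$summary$variant, "full")
  expect_s3_class(out$reports$full, "metricsReport")
})

test_that("zero-shot training improves over an untrained model", {
  ms <- evalModelAndSplit()
  world <- evalWorld()
  train <- world@samples[world@samples$cellLine %in%
                           metaTrainCells(ms$split), ]
  trained <- metaTrain(ms$model, train, ms$entities, episodes = 40, N = 3,
                       K = 5, Q = 5, seed = 7, zeroShot = TRUE,
                       optimizer = "adam")
  mseOf <- function(model) {
    r <- evaluateFewShot(model, world@samples, ms$entities, ms$split, K = 5,
                         Q = 5, nTasks = 8, repeats = 3, seed = 7,
                         mode = "zeroshot")
    mean(r$perRepeat$mse)
  }
  expect_lt(mseOf(trained), mseOf(ms$model))
})

test_that("the no_ft variant predicts exactly like the zero-shot path", {
  ms <- evalModelAndSplit()
  world <- evalWorld()
  mNoFt <- ms$model
  mNoFt@flags$ablation <- "no_ft"
  a <- evaluateFewShot(mNoFt, world@samples, ms$entities, ms$split, K = 5,
                       Q = 5, nTasks = 3, repeats = 2, seed = 13,
                       mode = "fewshot")
  b <- evaluateFewShot(ms$model, world@samples, ms$entities, ms$split,
                       K = 5, Q = 5, nTasks = 3, repeats = 2, seed = 13,
                       mode = "zeroshot")
  expect_identical(a$perRepeat, b$perRepeat)
})
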