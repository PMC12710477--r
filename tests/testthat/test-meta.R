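entsM <- function() tinyEntities()

makeTask <- function(K = 3, Q = 3, seed = 17, cell = "CL1",
                     scores = NULL) {
  pool <- randomSamples(8, cells = cell, seed = seed)
  task <- FewShotTask(cell, support = pool[seq_len(K), ],
                      query = pool[(K + 1):(K + Q), ])
  task
}

test_that("pretraining with 0 epochs is the identity; loss decreases with training", {
  m <- tinyModel()
  samples <- randomSamples(5)
  m0 <- pretrain(m, samples, entsM(), epochs = 0, seed = 1)
  expect_identical(m0@thetaE, m@thetaE)
  expect_identical(m0@thetaP, m@thetaP)

  m1 <- pretrain(m, samples, entsM(), epochs = 40, seed = 1, lr = 1e-3)
  log <- m1@flags$pretrainLog
  expect_lt(log[length(log)], log[1])
  expect_identical(modelStage(m1), "pretrained")
  expect_error(pretrain(m, samples[0, ], entsM(), epochs = 1, seed = 1),
               "empty")
})

test_that("a single small gradient step moves the prediction toward the target", {
  m <- tinyModel()
  s <- randomSamples(1, cells = "CL1")[1, , drop = FALSE]
  fwd <- FewShotSynergy:::forwardBatch(m, s, entsM())
  Z <- fwd$cache$Z
  hg <- FewShotSynergy:::headLossGrad(Z, s$score, m@thetaP)
  before <- abs(hg$yhat - s$score)
  tP <- FewShotSynergy:::paramAxpy(m@thetaP, hg$grads, -1e-3)
  after <- abs(FewShotSynergy:::headLossGrad(Z, s$score, tP)$yhat - s$score)
  expect_lt(after, before)
})

test_that("episode building is exact, deterministic, and near-uniform", {
  samples <- randomSamples(6)
  # forced case: exactly N lines with exactly K+Q samples each uses all rows
  ep <- buildEpisode(samples, N = 3, K = 3, Q = 3, seed = 5)
  used <- do.call(rbind, lapply(ep, function(t) rbind(supportSet(t),
                                                      querySet(t))))
  expect_equal(nrow(used), nrow(samples))
  expect_equal(sort(pairKey(paste(used$drugA, used$cellLine),
                            paste(used$drugB, used$cellLine))),
               sort(pairKey(paste(samples$drugA, samples$cellLine),
                            paste(samples$drugB, samples$cellLine))))
  # support and query are disjoint within every task
  for (t in ep) expect_true(validObject(t))

  ep2 <- buildEpisode(samples, N = 3, K = 3, Q = 3, seed = 5)
  expect_identical(lapply(ep, supportSet), lapply(ep2, supportSet))

  expect_error(buildEpisode(samples, N = 4, K = 3, Q = 3, seed = 1),
               "cell lines")
  expect_error(buildEpisode(samples, N = 2, K = 5, Q = 5, seed = 1),
               "K\\+Q")
})

test_that("episode sampling selects cell lines uniformly", {
  cells <- sprintf("CL%02d", 1:10)
  drugs <- names(tinyGraphs())
  pairs <- t(combn(drugs, 2))
  pool <- do.call(rbind, lapply(cells, function(cl)
    data.frame(drugA = pairs[, 1], drugB = pairs[, 2], cellLine = cl,
               score = 0, stringsAsFactors = FALSE)))
  counts <- table(unlist(lapply(1:1000, function(i)
    vapply(buildEpisode(pool, N = 3, K = 2, Q = 2, seed = 1000 + i),
           cellLineId, character(1)))))
  freq <- as.numeric(counts) / 1000  # per-episode inclusion frequency
  expect_true(all(abs(freq - 0.3) < 0.05))
})

test_that("inner adaptation follows the selective update rule", {
  m <- tinyModel()
  task <- makeTask()
  ad <- innerAdapt(m, task, entsM())
  # embedding parameters are bit-identical
  expect_identical(ad$thetaE, m@thetaE)
  # the head moved by exactly -alpha * support gradient
  fwd <- FewShotSynergy:::forwardBatch(m, supportSet(task), entsM())
  hg <- FewShotSynergy:::headLossGrad(fwd$cache$Z, supportSet(task)$score,
                                      m@thetaP)
  for (nm in names(m@thetaP))
    expect_equal(ad$thetaP[[nm]],
                 m@thetaP[[nm]] - m@hyper$alpha * hg$grads[[nm]],
                 tolerance = 1e-12)

  # zero support residuals (smooth region) give a zero gradient
  taskFit <- task
  taskFit@support$score <- predictScores(m, supportSet(task), entsM())
  adFit <- innerAdapt(m, taskFit, entsM())
  expect_equal(adFit$thetaP, m@thetaP, tolerance = 1e-12)

  # alpha = 0 override is the identity; negative alpha is rejected
  ad0 <- innerAdapt(m, task, entsM(), alpha = 0)
  expect_equal(ad0$thetaP, m@thetaP, tolerance = 1e-15)
  expect_error(innerAdapt(m, task, entsM(), alpha = -0.1), "alpha")
  expect_error(newSynergyModel(tinyModelConfig(), alpha = -1), "alpha")
})

test_that("the inner update matches the closed form on an effectively linear head", {
  ## Configure the head so yhat = w * (z1 + 10): one hidden unit, always
  ## active, reading the first embedding coordinate.
  cfg <- modelConfig(gcnDims = c(6L, 5L, 4L), convChannels = c(2L, 2L),
                     fdHidden = 6L, fdOut = 3L, fcOut = 3L, headHidden = 1L)
  m <- tinyModel(config = cfg, alpha = 0.05)
  m@thetaP$headW1 <- matrix(c(1, rep(0, cfg$zDim - 1)), cfg$zDim, 1)
  m@thetaP$headb1 <- 10
  w <- 0.7
  m@thetaP$headW2 <- matrix(w, 1, 1)
  m@thetaP$headb2 <- 0

  task <- makeTask(K = 1, Q = 1)
  fwd <- FewShotSynergy:::forwardBatch(m, supportSet(task), entsM())
  zt <- fwd$cache$Z[1, 1] + 10          # effective linear feature
  y <- supportSet(task)$score
  ad <- innerAdapt(m, task, entsM())
  expect_equal(ad$thetaP$headW2[1, 1],
               w - m@hyper$alpha * 2 * (w * zt - y) * zt,
               tolerance = 1e-10)
})

test_that("inner-tier gradients match central finite differences", {
  m <- tinyModel()
  task <- makeTask(K = 3)
  support <- supportSet(task)
  fwd <- FewShotSynergy:::forwardBatch(m, support, entsM())
  Z <- fwd$cache$Z
  hg <- FewShotSynergy:::headLossGrad(Z, support$score, m@thetaP)
  flat <- FewShotSynergy:::flattenParams(m@thetaP)
  ana <- FewShotSynergy:::flattenParams(hg$grads)
  lossAt <- function(v) {
    tP <- FewShotSynergy:::unflattenParams(v, m@thetaP)
    FewShotSynergy:::headLossGrad(Z, support$score, tP)$loss
  }
  num <- vapply(seq_along(flat), function(i) {
    e <- 1e-5
    vp <- flat; vp[i] <- vp[i] + e
    vm <- flat; vm[i] <- vm[i] - e
    (lossAt(vp) - lossAt(vm)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(num - ana)) / max(abs(num)), 1e-6)
})

test_that("the outer update accumulates per-task gradients without leakage", {
  m <- tinyModel()
  t1 <- makeTask(cell = "CL1", seed = 41)
  t2 <- makeTask(cell = "CL2", seed = 42)
  gBoth <- FewShotSynergy:::episodeGradient(m, list(t1, t2), entsM(),
                                            bnMode = "eval")
  g1 <- FewShotSynergy:::episodeGradient(m, list(t1), entsM(),
                                         bnMode = "eval")
  g2 <- FewShotSynergy:::episodeGradient(m, list(t2), entsM(),
                                         bnMode = "eval")
  for (nm in names(m@thetaP))
    expect_equal(gBoth$thetaP[[nm]], g1$thetaP[[nm]] + g2$thetaP[[nm]],
                 tolerance = 1e-10)
  for (nm in names(m@thetaE))
    expect_equal(gBoth$thetaE[[nm]], g1$thetaE[[nm]] + g2$thetaE[[nm]],
                 tolerance = 1e-10)
  expect_error(outerUpdate(m, list(), entsM()), "empty")
})

test_that("meta-training: 0 episodes is the identity; fixed seeds reproduce", {
  m <- tinyModel()
  samples <- randomSamples(6)
  m0 <- metaTrain(m, samples, entsM(), episodes = 0, N = 2, K = 2, Q = 2,
                  seed = 3)
  expect_identical(m0@thetaE, m@thetaE)
  a <- metaTrain(m, samples, entsM(), episodes = 3, N = 2, K = 2, Q = 2,
                 seed = 3, bnMode = "eval")
  b <- metaTrain(m, samples, entsM(), episodes = 3, N = 2, K = 2, Q = 2,
                 seed = 3, bnMode = "eval")
  expect_identical(a@thetaE, b@thetaE)
  expect_identical(a@thetaP, b@thetaP)
})

test_that("fine-tuning adapts without mutating the input model", {
  m <- tinyModel()
  task <- makeTask()
  snapE <- m@thetaE; snapP <- m@thetaP
  ft <- fineTune(m, task, entsM())
  expect_identical(m@thetaE, snapE)
  expect_identical(m@thetaP, snapP)
  expect_length(ft$predictions, nrow(querySet(task)))

  # already-perfect support: adapted predictions equal unadapted
  taskFit <- task
  taskFit@support$score <- predictScores(m, supportSet(task), entsM())
  ftFit <- fineTune(m, taskFit, entsM())
  expect_equal(ftFit$predictions, ftFit$unadapted, tolerance = 1e-10)

  # ablation no_ft routes to the unadapted forward pass
  mNoFt <- m
  mNoFt@flags$ablation <- "no_ft"
  ftNo <- fineTune(mNoFt, task, entsM())
  expect_identical(ftNo$predictions, zeroShotPredict(m, task, entsM()))
})

test_that("zero-shot prediction equals the encoder/integration/head composition", {
  m <- tinyModel()
  task <- makeTask()
  ents <- entsM()
  pred <- zeroShotPredict(m, task, ents)
  manual <- vapply(seq_len(nrow(querySet(task))), function(i) {
    row <- querySet(task)[i, ]
    gA <- tinyGraphs()[[row$drugA]]
    gB <- tinyGraphs()[[row$drugB]]
    grid <- new("ExpressionGrid", cellLineId = row$cellLine,
                grid = ents$grids[[row$cellLine]],
                geneOrder = sprintf("G%04d", 1:900))
    z <- integrateEmbeddings(m, encodeDrug(m, gA), encodeDrug(m, gB),
                             encodeCell(m, grid))
    predictHead(m, z)
  }, numeric(1))
  expect_equal(pred, manual, tolerance = 1e-12)
  expect_identical(pred, zeroShotPredict(m, task, ents))
})
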