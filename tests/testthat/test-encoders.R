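test_that("drug encoding: 1-node graph readout, composition oracle", {
  m <- tinyModel()
  g1 <- MolecularGraph("solo", matrix(rnorm(78), 1, 78),
                       matrix(integer(0), ncol = 2))
  # max over one node is that node's final-layer embedding
  H <- nodeFeatures(g1)
  for (l in 1:3) H <- gcnLayer(H, g1, m@thetaE[[paste0("gcnW", l)]])
  expect_equal(encodeDrug(m, g1), drop(H), tolerance = 1e-12)

  # multi-node graph equals three stacked layers + coordinate-wise max
  g <- tinyGraphs()$benzene
  H <- nodeFeatures(g)
  for (l in 1:3) H <- gcnLayer(H, g, m@thetaE[[paste0("gcnW", l)]])
  expect_equal(encodeDrug(m, g), apply(H, 2, max), tolerance = 1e-6)
})

test_that("drug encoding is invariant to node relabeling", {
  m <- tinyModel()
  g <- tinyGraphs()$acetone
  n <- nrow(nodeFeatures(g))
  withr::with_seed(21, perm <- sample(n))
  inv <- order(perm)
  e <- edgeMatrix(g)
  gp <- MolecularGraph(drugId(g), nodeFeatures(g)[perm, , drop = FALSE],
                       cbind(inv[e[, 1]], inv[e[, 2]]), edgeWeights(g))
  expect_equal(encodeDrug(m, gp), encodeDrug(m, g), tolerance = 1e-12)
})

test_that("cell encoding follows conv -> BN -> ReLU -> pool and flattens", {
  m <- tinyModel()
  # all-zero grid, zero conv biases, identity BN in eval mode -> zeros
  m0 <- m
  for (l in 1:2) {
    m0@thetaE[[paste0("conv", l, "b")]][] <- 0
    m0@thetaE[[paste0("bn", l, "beta")]][] <- 0
    m0@thetaE[[paste0("bn", l, "gamma")]][] <- 1
    m0@bnStats[[paste0("bn", l, "mean")]][] <- 0
    m0@bnStats[[paste0("bn", l, "var")]][] <- 1
  }
  zeroGrid <- new("ExpressionGrid", cellLineId = "z",
                  grid = matrix(0, 30, 30),
                  geneOrder = sprintf("G%04d", 1:900))
  expect_true(all(encodeCell(m0, zeroGrid) == 0))
  expect_length(encodeCell(m, zeroGrid), m@config$flatDim)

  # full layer matches the operator-by-operator oracle
  grid <- randomGrid("CL9", 77)
  h <- encodeCell(m, grid, bnMode = "eval")
  X <- array(gridValues(grid), c(30, 30, 1))
  for (l in 1:2) {
    cv <- convOracle(X, m@thetaE[[paste0("conv", l, "W")]],
                     m@thetaE[[paste0("conv", l, "b")]])
    gam <- m@thetaE[[paste0("bn", l, "gamma")]]
    bet <- m@thetaE[[paste0("bn", l, "beta")]]
    rm <- m@bnStats[[paste0("bn", l, "mean")]]
    rv <- m@bnStats[[paste0("bn", l, "var")]]
    for (c in seq_along(gam))
      cv[, , c] <- gam[c] * (cv[, , c] - rm[c]) / sqrt(rv[c] + 1e-5) + bet[c]
    cv <- pmax(cv, 0)
    d <- dim(cv)
    pooled <- array(0, c(d[1] / 2, d[2] / 2, d[3]))
    for (c in seq_len(d[3])) for (i in seq_len(d[1] / 2))
      for (j in seq_len(d[2] / 2))
        pooled[i, j, c] <- max(cv[(2 * i - 1):(2 * i), (2 * j - 1):(2 * j), c])
    X <- pooled
  }
  expect_equal(h, as.vector(X), tolerance = 1e-6)
})

test_that("integration shares the drug transform and concatenates", {
  m <- tinyModel()
  withr::with_seed(3, {
    hA <- rnorm(m@config$gcnDims[3]); hB <- rnorm(m@config$gcnDims[3])
    hC <- rnorm(m@config$flatDim)
  })
  z <- integrateEmbeddings(m, hA, hB, hC)
  zSwap <- integrateEmbeddings(m, hB, hA, hC)
  k <- m@config$fdOut
  # swapping drugs permutes the first two blocks, values unchanged
  expect_identical(z[1:k], zSwap[(k + 1):(2 * k)])
  expect_identical(z[(k + 1):(2 * k)], zSwap[1:k])
  expect_identical(z[(2 * k + 1):length(z)], zSwap[(2 * k + 1):length(z)])

  # zero inputs and zero biases give z = 0
  m0 <- m
  for (nm in c("fdb1", "fdb2", "fcb")) m0@thetaE[[nm]][] <- 0
  expect_equal(integrateEmbeddings(m0, hA * 0, hB * 0, hC * 0),
               numeric(m@config$zDim))

  # hand-computed affine/ReLU chain
  tE <- m@thetaE
  fd <- function(h) {
    z1 <- drop(h %*% tE$fdW1) + tE$fdb1
    drop(pmax(z1, 0) %*% tE$fdW2) + tE$fdb2
  }
  expect_equal(z, c(fd(hA), fd(hB), drop(hC %*% tE$fcW) + tE$fcb),
               tolerance = 1e-6)
})

test_that("prediction head is the two-layer affine chain", {
  m <- tinyModel()
  withr::with_seed(4, z <- rnorm(m@config$zDim))
  # constant-head cases
  mc <- m
  mc@thetaP$headW2[] <- 0
  mc@thetaP$headb2 <- 4.2
  expect_equal(predictHead(mc, z), 4.2)
  m0 <- m
  m0@thetaP$headb1[] <- 0
  expect_equal(predictHead(m0, z * 0), m0@thetaP$headb2)
  # hand arithmetic
  expect_equal(predictHead(m, z),
               drop(pmax(drop(z %*% m@thetaP$headW1) + m@thetaP$headb1, 0) %*%
                      m@thetaP$headW2) + m@thetaP$headb2,
               tolerance = 1e-6)
  expect_error(predictHead(m, rnorm(3)), "head expects")
})

test_that("parameters partition cleanly into thetaE and thetaP", {
  m <- tinyModel()
  expect_length(intersect(names(thetaE(m)), names(thetaP(m))), 0)
  # the head touches exactly thetaP; the encoders/integration exactly thetaE
  ents <- tinyEntities()
  batch <- randomSamples(3)[1:4, ]
  lg <- FewShotSynergy:::lossAndGrad(m, batch, ents, wrt = "all")
  expect_setequal(names(lg$grads$thetaE), names(thetaE(m)))
  expect_setequal(names(lg$grads$thetaP), names(thetaP(m)))
})

test_that("the forward pass is deterministic in eval mode", {
  m <- tinyModel()
  ents <- tinyEntities()
  batch <- randomSamples(4)
  p1 <- predictScores(m, batch, ents)
  p2 <- predictScores(m, batch, ents)
  expect_identical(p1, p2)
})
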