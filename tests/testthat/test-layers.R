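test_that("graph convolution matches forced small cases", {
  # isolated node: D-hat = 1, self term only; identity W keeps nonneg input
  g1 <- MolecularGraph("iso", matrix(abs(rnorm(78)), 1, 78),
                       matrix(integer(0), ncol = 2))
  W <- diag(78)
  expect_equal(gcnLayer(nodeFeatures(g1), g1, W),
               nodeFeatures(g1), tolerance = 1e-12)

  # two nodes, one unit edge: both coefficients are 1/2
  X <- matrix(abs(rnorm(4)), 2, 2)
  g2 <- new("MolecularGraph", drugId = "pair",
            nodeFeatures = matrix(0, 2, 78),
            edges = matrix(c(1L, 2L), 1), edgeWeights = 1)
  out <- FewShotSynergy:::relu(normalizedAdjacency(g2) %*% X %*% diag(2))
  expect_equal(out[1, ], (X[1, ] + X[2, ]) / 2, tolerance = 1e-12)
  expect_equal(out[2, ], (X[1, ] + X[2, ]) / 2, tolerance = 1e-12)
})

test_that("graph convolution equals the double-loop oracle on random graphs", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      n <- 5L
      edges <- unique(t(replicate(4, sort(sample(n, 2)))))
      edges <- matrix(as.integer(edges), ncol = 2)
      X <- matrix(rnorm(n * 78), n, 78)
      W <- matrix(rnorm(78 * 6), 78, 6)
      g <- new("MolecularGraph", drugId = "r",
               nodeFeatures = matrix(0, n, 78), edges = edges,
               edgeWeights = rep(1, nrow(edges)))
      expect_equal(gcnLayer(X, g, W),
                   gcnOracle(X, edges, rep(1, nrow(edges)), W),
                   tolerance = 1e-6)
    }
  })
})

test_that("convolution matches a hand-computed dot product", {
  withr::with_seed(7, {
    X <- array(rnorm(36), c(6, 6, 1))
    W <- array(rnorm(9), c(3, 3, 1, 1))
  })
  out <- FewShotSynergy:::convForward(X, W, b = 0.3)$out
  # position (2, 4) by hand
  expect_equal(out[2, 4, 1],
               sum(X[2:4, 4:6, 1] * W[, , 1, 1]) + 0.3, tolerance = 1e-12)
  expect_equal(out, convOracle(X, W, 0.3), tolerance = 1e-12)
})

test_that("batch norm, pooling and dropout behave as defined", {
  # zero input + identity BN (eval) + ReLU propagates zeros
  Z <- array(0, c(4, 4, 2))
  bn <- FewShotSynergy:::bnForward(Z, gamma = c(1, 1), beta = c(0, 0),
                                   rmean = c(0, 0), rvar = c(1, 1),
                                   mode = "eval")
  expect_true(all(bn$out == 0))

  # 2x2 toy: one 1x1-equivalent path through max pooling
  X <- array(c(1, 7, 3, 5), c(2, 2, 1))
  mp <- FewShotSynergy:::maxPoolForward(X)
  expect_equal(as.vector(mp$out), 7)

  # batch-mode BN standardizes each channel over positions
  withr::with_seed(8, A <- array(rnorm(32), c(4, 4, 2)))
  bnb <- FewShotSynergy:::bnForward(A, c(1, 1), c(0, 0), c(0, 0), c(1, 1),
                                    mode = "batch")
  for (c in 1:2) {
    expect_equal(mean(bnb$out[, , c]), 0, tolerance = 1e-10)
    expect_equal(mean(bnb$out[, , c]^2), 1, tolerance = 1e-3)  # eps-biased
  }

  expect_equal(FewShotSynergy:::dropoutMask(10, 0), rep(1, 10))
})

test_that("MSE equals the literal-loop definition to 1e-12", {
  withr::with_seed(12, {
    y <- rnorm(17); yhat <- rnorm(17)
  })
  expect_equal(mseLoss(y, yhat), mseOracle(y, yhat), tolerance = 1e-12)
  expect_error(mseLoss(1:3, 1:2), "length")
})
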