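## Shared small fixtures, built in code. Parsed structures are cached per
## test run because SMILES conversion shells out to the chemistry toolkit.

.fixtureCache <- new.env(parent = emptyenv())

cachedFixture <- function(key, builder) {
  if (!exists(key, envir = .fixtureCache))
    assign(key, builder(), envir = .fixtureCache)
  get(key, envir = .fixtureCache)
}

tinyGraphs <- function() {
  cachedFixture("tinyGraphs", function() {
    tf <- tempfile(fileext = ".smi")
    writeLines(c("ethanol\tCCO", "benzene\tc1ccccc1", "propylamine\tCCCN",
                 "acetone\tCC(=O)C"), tf)
    parseStructures(tf, format = "smiles")
  })
}

randomGrid <- function(id, seed) {
  withr::with_seed(seed,
    new("ExpressionGrid", cellLineId = id,
        grid = matrix(rnorm(900), 30, 30),
        geneOrder = sprintf("G%04d", 1:900)))
}

tinyModelConfig <- function() {
  modelConfig(gcnDims = c(6L, 5L, 4L), convChannels = c(2L, 2L),
              fdHidden = 6L, fdOut = 3L, fcOut = 3L, headHidden = 5L)
}

## Small model with every bias jittered away from zero so that no ReLU sits
## exactly on its kink (finite-difference checks need a smooth neighborhood).
tinyModel <- function(seed = 5L, alpha = 0.05, config = tinyModelConfig(),
                      ...) {
  m <- newSynergyModel(config, seed = seed, alpha = alpha, ...)
  withr::with_seed(seed + 1L, {
    jitterP <- function(p) lapply(p, function(x) {
      r <- stats::rnorm(length(x), sd = 0.05)
      if (!is.null(dim(x))) dim(r) <- dim(x)
      x + r
    })
    m@thetaE <- jitterP(m@thetaE)
    m@thetaP <- jitterP(m@thetaP)
  })
  m
}

tinyEntities <- function() {
  cachedFixture("tinyEntities", function() {
    g <- tinyGraphs()
    grids <- list(CL1 = randomGrid("CL1", 101), CL2 = randomGrid("CL2", 102),
                  CL3 = randomGrid("CL3", 103))
    FewShotSynergy:::buildEntityCache(g, grids)
  })
}

randomSamples <- function(n, cells = c("CL1", "CL2", "CL3"), seed = 9L) {
  drugs <- names(tinyGraphs())
  withr::with_seed(seed, {
    pairs <- t(combn(drugs, 2))
    rows <- do.call(rbind, lapply(cells, function(cl) {
      idx <- sample(nrow(pairs), min(n, nrow(pairs)))
      data.frame(drugA = pairs[idx, 1], drugB = pairs[idx, 2],
                 cellLine = cl, score = rnorm(length(idx)),
                 stringsAsFactors = FALSE)
    }))
  })
  rows
}

modelLoss <- function(model, batch, entities, bnMode = "eval") {
  fwd <- FewShotSynergy:::forwardBatch(model, batch, entities,
                                       training = FALSE, bnMode = bnMode)
  mean((fwd$yhat - batch$score)^2)
}

setParams <- function(model, params) {
  nE <- length(model@thetaE)
  model@thetaE <- params[seq_len(nE)]
  model@thetaP <- params[(nE + 1L):length(params)]
  model
}

## ---- literal-definition oracles -----------------------------------------

## Graph-convolution rule, term by term over neighbors.
gcnOracle <- function(nodeFeats, edges, weights, W) {
  n <- nrow(nodeFeats)
  A <- matrix(0, n, n)
  if (nrow(edges) > 0) for (k in seq_len(nrow(edges))) {
    A[edges[k, 1], edges[k, 2]] <- weights[k]
    A[edges[k, 2], edges[k, 1]] <- weights[k]
  }
  dhat <- 1 + rowSums(A)
  out <- matrix(0, n, ncol(W))
  for (u in seq_len(n)) {
    agg <- numeric(ncol(nodeFeats))
    for (v in seq_len(n)) {
      e <- if (u == v) 1 else A[v, u]
      if (e > 0) agg <- agg + e / sqrt(dhat[v] * dhat[u]) * nodeFeats[v, ]
    }
    out[u, ] <- pmax(drop(agg %*% W), 0)
  }
  out
}

## Valid convolution by explicit quadruple loop.
convOracle <- function(X, W, b) {
  k <- dim(W)[1]; inC <- dim(W)[3]; outC <- dim(W)[4]
  outH <- dim(X)[1] - k + 1; outW <- dim(X)[2] - k + 1
  out <- array(0, c(outH, outW, outC))
  for (oc in seq_len(outC)) for (i in seq_len(outH)) for (j in seq_len(outW)) {
    acc <- b[oc]
    for (ic in seq_len(inC)) for (di in seq_len(k)) for (dj in seq_len(k))
      acc <- acc + X[i + di - 1, j + dj - 1, ic] * W[di, dj, ic, oc]
    out[i, j, oc] <- acc
  }
  out
}

## Spearman correlation from the rank formula with average ties.
sccOracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

## AUC as all-pairs concordance (ties count 1/2).
aucOracle <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

## Average precision by walking the ranking.
apOracle <- function(labels, scores) {
  o <- order(scores, decreasing = TRUE)
  lab <- labels[o]
  nPos <- sum(lab)
  tp <- 0; ap <- 0
  for (i in seq_along(lab)) {
    if (lab[i] == 1) {
      tp <- tp + 1
      ap <- ap + (tp / i) / nPos
    }
  }
  ap
}

pairKeyTest <- function(a, b) FewShotSynergy:::pairKey(a, b)

mseOracle <- function(y, yhat) {
  s <- 0
  for (i in seq_along(y)) s <- s + (y[i] - yhat[i])^2
  s / length(y)
}
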