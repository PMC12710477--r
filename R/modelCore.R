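#' Model architecture configuration
#'
#' Declares every width of the synergy predictor. Defaults follow the
#' conventional graph-DTA-scale encoding the 78-dimensional atom descriptor
#' implies; all values are overridable and nothing in the package depends on
#' the defaults.
#'
#' @param nodeDim atom feature dimension (78 for the standard featurization).
#' @param gcnDims output widths of the three graph-convolution layers.
#' @param gridDim spatial size of the expression grid (30 x 30).
#' @param convChannels output channels of each convolutional layer of the
#'   cell encoder (one 3x3 convolution + batch norm + ReLU + 2x2 max pool per
#'   entry).
#' @param kernel convolution kernel size.
#' @param fdHidden,fdOut hidden and output widths of the shared drug
#'   transform applied to both drugs of a pair.
#' @param fcOut output width of the cell transform.
#' @param headHidden hidden width of the two-layer prediction head.
#' @return list describing the architecture, including the derived flattened
#'   cell-embedding dimension and joint-embedding dimension.
#' @export
modelConfig <- function(nodeDim = 78L, gcnDims = c(156L, 312L, 624L),
                        gridDim = c(30L, 30L), convChannels = c(16L, 32L),
                        kernel = 3L, fdHidden = 256L, fdOut = 128L,
                        fcOut = 128L, headHidden = 256L) {
  if (length(gcnDims) != 3L) stop("the drug encoder uses exactly 3 GCN layers")
  h <- gridDim[1L]; w <- gridDim[2L]
  for (l in seq_along(convChannels)) {
    h <- h - kernel + 1L; w <- w - kernel + 1L
    if (h < 2L || w < 2L || h %% 2L != 0L || w %% 2L != 0L)
      stop("grid size ", gridDim[1L], "x", gridDim[2L],
           " is incompatible with ", length(convChannels),
           " conv(", kernel, ")+pool(2) layers")
    h <- h %/% 2L; w <- w %/% 2L
  }
  flatDim <- h * w * convChannels[length(convChannels)]
  list(nodeDim = as.integer(nodeDim), gcnDims = as.integer(gcnDims),
       gridDim = as.integer(gridDim), convChannels = as.integer(convChannels),
       kernel = as.integer(kernel), fdHidden = as.integer(fdHidden),
       fdOut = as.integer(fdOut), fcOut = as.integer(fcOut),
       headHidden = as.integer(headHidden), flatDim = as.integer(flatDim),
       zDim = as.integer(2L * fdOut + fcOut))
}

heInit <- function(dims, fanIn) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fanIn)), dim = dims)
}

#' Create a freshly initialized SynergyModel
#'
#' Parameters are drawn with He-scaled Gaussian initialization under the
#' given seed; biases start at zero, batch-norm at identity.
#'
#' @param config a [modelConfig()].
#' @param seed integer seed for parameter initialization.
#' @param alpha inner-loop (task adaptation) learning rate, > 0.
#' @param beta outer-loop (meta-update) learning rate, > 0.
#' @param dropout dropout rate of the drug transform, in [0, 1).
#' @param innerSteps gradient steps of the inner loop (default 1, a single
#'   adaptation step).
#' @param secondOrder if TRUE (default) the outer gradient differentiates
#'   through the inner update; FALSE selects the first-order approximation.
#' @param ablation one of "none", "no_ml", "no_ft", "no_so", "no_pt".
#' @return a [SynergyModel-class].
#' @export
newSynergyModel <- function(config = modelConfig(), seed = 1L, alpha = 0.01,
                            beta = 0.001, dropout = 0.2, innerSteps = 1L,
                            secondOrder = TRUE, ablation = "none") {
  alpha <- assertNumber(alpha, "alpha", 0, strict = TRUE)
  beta <- assertNumber(beta, "beta", 0, strict = TRUE)
  if (dropout < 0 || dropout >= 1) stop("'dropout' must be in [0, 1)")
  k <- config$kernel
  withSeed(deriveSeed(seed, "init"), {
    thetaE <- list()
    dIn <- config$nodeDim
    for (l in 1:3) {
      dOut <- config$gcnDims[l]
      thetaE[[paste0("gcnW", l)]] <- heInit(c(dIn, dOut), dIn)
      dIn <- dOut
    }
    inC <- 1L
    bnStats <- list()
    for (l in seq_along(config$convChannels)) {
      outC <- config$convChannels[l]
      thetaE[[paste0("conv", l, "W")]] <- heInit(c(k, k, inC, outC),
                                                 k * k * inC)
      thetaE[[paste0("conv", l, "b")]] <- numeric(outC)
      thetaE[[paste0("bn", l, "gamma")]] <- rep(1, outC)
      thetaE[[paste0("bn", l, "beta")]] <- numeric(outC)
      bnStats[[paste0("bn", l, "mean")]] <- numeric(outC)
      bnStats[[paste0("bn", l, "var")]] <- rep(1, outC)
      inC <- outC
    }
    gOut <- config$gcnDims[3L]
    thetaE$fdW1 <- heInit(c(gOut, config$fdHidden), gOut)
    thetaE$fdb1 <- numeric(config$fdHidden)
    thetaE$fdW2 <- heInit(c(config$fdHidden, config$fdOut), config$fdHidden)
    thetaE$fdb2 <- numeric(config$fdOut)
    thetaE$fcW <- heInit(c(config$flatDim, config$fcOut), config$flatDim)
    thetaE$fcb <- numeric(config$fcOut)
    thetaP <- list(
      headW1 = heInit(c(config$zDim, config$headHidden), config$zDim),
      headb1 = numeric(config$headHidden),
      headW2 = heInit(c(config$headHidden, 1L), config$headHidden),
      headb2 = 0)
  })
  new("SynergyModel", thetaE = thetaE, thetaP = thetaP, bnStats = bnStats,
      config = config,
      hyper = list(alpha = alpha, beta = beta, dropout = dropout,
                   innerSteps = as.integer(innerSteps),
                   secondOrder = isTRUE(secondOrder)),
      flags = list(stage = "initialized", ablation = ablation))
}

## ---- parameter-list arithmetic ------------------------------------------

paramZero <- function(template) {
  lapply(template, function(p) {
    if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
  })
}

## a + s * b over matching named lists of arrays
paramAxpy <- function(a, b, s) {
  for (nm in names(b)) a[[nm]] <- a[[nm]] + s * b[[nm]]
  a
}

paramAdd <- function(a, b) paramAxpy(a, b, 1)

flattenParams <- function(p) unlist(p, use.names = FALSE)

unflattenParams <- function(v, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    n <- length(template[[nm]])
    x <- v[(pos + 1L):(pos + n)]
    dim(x) <- dim(template[[nm]])
    out[[nm]] <- x
    pos <- pos + n
  }
  out
}

## ---- graph convolution ---------------------------------------------------

#' Symmetrically normalized adjacency with self contribution
#'
#' Builds the dense aggregation matrix of the graph-convolution rule: entry
#' (u, v) is \eqn{e_{v,u} / \sqrt{\hat D_v \hat D_u}} for bonded pairs and
#' the self term \eqn{1 / \hat D_u} on the diagonal, where
#' \eqn{\hat D_u = 1 + \sum_{v \in N(u)} e_{v,u}} is the weighted degree.
#'
#' @param graph a [MolecularGraph-class].
#' @return dense n x n matrix.
#' @export
normalizedAdjacency <- function(graph) {
  n <- nrow(graph@nodeFeatures)
  A <- matrix(0, n, n)
  e <- graph@edges
  if (nrow(e) > 0L) {
    A[e] <- graph@edgeWeights
    A[e[, c(2L, 1L), drop = FALSE]] <- graph@edgeWeights
  }
  dhat <- 1 + rowSums(A)
  M <- A + diag(1, n)
  M / sqrt(outer(dhat, dhat))
}

#' One graph-convolution layer
#'
#' Neighborhood aggregation with symmetric degree normalization and self
#' contribution, followed by a linear transform and ReLU:
#' \deqn{h_u' = ReLU\left(W \sum_{v \in N(u) \cup \{u\}}
#'   \frac{e_{v,u}}{\sqrt{\hat D_v \hat D_u}} h_v\right)}
#'
#' @param nodeFeats n x d matrix of node features (rows are atoms).
#' @param graph the [MolecularGraph-class] supplying edges and weights.
#' @param W d x d' weight matrix.
#' @return n x d' matrix of updated node features.
#' @export
gcnLayer <- function(nodeFeats, graph, W) {
  if (ncol(nodeFeats) != nrow(W))
    stop("gcnLayer shape mismatch: features have ", ncol(nodeFeats),
         " columns, W expects ", nrow(W))
  relu(normalizedAdjacency(graph) %*% nodeFeats %*% W)
}

drugForwardInternal <- function(X, Anorm, thetaE) {
  H <- X
  layers <- vector("list", 3L)
  for (l in 1:3) {
    S <- Anorm %*% H
    Zpre <- S %*% thetaE[[paste0("gcnW", l)]]
    H <- relu(Zpre)
    layers[[l]] <- list(S = S, Zpre = Zpre)
  }
  amax <- apply(H, 2L, which.max)
  list(h = apply(H, 2L, max), layers = layers, H = H, amax = amax,
       Anorm = Anorm)
}

drugBackwardInternal <- function(dh, cache, thetaE) {
  n <- nrow(cache$H)
  dH <- matrix(0, n, ncol(cache$H))
  dH[cbind(cache$amax, seq_along(dh))] <- dh
  grads <- list()
  for (l in 3:1) {
    W <- thetaE[[paste0("gcnW", l)]]
    dZ <- dH * (cache$layers[[l]]$Zpre > 0)
    grads[[paste0("gcnW", l)]] <- crossprod(cache$layers[[l]]$S, dZ)
    if (l > 1L) dH <- cache$Anorm %*% (dZ %*% t(W))
  }
  grads
}

## ---- cell encoder --------------------------------------------------------

cellForwardInternal <- function(grid, thetaE, bnStats, config, bnMode) {
  X <- array(grid, c(dim(grid), 1L))
  caches <- vector("list", length(config$convChannels))
  for (l in seq_along(config$convChannels)) {
    cv <- convForward(X, thetaE[[paste0("conv", l, "W")]],
                      thetaE[[paste0("conv", l, "b")]])
    bn <- bnForward(cv$out, thetaE[[paste0("bn", l, "gamma")]],
                    thetaE[[paste0("bn", l, "beta")]],
                    bnStats[[paste0("bn", l, "mean")]],
                    bnStats[[paste0("bn", l, "var")]], mode = bnMode)
    act <- relu(bn$out)
    pl <- maxPoolForward(act)
    caches[[l]] <- list(conv = cv, bn = bn$cache, bnPre = bn$out, pool = pl)
    X <- pl$out
  }
  list(h = as.vector(X), caches = caches, outDim = dim(X))
}

cellBackwardInternal <- function(dh, fwd, thetaE, config) {
  dX <- array(dh, fwd$outDim)
  grads <- list()
  for (l in rev(seq_along(config$convChannels))) {
    cc <- fwd$caches[[l]]
    dAct <- maxPoolBackward(dX, cc$pool)
    dBn <- dAct * (cc$bnPre > 0)
    bb <- bnBackward(dBn, cc$bn, thetaE[[paste0("bn", l, "gamma")]])
    grads[[paste0("bn", l, "gamma")]] <- bb$dgamma
    grads[[paste0("bn", l, "beta")]] <- bb$dbeta
    cb <- convBackward(bb$dX, cc$conv, thetaE[[paste0("conv", l, "W")]])
    grads[[paste0("conv", l, "W")]] <- cb$dW
    grads[[paste0("conv", l, "b")]] <- cb$db
    dX <- cb$dX
  }
  grads
}

## ---- batched full forward / backward ------------------------------------

#' Precompute per-entity forward-pass inputs
#'
#' Builds the cache the batched forward pass indexes into: per drug the node
#' feature matrix and normalized adjacency, per cell line the expression
#' grid. Build it once per dataset and reuse it across training and
#' evaluation calls.
#'
#' @param drugs named list of [MolecularGraph-class].
#' @param profiles named list of [ExpressionGrid-class].
#' @return entity cache list with elements `graphs` and `grids`.
#' @export
buildEntityCache <- function(drugs, profiles) {
  graphs <- lapply(drugs, function(g)
    list(X = g@nodeFeatures, A = normalizedAdjacency(g)))
  names(graphs) <- vapply(drugs, drugId, character(1))
  grids <- lapply(profiles, gridValues)
  names(grids) <- vapply(profiles, cellLineId, character(1))
  list(graphs = graphs, grids = grids)
}

## One forward pass over a batch of (drugA, drugB, cellLine) samples.
## Embeddings are computed once per unique drug / cell line and indexed.
forwardBatch <- function(model, batch, entities, training = FALSE,
                         bnMode = c("eval", "batch")) {
  bnMode <- match.arg(bnMode)
  cfg <- model@config
  tE <- model@thetaE; tP <- model@thetaP

  ud <- unique(c(batch$drugA, batch$drugB))
  missingD <- setdiff(ud, names(entities$graphs))
  if (length(missingD)) stop("no structure for drug(s): ",
                             paste(missingD, collapse = ", "))
  dCaches <- lapply(ud, function(id) {
    g <- entities$graphs[[id]]
    drugForwardInternal(g$X, g$A, tE)
  })
  Hd <- do.call(rbind, lapply(dCaches, `[[`, "h"))

  # shared drug transform: FC1 -> Dropout -> ReLU -> FC2 (as the integration
  # layer orders them)
  d1 <- denseForward(Hd, tE$fdW1, tE$fdb1)
  mask <- if (training && model@hyper$dropout > 0)
    matrix(dropoutMask(length(d1$out), model@hyper$dropout), nrow(d1$out))
  else matrix(1, nrow(d1$out), ncol(d1$out))
  D <- d1$out * mask
  R <- relu(D)
  d2 <- denseForward(R, tE$fdW2, tE$fdb2)
  Fd <- d2$out

  uc <- unique(batch$cellLine)
  missingC <- setdiff(uc, names(entities$grids))
  if (length(missingC)) stop("no expression profile for cell line(s): ",
                             paste(missingC, collapse = ", "))
  cCaches <- lapply(uc, function(id)
    cellForwardInternal(entities$grids[[id]], tE, model@bnStats, cfg, bnMode))
  Hc <- do.call(rbind, lapply(cCaches, `[[`, "h"))
  fc <- denseForward(Hc, tE$fcW, tE$fcb)
  Fc <- fc$out

  ia <- match(batch$drugA, ud); ib <- match(batch$drugB, ud)
  ic <- match(batch$cellLine, uc)
  Z <- cbind(Fd[ia, , drop = FALSE], Fd[ib, , drop = FALSE],
             Fc[ic, , drop = FALSE])

  h1 <- denseForward(Z, tP$headW1, tP$headb1)
  H1 <- relu(h1$out)
  yhat <- drop(H1 %*% tP$headW2) + tP$headb2

  list(yhat = yhat,
       cache = list(ud = ud, uc = uc, ia = ia, ib = ib, ic = ic,
                    dCaches = dCaches, cCaches = cCaches, Hd = Hd, Hc = Hc,
                    D = D, R = R, mask = mask, Fd = Fd, Fc = Fc, Z = Z,
                    h1pre = h1$out, H1 = H1, bnMode = bnMode))
}

## Accumulate rows of `g` into groups (unique-entity rows).
accumulateRows <- function(g, group, n) {
  out <- matrix(0, n, ncol(g))
  s <- rowsum(g, group)
  out[as.integer(rownames(s)), ] <- s
  out
}

## Backward pass for a batch given d(loss)/d(yhat). wrt = "thetaP" stops at
## the head (the inner loop's selective adaptation needs nothing deeper).
backwardBatch <- function(model, cache, dy, wrt = c("all", "thetaP")) {
  wrt <- match.arg(wrt)
  tE <- model@thetaE; tP <- model@thetaP
  cfg <- model@config

  dyM <- matrix(dy, ncol = 1L)
  gP <- list(headW2 = crossprod(cache$H1, dyM),
             headb2 = sum(dy))
  dH1 <- dyM %*% t(tP$headW2)
  dH1 <- dH1 * (cache$h1pre > 0)
  gP$headW1 <- crossprod(cache$Z, dH1)
  gP$headb1 <- colSums(dH1)
  gP <- gP[c("headW1", "headb1", "headW2", "headb2")]
  if (wrt == "thetaP")
    return(list(thetaP = gP, thetaE = NULL))

  dZ <- dH1 %*% t(tP$headW1)
  k <- cfg$fdOut
  dZA <- dZ[, 1:k, drop = FALSE]
  dZB <- dZ[, (k + 1L):(2L * k), drop = FALSE]
  dZC <- dZ[, (2L * k + 1L):ncol(dZ), drop = FALSE]

  gE <- paramZero(tE)

  dFd <- accumulateRows(rbind(dZA, dZB), c(cache$ia, cache$ib),
                        length(cache$ud))
  dR <- dFd %*% t(tE$fdW2)
  gE$fdW2 <- crossprod(cache$R, dFd)
  gE$fdb2 <- colSums(dFd)
  dD <- dR * (cache$D > 0)
  dZ1 <- dD * cache$mask
  gE$fdW1 <- crossprod(cache$Hd, dZ1)
  gE$fdb1 <- colSums(dZ1)
  dHd <- dZ1 %*% t(tE$fdW1)
  for (u in seq_along(cache$ud)) {
    gd <- drugBackwardInternal(dHd[u, ], cache$dCaches[[u]], tE)
    for (nm in names(gd)) gE[[nm]] <- gE[[nm]] + gd[[nm]]
  }

  dFc <- accumulateRows(dZC, cache$ic, length(cache$uc))
  gE$fcW <- crossprod(cache$Hc, dFc)
  gE$fcb <- colSums(dFc)
  dHc <- dFc %*% t(tE$fcW)
  for (cI in seq_along(cache$uc)) {
    gc <- cellBackwardInternal(dHc[cI, ], cache$cCaches[[cI]], tE, cfg)
    for (nm in names(gc)) gE[[nm]] <- gE[[nm]] + gc[[nm]]
  }

  list(thetaP = gP, thetaE = gE)
}

## Loss + gradient in one call. loss = "mse" (mean) or "half_sum"
## (pretraining objective).
lossAndGrad <- function(model, batch, entities, loss = c("mse", "half_sum"),
                        wrt = c("all", "thetaP"), training = FALSE,
                        bnMode = "eval") {
  loss <- match.arg(loss)
  wrt <- match.arg(wrt)
  fwd <- forwardBatch(model, batch, entities, training = training,
                      bnMode = bnMode)
  resid <- fwd$yhat - batch$score
  m <- length(resid)
  if (loss == "mse") {
    value <- mean(resid^2)
    dy <- 2 * resid / m
  } else {
    value <- 0.5 * sum(resid^2)
    dy <- resid
  }
  grads <- backwardBatch(model, fwd$cache, dy, wrt = wrt)
  list(loss = value, grads = grads, fwd = fwd)
}

## Refresh batch-norm running statistics from the per-instance statistics of
## a training forward pass (momentum 0.1), one update per unique cell line.
updateBnStats <- function(bnStats, cache, config, momentum = 0.1) {
  for (cc in cache$cCaches) {
    for (l in seq_along(config$convChannels)) {
      upd <- bnUpdateRunning(bnStats[[paste0("bn", l, "mean")]],
                             bnStats[[paste0("bn", l, "var")]],
                             cc$caches[[l]]$bn, momentum)
      bnStats[[paste0("bn", l, "mean")]] <- upd$mean
      bnStats[[paste0("bn", l, "var")]] <- upd$var
    }
  }
  bnStats
}

## ---- public forward-pass pieces -----------------------------------------

setMethod("encodeDrug", c("SynergyModel", "MolecularGraph"),
  function(model, x) {
    drugForwardInternal(x@nodeFeatures, normalizedAdjacency(x),
                        model@thetaE)$h
  })

setMethod("encodeCell", c("SynergyModel", "ExpressionGrid"),
  function(model, x, bnMode = "eval") {
    cellForwardInternal(gridValues(x), model@thetaE, model@bnStats,
                        model@config, match.arg(bnMode, c("eval", "batch")))$h
  })

#' Integrate drug-pair and cell-line embeddings into the joint embedding
#'
#' Applies the shared drug transform (FC, dropout, ReLU, FC) to both drug
#' embeddings and a single FC layer to the cell embedding, then concatenates.
#' Dropout is active only when `training = TRUE`.
#'
#' @param model a [SynergyModel-class].
#' @param hA,hB drug embeddings (vectors from [encodeDrug()]).
#' @param hC cell embedding (vector from [encodeCell()]).
#' @param training logical; enables dropout.
#' @return numeric joint-embedding vector of length `config$zDim`.
#' @export
integrateEmbeddings <- function(model, hA, hB, hC, training = FALSE) {
  tE <- model@thetaE
  fd <- function(h) {
    z1 <- drop(h %*% tE$fdW1) + tE$fdb1
    if (training && model@hyper$dropout > 0)
      z1 <- z1 * dropoutMask(length(z1), model@hyper$dropout)
    drop(relu(z1) %*% tE$fdW2) + tE$fdb2
  }
  c(fd(hA), fd(hB), drop(hC %*% tE$fcW) + tE$fcb)
}

#' Map a joint embedding to a predicted synergy score
#'
#' Two fully connected layers: \eqn{\hat y = ReLU(z W_1 + b_1) W_2 + b_2}.
#'
#' @param model a [SynergyModel-class].
#' @param z joint embedding vector or matrix (rows = samples).
#' @return numeric vector of predicted scores.
#' @export
predictHead <- function(model, z) {
  if (is.null(dim(z))) z <- matrix(z, nrow = 1L)
  tP <- model@thetaP
  if (ncol(z) != nrow(tP$headW1))
    stop("joint embedding has ", ncol(z), " dimensions, head expects ",
         nrow(tP$headW1))
  H1 <- relu(sweep(z %*% tP$headW1, 2L, tP$headb1, "+"))
  drop(H1 %*% tP$headW2) + tP$headb2
}

#' Predict synergy scores for a sample table
#'
#' Pure forward pass in evaluation mode (dropout off, batch-norm running
#' statistics); no parameters change.
#'
#' @param model a [SynergyModel-class].
#' @param samples data.frame with columns drugA, drugB, cellLine (and
#'   optionally score, ignored).
#' @param entities an entity cache from [buildEntityCache()], or a
#'   [SyntheticWorld-class].
#' @return numeric vector of predicted synergy scores.
#' @export
predictScores <- function(model, samples, entities) {
  entities <- asEntityCache(entities)
  forwardBatch(model, samples, entities, training = FALSE,
               bnMode = "eval")$yhat
}

asEntityCache <- function(x) {
  if (is(x, "SyntheticWorld"))
    return(buildEntityCache(x@drugs, x@profiles))
  if (is.list(x) && !is.null(x$graphs) && !is.null(x$grids)) return(x)
  stop("expected an entity cache (buildEntityCache) or a SyntheticWorld")
}

#' Mean squared error
#'
#' \eqn{\frac{1}{m} \sum_i (y_i - \hat y_i)^2}, the task loss used by both
#' optimization tiers.
#'
#' @param y true scores.
#' @param yhat predicted scores.
#' @return single number.
#' @export
mseLoss <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  mean((y - yhat)^2)
}
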