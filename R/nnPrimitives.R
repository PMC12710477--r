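## Minimal dense/conv/batch-norm/pool primitives with explicit backward
## passes. Everything operates on plain double matrices/arrays; feature maps
## are (H, W, C) arrays. Each forward returns the output plus the cache its
## backward needs; each backward returns input and parameter gradients.

relu <- function(x) pmax(x, 0)

denseForward <- function(X, W, b) {
  if (ncol(X) != nrow(W)) stop("dense layer shape mismatch: input has ",
                               ncol(X), " columns, weight expects ", nrow(W))
  Z <- X %*% W
  Z <- sweep(Z, 2L, b, "+")
  list(out = Z, X = X)
}

denseBackward <- function(dOut, cache, W) {
  list(dX = dOut %*% t(W),
       dW = crossprod(cache$X, dOut),
       db = colSums(dOut))
}

## -- im2col convolution (valid, stride 1) ---------------------------------

im2col <- function(X, k) {
  d <- dim(X)
  H <- d[1L]; W <- d[2L]; C <- d[3L]
  outH <- H - k + 1L; outW <- W - k + 1L
  if (outH < 1L || outW < 1L)
    stop("kernel larger than input (", H, "x", W, " vs k=", k, ")")
  cols <- matrix(0, outH * outW, k * k * C)
  for (c in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- (c - 1L) * k * k + (dj - 1L) * k + di
    cols[, idx] <- X[di:(di + outH - 1L), dj:(dj + outW - 1L), c]
  }
  cols
}

col2im <- function(dCols, dimX, k) {
  H <- dimX[1L]; W <- dimX[2L]; C <- dimX[3L]
  outH <- H - k + 1L; outW <- W - k + 1L
  dX <- array(0, dimX)
  for (c in seq_len(C)) for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx <- (c - 1L) * k * k + (dj - 1L) * k + di
    block <- matrix(dCols[, idx], outH, outW)
    rows <- di:(di + outH - 1L); colsi <- dj:(dj + outW - 1L)
    dX[rows, colsi, c] <- dX[rows, colsi, c] + block
  }
  dX
}

## W: (k, k, inC, outC) array, b: outC vector, X: (H, W, inC) array.
convForward <- function(X, W, b) {
  d <- dim(W)
  k <- d[1L]; inC <- d[3L]; outC <- d[4L]
  if (dim(X)[3L] != inC) stop("convolution channel mismatch")
  cols <- im2col(X, k)
  Wmat <- matrix(W, nrow = k * k * inC, ncol = outC)
  out <- sweep(cols %*% Wmat, 2L, b, "+")
  outH <- dim(X)[1L] - k + 1L; outW <- dim(X)[2L] - k + 1L
  list(out = array(out, c(outH, outW, outC)),
       cols = cols, dimX = dim(X), k = k)
}

convBackward <- function(dOut, cache, W) {
  d <- dim(W)
  k <- d[1L]; inC <- d[3L]; outC <- d[4L]
  dOutMat <- matrix(dOut, ncol = outC)
  Wmat <- matrix(W, nrow = k * k * inC, ncol = outC)
  dW <- array(crossprod(cache$cols, dOutMat), dim = d)
  db <- colSums(dOutMat)
  dX <- col2im(dOutMat %*% t(Wmat), cache$dimX, k)
  list(dX = dX, dW = dW, db = db)
}

## -- batch normalization (per channel over spatial positions) -------------

bnEps <- 1e-5

bnForward <- function(X, gamma, beta, rmean, rvar, mode = c("batch", "eval")) {
  mode <- match.arg(mode)
  d <- dim(X); C <- d[3L]
  out <- array(0, d)
  cache <- list(mode = mode, dimX = d, xhat = array(0, d),
                invstd = numeric(C), mu = numeric(C), varb = numeric(C))
  for (c in seq_len(C)) {
    x <- X[, , c]
    if (mode == "batch") {
      mu <- mean(x)
      varb <- mean((x - mu)^2)
    } else {
      mu <- rmean[c]
      varb <- rvar[c]
    }
    invstd <- 1 / sqrt(varb + bnEps)
    xhat <- (x - mu) * invstd
    out[, , c] <- gamma[c] * xhat + beta[c]
    cache$xhat[, , c] <- xhat
    cache$invstd[c] <- invstd
    cache$mu[c] <- mu
    cache$varb[c] <- varb
  }
  list(out = out, cache = cache)
}

bnBackward <- function(dOut, cache, gamma) {
  d <- cache$dimX; C <- d[3L]; N <- d[1L] * d[2L]
  dX <- array(0, d)
  dgamma <- numeric(C); dbeta <- numeric(C)
  for (c in seq_len(C)) {
    dy <- dOut[, , c]
    xhat <- cache$xhat[, , c]
    dgamma[c] <- sum(dy * xhat)
    dbeta[c] <- sum(dy)
    if (cache$mode == "batch") {
      # full backward: batch statistics depend on the input
      dX[, , c] <- (gamma[c] * cache$invstd[c] / N) *
        (N * dy - sum(dy) - xhat * sum(dy * xhat))
    } else {
      dX[, , c] <- dy * gamma[c] * cache$invstd[c]
    }
  }
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

bnUpdateRunning <- function(rmean, rvar, cache, momentum = 0.1) {
  list(mean = (1 - momentum) * rmean + momentum * cache$mu,
       var = (1 - momentum) * rvar + momentum * cache$varb)
}

## -- 2x2 max pooling, stride 2 --------------------------------------------

maxPoolForward <- function(X) {
  d <- dim(X)
  if (d[1L] %% 2L != 0L || d[2L] %% 2L != 0L)
    stop("max pooling requires even spatial dimensions, got ",
         d[1L], "x", d[2L])
  oi <- seq(1L, d[1L], 2L); oj <- seq(1L, d[2L], 2L)
  subs <- list(X[oi, oj, , drop = FALSE], X[oi + 1L, oj, , drop = FALSE],
               X[oi, oj + 1L, , drop = FALSE],
               X[oi + 1L, oj + 1L, , drop = FALSE])
  out <- pmax(subs[[1L]], subs[[2L]], subs[[3L]], subs[[4L]])
  list(out = out, subs = subs, dimX = d)
}

maxPoolBackward <- function(dOut, cache) {
  d <- cache$dimX
  oi <- seq(1L, d[1L], 2L); oj <- seq(1L, d[2L], 2L)
  dX <- array(0, d)
  taken <- array(FALSE, dim(dOut))
  out <- pmax(cache$subs[[1L]], cache$subs[[2L]], cache$subs[[3L]],
              cache$subs[[4L]])
  off <- list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(1L, 1L))
  for (k in 1:4) {
    hit <- (cache$subs[[k]] == out) & !taken  # ties: first window slot wins
    taken <- taken | hit
    g <- dOut * hit
    rows <- oi + off[[k]][1L]; cols <- oj + off[[k]][2L]
    dX[rows, cols, ] <- dX[rows, cols, , drop = FALSE] + g
  }
  dX
}

## -- inverted dropout ------------------------------------------------------

dropoutMask <- function(n, rate) {
  if (rate <= 0) return(rep(1, n))
  (stats::runif(n) >= rate) / (1 - rate)
}
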