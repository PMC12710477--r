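## Stage-wise training: cross-domain pretraining, episodic cross-tier
## meta-optimization (selective head-only inner loop, second-order outer
## update), and few-shot fine-tuning, plus the zero-shot mode and the
## ablation variants (no_ml / no_ft / no_so / no_pt).

## Head-only loss and gradient on a fixed joint-embedding matrix. The
## selective inner loop never needs anything deeper.
headLossGrad <- function(Z, y, tP) {
  h1pre <- sweep(Z %*% tP$headW1, 2L, tP$headb1, "+")
  H1 <- relu(h1pre)
  yhat <- drop(H1 %*% tP$headW2) + tP$headb2
  resid <- yhat - y
  m <- length(y)
  dy <- matrix(2 * resid / m, ncol = 1L)
  dH1 <- (dy %*% t(tP$headW2)) * (h1pre > 0)
  list(loss = mean(resid^2),
       grads = list(headW1 = crossprod(Z, dH1), headb1 = colSums(dH1),
                    headW2 = crossprod(H1, dy), headb2 = sum(dy)),
       yhat = yhat)
}

## ---- Adam (used for pretraining; the outer tier is plain gradient
## descent as the meta-update rule prescribes) ------------------------------

adamInit <- function(template) {
  list(m = paramZero(template), v = paramZero(template), t = 0L)
}

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Cross-domain pretraining
#'
#' Jointly optimizes the embedding parameters and the prediction head on
#' synergy samples from the base (data-rich) cell lines, minimizing the
#' half-sum-of-squares objective \eqn{\frac12 \sum_i (\hat y_i - y_i)^2} by
#' mini-batch gradient descent. Dropout is active and batch-norm uses (and
#' updates) per-instance statistics during these forward passes.
#'
#' @param model a [SynergyModel-class].
#' @param samples synergy sample data.frame (base cell lines).
#' @param entities entity cache or [SyntheticWorld-class].
#' @param epochs number of passes over the data (0 returns the model
#'   unchanged).
#' @param batchSize mini-batch size.
#' @param seed seed for batch shuffling and dropout.
#' @param lr learning rate.
#' @param optimizer "adam" (default) or "sgd".
#' @return the updated [SynergyModel-class], with stage "pretrained" and the
#'   per-epoch training-loss trajectory in `flags$pretrainLog`.
#' @export
pretrain <- function(model, samples, entities, epochs = 500L,
                     batchSize = 128L, seed = 1L, lr = 1e-3,
                     optimizer = c("adam", "sgd")) {
  optimizer <- match.arg(optimizer)
  assertSynergyTable(samples)
  epochs <- assertCount(epochs, "epochs", min = 0L)
  if (model@flags$ablation == "no_pt")
    stop("pretraining is disabled under ablation 'no_pt'")
  entities <- asEntityCache(entities)
  n <- nrow(samples)
  params <- c(model@thetaE, model@thetaP)
  nE <- length(model@thetaE)
  opt <- adamInit(params)
  log <- numeric(epochs)
  withSeed(deriveSeed(seed, "pretrain"), {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(n)
      total <- 0
      for (start in seq(1L, n, by = batchSize)) {
        idx <- ord[start:min(start + batchSize - 1L, n)]
        batch <- samples[idx, , drop = FALSE]
        model@thetaE <- params[seq_len(nE)]
        model@thetaP <- params[(nE + 1L):length(params)]
        lg <- lossAndGrad(model, batch, entities, loss = "half_sum",
                          wrt = "all", training = TRUE, bnMode = "batch")
        model@bnStats <- updateBnStats(model@bnStats, lg$fwd$cache,
                                       model@config)
        grads <- c(lg$grads$thetaE, lg$grads$thetaP)
        if (optimizer == "adam") {
          st <- adamStep(params, grads, opt, lr)
          params <- st$params; opt <- st$state
        } else {
          params <- paramAxpy(params, grads, -lr)
        }
        total <- total + lg$loss
      }
      log[ep] <- total
    }
  })
  model@thetaE <- params[seq_len(nE)]
  model@thetaP <- params[(nE + 1L):length(params)]
  model@flags$stage <- "pretrained"
  model@flags$pretrainLog <- log
  model
}

#' Sample one episode of few-shot tasks
#'
#' Draws N distinct cell lines without replacement, and for each K + Q of its
#' samples without replacement, split into a K-sample support set and a
#' Q-sample query set.
#'
#' @param samples synergy sample data.frame.
#' @param N tasks (cell lines) per episode.
#' @param K support-set size.
#' @param Q query-set size.
#' @param seed episode seed; the same seed reproduces the same episode.
#' @param cells optional subset of cell lines to draw from.
#' @return list of N [FewShotTask-class] objects.
#' @export
buildEpisode <- function(samples, N, K, Q, seed, cells = NULL) {
  assertSynergyTable(samples)
  N <- assertCount(N, "N"); K <- assertCount(K, "K"); Q <- assertCount(Q, "Q")
  if (!is.null(cells)) samples <- samples[samples$cellLine %in% cells, ]
  samples <- samples[!duplicated(cbind(samples$cellLine,
                                       pairKey(samples$drugA,
                                               samples$drugB))), ]
  counts <- table(samples$cellLine)
  eligible <- names(counts)[counts >= K + Q]
  short <- names(counts)[counts < K + Q]
  if (length(eligible) < N)
    stop("need ", N, " cell lines with at least K+Q = ", K + Q,
         " samples, but only ", length(eligible), " qualify",
         if (length(short)) paste0(" (insufficient: ",
                                   paste(utils::head(short, 5L),
                                         collapse = ", "), ")") else "")
  withSeed(seed, {
    lines <- sample(eligible, N)
    lapply(lines, function(cl) {
      rows <- samples[samples$cellLine == cl, , drop = FALSE]
      pick <- rows[sample.int(nrow(rows), K + Q), , drop = FALSE]
      FewShotTask(cl, support = pick[seq_len(K), , drop = FALSE],
                  query = pick[(K + 1L):(K + Q), , drop = FALSE])
    })
  })
}

#' Inner-tier adaptation of the prediction head
#'
#' Computes the support-set MSE through the full network and takes
#' `steps` gradient steps of size alpha on the prediction-head parameters:
#' \eqn{\theta' = (\theta_E,\; \theta_p - \alpha \nabla_{\theta_p}
#' L_{s})}. The embedding parameters are returned untouched (bit-identical)
#' unless the model's ablation flag is `no_so`, in which case both groups
#' adapt.
#'
#' @param model a [SynergyModel-class].
#' @param task a [FewShotTask-class] (its support set drives adaptation).
#' @param entities entity cache or [SyntheticWorld-class].
#' @param alpha inner learning rate; defaults to the model's.
#' @param steps gradient steps; defaults to the model's `innerSteps`.
#' @param bnMode batch-norm mode of the embedding forward pass ("eval" for
#'   adaptation on new cell lines, "batch" inside meta-training).
#' @return list with `thetaP` (adapted head), `thetaE` (adapted only under
#'   `no_so`), `supportLoss` (pre-adaptation), and `supportZ` (cached
#'   support joint embeddings).
#' @export
innerAdapt <- function(model, task, entities, alpha = NULL, steps = NULL,
                       bnMode = "eval") {
  entities <- asEntityCache(entities)
  alpha <- if (is.null(alpha)) model@hyper$alpha else
    assertNumber(alpha, "alpha", 0)
  steps <- if (is.null(steps)) model@hyper$innerSteps else
    assertCount(steps, "steps")
  support <- if (is(task, "FewShotTask")) supportSet(task) else task
  if (nrow(support) == 0L) stop("inner adaptation requires a non-empty ",
                                "support set (use zeroShotPredict instead)")
  adaptAll <- identical(model@flags$ablation, "no_so")

  if (!adaptAll) {
    fwd <- forwardBatch(model, support, entities, training = FALSE,
                        bnMode = bnMode)
    Z <- fwd$cache$Z
    tP <- model@thetaP
    first <- headLossGrad(Z, support$score, tP)
    loss0 <- first$loss
    tP <- paramAxpy(tP, first$grads, -alpha)
    if (steps > 1L) for (s in 2:steps)
      tP <- paramAxpy(tP, headLossGrad(Z, support$score, tP)$grads, -alpha)
    list(thetaP = tP, thetaE = model@thetaE, supportLoss = loss0,
         supportZ = Z)
  } else {
    loss0 <- NA_real_
    for (s in seq_len(steps)) {
      lg <- lossAndGrad(model, support, entities, loss = "mse", wrt = "all",
                        training = FALSE, bnMode = bnMode)
      if (s == 1L) loss0 <- lg$loss
      model@thetaP <- paramAxpy(model@thetaP, lg$grads$thetaP, -alpha)
      model@thetaE <- paramAxpy(model@thetaE, lg$grads$thetaE, -alpha)
    }
    list(thetaP = model@thetaP, thetaE = model@thetaE, supportLoss = loss0,
         supportZ = NULL)
  }
}

## Outer-tier gradient for one task: query loss at the adapted parameters,
## differentiated through the inner update. The second-order correction is
## g_outer = g_query - alpha * H_support %*% g_query|adapted-subset, with the
## Hessian-vector product obtained by central differencing of exact support
## gradients (truncation error O(eps^2)).
outerTaskGrad <- function(model, task, entities, bnMode = "batch") {
  hy <- model@hyper
  adaptAll <- identical(model@flags$ablation, "no_so")
  secondOrder <- hy$secondOrder && hy$innerSteps == 1L

  gs <- lossAndGrad(model, supportSet(task), entities, loss = "mse",
                    wrt = "all", training = FALSE, bnMode = bnMode)
  adapted <- model
  adapted@thetaP <- paramAxpy(model@thetaP, gs$grads$thetaP, -hy$alpha)
  if (adaptAll)
    adapted@thetaE <- paramAxpy(model@thetaE, gs$grads$thetaE, -hy$alpha)
  if (hy$innerSteps > 1L) {
    more <- innerAdapt(model, task, entities, bnMode = bnMode)
    adapted@thetaP <- more$thetaP
    adapted@thetaE <- more$thetaE
  }

  gq <- lossAndGrad(adapted, querySet(task), entities, loss = "mse",
                    wrt = "all", training = FALSE, bnMode = bnMode)
  gE <- gq$grads$thetaE
  gP <- gq$grads$thetaP

  if (secondOrder) {
    vP <- gP
    vE <- if (adaptAll) gE else NULL
    vnorm <- sqrt(sum(flattenParams(vP)^2) +
                  if (adaptAll) sum(flattenParams(vE)^2) else 0)
    if (vnorm > 0) {
      scale <- sqrt(sum(flattenParams(model@thetaP)^2))
      eps <- 1e-4 * (1 + scale) / vnorm
      perturb <- function(sign) {
        m <- model
        m@thetaP <- paramAxpy(model@thetaP, vP, sign * eps)
        if (adaptAll) m@thetaE <- paramAxpy(model@thetaE, vE, sign * eps)
        lossAndGrad(m, supportSet(task), entities, loss = "mse",
                    wrt = "all", training = FALSE, bnMode = bnMode)$grads
      }
      gPlus <- perturb(1); gMinus <- perturb(-1)
      coef <- -hy$alpha / (2 * eps)
      gP <- paramAxpy(gP, paramAxpy(gPlus$thetaP, gMinus$thetaP, -1), coef)
      gE <- paramAxpy(gE, paramAxpy(gPlus$thetaE, gMinus$thetaE, -1), coef)
    }
  }
  list(thetaE = gE, thetaP = gP, queryLoss = gq$loss,
       supportCache = gs$fwd$cache)
}

## Summed outer-tier gradient over one episode (gradient of sum_j L_{q,j}
## with respect to the shared initialization). Also refreshes batch-norm
## running statistics when the episode runs in batch mode.
episodeGradient <- function(model, episode, entities, zeroShot = FALSE,
                            bnMode = "batch") {
  if (length(episode) == 0L) stop("empty episode")
  if (model@flags$ablation == "no_ml")
    stop("meta-optimization is disabled under ablation 'no_ml'")
  accE <- paramZero(model@thetaE)
  accP <- paramZero(model@thetaP)
  losses <- numeric(length(episode))
  for (j in seq_along(episode)) {
    if (zeroShot) {
      g <- lossAndGrad(model, querySet(episode[[j]]), entities, loss = "mse",
                       wrt = "all", training = FALSE, bnMode = bnMode)
      tg <- list(thetaE = g$grads$thetaE, thetaP = g$grads$thetaP,
                 queryLoss = g$loss, supportCache = g$fwd$cache)
    } else {
      tg <- outerTaskGrad(model, episode[[j]], entities, bnMode = bnMode)
    }
    accE <- paramAdd(accE, tg$thetaE)
    accP <- paramAdd(accP, tg$thetaP)
    losses[j] <- tg$queryLoss
    if (bnMode == "batch")
      model@bnStats <- updateBnStats(model@bnStats, tg$supportCache,
                                     model@config)
  }
  list(thetaE = accE, thetaP = accP, queryLoss = mean(losses),
       bnStats = model@bnStats)
}

#' Outer-tier meta-update over one episode
#'
#' Runs the inner adaptation for every task of the episode, evaluates each
#' task's query loss at its adapted parameters, and updates the shared
#' initialization by one gradient-descent step on the summed query losses:
#' \eqn{\theta \leftarrow \theta - \beta \nabla_\theta \sum_j L_{q,j}}.
#' Both parameter groups are updated in the outer tier; by default the
#' gradient flows through the inner update (second order), with a
#' first-order approximation selectable via the model's `secondOrder` flag.
#'
#' @param model a [SynergyModel-class].
#' @param episode list of [FewShotTask-class] (from [buildEpisode()]).
#' @param entities entity cache or [SyntheticWorld-class].
#' @param zeroShot if TRUE the inner loop is disabled and query losses are
#'   taken at the unadapted parameters.
#' @param bnMode batch-norm mode for the episode's forward passes.
#' @return list with the updated `model` and `queryLoss` (mean over tasks).
#' @export
outerUpdate <- function(model, episode, entities, zeroShot = FALSE,
                        bnMode = "batch") {
  entities <- asEntityCache(entities)
  eg <- episodeGradient(model, episode, entities, zeroShot = zeroShot,
                        bnMode = bnMode)
  model@bnStats <- eg$bnStats
  model@thetaE <- paramAxpy(model@thetaE, eg$thetaE, -model@hyper$beta)
  model@thetaP <- paramAxpy(model@thetaP, eg$thetaP, -model@hyper$beta)
  list(model = model, queryLoss = eg$queryLoss)
}

#' Episodic cross-tier meta-training
#'
#' Iterates episode sampling and outer-tier updates. Each episode draws N
#' tasks from N distinct cell lines with K support and Q query samples each.
#'
#' @inheritParams outerUpdate
#' @param samples synergy samples of the meta-training (base) cell lines.
#' @param episodes number of episodes (0 returns the model unchanged).
#' @param N,K,Q episode geometry (see [buildEpisode()]).
#' @param seed root seed; episode e uses a derived per-episode seed.
#' @param cells optional restriction of the cell-line pool.
#' @param optimizer outer-tier optimizer: "sgd" is the plain gradient-descent
#'   meta-update rule (default); "adam" applies the summed outer gradient
#'   through an adaptive step instead.
#' @return the updated [SynergyModel-class], stage "meta-trained", with the
#'   per-episode mean query loss in `flags$metaLog`.
#' @export
metaTrain <- function(model, samples, entities, episodes, N = 5L, K = 10L,
                      Q = 10L, seed = 1L, cells = NULL, zeroShot = FALSE,
                      bnMode = "batch", optimizer = c("sgd", "adam")) {
  optimizer <- match.arg(optimizer)
  episodes <- assertCount(episodes, "episodes", min = 0L)
  entities <- asEntityCache(entities)
  base <- deriveSeed(seed, "episode")
  log <- numeric(episodes)
  nE <- length(model@thetaE)
  opt <- if (optimizer == "adam") adamInit(c(model@thetaE, model@thetaP))
  for (ep in seq_len(episodes)) {
    episode <- buildEpisode(samples, N = N, K = K, Q = Q,
                            seed = (base + ep) %% 2147483647L, cells = cells)
    if (optimizer == "sgd") {
      upd <- outerUpdate(model, episode, entities, zeroShot = zeroShot,
                         bnMode = bnMode)
      model <- upd$model
      log[ep] <- upd$queryLoss
    } else {
      eg <- episodeGradient(model, episode, entities, zeroShot = zeroShot,
                            bnMode = bnMode)
      model@bnStats <- eg$bnStats
      st <- adamStep(c(model@thetaE, model@thetaP),
                     c(eg$thetaE, eg$thetaP), opt, model@hyper$beta)
      opt <- st$state
      model@thetaE <- st$params[seq_len(nE)]
      model@thetaP <- st$params[(nE + 1L):length(st$params)]
      log[ep] <- eg$queryLoss
    }
  }
  model@flags$stage <- "meta-trained"
  model@flags$metaLog <- log
  model
}

#' Few-shot fine-tuning on a new cell line
#'
#' Adapts the prediction head on the task's support set (the inner-tier
#' update rule, embedding parameters frozen unless ablation `no_so`), then
#' predicts the query samples with the adapted parameters. The input model is
#' never mutated. Under ablation `no_ft` no adaptation happens and the
#' prediction equals [zeroShotPredict()].
#'
#' @param model a trained [SynergyModel-class].
#' @param task a [FewShotTask-class].
#' @param entities entity cache or [SyntheticWorld-class].
#' @param alpha,steps optional overrides of the adaptation hyperparameters.
#' @return list with `predictions` (adapted query predictions),
#'   `unadapted` (query predictions before adaptation), `thetaP` (adapted
#'   head), `supportLoss`, and `queryMse`/`unadaptedMse` when the task
#'   carries query scores.
#' @export
fineTune <- function(model, task, entities, alpha = NULL, steps = NULL) {
  entities <- asEntityCache(entities)
  query <- querySet(task)
  unadapted <- predictScores(model, query, entities)
  if (model@flags$ablation == "no_ft" || nrow(supportSet(task)) == 0L) {
    if (model@flags$ablation != "no_ft" && nrow(supportSet(task)) == 0L)
      stop("fine-tuning requires support samples; ",
           "use zeroShotPredict for zero-shot evaluation")
    return(list(predictions = unadapted, unadapted = unadapted,
                thetaP = model@thetaP, supportLoss = NA_real_,
                queryMse = mseLoss(query$score, unadapted),
                unadaptedMse = mseLoss(query$score, unadapted)))
  }
  ad <- innerAdapt(model, task, entities, alpha = alpha, steps = steps,
                   bnMode = "eval")
  adapted <- model
  adapted@thetaP <- ad$thetaP
  adapted@thetaE <- ad$thetaE
  predictions <- predictScores(adapted, query, entities)
  list(predictions = predictions, unadapted = unadapted, thetaP = ad$thetaP,
       supportLoss = ad$supportLoss,
       queryMse = if (!is.null(query$score))
         mseLoss(query$score, predictions) else NA_real_,
       unadaptedMse = if (!is.null(query$score))
         mseLoss(query$score, unadapted) else NA_real_)
}

#' Zero-shot prediction
#'
#' Pure forward pass with the shared initialization; no adaptation, no
#' parameter change. Equals the composition of the encoders, the integration
#' layer and the prediction head.
#'
#' @param model a [SynergyModel-class].
#' @param x a [FewShotTask-class] (its query set is predicted) or a synergy
#'   sample data.frame.
#' @param entities entity cache or [SyntheticWorld-class].
#' @return numeric vector of predicted scores.
#' @export
zeroShotPredict <- function(model, x, entities) {
  samples <- if (is(x, "FewShotTask")) querySet(x) else x
  predictScores(model, samples, entities)
}
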