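#' Benchmark training/evaluation configuration
#'
#' Bundles the knobs of the desk-scale benchmark harness: a reduced-width
#' model, short pretraining, 300 meta-training episodes of 5 tasks each, and
#' single-step head adaptation at the default inner learning rate.
#'
#' @param model a [modelConfig()].
#' @param pretrainEpochs,episodes stage lengths.
#' @param N,K,Q episode geometry.
#' @param alpha,beta,dropout,lr optimization hyperparameters (inner lr,
#'   outer lr, dropout rate, pretraining lr).
#' @param metaOptimizer outer-tier optimizer ("adam" here; the plain
#'   gradient-descent rule remains the model default).
#' @param evalTasks,evalRepeats evaluation protocol sizes.
#' @param testFraction meta-test fraction of the cell-line split.
#' @param seed root seed.
#' @return config list.
#' @export
benchmarkConfig <- function(model = modelConfig(gcnDims = c(32L, 32L, 32L),
                                                convChannels = c(4L, 8L),
                                                fdHidden = 64L, fdOut = 32L,
                                                fcOut = 32L,
                                                headHidden = 64L),
                            pretrainEpochs = 30L, episodes = 300L, N = 5L,
                            K = 10L, Q = 10L, alpha = 0.01, beta = 1e-3,
                            dropout = 0.1, lr = 1e-3,
                            metaOptimizer = "adam", evalTasks = 30L,
                            evalRepeats = 20L, testFraction = 0.2,
                            seed = 1L) {
  list(model = model, pretrainEpochs = as.integer(pretrainEpochs),
       episodes = as.integer(episodes), N = as.integer(N), K = as.integer(K),
       Q = as.integer(Q), alpha = alpha, beta = beta, dropout = dropout,
       lr = lr, metaOptimizer = metaOptimizer,
       evalTasks = as.integer(evalTasks),
       evalRepeats = as.integer(evalRepeats), testFraction = testFraction,
       seed = as.integer(seed))
}

## Draw one K/Q few-shot task from a single cell line's samples.
sampleTask <- function(samples, cell, K, Q, seed) {
  rows <- samples[samples$cellLine == cell, , drop = FALSE]
  rows <- rows[!duplicated(pairKey(rows$drugA, rows$drugB)), , drop = FALSE]
  if (nrow(rows) < K + Q)
    stop("cell line ", cell, " has only ", nrow(rows),
         " distinct drug pairs, need ", K + Q)
  withSeed(seed, {
    pick <- rows[sample.int(nrow(rows), K + Q), , drop = FALSE]
  })
  FewShotTask(cell, support = pick[seq_len(K), , drop = FALSE],
              query = pick[(K + 1L):(K + Q), , drop = FALSE])
}

#' Repeated few-shot (or zero-shot) evaluation on meta-test cell lines
#'
#' Per repeat, samples `nTasks` K-shot tasks from the meta-test cell lines,
#' fine-tunes on each task's support set (or predicts without adaptation in
#' zero-shot mode), pools the query predictions, and computes the metrics.
#' Reported as per-repeat rows plus mean and SD.
#'
#' @param model a trained [SynergyModel-class].
#' @param samples the full synergy sample table.
#' @param entities entity cache or [SyntheticWorld-class].
#' @param split a [SplitSpec-class]; tasks come from its meta-test side.
#' @param K,Q support/query sizes.
#' @param nTasks tasks per repeat.
#' @param repeats number of repeats.
#' @param seed root seed; repeat r derives its own task seeds.
#' @param mode "fewshot" (fine-tune per task) or "zeroshot" (no adaptation).
#' @param threshold binarization threshold for AUC/AUPR.
#' @return list of class "metricsReport": `perRepeat` (data.frame), `mean`,
#'   `sd`, and the protocol sizes.
#' @export
evaluateFewShot <- function(model, samples, entities, split, K = 10L,
                            Q = 10L, nTasks = 30L, repeats = 20L, seed = 1L,
                            mode = c("fewshot", "zeroshot"), threshold = 0) {
  mode <- match.arg(mode)
  entities <- asEntityCache(entities)
  testCells <- metaTestCells(split)
  base <- deriveSeed(seed, "eval")
  rows <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    cells <- withSeed((base + 7919L * r) %% 2147483647L,
                      sample(testCells, nTasks, replace = TRUE))
    yTrue <- numeric(0); yPred <- numeric(0)
    for (t in seq_len(nTasks)) {
      task <- sampleTask(samples, cells[t], K, Q,
                         seed = (base + 7919L * r + t) %% 2147483647L)
      pred <- if (mode == "zeroshot") zeroShotPredict(model, task, entities)
      else fineTune(model, task, entities)$predictions
      yTrue <- c(yTrue, querySet(task)$score)
      yPred <- c(yPred, pred)
    }
    m <- computeMetrics(yTrue, yPred, threshold = threshold)
    rows[[r]] <- data.frame(repeatIndex = r, mse = m$mse, scc = m$scc,
                            r2 = m$r2, auc = m$auc, aupr = m$aupr)
  }
  perRepeat <- do.call(rbind, rows)
  metricCols <- c("mse", "scc", "r2", "auc", "aupr")
  structure(list(perRepeat = perRepeat,
                 mean = colMeans(perRepeat[metricCols], na.rm = TRUE),
                 sd = vapply(perRepeat[metricCols], stats::sd, numeric(1)),
                 nTasks = nTasks, repeats = repeats, K = K, Q = Q,
                 mode = mode),
            class = "metricsReport")
}

#' @export
print.metricsReport <- function(x, ...) {
  cat("Few-shot evaluation (", x$mode, "): ", x$repeats, " repeats x ",
      x$nTasks, " tasks (K = ", x$K, ", Q = ", x$Q, ")\n", sep = "")
  for (m in names(x$mean))
    cat(sprintf("  %-5s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  invisible(x)
}

#' Per-cell-line error analysis and dispersion-error correlation
#'
#' For every meta-test cell line, samples `nTasksPerLine` K-shot tasks,
#' fine-tunes on each, and records the mean query MSE; then correlates the
#' per-line MSE with the per-line synergy-score dispersion (score range by
#' default, SD optionally). Greater within-line score variability is expected
#' to make tasks harder, so the correlation is positive when the model is
#' otherwise well calibrated.
#'
#' @inheritParams evaluateFewShot
#' @param nTasksPerLine tasks per cell line.
#' @param dispersion "range" (max - min) or "sd".
#' @return list with `table` (one row per included cell line: cellLine, mse,
#'   dispersion, nTasks), `correlation` (Pearson r), `pValue`, and
#'   `excluded` (lines with too few samples).
#' @export
perCellLineAnalysis <- function(model, samples, entities, split, K = 10L,
                                Q = 10L, nTasksPerLine = 30L, seed = 1L,
                                dispersion = c("range", "sd")) {
  dispersion <- match.arg(dispersion)
  entities <- asEntityCache(entities)
  base <- deriveSeed(seed, "task")
  rows <- list(); excluded <- character(0)
  for (cell in metaTestCells(split)) {
    pool <- samples[samples$cellLine == cell, , drop = FALSE]
    if (nrow(pool) < K + Q) {
      excluded <- c(excluded, cell)
      next
    }
    mses <- vapply(seq_len(nTasksPerLine), function(t) {
      task <- sampleTask(samples, cell, K, Q,
                         seed = (base + 104729L * length(rows) + t) %%
                           2147483647L)
      fineTune(model, task, entities)$queryMse
    }, numeric(1))
    disp <- if (dispersion == "range") diff(range(pool$score))
    else stats::sd(pool$score)
    rows[[cell]] <- data.frame(cellLine = cell, mse = mean(mses),
                               dispersion = disp, nTasks = nTasksPerLine)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (is.null(tab) || nrow(tab) < 3L || stats::sd(tab$dispersion) == 0 ||
      stats::sd(tab$mse) == 0) {
    corr <- NA_real_; p <- NA_real_
  } else {
    ct <- stats::cor.test(tab$mse, tab$dispersion, method = "pearson")
    corr <- unname(ct$estimate); p <- ct$p.value
  }
  list(table = tab, correlation = corr, pValue = p, excluded = excluded,
       dispersion = dispersion)
}

#' Train one model variant on a synthetic world
#'
#' Runs the stage sequence appropriate to the variant: the full model
#' pretrains then meta-trains; `no_ml` trains by supervised learning only;
#' `no_ft` trains like the full model (adaptation is dropped at test time);
#' `no_so` meta-trains with full-parameter inner adaptation; `no_pt`
#' meta-trains from random initialization.
#'
#' @param world a [SyntheticWorld-class].
#' @param split a [SplitSpec-class] over the world's cell lines.
#' @param cfg a [benchmarkConfig()].
#' @param variant "none" (the full model) or one of "no_ml", "no_ft",
#'   "no_so", "no_pt".
#' @return the trained [SynergyModel-class].
#' @export
trainVariant <- function(world, split, cfg = benchmarkConfig(),
                         variant = "none") {
  entities <- buildEntityCache(world@drugs, world@profiles)
  trainSamples <- world@samples[world@samples$cellLine %in%
                                  metaTrainCells(split), , drop = FALSE]
  model <- newSynergyModel(cfg$model, seed = cfg$seed, alpha = cfg$alpha,
                           beta = cfg$beta, dropout = cfg$dropout,
                           ablation = variant)
  if (variant == "no_ml") {
    # standard supervised training, matched to the full model's combined
    # stage budget
    model <- pretrain(model, trainSamples, entities,
                      epochs = 2L * cfg$pretrainEpochs, seed = cfg$seed,
                      lr = cfg$lr)
    return(model)
  }
  if (variant != "no_pt")
    model <- pretrain(model, trainSamples, entities,
                      epochs = cfg$pretrainEpochs, seed = cfg$seed,
                      lr = cfg$lr)
  metaTrain(model, trainSamples, entities, episodes = cfg$episodes,
            N = cfg$N, K = cfg$K, Q = cfg$Q, seed = cfg$seed,
            optimizer = cfg$metaOptimizer)
}

#' Ablation study on a synthetic world
#'
#' Trains and evaluates the full model and the requested variants under
#' identical seeds, splits and evaluation task samples, and reports their
#' few-shot metrics side by side.
#'
#' @param world a [SyntheticWorld-class].
#' @param variants subset of c("no_ml", "no_ft", "no_so", "no_pt").
#' @param cfg a [benchmarkConfig()].
#' @param split optional [SplitSpec-class]; defaults to a random split at
#'   `cfg$testFraction`.
#' @return list with `summary` (data.frame of mean metrics per variant) and
#'   `reports` (named list of full metricsReport objects).
#' @export
runAblation <- function(world, variants = c("no_ml", "no_ft", "no_so",
                                            "no_pt"),
                        cfg = benchmarkConfig(), split = NULL) {
  bad <- setdiff(variants, c("no_ml", "no_ft", "no_so", "no_pt"))
  if (length(bad)) stop("unknown ablation variant(s): ",
                        paste(bad, collapse = ", "))
  if (is.null(split))
    split <- splitRandom(names(world@profiles),
                         fraction = 1 - cfg$testFraction, seed = cfg$seed)
  entities <- buildEntityCache(world@drugs, world@profiles)

  full <- trainVariant(world, split, cfg, "none")
  reports <- list(full = evaluateFewShot(full, world@samples, entities,
                                         split, K = cfg$K, Q = cfg$Q,
                                         nTasks = cfg$evalTasks,
                                         repeats = cfg$evalRepeats,
                                         seed = cfg$seed))
  for (v in variants) {
    m <- if (v == "no_ft") {
      ft <- full  # same training; adaptation is dropped at test time
      ft@flags$ablation <- "no_ft"
      ft
    } else trainVariant(world, split, cfg, v)
    reports[[v]] <- evaluateFewShot(m, world@samples, entities, split,
                                    K = cfg$K, Q = cfg$Q,
                                    nTasks = cfg$evalTasks,
                                    repeats = cfg$evalRepeats,
                                    seed = cfg$seed)
  }
  summary <- do.call(rbind, lapply(names(reports), function(nm)
    data.frame(variant = nm, mse = reports[[nm]]$mean[["mse"]],
               scc = reports[[nm]]$mean[["scc"]],
               r2 = reports[[nm]]$mean[["r2"]])))
  list(summary = summary, reports = reports, split = split)
}
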