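#' Synthetic benchmark configuration
#'
#' Parameters of the generated world: a library of small-molecule drugs, a
#' panel of cell lines whose latent factors have controllable pairwise
#' correlation, and synergy scores composed of a cross-cell-line shared
#' component, a cell-line-specific component, and observation noise.
#'
#' @param nDrugs drug library size (>= 2).
#' @param nCellLines number of cell lines.
#' @param samplesPerCellLine labeled drug pairs per cell line (at most
#'   choose(nDrugs, 2)).
#' @param sharedWeight in [0, 1]; fraction of signal variance carried by the
#'   shared (cell-line-independent) synergy component.
#' @param cellLineSimilarity in [0, 1]; target pairwise correlation of the
#'   cell-line latent factors.
#' @param noiseSd standard deviation of observation noise, on the
#'   pre-standardization score scale.
#' @param dispersionRange optional c(lo, hi) bounds of per-cell-line score
#'   variance; NULL leaves each line's natural dispersion.
#' @param expressionNoiseSd per-gene readout noise of the expression
#'   profiles.
#' @param latentDim dimension of the cell-line latent factors.
#' @param seed root seed; every stochastic draw flows from it via named
#'   substreams.
#' @return config list.
#' @export
syntheticWorldConfig <- function(nDrugs = 40L, nCellLines = 15L,
                                 samplesPerCellLine = 60L,
                                 sharedWeight = 0.8,
                                 cellLineSimilarity = 0.5, noiseSd = 0.1,
                                 dispersionRange = NULL,
                                 expressionNoiseSd = 0.1, latentDim = 32L,
                                 seed = 1L) {
  nDrugs <- assertCount(nDrugs, "nDrugs", min = 2L)
  nCellLines <- assertCount(nCellLines, "nCellLines", min = 2L)
  samplesPerCellLine <- assertCount(samplesPerCellLine, "samplesPerCellLine")
  if (samplesPerCellLine > choose(nDrugs, 2))
    stop("samplesPerCellLine exceeds the number of distinct drug pairs (",
         choose(nDrugs, 2), ")")
  if (sharedWeight < 0 || sharedWeight > 1)
    stop("'sharedWeight' must be in [0, 1]")
  if (cellLineSimilarity < 0 || cellLineSimilarity > 1)
    stop("'cellLineSimilarity' must be in [0, 1]")
  noiseSd <- assertNumber(noiseSd, "noiseSd", 0)
  if (!is.null(dispersionRange)) {
    if (length(dispersionRange) != 2L || any(dispersionRange <= 0) ||
        dispersionRange[1L] > dispersionRange[2L])
      stop("'dispersionRange' must be increasing positive bounds")
  }
  list(nDrugs = nDrugs, nCellLines = nCellLines,
       samplesPerCellLine = samplesPerCellLine, sharedWeight = sharedWeight,
       cellLineSimilarity = cellLineSimilarity, noiseSd = noiseSd,
       dispersionRange = dispersionRange,
       expressionNoiseSd = assertNumber(expressionNoiseSd,
                                        "expressionNoiseSd", 0),
       latentDim = assertCount(latentDim, "latentDim", 2L),
       seed = as.integer(seed))
}

## Drug-like scaffolds with one open substitution site, decorated with small
## substituents. Every emitted SMILES is validated by the parser; candidates
## that fail round-trip are skipped.
syntheticScaffolds <- c(
  "c1ccc(%s)cc1", "c1ccc2cc(%s)ccc2c1", "c1cc(%s)ncc1", "c1cc(%s)sc1",
  "c1cc(%s)oc1", "C1CCN(%s)CC1", "C1CCC(%s)CC1", "c1ccc(O%s)cc1",
  "c1ccc(N%s)cc1", "O=C(%s)c1ccccc1", "O=C(N%s)c1ccccc1",
  "c1ccc2[nH]cc(%s)c2c1")

syntheticSubstituents <- c(
  "C", "CC", "CCC", "C(C)C", "CO", "CCO", "CN", "CCN", "F", "Cl", "Br",
  "C(F)(F)F")

syntheticBaseMolecules <- c(
  "CCO", "CC(=O)O", "c1ccccc1", "c1ccncc1", "C1CCNCC1", "CC(C)Cc1ccccc1",
  "CC(=O)Nc1ccccc1", "OCC1OC(O)C(O)C(O)C1O", "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  "CC(=O)Oc1ccccc1C(=O)O", "NCCc1ccc(O)c(O)c1", "CN1CCC(c2ccccc2)CC1")

#' Generate the synthetic drug library
#'
#' Draws a seeded permutation of a combinatorial pool of scaffold x
#' substituent SMILES (plus a set of complete drug-like molecules), parses
#' each candidate, and keeps the first `nDrugs` that yield valid heavy-atom
#' graphs. Deterministic under the config seed.
#'
#' @param cfg a [syntheticWorldConfig()].
#' @return named list of [MolecularGraph-class] with the source SMILES in
#'   attribute "smiles".
#' @export
generateDrugLibrary <- function(cfg) {
  pool <- c(syntheticBaseMolecules,
            as.vector(outer(syntheticScaffolds, syntheticSubstituents,
                            function(sc, su) sprintf(sc, su))))
  if (cfg$nDrugs > length(pool))
    stop("drug library pool supports at most ", length(pool), " drugs")
  ord <- withSeed(deriveSeed(cfg$seed, "drugs"), sample.int(length(pool)))
  graphs <- list(); smiles <- character()
  for (i in ord) {
    id <- sprintf("DRUG%03d", length(graphs) + 1L)
    g <- smilesToGraph(pool[i], id)
    if (is.null(g)) next
    graphs[[id]] <- g
    smiles[id] <- pool[i]
    if (length(graphs) == cfg$nDrugs) break
  }
  if (length(graphs) < cfg$nDrugs)
    stop("could not assemble ", cfg$nDrugs, " valid drugs")
  attr(graphs, "smiles") <- smiles
  graphs
}

#' Generate synthetic cell-line expression profiles
#'
#' Each cell line receives a latent factor vector
#' \eqn{f_c = \sqrt{s}\, g_0 + \sqrt{1-s}\, g_c} (shared draw \eqn{g_0},
#' line-specific \eqn{g_c}), so the expected pairwise factor correlation is
#' the configured similarity `s`. The 900 marker-gene values are noisy linear
#' readouts of the factors, arranged on the 30 x 30 grid.
#'
#' @param cfg a [syntheticWorldConfig()].
#' @return list with `profiles` (named list of [ExpressionGrid-class]),
#'   `factors` (cell lines x latentDim matrix), and `geneOrder`.
#' @export
generateCellProfiles <- function(cfg) {
  genes <- sprintf("SYNGENE%04d", 1:900)
  s <- cfg$cellLineSimilarity
  p <- cfg$latentDim
  withSeed(deriveSeed(cfg$seed, "cells"), {
    g0 <- stats::rnorm(p)
    factors <- t(vapply(seq_len(cfg$nCellLines), function(i)
      sqrt(s) * g0 + sqrt(1 - s) * stats::rnorm(p), numeric(p)))
    loading <- matrix(stats::rnorm(900L * p, sd = 1 / sqrt(p)), 900L, p)
    profiles <- lapply(seq_len(cfg$nCellLines), function(i) {
      vals <- drop(loading %*% factors[i, ]) +
        stats::rnorm(900L, sd = cfg$expressionNoiseSd)
      ExpressionGrid(sprintf("CELL%03d", i), vals, genes)
    })
  })
  names(profiles) <- vapply(profiles, cellLineId, character(1))
  rownames(factors) <- names(profiles)
  list(profiles = profiles, factors = factors, geneOrder = genes)
}

## Graph-level descriptor feeding the ground-truth synergy function: mean
## atom features plus normalized size terms, so the synergy landscape is a
## real function of molecular structure the encoders can learn.
drugDescriptor <- function(graph) {
  c(colMeans(graph@nodeFeatures), nrow(graph@nodeFeatures) / 20,
    nrow(graph@edges) / 20)
}

#' Generate synthetic synergy samples and the ground-truth function
#'
#' Scores follow
#' \eqn{y = w\, g_{shared}(\phi_A, \phi_B) + (1-w)\, g_{cell}(\phi_A,
#' \phi_B; f_c) + \varepsilon}: the drug representations \eqn{\phi} are fixed
#' random projections of graph descriptors, both g's are smooth symmetric
#' functions (standardized so `sharedWeight` is the shared variance
#' fraction), the cell-specific g is parameterized by the line's latent
#' factors, per-line variance is optionally rescaled into
#' `dispersionRange`, and the final scores are standardized to zero mean and
#' unit variance over the world.
#'
#' @param cfg a [syntheticWorldConfig()].
#' @param drugs drug library from [generateDrugLibrary()].
#' @param factors latent factor matrix from [generateCellProfiles()].
#' @return list with `samples` (synergy data.frame), `truth`
#'   (function(drugA, drugB, cellLine, standardized = TRUE, raw = FALSE)
#'   returning noiseless scores), and `meta` (generator internals).
#' @export
generateSynergy <- function(cfg, drugs, factors) {
  drugIds <- names(drugs)
  q <- 8L
  desc <- t(vapply(drugs, drugDescriptor, numeric(80L)))
  cellIds <- rownames(factors)

  withSeed(deriveSeed(cfg$seed, "synergy"), {
    proj <- matrix(stats::rnorm(80L * q, sd = 1 / sqrt(80)), 80L, q)
    phi <- tanh(desc %*% proj)  # drugs x q
    wS1 <- stats::rnorm(q); wS2 <- stats::rnorm(q); wS3 <- stats::rnorm(q)
    cS <- stats::rnorm(1)
    B1 <- matrix(stats::rnorm(cfg$latentDim * q, sd = 1 / sqrt(cfg$latentDim)),
                 q, cfg$latentDim, byrow = FALSE)
    dim(B1) <- c(q, cfg$latentDim)
    B2 <- matrix(stats::rnorm(q * cfg$latentDim, sd = 1 / sqrt(cfg$latentDim)),
                 q, cfg$latentDim)

    pairs <- t(utils::combn(length(drugIds), 2L))
    U <- phi[pairs[, 1L], , drop = FALSE] + phi[pairs[, 2L], , drop = FALSE]
    V <- phi[pairs[, 1L], , drop = FALSE] * phi[pairs[, 2L], , drop = FALSE]
    gShared <- drop(U %*% wS1) + drop(V %*% wS2) + cS * tanh(drop(U %*% wS3))
    sharedMu <- mean(gShared)
    sharedSd <- max(stats::sd(gShared), 1e-12)
    gSharedStd <- (gShared - sharedMu) / sharedSd

    # cell-specific component, standardized over all (line, pair) combos
    cellRaw <- vapply(seq_len(nrow(factors)), function(j) {
      w1 <- drop(B1 %*% factors[j, ]); w2 <- drop(B2 %*% factors[j, ])
      drop(U %*% w1) + drop(V %*% w2)
    }, numeric(nrow(pairs)))
    cellMu <- mean(cellRaw)
    cellSd <- max(stats::sd(as.vector(cellRaw)), 1e-12)
    cellStd <- (cellRaw - cellMu) / cellSd

    w <- cfg$sharedWeight
    rawScores <- w * gSharedStd + (1 - w) * cellStd  # pairs x lines

    # optional per-line variance control
    lineMean <- colMeans(rawScores)
    lineScale <- rep(1, ncol(rawScores))
    if (!is.null(cfg$dispersionRange)) {
      tau <- seq(cfg$dispersionRange[1L], cfg$dispersionRange[2L],
                 length.out = ncol(rawScores))
      tau <- tau[sample.int(length(tau))]
      v <- apply(rawScores, 2L, stats::var) + cfg$noiseSd^2
      lineScale <- sqrt(tau / pmax(v, 1e-12))
    }
    # sample labeled pairs per line; the per-line affine transform maps the
    # whole observation distribution (signal + noise) into the target
    # variance, so dispersionRange controls the variance of the scores a
    # line actually shows
    rows <- do.call(rbind, lapply(seq_along(cellIds), function(j) {
      pick <- sample.int(nrow(pairs), cfg$samplesPerCellLine)
      noisy <- rawScores[pick, j] +
        stats::rnorm(length(pick), sd = cfg$noiseSd)
      data.frame(drugA = drugIds[pairs[pick, 1L]],
                 drugB = drugIds[pairs[pick, 2L]],
                 cellLine = cellIds[j],
                 score = lineMean[j] + lineScale[j] * (noisy - lineMean[j]),
                 stringsAsFactors = FALSE)
    }))
  })
  globalMu <- mean(rows$score)
  globalSd <- stats::sd(rows$score)
  if (!is.finite(globalSd) || globalSd < 1e-12) globalSd <- 1
  rows$score <- (rows$score - globalMu) / globalSd
  rownames(rows) <- NULL

  meta <- list(phi = phi, wS1 = wS1, wS2 = wS2, wS3 = wS3, cS = cS,
               sharedMu = sharedMu, sharedSd = sharedSd, cellMu = cellMu,
               cellSd = cellSd, B1 = B1, B2 = B2, factors = factors,
               lineMean = lineMean, lineScale = lineScale,
               cellIds = cellIds, globalMu = globalMu, globalSd = globalSd,
               sharedWeight = cfg$sharedWeight)

  truth <- function(drugA, drugB, cellLine, standardized = TRUE,
                    raw = FALSE) {
    iA <- match(drugA, rownames(meta$phi))
    iB <- match(drugB, rownames(meta$phi))
    j <- match(cellLine, meta$cellIds)
    if (any(is.na(iA)) || any(is.na(iB)) || any(is.na(j)))
      stop("unknown drug or cell line")
    u <- meta$phi[iA, , drop = FALSE] + meta$phi[iB, , drop = FALSE]
    v <- meta$phi[iA, , drop = FALSE] * meta$phi[iB, , drop = FALSE]
    gs <- (drop(u %*% meta$wS1) + drop(v %*% meta$wS2) +
           meta$cS * tanh(drop(u %*% meta$wS3)) - meta$sharedMu) /
      meta$sharedSd
    w1 <- t(meta$B1 %*% t(meta$factors[j, , drop = FALSE]))
    w2 <- t(meta$B2 %*% t(meta$factors[j, , drop = FALSE]))
    gc <- (rowSums(u * w1) + rowSums(v * w2) - meta$cellMu) / meta$cellSd
    y <- unname(meta$sharedWeight * gs + (1 - meta$sharedWeight) * gc)
    if (raw) return(y)
    y <- unname(meta$lineMean[j]) + unname(meta$lineScale[j]) *
      (y - unname(meta$lineMean[j]))
    if (standardized) (y - meta$globalMu) / meta$globalSd else y
  }
  rownames(meta$phi) <- drugIds

  list(samples = rows, truth = truth, meta = meta)
}

#' Generate a complete synthetic benchmark world
#'
#' Runs [generateDrugLibrary()], [generateCellProfiles()] and
#' [generateSynergy()] under one root seed.
#'
#' @param cfg a [syntheticWorldConfig()].
#' @return a [SyntheticWorld-class].
#' @examples
#' world <- generateWorld(syntheticWorldConfig(nDrugs = 8, nCellLines = 4,
#'                                             samplesPerCellLine = 10))
#' world
#' @export
generateWorld <- function(cfg = syntheticWorldConfig()) {
  drugs <- generateDrugLibrary(cfg)
  prof <- generateCellProfiles(cfg)
  syn <- generateSynergy(cfg, drugs, prof$factors)
  smiles <- attr(drugs, "smiles")
  attr(drugs, "smiles") <- NULL
  new("SyntheticWorld", config = cfg, drugs = drugs,
      profiles = prof$profiles, factors = prof$factors,
      samples = syn$samples, truth = syn$truth,
      meta = c(syn$meta, list(smiles = smiles, geneOrder = prof$geneOrder)))
}

#' Write a synthetic world to disk in the real-data input formats
#'
#' Emits `drugs.smi` (drug_id, smiles), `expression.tsv` (cell lines x
#' genes, header row), `markers.txt` (900 gene ids, one per line) and
#' `synergy.tsv` (drugA, drugB, cellLine, score) -- exactly the formats the
#' data-loading path consumes.
#'
#' @param world a [SyntheticWorld-class].
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
writeWorld <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  smi <- file.path(dir, "drugs.smi")
  writeLines(paste(names(world@meta$smiles), world@meta$smiles, sep = "\t"),
             smi)
  expr <- t(vapply(world@profiles, function(p) as.vector(t(gridValues(p))),
                   numeric(900L)))
  colnames(expr) <- world@meta$geneOrder
  exprPath <- file.path(dir, "expression.tsv")
  utils::write.table(data.frame(cell_line = rownames(expr), expr,
                                check.names = FALSE),
                     exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  markers <- file.path(dir, "markers.txt")
  writeLines(world@meta$geneOrder, markers)
  syn <- file.path(dir, "synergy.tsv")
  utils::write.table(world@samples, syn, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(drugs = smi, expression = exprPath, markers = markers,
              synergy = syn))
}
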