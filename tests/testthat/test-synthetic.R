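smallWorldCfg <- function(...) {
  args <- list(...)
  defaults <- list(nDrugs = 8L, nCellLines = 6L, samplesPerCellLine = 12L,
                   sharedWeight = 0.7, cellLineSimilarity = 0.5,
                   noiseSd = 0.05, seed = 33L)
  defaults[names(args)] <- args
  do.call(syntheticWorldConfig, defaults)
}

test_that("drug library generation is valid, deterministic, and round-trips", {
  cfg <- smallWorldCfg(nDrugs = 6L)
  lib <- generateDrugLibrary(cfg)
  expect_length(lib, 6)
  for (g in lib) {
    expect_s4_class(g, "MolecularGraph")
    expect_equal(ncol(nodeFeatures(g)), 78)
  }
  lib2 <- generateDrugLibrary(cfg)
  expect_identical(lapply(lib, nodeFeatures), lapply(lib2, nodeFeatures))

  # emitted SMILES parse round-trip to the same graphs
  smiles <- attr(lib, "smiles")
  tf <- tempfile(fileext = ".smi")
  writeLines(paste(names(smiles), smiles, sep = "\t"), tf)
  re <- parseStructures(tf)
  expect_identical(unname(lapply(re, nodeFeatures)),
                   unname(lapply(lib, nodeFeatures)))
})

test_that("cell profiles hit the target factor correlation and grid invariants", {
  prof <- generateCellProfiles(smallWorldCfg(nCellLines = 20L,
                                             cellLineSimilarity = 0.6))
  for (p in prof$profiles) expect_true(validObject(p))
  C <- cor(t(prof$factors))
  meanCor <- mean(C[upper.tri(C)])
  expect_lt(abs(meanCor - 0.6), 0.1)

  # perfect similarity and no readout noise collapse all grids
  prof1 <- generateCellProfiles(smallWorldCfg(cellLineSimilarity = 1,
                                              expressionNoiseSd = 0))
  g1 <- gridValues(prof1$profiles[[1]])
  for (p in prof1$profiles) expect_equal(gridValues(p), g1)
})

test_that("grid layout maps gene k to row-major position", {
  prof <- generateCellProfiles(smallWorldCfg())
  p <- prof$profiles[[1]]
  vals <- as.vector(t(gridValues(p)))   # row-major read-back
  eg <- ExpressionGrid(cellLineId(p), vals, geneOrder(p))
  expect_equal(gridValues(eg), gridValues(p))
})

test_that("synergy scores are symmetric, shared-limit consistent, standardized", {
  cfg <- smallWorldCfg(sharedWeight = 1, noiseSd = 0)
  world <- generateWorld(cfg)
  ids <- names(world@drugs)
  cells <- names(world@profiles)
  # same drug pair scores identically in every cell line at w = 1, noise 0
  y <- world@truth(rep(ids[1], length(cells)), rep(ids[2], length(cells)),
                   cells)
  expect_equal(max(y) - min(y), 0, tolerance = 1e-12)
  # symmetry in the drug pair
  expect_equal(world@truth(ids[1], ids[3], cells[1]),
               world@truth(ids[3], ids[1], cells[1]), tolerance = 1e-12)
  # world-level standardization
  w2 <- generateWorld(smallWorldCfg())
  expect_equal(mean(w2@samples$score), 0, tolerance = 1e-10)
  expect_equal(sd(w2@samples$score), 1, tolerance = 1e-10)
  # sampled scores equal truth plus noise at noise 0
  expect_equal(world@samples$score,
               world@truth(world@samples$drugA, world@samples$drugB,
                           world@samples$cellLine),
               tolerance = 1e-10)
})

test_that("per-cell-line variance lands inside the dispersion range", {
  cfg <- syntheticWorldConfig(nDrugs = 35L, nCellLines = 6L,
                              samplesPerCellLine = 500L, sharedWeight = 0.6,
                              noiseSd = 0, dispersionRange = c(0.5, 2),
                              seed = 44L)
  world <- generateWorld(cfg)
  # pre-standardization scale: undo the global standardization
  sdG <- world@meta$globalSd
  byLine <- split(world@samples$score * sdG, world@samples$cellLine)
  v <- vapply(byLine, var, numeric(1))
  expect_true(all(v > 0.5 * 0.85 & v < 2 * 1.15))
  # and the assigned targets span the range
  expect_gt(max(v) / min(v), 2)
})

test_that("duplicate drug pairs within a cell line are impossible", {
  world <- generateWorld(smallWorldCfg())
  key <- paste(world@samples$cellLine,
               pairKeyTest(world@samples$drugA, world@samples$drugB))
  expect_equal(anyDuplicated(key), 0)
})

test_that("world writing emits the four consumable artifacts", {
  world <- generateWorld(smallWorldCfg(nDrugs = 4L, nCellLines = 3L,
                                       samplesPerCellLine = 5L))
  dir <- tempfile()
  paths <- writeWorld(world, dir)
  expect_true(all(file.exists(paths)))
  expect_length(readMarkerList(paths["markers"]), 900)
  syn <- readSynergyTable(paths["synergy"])
  expect_equal(nrow(syn), nrow(world@samples))
  expr <- readExpressionTable(paths["expression"])
  expect_equal(dim(expr), c(3L, 900L))
  relib <- parseStructures(paths["drugs"], format = "smiles")
  expect_length(relib, 4)
})
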