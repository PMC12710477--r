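#' MolecularGraph: an atom-featurized undirected molecular graph
#'
#' One drug, represented as the heavy-atom graph RDKit-style encodings use:
#' every atom carries a 78-dimensional descriptor vector (one-hot blocks for
#' element symbol, heavy-neighbor count, implicit valence and bonded-hydrogen
#' count, plus an aromaticity bit) and every chemical bond is one undirected
#' edge with a nonnegative weight (1 for all bonds). Each undirected edge is
#' stored once in canonical (low index, high index) order; the self
#' contribution of the graph convolution is added inside the layer, never
#' stored as a self-loop.
#'
#' @slot drugId character(1) drug identifier.
#' @slot nodeFeatures numeric matrix, atoms x 78.
#' @slot edges integer matrix with two columns, one row per undirected bond.
#' @slot edgeWeights numeric vector, one nonnegative weight per edge.
#'
#' @seealso [parseStructures()], [featurizeAtom()], [encodeDrug()]
#' @export
setClass("MolecularGraph",
  representation(drugId = "character", nodeFeatures = "matrix",
                 edges = "matrix", edgeWeights = "numeric"))

setValidity("MolecularGraph", function(object) {
  msg <- character()
  if (length(object@drugId) != 1L || !nzchar(object@drugId))
    msg <- c(msg, "drugId must be a single non-empty string")
  nf <- object@nodeFeatures
  if (ncol(nf) != 78L)
    msg <- c(msg, "nodeFeatures must have exactly 78 columns")
  if (nrow(nf) < 1L)
    msg <- c(msg, "graph must contain at least one atom")
  e <- object@edges
  if (ncol(e) != 2L)
    msg <- c(msg, "edges must have two columns")
  if (nrow(e) > 0L) {
    if (any(e < 1L) || any(e > nrow(nf)))
      msg <- c(msg, "edge indices must lie in [1, n_atoms]")
    if (any(e[, 1L] == e[, 2L]))
      msg <- c(msg, "self-loops are not stored")
    if (any(e[, 1L] > e[, 2L]))
      msg <- c(msg, "edges must be in canonical (low, high) order")
    if (anyDuplicated(paste(e[, 1L], e[, 2L])))
      msg <- c(msg, "duplicate edges")
  }
  if (length(object@edgeWeights) != nrow(e))
    msg <- c(msg, "edgeWeights must have one entry per edge")
  if (any(object@edgeWeights < 0))
    msg <- c(msg, "edgeWeights must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' Construct a MolecularGraph
#'
#' @param drugId drug identifier.
#' @param nodeFeatures atoms x 78 feature matrix (see [featurizeAtom()]).
#' @param edges two-column matrix of undirected bonds (any order; canonicalized).
#' @param edgeWeights per-bond weight, recycled from 1.
#' @return A [MolecularGraph-class] object.
#' @export
MolecularGraph <- function(drugId, nodeFeatures, edges,
                           edgeWeights = rep(1, nrow(edges))) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (nrow(edges) > 0L) {
    swap <- edges[, 1L] > edges[, 2L]
    edges[swap, ] <- edges[swap, c(2L, 1L)]
    o <- order(edges[, 1L], edges[, 2L])
    edges <- edges[o, , drop = FALSE]
    edgeWeights <- as.numeric(edgeWeights)[o]
  }
  new("MolecularGraph", drugId = as.character(drugId),
      nodeFeatures = nodeFeatures, edges = edges,
      edgeWeights = as.numeric(edgeWeights))
}

#' ExpressionGrid: one cell line's marker-gene profile as a 30 x 30 matrix
#'
#' 900 marker-gene expression values arranged row-major on a square grid so a
#' convolutional encoder can exploit local receptive fields:
#' \code{grid[i, j]} is the value of \code{geneOrder[30 * (i - 1) + j]}.
#'
#' @slot cellLineId character(1).
#' @slot grid 30 x 30 numeric matrix.
#' @slot geneOrder character(900), unique gene identifiers in grid order.
#' @export
setClass("ExpressionGrid",
  representation(cellLineId = "character", grid = "matrix",
                 geneOrder = "character"))

setValidity("ExpressionGrid", function(object) {
  msg <- character()
  if (length(object@cellLineId) != 1L || !nzchar(object@cellLineId))
    msg <- c(msg, "cellLineId must be a single non-empty string")
  if (!all(dim(object@grid) == c(30L, 30L)))
    msg <- c(msg, "grid must be exactly 30 x 30")
  if (length(object@geneOrder) != 900L)
    msg <- c(msg, "geneOrder must have exactly 900 entries")
  if (anyDuplicated(object@geneOrder))
    msg <- c(msg, "geneOrder contains duplicates")
  if (any(!is.finite(object@grid)))
    msg <- c(msg, "grid contains non-finite values")
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionGrid from a 900-gene expression vector
#'
#' @param cellLineId cell line identifier.
#' @param values numeric vector of length 900, in `geneOrder` order.
#' @param geneOrder character vector of 900 unique gene ids.
#' @return An [ExpressionGrid-class].
#' @export
ExpressionGrid <- function(cellLineId, values, geneOrder) {
  if (length(values) != 900L)
    stop("'values' must have length 900")
  new("ExpressionGrid", cellLineId = as.character(cellLineId),
      grid = matrix(as.numeric(values), nrow = 30L, ncol = 30L, byrow = TRUE),
      geneOrder = as.character(geneOrder))
}

#' FewShotTask: one cell line's support/query split
#'
#' K labeled support samples used for adaptation and Q held-out query samples
#' used for evaluation, all drawn from a single cell line; support and query
#' never share a drug pair.
#'
#' @slot cellLine character(1).
#' @slot support data.frame with columns drugA, drugB, cellLine, score.
#' @slot query data.frame, same columns.
#' @export
setClass("FewShotTask",
  representation(cellLine = "character", support = "data.frame",
                 query = "data.frame"))

setValidity("FewShotTask", function(object) {
  msg <- character()
  for (part in c("support", "query")) {
    df <- slot(object, part)
    if (!all(synergyColumns %in% names(df)))
      msg <- c(msg, paste(part, "must carry the synergy sample columns"))
    else if (nrow(df) > 0L && any(df$cellLine != object@cellLine))
      msg <- c(msg, paste(part, "contains samples from another cell line"))
  }
  if (nrow(object@query) < 1L)
    msg <- c(msg, "query set must be non-empty")
  if (nrow(object@support) > 0L && nrow(object@query) > 0L &&
      length(intersect(pairKey(object@support$drugA, object@support$drugB),
                       pairKey(object@query$drugA, object@query$drugB))))
    msg <- c(msg, "support and query share a drug pair")
  if (length(msg)) msg else TRUE
})

#' Construct a FewShotTask
#' @param cellLine cell line id.
#' @param support,query synergy sample data.frames (support may have 0 rows
#'   for zero-shot evaluation).
#' @return A [FewShotTask-class].
#' @export
FewShotTask <- function(cellLine, support, query) {
  new("FewShotTask", cellLine = as.character(cellLine),
      support = support, query = query)
}

#' SynergyModel: parameter state of the synergy predictor
#'
#' Trainable parameters are partitioned into the embedding group `thetaE`
#' (three GCN weight matrices; convolutional weights, biases and batch-norm
#' affine parameters of the cell encoder; integration-layer weights of the
#' shared drug transform and the cell transform) and the prediction-head
#' group `thetaP` (two fully connected layers). Batch-norm running statistics
#' are state, not parameters, and live in `bnStats`.
#'
#' @slot thetaE named list of embedding parameters.
#' @slot thetaP named list of prediction-head parameters.
#' @slot bnStats named list of batch-norm running means/variances.
#' @slot config model architecture configuration (see [modelConfig()]).
#' @slot hyper list: alpha (inner lr), beta (outer lr), dropout, innerSteps,
#'   secondOrder.
#' @slot flags list: stage in {initialized, pretrained, meta-trained},
#'   ablation in {none, no_ml, no_ft, no_so, no_pt}.
#' @export
setClass("SynergyModel",
  representation(thetaE = "list", thetaP = "list", bnStats = "list",
                 config = "list", hyper = "list", flags = "list"))

setValidity("SynergyModel", function(object) {
  msg <- character()
  if (length(intersect(names(object@thetaE), names(object@thetaP))))
    msg <- c(msg, "thetaE and thetaP must not share parameter names")
  h <- object@hyper
  if (!is.numeric(h$alpha) || h$alpha <= 0)
    msg <- c(msg, "inner learning rate alpha must be > 0")
  if (!is.numeric(h$beta) || h$beta <= 0)
    msg <- c(msg, "outer learning rate beta must be > 0")
  if (!object@flags$ablation %in% c("none", "no_ml", "no_ft", "no_so", "no_pt"))
    msg <- c(msg, "unknown ablation flag")
  if (length(msg)) msg else TRUE
})

#' SyntheticWorld: a generated benchmark universe
#'
#' Drug library, cell-line profiles with latent factors, synergy samples, and
#' the noiseless ground-truth synergy function, all derived from one seed.
#'
#' @slot config the [syntheticWorldConfig()] used.
#' @slot drugs named list of [MolecularGraph-class].
#' @slot profiles named list of [ExpressionGrid-class].
#' @slot factors cell lines x latent-dimension matrix of latent factors.
#' @slot samples synergy sample data.frame.
#' @slot truth function(drugA, drugB, cellLine) returning the noiseless
#'   standardized synergy score.
#' @slot meta internal generator state (projections, per-line scalings).
#' @export
setClass("SyntheticWorld",
  representation(config = "list", drugs = "list", profiles = "list",
                 factors = "matrix", samples = "data.frame",
                 truth = "function", meta = "list"))

#' SplitSpec: a cell-line partition into meta-training and meta-testing sets
#'
#' @slot metaTrain character vector of cell line ids.
#' @slot metaTest character vector of cell line ids.
#' @slot method "random" or "low_similarity".
#' @slot similarity cell x cell similarity matrix (may be 0 x 0 for random
#'   splits).
#' @slot details list of method-specific diagnostics (e.g. achieved
#'   train-test similarity range).
#' @export
setClass("SplitSpec",
  representation(metaTrain = "character", metaTest = "character",
                 method = "character", similarity = "matrix",
                 details = "list"))

setValidity("SplitSpec", function(object) {
  msg <- character()
  if (length(intersect(object@metaTrain, object@metaTest)))
    msg <- c(msg, "meta-train and meta-test sets overlap")
  if (length(object@metaTrain) < 1L || length(object@metaTest) < 1L)
    msg <- c(msg, "both split sides must be non-empty")
  if (!object@method %in% c("random", "low_similarity"))
    msg <- c(msg, "method must be 'random' or 'low_similarity'")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------------

#' @name show-methods
#' @title Compact display of FewShotSynergy objects
#' @param object the object to display.
#' @aliases show,MolecularGraph-method show,ExpressionGrid-method
#'   show,FewShotTask-method show,SynergyModel-method
#'   show,SyntheticWorld-method show,SplitSpec-method
#' @exportMethod show
setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph '", object@drugId, "': ", nrow(object@nodeFeatures),
      " atoms, ", nrow(object@edges), " bonds, ",
      sum(object@nodeFeatures[, 78L] > 0), " aromatic atoms\n", sep = "")
})

setMethod("show", "ExpressionGrid", function(object) {
  cat("ExpressionGrid '", object@cellLineId, "': 30 x 30 (900 genes), ",
      "range [", signif(min(object@grid), 3), ", ",
      signif(max(object@grid), 3), "]\n", sep = "")
})

setMethod("show", "FewShotTask", function(object) {
  cat("FewShotTask on '", object@cellLine, "': K = ", nrow(object@support),
      " support, Q = ", nrow(object@query), " query samples\n", sep = "")
})

setMethod("show", "SynergyModel", function(object) {
  np <- function(l) sum(vapply(l, length, 1L))
  cat("SynergyModel (stage: ", object@flags$stage,
      ", ablation: ", object@flags$ablation, ")\n",
      "  thetaE: ", length(object@thetaE), " tensors, ", np(object@thetaE),
      " parameters\n",
      "  thetaP: ", length(object@thetaP), " tensors, ", np(object@thetaP),
      " parameters\n",
      "  alpha = ", object@hyper$alpha, ", beta = ", object@hyper$beta,
      ", dropout = ", object@hyper$dropout, "\n", sep = "")
})

setMethod("show", "SyntheticWorld", function(object) {
  cat("SyntheticWorld: ", length(object@drugs), " drugs, ",
      length(object@profiles), " cell lines, ", nrow(object@samples),
      " synergy samples (shared weight ", object@config$sharedWeight,
      ", noise sd ", object@config$noiseSd, ")\n", sep = "")
})

setMethod("show", "SplitSpec", function(object) {
  cat("SplitSpec (", object@method, "): ", length(object@metaTrain),
      " meta-train / ", length(object@metaTest), " meta-test cell lines\n",
      sep = "")
})
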