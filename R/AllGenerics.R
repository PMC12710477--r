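#' @name accessors
#' @title Accessors for FewShotSynergy classes
#' @param object an object of the documented class.
#' @description Slot accessors; user code should use these rather than `@`.
NULL

#' @rdname accessors
#' @export
setGeneric("drugId", function(object) standardGeneric("drugId"))
#' @rdname accessors
#' @export
setGeneric("nodeFeatures", function(object) standardGeneric("nodeFeatures"))
#' @rdname accessors
#' @export
setGeneric("edgeMatrix", function(object) standardGeneric("edgeMatrix"))
#' @rdname accessors
#' @export
setGeneric("edgeWeights", function(object) standardGeneric("edgeWeights"))
#' @rdname accessors
#' @export
setGeneric("cellLineId", function(object) standardGeneric("cellLineId"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(object) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("geneOrder", function(object) standardGeneric("geneOrder"))
#' @rdname accessors
#' @export
setGeneric("supportSet", function(object) standardGeneric("supportSet"))
#' @rdname accessors
#' @export
setGeneric("querySet", function(object) standardGeneric("querySet"))
#' @rdname accessors
#' @export
setGeneric("thetaE", function(object) standardGeneric("thetaE"))
#' @rdname accessors
#' @export
setGeneric("thetaP", function(object) standardGeneric("thetaP"))
#' @rdname accessors
#' @export
setGeneric("modelStage", function(object) standardGeneric("modelStage"))
#' @rdname accessors
#' @export
setGeneric("ablation", function(object) standardGeneric("ablation"))
#' @rdname accessors
#' @export
setGeneric("metaTrainCells", function(object) standardGeneric("metaTrainCells"))
#' @rdname accessors
#' @export
setGeneric("metaTestCells", function(object) standardGeneric("metaTestCells"))
#' @rdname accessors
#' @export
setGeneric("worldSamples", function(object) standardGeneric("worldSamples"))

#' Encode a drug molecular graph into its graph-level embedding
#'
#' Three stacked graph-convolution layers followed by a coordinate-wise
#' max-pool readout over atoms.
#'
#' @param model a [SynergyModel-class].
#' @param x a [MolecularGraph-class].
#' @return numeric embedding vector.
#' @export
setGeneric("encodeDrug", function(model, x) standardGeneric("encodeDrug"))

#' Encode a cell-line expression grid into its embedding
#'
#' Per convolutional layer: convolution, batch normalization, ReLU, 2x2 max
#' pooling; the final feature map is flattened.
#'
#' @param model a [SynergyModel-class].
#' @param x an [ExpressionGrid-class].
#' @param bnMode "eval" (running statistics; default) or "batch"
#'   (per-instance spatial statistics).
#' @return numeric embedding vector.
#' @export
setGeneric("encodeCell",
           function(model, x, bnMode = "eval") standardGeneric("encodeCell"))

setMethod("drugId", "MolecularGraph", function(object) object@drugId)
setMethod("nodeFeatures", "MolecularGraph", function(object) object@nodeFeatures)
setMethod("edgeMatrix", "MolecularGraph", function(object) object@edges)
setMethod("edgeWeights", "MolecularGraph", function(object) object@edgeWeights)
setMethod("cellLineId", "ExpressionGrid", function(object) object@cellLineId)
setMethod("gridValues", "ExpressionGrid", function(object) object@grid)
setMethod("geneOrder", "ExpressionGrid", function(object) object@geneOrder)
setMethod("cellLineId", "FewShotTask", function(object) object@cellLine)
setMethod("supportSet", "FewShotTask", function(object) object@support)
setMethod("querySet", "FewShotTask", function(object) object@query)
setMethod("thetaE", "SynergyModel", function(object) object@thetaE)
setMethod("thetaP", "SynergyModel", function(object) object@thetaP)
setMethod("modelStage", "SynergyModel", function(object) object@flags$stage)
setMethod("ablation", "SynergyModel", function(object) object@flags$ablation)
setMethod("metaTrainCells", "SplitSpec", function(object) object@metaTrain)
setMethod("metaTestCells", "SplitSpec", function(object) object@metaTest)
setMethod("worldSamples", "SyntheticWorld", function(object) object@samples)
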