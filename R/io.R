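## Readers for the delimited input formats (the same formats writeWorld
## emits) and versioned model checkpoints.

#' Read a synergy sample table
#'
#' Tab/whitespace-delimited with a header; columns drugA, drugB, cellLine,
#' score (the aliases drug_a_id/drug_b_id/cell_line_id/synergy_score are
#' accepted).
#'
#' @param path file path.
#' @return synergy sample data.frame.
#' @export
readSynergyTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  aliases <- c(drug_a_id = "drugA", drug_a = "drugA", drug_b_id = "drugB",
               drug_b = "drugB", cell_line_id = "cellLine",
               cell_line = "cellLine", synergy_score = "score",
               synergy = "score")
  hits <- match(tolower(names(tab)), names(aliases))
  names(tab)[!is.na(hits)] <- aliases[hits[!is.na(hits)]]
  assertSynergyTable(tab, path)
}

#' Read a marker-gene list (900 ids, one per line)
#' @param path file path.
#' @return character vector of 900 gene ids.
#' @export
readMarkerList <- function(path) {
  genes <- readLines(path)
  genes <- genes[nzchar(genes)]
  if (length(genes) != 900L)
    stop("marker list must contain exactly 900 genes, found ", length(genes))
  if (anyDuplicated(genes)) stop("marker list contains duplicates")
  genes
}

#' Read a cell line x gene expression table
#'
#' Delimited text with a header row of gene identifiers; the first column
#' holds cell line ids.
#'
#' @param path file path.
#' @return numeric matrix, cell lines x genes.
#' @export
readExpressionTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  m
}

#' Arrange expression profiles on the 30 x 30 marker grid
#'
#' Subsets each profile to the 900-gene marker list (in list order), applies
#' per-gene standardization across cell lines, fills genes missing from the
#' table with 0 (the post-standardization mean), and reshapes row-major into
#' [ExpressionGrid-class] objects.
#'
#' @param expr cell line x gene matrix from [readExpressionTable()].
#' @param markers character vector of 900 gene ids defining the grid order.
#' @return named list of [ExpressionGrid-class].
#' @export
prepareExpressionGrids <- function(expr, markers) {
  if (length(markers) != 900L) stop("'markers' must list exactly 900 genes")
  vals <- matrix(0, nrow(expr), 900L,
                 dimnames = list(rownames(expr), markers))
  present <- intersect(markers, colnames(expr))
  if (length(present) == 0L)
    stop("no marker genes found in the expression table")
  sub <- expr[, present, drop = FALSE]
  mu <- colMeans(sub)
  sg <- apply(sub, 2L, stats::sd)
  sg[sg == 0 | !is.finite(sg)] <- 1
  vals[, present] <- sweep(sweep(sub, 2L, mu, "-"), 2L, sg, "/")
  out <- lapply(rownames(expr), function(cl)
    ExpressionGrid(cl, vals[cl, ], markers))
  names(out) <- rownames(expr)
  out
}

checkpointFormatVersion <- "1.0"

#' Save / load a SynergyModel checkpoint
#'
#' The archive keeps the thetaE/thetaP grouping explicit and carries a
#' format-version tag; loading refuses a mismatched version, since the
#' parameter partition is load-bearing for the selective-adaptation
#' contract.
#'
#' @param model a [SynergyModel-class].
#' @param path checkpoint path (.rds).
#' @return `saveModel` invisibly returns `path`; `loadModel` returns the
#'   model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(format = checkpointFormatVersion,
               package = as.character(utils::packageVersion("FewShotSynergy")),
               thetaE = model@thetaE, thetaP = model@thetaP,
               bnStats = model@bnStats, config = model@config,
               hyper = model@hyper, flags = model@flags), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, checkpointFormatVersion))
    stop("checkpoint format version ", obj$format,
         " does not match supported version ", checkpointFormatVersion)
  new("SynergyModel", thetaE = obj$thetaE, thetaP = obj$thetaP,
      bnStats = obj$bnStats, config = obj$config, hyper = obj$hyper,
      flags = obj$flags)
}
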