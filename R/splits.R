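#' Random cell-line split
#'
#' Partitions cell lines into meta-training and meta-testing sets at the
#' given fraction (e.g. 106 lines at 0.8 give 85/21). Deterministic under
#' the seed.
#'
#' @param cellLines character vector of cell line ids.
#' @param fraction meta-training fraction, strictly in (0, 1).
#' @param seed split seed.
#' @return a [SplitSpec-class].
#' @export
splitRandom <- function(cellLines, fraction = 0.8, seed = 1L) {
  cellLines <- unique(as.character(cellLines))
  if (fraction <= 0 || fraction >= 1)
    stop("'fraction' must be strictly between 0 and 1")
  n <- length(cellLines)
  nTrain <- round(fraction * n)
  if (nTrain < 1L || nTrain >= n)
    stop("split leaves one side empty")
  train <- withSeed(deriveSeed(seed, "split"), sample(cellLines, nTrain))
  new("SplitSpec", metaTrain = train,
      metaTest = setdiff(cellLines, train), method = "random",
      similarity = matrix(numeric(0), 0L, 0L), details = list())
}

#' Pairwise Pearson similarity of cell-line expression profiles
#'
#' @param profiles named list of [ExpressionGrid-class].
#' @return cell x cell correlation matrix.
#' @export
expressionSimilarity <- function(profiles) {
  M <- vapply(profiles, function(p) as.vector(gridValues(p)), numeric(900L))
  stats::cor(M)  # columns are cell lines
}

#' Low-similarity cell-line split by hierarchical clustering
#'
#' Clusters cell lines by average-linkage agglomerative clustering on
#' pairwise expression correlation, then assigns whole clusters to the test
#' side -- lowest maximum similarity to the remaining lines first -- until at
#' least `nTest` lines are held out. This stresses generalization: test cell
#' lines are transcriptomically dissimilar from every training line.
#'
#' @param profiles named list of [ExpressionGrid-class], or a precomputed
#'   similarity matrix in [-1, 1] with dimnames.
#' @param nTest minimum number of test cell lines.
#' @param nClusters number of clusters to cut the tree into (default
#'   `max(4, 2 * ceiling(n / nTest))`, keeping clusters small relative to the
#'   test side).
#' @return a [SplitSpec-class]; `details` carries the achieved train-test
#'   similarity range.
#' @export
splitLowSimilarity <- function(profiles, nTest, nClusters = NULL) {
  if (is.matrix(profiles)) sim <- profiles
  else sim <- expressionSimilarity(profiles)
  ids <- colnames(sim)
  n <- length(ids)
  nTest <- assertCount(nTest, "nTest")
  if (nTest >= n) stop("'nTest' must be smaller than the number of cell lines")
  if (is.null(nClusters))
    nClusters <- min(n - 1L, max(4L, 2L * ceiling(n / nTest)))
  hc <- stats::hclust(stats::as.dist(1 - sim), method = "average")
  cl <- stats::cutree(hc, k = nClusters)

  ## a cluster's isolation = the largest similarity any member has outside it
  isolation <- vapply(sort(unique(cl)), function(k) {
    inK <- cl == k
    if (all(inK)) return(Inf)
    max(sim[inK, !inK, drop = FALSE])
  }, numeric(1))
  orderK <- sort(unique(cl))[order(isolation)]

  test <- character(0)
  for (k in orderK) {
    if (length(test) >= nTest) break
    test <- c(test, ids[cl == k])
  }
  train <- setdiff(ids, test)
  if (length(train) == 0L)
    stop("cannot hold out ", nTest, " lines without emptying the train side")
  cross <- sim[train, test, drop = FALSE]
  new("SplitSpec", metaTrain = train, metaTest = test,
      method = "low_similarity", similarity = sim,
      details = list(crossSimilarityRange = range(cross),
                     nClusters = nClusters))
}

#' Train-test similarity range of a split
#'
#' @param split a [SplitSpec-class].
#' @param similarity cell x cell similarity matrix with dimnames (taken from
#'   the split itself when it carries one).
#' @return c(min, max) over all train-test cell line pairs.
#' @export
crossSimilarityRange <- function(split, similarity = NULL) {
  sim <- if (!is.null(similarity)) similarity else split@similarity
  if (length(sim) == 0L) stop("no similarity matrix available")
  range(sim[split@metaTrain, split@metaTest, drop = FALSE])
}
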