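#' @import methods
#' @importFrom stats rnorm runif cor cor.test sd var quantile
#' @importFrom utils head read.delim write.table packageVersion
NULL

## Evaluate an expression under a fixed RNG state and restore the caller's
## stream afterwards. All randomness in the package flows through this.
withSeed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Named substreams derived from a root seed. Offsets keep every stage
## (init, batching, episodes, dropout, ...) on its own reproducible stream
## while staying inside the 32-bit integer range.
deriveSeed <- function(seed, stream) {
  offsets <- c(init = 11L, pretrain = 23L, episode = 37L, dropout = 51L,
               world = 67L, drugs = 71L, cells = 83L, synergy = 97L,
               split = 113L, eval = 131L, task = 149L)
  if (!stream %in% names(offsets))
    stop("unknown random stream: ", stream)
  (as.integer(seed) * 1009L + offsets[[stream]]) %% 2147483647L
}

assertFlag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop("'", what, "' must be TRUE or FALSE")
  x
}

assertCount <- function(x, what, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop("'", what, "' must be an integer >= ", min)
  as.integer(x)
}

assertNumber <- function(x, what, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", what, "' must be a single finite number")
  if (if (strict) x <= min else x < min)
    stop("'", what, "' must be ", if (strict) "> " else ">= ", min)
  as.numeric(x)
}

## Columns every synergy sample table must carry.
synergyColumns <- c("drugA", "drugB", "cellLine", "score")

assertSynergyTable <- function(x, what = "samples") {
  if (!is.data.frame(x) || !all(synergyColumns %in% names(x)))
    stop("'", what, "' must be a data.frame with columns ",
         paste(synergyColumns, collapse = ", "))
  if (nrow(x) == 0L) stop("'", what, "' is empty")
  if (any(x$drugA == x$drugB))
    stop("'", what, "' contains self-paired drugs")
  if (any(!is.finite(x$score)))
    stop("'", what, "' contains non-finite synergy scores")
  x
}

## Canonical undirected drug-pair key, order-independent.
pairKey <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}
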