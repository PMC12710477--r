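#' Atom feature configuration
#'
#' Defines the one-hot block layout of the 78-dimensional atom descriptor:
#' element symbol (44 slots, the 43 elements below plus a reserved "other"
#' slot), heavy-neighbor count 0..10, implicit valence 0..10, bonded-hydrogen
#' count 0..10, and one aromaticity bit: 44 + 11 + 11 + 11 + 1 = 78.
#' Alternative partitions are accepted as long as the blocks sum to 78.
#'
#' @param symbols character vector of recognized element symbols; anything
#'   else maps to the reserved "other" slot.
#' @param maxDegree,maxValence,maxH upper bounds of the count one-hot blocks;
#'   larger observed counts are clamped to the top slot.
#' @return list with the block layout and total dimension.
#' @export
atomFeatureConfig <- function(
    symbols = c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg", "Na",
                "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl", "Yb", "Sb",
                "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn", "H", "Li", "Ge",
                "Cu", "Au", "Ni", "Cd", "In", "Mn", "Zr", "Cr", "Pt", "Hg",
                "Pb"),
    maxDegree = 10L, maxValence = 10L, maxH = 10L) {
  dim <- (length(symbols) + 1L) + (maxDegree + 1L) + (maxValence + 1L) +
    (maxH + 1L) + 1L
  if (dim != 78L)
    stop("atom feature blocks must sum to 78 dimensions, got ", dim)
  list(symbols = symbols, maxDegree = as.integer(maxDegree),
       maxValence = as.integer(maxValence), maxH = as.integer(maxH),
       dim = 78L)
}

oneHot <- function(index, size) {
  v <- numeric(size)
  v[index] <- 1
  v
}

#' Featurize one atom into its 78-dimensional descriptor vector
#'
#' Concatenates one-hot blocks for element symbol, heavy-neighbor count,
#' implicit valence and bonded-hydrogen count, plus a single aromaticity bit.
#' Unrecognized element symbols map to the reserved "other" slot; counts above
#' a block's bound are clamped to its top slot; negative counts are an error.
#'
#' @param symbol element symbol, e.g. "C".
#' @param degree number of heavy-atom neighbors.
#' @param implicitValence implicit valence (implicit hydrogen count).
#' @param numH total bonded hydrogens (implicit + explicit).
#' @param aromatic logical aromaticity flag.
#' @param config an [atomFeatureConfig()].
#' @return numeric vector of length 78.
#' @examples
#' v <- featurizeAtom("C", degree = 2, implicitValence = 1, numH = 1,
#'                    aromatic = TRUE)
#' sum(v)  # 5 set entries: 4 one-hot blocks + aromaticity bit
#' @export
featurizeAtom <- function(symbol, degree, implicitValence, numH,
                          aromatic = FALSE, config = atomFeatureConfig()) {
  degree <- assertNumber(degree, "degree")
  implicitValence <- assertNumber(implicitValence, "implicitValence")
  numH <- assertNumber(numH, "numH")
  if (degree < 0 || implicitValence < 0 || numH < 0)
    stop("atom descriptor counts must be nonnegative")
  si <- match(symbol, config$symbols)
  if (is.na(si)) si <- length(config$symbols) + 1L
  c(oneHot(si, length(config$symbols) + 1L),
    oneHot(min(degree, config$maxDegree) + 1L, config$maxDegree + 1L),
    oneHot(min(implicitValence, config$maxValence) + 1L,
           config$maxValence + 1L),
    oneHot(min(numH, config$maxH) + 1L, config$maxH + 1L),
    as.numeric(isTRUE(aromatic)))
}
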