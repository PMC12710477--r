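## Allowed valences of the common organic elements, used to derive implicit
## hydrogen counts from the kekulized connection table. The smallest allowed
## valence >= the bond-order sum is used; elements outside the table get no
## implicit hydrogens. Formal charges are not modeled: a charged atom's extra
## or missing bonds already shift its bond-order sum in the right direction.
standardValences <- list(
  H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
  S = c(2, 4, 6), Cl = 1, Br = 1, I = 1)

## Build a MolecularGraph from one ChemmineR SDF record. Hydrogen atoms are
## folded into their heavy neighbor's hydrogen count; the stored graph is
## heavy-atom only.
sdfToMolecularGraph <- function(sdf, drugId, config = atomFeatureConfig()) {
  ab <- ChemmineR::atomblock(sdf)
  atomNames <- rownames(ab)
  elements <- sub("_\\d+$", "", atomNames)
  bb <- ChemmineR::bondblock(sdf)
  bondFrom <- integer(0); bondTo <- integer(0); bondOrder <- numeric(0)
  if (!is.null(bb) && nrow(bb) > 0L) {
    bondFrom <- as.integer(bb[, 1L])
    bondTo <- as.integer(bb[, 2L])
    bondOrder <- as.numeric(bb[, 3L])
    bondOrder[bondOrder == 4] <- 1.5  # aromatic-typed bonds in raw SDF input
  }

  heavy <- which(elements != "H")
  if (length(heavy) == 0L) return(NULL)

  nAll <- length(elements)
  degree <- integer(nAll); orderSum <- numeric(nAll); explicitH <- integer(nAll)
  for (k in seq_along(bondFrom)) {
    u <- bondFrom[k]; v <- bondTo[k]; o <- bondOrder[k]
    orderSum[u] <- orderSum[u] + o
    orderSum[v] <- orderSum[v] + o
    if (elements[v] == "H") explicitH[u] <- explicitH[u] + 1L
    else if (elements[u] != "H") degree[u] <- degree[u] + 1L
    if (elements[u] == "H") explicitH[v] <- explicitH[v] + 1L
    else if (elements[v] != "H") degree[v] <- degree[v] + 1L
  }

  aromatic <- logical(nAll)
  ringInfo <- tryCatch(
    suppressWarnings(ChemmineR::rings(sdf, type = "all", arom = TRUE)),
    error = function(e) NULL)
  if (!is.null(ringInfo) && length(ringInfo$RINGS)) {
    for (i in seq_along(ringInfo$RINGS)) {
      if (isTRUE(ringInfo$AROMATIC[[i]])) {
        idx <- match(ringInfo$RINGS[[i]], atomNames)
        aromatic[idx[!is.na(idx)]] <- TRUE
      }
    }
  }

  implicitH <- vapply(seq_len(nAll), function(i) {
    allowed <- standardValences[[elements[i]]]
    if (is.null(allowed)) return(0L)
    s <- round(orderSum[i])
    fit <- allowed[allowed >= s]
    if (length(fit) == 0L) return(0L)
    as.integer(fit[1L] - s)
  }, integer(1))

  newIndex <- integer(nAll)
  newIndex[heavy] <- seq_along(heavy)
  feats <- t(vapply(heavy, function(i) {
    featurizeAtom(elements[i], degree = degree[i],
                  implicitValence = implicitH[i],
                  numH = implicitH[i] + explicitH[i],
                  aromatic = aromatic[i], config = config)
  }, numeric(config$dim)))

  keep <- elements[bondFrom] != "H" & elements[bondTo] != "H"
  edges <- cbind(newIndex[bondFrom[keep]], newIndex[bondTo[keep]])
  if (length(edges) == 0L) edges <- matrix(integer(0), ncol = 2L)
  MolecularGraph(drugId = drugId, nodeFeatures = feats, edges = edges,
                 edgeWeights = rep(1, nrow(edges)))
}

## Bond-less molecules (single heavy atom, e.g. methane) fall outside the
## toolkit's SDF validity model, which requires a bond block; their trivial
## graphs are built directly from the V2000 atom lines instead.
bondlessSdfToGraph <- function(lines, drugId, config = atomFeatureConfig()) {
  if (length(lines) < 5L) return(NULL)
  counts <- lines[4L]
  nAtoms <- suppressWarnings(as.integer(substr(counts, 1L, 3L)))
  nBonds <- suppressWarnings(as.integer(substr(counts, 4L, 6L)))
  if (is.na(nAtoms) || is.na(nBonds) || nBonds != 0L || nAtoms < 1L)
    return(NULL)
  elements <- vapply(lines[4L + seq_len(nAtoms)], function(l)
    strsplit(trimws(l), "\\s+")[[1L]][4L], character(1), USE.NAMES = FALSE)
  heavy <- elements[elements != "H"]
  nH <- sum(elements == "H")
  if (length(heavy) == 0L) return(NULL)
  feats <- t(vapply(heavy, function(el) {
    allowed <- standardValences[[el]]
    impH <- if (is.null(allowed)) 0L else as.integer(allowed[1L])
    featurizeAtom(el, degree = 0, implicitValence = impH,
                  numH = impH + nH, aromatic = FALSE, config = config)
  }, numeric(config$dim)))
  MolecularGraph(drugId = drugId, nodeFeatures = feats,
                 edges = matrix(integer(0), ncol = 2L))
}

## SMILES string -> MolecularGraph (NULL on parse failure).
smilesToGraph <- function(smiles, drugId, config = atomFeatureConfig()) {
  sdfset <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, drugId))),
    error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) == 0L) return(NULL)
  g <- tryCatch(sdfToMolecularGraph(sdfset[[1L]], drugId, config),
                error = function(e) NULL)
  if (!is.null(g)) return(g)
  # bond-less corner case: rebuild from the raw SDF text
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", source = paste0(smiles, "\n"))),
    error = function(e) NULL)
  if (is.null(txt)) return(NULL)
  tryCatch(bondlessSdfToGraph(strsplit(txt, "\n", fixed = TRUE)[[1L]],
                              drugId, config),
           error = function(e) NULL)
}

#' Parse drug structures into atom-featurized molecular graphs
#'
#' Reads an SDF file or a two-column delimited SMILES file (drug_id, smiles;
#' no header) and returns one [MolecularGraph-class] per parseable record.
#' Hydrogens are implicit: the graph covers heavy atoms only, with hydrogen
#' counts encoded as node features. Unparseable records and records with zero
#' heavy atoms are skipped with a warning naming their identifiers.
#'
#' @param path path to the structure file.
#' @param format "smiles" or "sdf".
#' @param config an [atomFeatureConfig()].
#' @return named list of [MolecularGraph-class] objects.
#' @examples
#' tf <- tempfile(fileext = ".smi")
#' writeLines(c("ethanol\tCCO", "benzene\tc1ccccc1"), tf)
#' graphs <- parseStructures(tf, format = "smiles")
#' graphs$benzene
#' @export
parseStructures <- function(path, format = c("smiles", "sdf"),
                            config = atomFeatureConfig()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty structure file: ", path)

  if (format == "smiles") {
    tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                             col.names = c("drugId", "smiles"),
                             comment.char = "")
    if (nrow(tab) == 0L) stop("empty structure file: ", path)
    ids <- as.character(tab$drugId)
    graphs <- lapply(seq_len(nrow(tab)), function(i)
      smilesToGraph(tab$smiles[i], ids[i], config))
    names(graphs) <- ids
  } else {
    sdfstr <- ChemmineR::read.SDFstr(path)
    sdfset <- suppressWarnings(ChemmineR::read.SDFset(sdfstr))
    if (length(sdfset) == 0L) stop("no records in SDF file: ", path)
    ids <- ChemmineR::sdfid(sdfset)
    ids[!nzchar(ids) | is.na(ids)] <-
      paste0("record_", which(!nzchar(ids) | is.na(ids)))
    graphs <- lapply(seq_along(sdfset), function(i) {
      g <- tryCatch(sdfToMolecularGraph(sdfset[[i]], ids[i], config),
                    error = function(e) NULL)
      if (is.null(g))  # bond-less corner case: use the raw record text
        g <- tryCatch(bondlessSdfToGraph(sdfstr[[i]], ids[i], config),
                      error = function(e) NULL)
      g
    })
    names(graphs) <- ids
  }

  failed <- vapply(graphs, is.null, logical(1))
  if (any(failed))
    warning("skipped unparseable or hydrogen-only records: ",
            paste(names(graphs)[failed], collapse = ", "))
  graphs[!failed]
}
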