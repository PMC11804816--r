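## MolecularGraph input and eccentricity machinery.

#' Read a molecular graph from a plain edge-list file
#'
#' The file contains one edge per line as two whitespace-separated positive
#' integer vertex ids (1-based). Blank lines and lines starting with `#` are
#' ignored. The graph is taken on exactly the vertices mentioned; malformed
#' input is an error, never silently repaired.
#'
#' @param path path to the edge-list file.
#' @return a \linkS4class{MolecularGraph}.
#' @examples
#' f <- tempfile()
#' writeLines(c("# propane skeleton", "1 2", "2 3"), f)
#' readEdgeList(f)
#' @export
readEdgeList <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    stop("edge-list file '", path, "' contains no edges")
  }
  edges <- matrix(NA_integer_, nrow = length(lines), ncol = 2L)
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[[i]], "[[:space:]]+")[[1]]
    if (length(tok) != 2L) {
      stop("line ", i, ": expected two vertex ids, got '", lines[[i]], "'")
    }
    num <- suppressWarnings(as.numeric(tok))
    if (anyNA(num) || any(num != floor(num))) {
      stop("line ", i, ": non-integer vertex token in '", lines[[i]], "'")
    }
    if (any(num < 1)) stop("line ", i, ": vertex ids must be positive")
    edges[i, ] <- as.integer(num)
  }
  if (any(edges[, 1L] == edges[, 2L])) {
    bad <- which(edges[, 1L] == edges[, 2L])[1L]
    stop("self-loop at line ", bad, ": vertex ", edges[bad, 1L])
  }
  key <- paste(pmin(edges[, 1L], edges[, 2L]),
               pmax(edges[, 1L], edges[, 2L]))
  if (anyDuplicated(key)) {
    stop("duplicate edge: ", key[duplicated(key)][1L])
  }
  v <- sort(unique(as.vector(edges)))
  if (!.isConnected(v, cbind(pmin(edges[, 1L], edges[, 2L]),
                             pmax(edges[, 1L], edges[, 2L])))) {
    stop("disconnected graph: not every vertex is reachable from vertex ",
         v[1L])
  }
  molecularGraph(edges)
}

#' Read a molecular graph from a SMILES string
#'
#' Parses a SMILES string into its hydrogen-suppressed heavy-atom skeleton:
#' hydrogens are dropped and bond multiplicity and aromaticity are collapsed
#' to single edges. Requires the optional ChemmineR/ChemmineOB backend; the
#' edge-list reader ([readEdgeList()]) works without it.
#'
#' @param smiles a single SMILES string.
#' @return a \linkS4class{MolecularGraph} with element labels.
#' @examples
#' if (requireNamespace("ChemmineR", quietly = TRUE) &&
#'     requireNamespace("ChemmineOB", quietly = TRUE)) {
#'   readSmiles("C1CCCCC1")  # cyclohexane: n = 6, m = 6
#' }
#' @export
readSmiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  if (!requireNamespace("ChemmineR", quietly = TRUE) ||
      !requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("SMILES parsing needs the ChemmineR and ChemmineOB packages; ",
         "use readEdgeList() instead")
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)[[1L]]),
    error = function(e) stop("unparsable SMILES '", smiles, "': ",
                             conditionMessage(e))
  )
  atoms <- ChemmineR::atomblock(sdf)
  bonds <- ChemmineR::bondblock(sdf)
  elem <- sub("_.*$", "", rownames(atoms))
  heavy <- which(toupper(elem) != "H")
  if (length(heavy) == 0L) stop("SMILES '", smiles, "' has no heavy atoms")
  e <- cbind(as.integer(bonds[, 1L]), as.integer(bonds[, 2L]))
  e <- e[e[, 1L] %in% heavy & e[, 2L] %in% heavy, , drop = FALSE]
  ## collapse multiple bond records to single edges
  e <- unique(cbind(pmin(e[, 1L], e[, 2L]), pmax(e[, 1L], e[, 2L])))
  ## renumber heavy atoms 1..n
  remap <- integer(max(heavy))
  remap[heavy] <- seq_along(heavy)
  e <- cbind(remap[e[, 1L]], remap[e[, 2L]])
  molecularGraph(e, vertexIds = seq_along(heavy), labels = elem[heavy])
}

.asIgraph <- function(x) {
  igraph::graph_from_edgelist(
    matrix(match(x@edges, x@vertexIds), ncol = 2L),
    directed = FALSE
  )
}

#' @rdname distanceMatrix
#' @export
setMethod("distanceMatrix", "MolecularGraph", function(x) {
  if (numVertices(x) == 1L) {
    d <- matrix(0L, 1L, 1L)
  } else {
    d <- igraph::distances(.asIgraph(x), algorithm = "unweighted")
    if (any(!is.finite(d))) stop("graph is disconnected")
    storage.mode(d) <- "integer"
  }
  dimnames(d) <- list(as.character(x@vertexIds), as.character(x@vertexIds))
  d
})

#' @rdname eccentricities
#' @export
setMethod("eccentricities", "MolecularGraph", function(x) {
  d <- distanceMatrix(x)
  ecc <- apply(d, 1L, max)
  storage.mode(ecc) <- "integer"
  ecc
})

#' Radius and diameter of a molecular graph
#'
#' The radius (diameter) is the minimum (maximum) vertex eccentricity.
#'
#' @param x a connected \linkS4class{MolecularGraph}.
#' @return integer scalar.
#' @export
graphRadius <- function(x) min(eccentricities(x))

#' @rdname graphRadius
#' @export
graphDiameter <- function(x) max(eccentricities(x))

#' Vertex eccentricity partition
#'
#' Counts vertices by eccentricity value. Eccentricity classes are the
#' grouping the index formulas are evaluated on.
#'
#' @param ecc integer eccentricity vector as returned by [eccentricities()].
#' @return named integer vector: names are eccentricity values (increasing),
#'   values are vertex counts; counts sum to the number of vertices.
#' @examples
#' vertexEccPartition(eccentricities(molecularGraph(rbind(c(1, 2), c(2, 3)))))
#' @export
vertexEccPartition <- function(ecc) {
  stopifnot(length(ecc) > 0L)
  tab <- table(as.integer(ecc))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Edge eccentricity partition
#'
#' Groups the edges of a graph by the unordered pair of endpoint
#' eccentricities. Because endpoint eccentricities of an edge differ by at
#' most one, every class has |ecc1 - ecc2| <= 1.
#'
#' @param g a connected \linkS4class{MolecularGraph}.
#' @param ecc eccentricities of `g`; computed if not supplied.
#' @return data.frame with integer columns `ecc1 <= ecc2` and `count`,
#'   ordered by (ecc1, ecc2); counts sum to the number of edges.
#' @examples
#' g <- molecularGraph(rbind(c(1, 2), c(2, 3)))
#' edgeEccPartition(g)
#' @export
edgeEccPartition <- function(g, ecc = eccentricities(g)) {
  e <- edgeMatrix(g)
  ids <- as.character(vertexIds(g))
  eu <- ecc[match(as.character(e[, 1L]), ids)]
  ev <- ecc[match(as.character(e[, 2L]), ids)]
  lo <- pmin(eu, ev)
  hi <- pmax(eu, ev)
  key <- paste(lo, hi)
  tab <- table(key)
  parts <- do.call(rbind, strsplit(names(tab), " "))
  out <- data.frame(ecc1 = as.integer(parts[, 1L]),
                    ecc2 = as.integer(parts[, 2L]),
                    count = as.integer(tab))
  out[order(out$ecc1, out$ecc2), , drop = FALSE]
}

#' Summarise a molecular graph as a JSON-ready list
#'
#' @param g a connected \linkS4class{MolecularGraph}.
#' @return list with elements `n`, `m`, `radius`, `diameter`,
#'   `vertex_partition` (named counts) and `edge_partition` (data.frame),
#'   suitable for `jsonlite::toJSON()`.
#' @export
graphSummary <- function(g) {
  ecc <- eccentricities(g)
  list(
    n = numVertices(g),
    m = numEdges(g),
    radius = min(ecc),
    diameter = max(ecc),
    vertex_partition = as.list(vertexEccPartition(ecc)),
    edge_partition = edgeEccPartition(g, ecc)
  )
}
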