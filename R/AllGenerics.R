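#' @import methods
NULL

#' Number of vertices (heavy atoms) in a molecular graph
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @return integer scalar.
#' @export
setGeneric("numVertices", function(x) standardGeneric("numVertices"))

#' Number of edges (bonds) in a molecular graph
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @return integer scalar.
#' @export
setGeneric("numEdges", function(x) standardGeneric("numEdges"))

#' Vertex identifiers of a molecular graph
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @return sorted integer vector of vertex ids.
#' @export
setGeneric("vertexIds", function(x) standardGeneric("vertexIds"))

#' Edge matrix of a molecular graph
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @return a two-column integer matrix, one edge per row, endpoints ordered
#'   as (min, max).
#' @export
setGeneric("edgeMatrix", function(x) standardGeneric("edgeMatrix"))

#' Element labels of the vertices, if any
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @return character vector named by vertex id, or a zero-length character
#'   vector when no labels were recorded.
#' @export
setGeneric("vertexLabels", function(x) standardGeneric("vertexLabels"))

#' Vertex degrees of a molecular graph
#'
#' @param x a \linkS4class{MolecularGraph}.
#' @return integer vector named by vertex id.
#' @export
setGeneric("vertexDegrees", function(x) standardGeneric("vertexDegrees"))

#' All-pairs shortest-path distance matrix
#'
#' Distances are unweighted shortest-path lengths obtained by one
#' breadth-first search per source vertex.
#'
#' @param x a connected \linkS4class{MolecularGraph}.
#' @return square integer matrix with dimnames set to the vertex ids;
#'   zero diagonal, symmetric, all entries finite.
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' Vertex eccentricities
#'
#' The eccentricity of a vertex is the largest shortest-path distance from
#' that vertex to any other vertex of the (connected) graph.
#'
#' @param x a connected \linkS4class{MolecularGraph}.
#' @return integer vector of eccentricities named by vertex id.
#' @export
setGeneric("eccentricities", function(x) standardGeneric("eccentricities"))
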