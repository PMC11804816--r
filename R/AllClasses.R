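#' MolecularGraph: a hydrogen-suppressed molecular skeleton
#'
#' A simple, undirected, connected graph whose vertices are heavy
#' (non-hydrogen) atoms and whose edges are covalent bonds with bond order
#' and aromaticity collapsed to single edges. This is the object on which
#' all eccentricity-based indices are computed.
#'
#' @slot vertexIds sorted integer vector of vertex identifiers.
#' @slot edges two-column integer matrix, one edge per row, each row stored
#'   as (min, max); no self-loops, no duplicates.
#' @slot labels character vector of element labels named by vertex id, or
#'   zero-length when unknown.
#'
#' @seealso [molecularGraph()], [readEdgeList()], [readSmiles()]
#' @export
setClass("MolecularGraph",
  representation(
    vertexIds = "integer",
    edges = "matrix",
    labels = "character"
  )
)

.validMolecularGraph <- function(object) {
  msg <- character()
  v <- object@vertexIds
  e <- object@edges
  if (length(v) < 1L) msg <- c(msg, "graph must have at least one vertex")
  if (anyDuplicated(v)) msg <- c(msg, "duplicated vertex ids")
  if (is.unsorted(v)) msg <- c(msg, "vertexIds must be sorted")
  if (ncol(e) != 2L) msg <- c(msg, "edges must be a two-column matrix")
  if (nrow(e) > 0L) {
    if (!all(e %in% v)) msg <- c(msg, "edge endpoint not a declared vertex")
    if (any(e[, 1L] == e[, 2L])) msg <- c(msg, "self-loop")
    if (any(e[, 1L] > e[, 2L])) msg <- c(msg, "edge rows must be (min, max)")
    key <- paste(e[, 1L], e[, 2L])
    if (anyDuplicated(key)) msg <- c(msg, "duplicate edge")
  }
  if (length(object@labels) > 0L &&
      length(object@labels) != length(v)) {
    msg <- c(msg, "labels must be empty or one per vertex")
  }
  if (length(msg) == 0L && !.isConnected(v, e)) {
    msg <- c(msg, "graph is disconnected")
  }
  if (length(msg)) msg else TRUE
}

setValidity("MolecularGraph", .validMolecularGraph)

## connectivity by breadth-first search over an adjacency list
.isConnected <- function(v, e) {
  n <- length(v)
  if (n == 1L) return(TRUE)
  idx <- match(e, v)
  dim(idx) <- dim(e)
  adj <- vector("list", n)
  for (i in seq_len(nrow(idx))) {
    a <- idx[i, 1L]; b <- idx[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  seen <- logical(n)
  queue <- 1L
  seen[1L] <- TRUE
  while (length(queue)) {
    cur <- queue[[1L]]
    queue <- queue[-1L]
    nb <- adj[[cur]]
    new <- nb[!seen[nb]]
    seen[new] <- TRUE
    queue <- c(queue, new)
  }
  all(seen)
}

#' Construct a MolecularGraph
#'
#' @param edges two-column matrix (or data.frame) of integer vertex-id pairs,
#'   one edge per row. Orientation is irrelevant.
#' @param vertexIds optional integer vector of vertex ids; defaults to the
#'   ids mentioned in `edges`.
#' @param labels optional character vector of element labels, one per vertex
#'   (in `vertexIds` order).
#'
#' @return a validated \linkS4class{MolecularGraph}.
#' @examples
#' p3 <- molecularGraph(rbind(c(1, 2), c(2, 3)))
#' numVertices(p3)
#' @export
molecularGraph <- function(edges, vertexIds = NULL, labels = character()) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) edges <- matrix(integer(), ncol = 2L)
  storage.mode(edges) <- "integer"
  if (is.null(vertexIds)) vertexIds <- sort(unique(as.vector(edges)))
  vertexIds <- sort(as.integer(vertexIds))
  if (nrow(edges) > 0L) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  dimnames(edges) <- NULL
  if (length(labels) > 0L && is.null(names(labels))) {
    names(labels) <- as.character(vertexIds)
  }
  new("MolecularGraph", vertexIds = vertexIds, edges = edges,
      labels = as.character(labels))
}

#' @rdname numVertices
#' @export
setMethod("numVertices", "MolecularGraph", function(x) length(x@vertexIds))

#' @rdname numEdges
#' @export
setMethod("numEdges", "MolecularGraph", function(x) nrow(x@edges))

#' @rdname vertexIds
#' @export
setMethod("vertexIds", "MolecularGraph", function(x) x@vertexIds)

#' @rdname edgeMatrix
#' @export
setMethod("edgeMatrix", "MolecularGraph", function(x) x@edges)

#' @rdname vertexLabels
#' @export
setMethod("vertexLabels", "MolecularGraph", function(x) x@labels)

#' @rdname vertexDegrees
#' @export
setMethod("vertexDegrees", "MolecularGraph", function(x) {
  d <- integer(length(x@vertexIds))
  names(d) <- as.character(x@vertexIds)
  if (nrow(x@edges)) {
    tab <- table(factor(as.vector(x@edges), levels = x@vertexIds))
    d[] <- as.integer(tab)
  }
  d
})

setMethod("show", "MolecularGraph", function(object) {
  ecc <- tryCatch(eccentricities(object), error = function(e) NULL)
  cat("MolecularGraph with", numVertices(object), "vertices and",
      numEdges(object), "edges\n")
  if (!is.null(ecc)) {
    cat("  radius:", min(ecc), " diameter:", max(ecc), "\n")
  }
  if (length(object@labels)) {
    cat("  elements:", paste(sort(unique(object@labels)), collapse = " "),
        "\n")
  }
  invisible(object)
})

#' RegressionFit: one property ~ index QSPR model
#'
#' Holds the ordinary-least-squares fit of one physicochemical property on
#' one topological index, either linear (Y = alpha + beta X) or quadratic
#' (Y = alpha + beta X + gamma X^2), together with the overall-model
#' statistics used for significance screening.
#'
#' @slot kind "linear" or "quadratic".
#' @slot alpha intercept.
#' @slot beta linear coefficient.
#' @slot gamma quadratic coefficient (`NA` for linear fits).
#' @slot r multiple correlation, reported non-negative as sqrt(r2).
#' @slot r2 coefficient of determination.
#' @slot f overall F statistic (Inf for a perfect fit).
#' @slot p upper-tail F-test p-value.
#' @slot n sample size.
#'
#' @seealso [fitPropertyModel()], [significance()]
#' @export
setClass("RegressionFit",
  representation(
    kind = "character",
    alpha = "numeric",
    beta = "numeric",
    gamma = "numeric",
    r = "numeric",
    r2 = "numeric",
    f = "numeric",
    p = "numeric",
    n = "integer"
  )
)

setValidity("RegressionFit", function(object) {
  msg <- character()
  if (!object@kind %in% c("linear", "quadratic")) {
    msg <- c(msg, "kind must be 'linear' or 'quadratic'")
  }
  if (object@r2 < -1e-12 || object@r2 > 1 + 1e-12) {
    msg <- c(msg, "r2 outside [0, 1]")
  }
  if (abs(object@r - sqrt(max(object@r2, 0))) > 1e-8) {
    msg <- c(msg, "r must equal sqrt(r2)")
  }
  k <- if (object@kind == "linear") 1L else 2L
  if (object@n <= k + 1L) msg <- c(msg, "n must exceed the coefficient count")
  if (length(msg)) msg else TRUE
})

setMethod("show", "RegressionFit", function(object) {
  eq <- if (object@kind == "linear") {
    sprintf("Y = %.4g + %.4g X", object@alpha, object@beta)
  } else {
    sprintf("Y = %.4g + %.4g X + %.4g X^2",
            object@alpha, object@beta, object@gamma)
  }
  cat(sprintf("%s QSPR fit (n = %d)\n  %s\n", object@kind, object@n, eq))
  cat(sprintf("  r = %.4f, r2 = %.4f, F = %.4g, p = %.4g\n",
              object@r, object@r2, object@f, object@p))
  invisible(object)
})

#' Extract the fitted statistics as a named vector
#'
#' @param fit a \linkS4class{RegressionFit}.
#' @return named numeric vector with elements alpha, beta, gamma, r, r2, f,
#'   p, n.
#' @export
fitStats <- function(fit) {
  stopifnot(is(fit, "RegressionFit"))
  c(alpha = fit@alpha, beta = fit@beta, gamma = fit@gamma,
    r = fit@r, r2 = fit@r2, f = fit@f, p = fit@p, n = as.numeric(fit@n))
}
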