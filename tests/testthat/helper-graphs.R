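# small named graphs used across the suite

makePath <- function(n) {
  molecularGraph(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L))
}

makeCycle <- function(n) {
  molecularGraph(rbind(cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L),
                       c(1L, n)))
}

k2 <- function() makePath(2L)

writeEdgeFile <- function(lines) {
  f <- tempfile(fileext = ".edges")
  writeLines(lines, f)
  f
}

# relabel the vertices of a graph by a permutation of its ids
permuteGraph <- function(g, perm) {
  ids <- vertexIds(g)
  stopifnot(length(perm) == length(ids))
  map <- stats::setNames(perm, ids)
  e <- edgeMatrix(g)
  molecularGraph(cbind(map[as.character(e[, 1])],
                       map[as.character(e[, 2])]),
                 vertexIds = perm)
}
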