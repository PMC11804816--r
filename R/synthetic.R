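## Synthetic data: chemical-like random graphs, regression datasets, and
## brute-force oracles for property testing.

## run expr under a local RNG state so generators never disturb (or depend
## on) the caller's random stream
.withLocalSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

#' Generate a random chemical-like molecular graph
#'
#' Emulates a hydrogen-suppressed drug skeleton: a random spanning tree grown
#' by uniform attachment under a degree cap, plus `rings` extra edges between
#' non-adjacent vertex pairs that respect the cap. The default cap of 4
#' mimics carbon valence.
#'
#' @param n number of vertices (3 to 60).
#' @param rings number of ring-closing edges (0 to 5).
#' @param maxDegree degree cap (default 4).
#' @param seed integer seed; the generator is deterministic given the seed
#'   and does not touch the global random stream.
#' @return a connected simple \linkS4class{MolecularGraph} with
#'   `n + rings` edges and maximum degree at most `maxDegree`.
#' @examples
#' g <- randomMolecularGraph(12, rings = 2, seed = 1)
#' numEdges(g)  # 13
#' @export
randomMolecularGraph <- function(n, rings = 0, maxDegree = 4, seed = NULL) {
  stopifnot(n >= 3, n <= 60, rings >= 0, rings <= 5, maxDegree >= 2)
  .withLocalSeed(seed, {
    deg <- integer(n)
    edges <- matrix(0L, nrow = n - 1L + rings, ncol = 2L)
    for (v in 2:n) {
      open <- which(deg[seq_len(v - 1L)] < maxDegree)
      if (length(open) == 0L) {
        stop("infeasible: degree cap ", maxDegree,
             " cannot accommodate ", n, " vertices")
      }
      u <- open[sample.int(length(open), 1L)]
      edges[v - 1L, ] <- c(min(u, v), max(u, v))
      deg[u] <- deg[u] + 1L
      deg[v] <- deg[v] + 1L
    }
    if (rings > 0) {
      key <- paste(edges[seq_len(n - 1L), 1L], edges[seq_len(n - 1L), 2L])
      cand <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      for (r in seq_len(rings)) {
        ok <- deg[cand[, 1L]] < maxDegree & deg[cand[, 2L]] < maxDegree &
          !(paste(cand[, 1L], cand[, 2L]) %in% key)
        pool <- which(ok)
        if (length(pool) == 0L) {
          stop("infeasible: no non-adjacent pair left under degree cap ",
               maxDegree, " for ring edge ", r)
        }
        pick <- cand[pool[sample.int(length(pool), 1L)], ]
        edges[n - 1L + r, ] <- as.integer(pick)
        deg[pick[1L]] <- deg[pick[1L]] + 1L
        deg[pick[2L]] <- deg[pick[2L]] + 1L
        key <- c(key, paste(pick[1L], pick[2L]))
      }
    }
    molecularGraph(edges, vertexIds = seq_len(n))
  })
}

#' Floyd-Warshall all-pairs distance oracle
#'
#' An independent brute-force check of the breadth-first-search distances:
#' the classic O(n^3) dynamic program, sharing no code with
#' [distanceMatrix()].
#'
#' @param g a connected \linkS4class{MolecularGraph}.
#' @return square numeric matrix of shortest-path lengths with vertex-id
#'   dimnames.
#' @export
floydWarshallOracle <- function(g) {
  v <- vertexIds(g)
  n <- length(v)
  d <- matrix(Inf, n, n, dimnames = list(as.character(v), as.character(v)))
  diag(d) <- 0
  e <- match(edgeMatrix(g), v)
  dim(e) <- c(numEdges(g), 2L)
  d[e] <- 1
  d[e[, 2:1, drop = FALSE]] <- 1
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], `+`))
  }
  if (any(!is.finite(d))) stop("graph is disconnected")
  d
}

#' Generate a synthetic regression dataset
#'
#' Draws x uniformly on `xRange` and sets
#' y = alpha + beta x + gamma x^2 + N(0, noiseSd^2), emulating the
#' property ~ index model forms for parameter-recovery tests. The default
#' `xRange` of (0, 35) spans the scale of the GA4 index across the drug set.
#'
#' @param n number of observations (>= 10).
#' @param alpha,beta,gamma true coefficients (`gamma = 0` gives a linear
#'   truth).
#' @param noiseSd standard deviation of the additive Gaussian noise (>= 0).
#' @param seed integer seed; deterministic given the seed.
#' @param xRange length-2 numeric interval for the uniform predictor.
#' @return list with numeric vectors `x` and `y` of length `n`.
#' @export
randomRegressionData <- function(n, alpha, beta, gamma = 0, noiseSd = 1,
                                 seed = NULL, xRange = c(0, 35)) {
  stopifnot(n >= 10, noiseSd >= 0, length(xRange) == 2L,
            xRange[1L] < xRange[2L])
  .withLocalSeed(seed, {
    x <- stats::runif(n, xRange[1L], xRange[2L])
    y <- alpha + beta * x + gamma * x^2 +
      stats::rnorm(n, sd = noiseSd)
    list(x = x, y = y)
  })
}
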