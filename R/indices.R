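## Eccentricity-based topological indices.
##
## All index formulas are evaluated on the eccentricity partitions rather
## than edge by edge; the two views are equivalent because every per-edge
## term depends only on the endpoint eccentricities.
##
## Two conventions are supported. "standard" follows the literature
## definitions of the second Zagreb eccentricity index (sum over vertices of
## squared eccentricity) and the eccentric ABC index (square root over the
## whole per-edge ratio). "paper_faithful" reproduces the arithmetic used in
## the published worked example and Table 2 for the thirteen
## anti-schizophrenia drugs: the second Zagreb index squares each class sum
## (count x eccentricity), and the ABC root covers the numerator only. The
## other six indices are identical under both conventions.

.conventions <- c("standard", "paper_faithful")

.checkConvention <- function(convention) {
  match.arg(convention, .conventions)
}

#' Total eccentricity index
#'
#' Sum of all vertex eccentricities, zeta(G).
#'
#' @param ecc integer eccentricity vector as returned by [eccentricities()].
#' @return integer-valued numeric scalar.
#' @examples
#' totalEccentricity(eccentricities(chlorpromazineGraph()))  # 156
#' @export
totalEccentricity <- function(ecc) {
  stopifnot(length(ecc) > 0L)
  sum(as.numeric(ecc))
}

#' Average eccentricity index
#'
#' Mean vertex eccentricity, avec(G) = zeta(G) / n.
#'
#' @inheritParams totalEccentricity
#' @return numeric scalar.
#' @export
averageEccentricity <- function(ecc) {
  totalEccentricity(ecc) / length(ecc)
}

#' First Zagreb eccentricity index (M1*)
#'
#' Sum over edges of the endpoint eccentricity sums. Equals
#' sum over vertices of degree(v) * eccentricity(v).
#'
#' @param edgePart edge eccentricity partition as returned by
#'   [edgeEccPartition()].
#' @return integer-valued numeric scalar.
#' @export
firstZagrebEcc <- function(edgePart) {
  sum(edgePart$count * (edgePart$ecc1 + edgePart$ecc2))
}

#' Second Zagreb eccentricity index (M1**)
#'
#' Under the `standard` convention this is the vertex sum of squared
#' eccentricities. Under `paper_faithful` it is the sum over eccentricity
#' classes of the squared class totals (count x eccentricity)^2, which is
#' the arithmetic behind the published drug table; unlike the standard form
#' it is a function of the eccentricity partition, not vertex-additive.
#'
#' @param ecc integer eccentricity vector.
#' @param part vertex eccentricity partition of `ecc`; computed if missing.
#' @param convention `"standard"` or `"paper_faithful"`.
#' @return numeric scalar.
#' @examples
#' ecc <- eccentricities(chlorpromazineGraph())
#' secondZagrebEcc(ecc)                                # 1192
#' secondZagrebEcc(ecc, convention = "paper_faithful") # 5978
#' @export
secondZagrebEcc <- function(ecc, part = vertexEccPartition(ecc),
                            convention = "standard") {
  convention <- .checkConvention(convention)
  if (convention == "standard") {
    sum(as.numeric(ecc)^2)
  } else {
    k <- as.numeric(names(part))
    sum((as.numeric(part) * k)^2)
  }
}

#' Third Zagreb eccentricity index (M2*)
#'
#' Sum over edges of the endpoint eccentricity products.
#'
#' @inheritParams firstZagrebEcc
#' @return integer-valued numeric scalar.
#' @export
thirdZagrebEcc <- function(edgePart) {
  sum(edgePart$count * edgePart$ecc1 * edgePart$ecc2)
}

#' Eccentric geometric-arithmetic index (GA4)
#'
#' Sum over edges of 2 * sqrt(ecc(u) * ecc(v)) / (ecc(u) + ecc(v)). Each
#' term lies in (0, 1], with equality exactly when the endpoint
#' eccentricities agree, so GA4 <= m.
#'
#' @inheritParams firstZagrebEcc
#' @return numeric scalar.
#' @export
geometricArithmeticEcc <- function(edgePart) {
  with(edgePart, sum(count * 2 * sqrt(ecc1 * ecc2) / (ecc1 + ecc2)))
}

#' Eccentric atom-bond-connectivity index
#'
#' Under the `standard` convention the per-edge term is
#' sqrt((ecc(u) + ecc(v) - 2) / (ecc(u) * ecc(v))). Under `paper_faithful`
#' the square root covers the numerator only,
#' sqrt(ecc(u) + ecc(v) - 2) / (ecc(u) * ecc(v)), matching the published
#' worked example. For eccentricities >= 1 the paper-faithful term never
#' exceeds the standard one.
#'
#' @inheritParams firstZagrebEcc
#' @param convention `"standard"` or `"paper_faithful"`.
#' @return non-negative numeric scalar (0 for a single-edge graph).
#' @export
atomBondConnectivityEcc <- function(edgePart, convention = "standard") {
  convention <- .checkConvention(convention)
  num <- edgePart$ecc1 + edgePart$ecc2 - 2
  den <- edgePart$ecc1 * edgePart$ecc2
  if (convention == "standard") {
    sum(edgePart$count * sqrt(num / den))
  } else {
    sum(edgePart$count * sqrt(num) / den)
  }
}

#' Eccentric harmonic index (He)
#'
#' Sum over edges of 2 / (ecc(u) + ecc(v)).
#'
#' @inheritParams firstZagrebEcc
#' @return positive numeric scalar, at most m / radius.
#' @export
eccentricHarmonic <- function(edgePart) {
  with(edgePart, sum(count * 2 / (ecc1 + ecc2)))
}

#' Degree-based harmonic index
#'
#' Sum over edges of 2 / (deg(u) + deg(v)). Provided for completeness; it is
#' a degree (not eccentricity) descriptor and does not enter the QSPR index
#' set.
#'
#' @param g a \linkS4class{MolecularGraph}.
#' @return positive numeric scalar.
#' @export
harmonicDegree <- function(g) {
  d <- vertexDegrees(g)
  e <- edgeMatrix(g)
  du <- d[as.character(e[, 1L])]
  dv <- d[as.character(e[, 2L])]
  sum(2 / (du + dv))
}

#' Compute all eight eccentric indices of a molecular graph
#'
#' Runs one eccentricity computation and evaluates the full index set:
#' zeta, avec, M1*, M1**, M2*, GA4, eccentric ABC, and He.
#'
#' @param g a connected \linkS4class{MolecularGraph}.
#' @param convention `"standard"` (default) or `"paper_faithful"`; affects
#'   only M1** (`m1_dstar`) and the eccentric ABC index.
#' @return one-row data.frame with columns `n`, `m`, `zeta`, `avec`,
#'   `m1_star`, `m1_dstar`, `m2_star`, `ga4`, `abc`, `he`, `convention`.
#' @examples
#' computeIndices(chlorpromazineGraph(), convention = "paper_faithful")
#' @export
computeIndices <- function(g, convention = "standard") {
  convention <- .checkConvention(convention)
  ecc <- eccentricities(g)
  vp <- vertexEccPartition(ecc)
  ep <- edgeEccPartition(g, ecc)
  data.frame(
    n = numVertices(g),
    m = numEdges(g),
    zeta = totalEccentricity(ecc),
    avec = averageEccentricity(ecc),
    m1_star = firstZagrebEcc(ep),
    m1_dstar = secondZagrebEcc(ecc, vp, convention),
    m2_star = thirdZagrebEcc(ep),
    ga4 = geometricArithmeticEcc(ep),
    abc = atomBondConnectivityEcc(ep, convention),
    he = eccentricHarmonic(ep),
    convention = convention,
    stringsAsFactors = FALSE
  )
}

## canonical column order shared by computeIndices() and the fixtures
.indexColumns <- c("zeta", "avec", "m1_star", "m1_dstar", "m2_star",
                   "ga4", "abc", "he")
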