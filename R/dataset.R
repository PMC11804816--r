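## Curated dataset: thirteen anti-schizophrenia drugs (labelled a..m).
##
## The property and index tables are stored verbatim as published, including
## internal inconsistencies; validateConsistency() audits them rather than
## correcting them. A handful of cells whose digit grouping was ambiguous in
## the available rendering of the source tables are flagged in
## fixtureFlags().

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "eccQSPR", mustWork = TRUE)
  path
}

#' Physicochemical properties of the thirteen anti-schizophrenia drugs
#'
#' Boiling point `BP` (deg C), melting point `MP` (deg C), enthalpy of
#' vaporisation `E` (kJ/mol), flash point `FP` (deg C), molar refractivity
#' `MR` (cm^3), complexity `C` (unitless), molecular weight `MW` (g/mol) and
#' refractive index `R` (as published; the published values, ~90-140, are
#' not on the usual dimensionless refractive-index scale and are used as
#' printed). Drugs are labelled `a` to `m`.
#'
#' @return 13-row data.frame with columns `drug`, `BP`, `MP`, `E`, `FP`,
#'   `MR`, `C`, `MW`, `R`.
#' @seealso [fixtureFlags()] for cells with ambiguous transcription.
#' @export
drugProperties <- function() {
  utils::read.csv(.extdata("drug_properties.csv"), stringsAsFactors = FALSE)
}

#' Published eccentric index values of the thirteen drugs
#'
#' The index table as published (paper-faithful convention for `m1_dstar`
#' and `abc`), anomalies included; see [validateConsistency()].
#'
#' @return 13-row data.frame with columns `drug`, `zeta`, `avec`, `m1_star`,
#'   `m1_dstar`, `m2_star`, `ga4`, `abc`, `he`.
#' @export
paperIndices <- function() {
  utils::read.csv(.extdata("paper_indices.csv"), stringsAsFactors = FALSE)
}

#' Published index-property correlation tables
#'
#' The published 8 x 8 comparison matrices of correlation coefficients r,
#' one per model kind, stored as printed.
#'
#' @param model `"linear"` or `"quadratic"`.
#' @return numeric matrix with index rownames and property colnames.
#' @export
paperCorrelations <- function(model = c("linear", "quadratic")) {
  model <- match.arg(model)
  df <- utils::read.csv(.extdata(sprintf("paper_correlations_%s.csv", model)),
                        stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L])
  rownames(m) <- df$index
  m
}

#' Transcription flags for ambiguous fixture cells
#'
#' @return data.frame with columns `table`, `drug`, `cell`, `note`.
#' @export
fixtureFlags <- function() {
  utils::read.csv(.extdata("fixture_flags.csv"), stringsAsFactors = FALSE)
}

#' The chlorpromazine heavy-atom graph
#'
#' Chlorpromazine (drug `a`) is the one drug whose full structure is worked
#' through in the source: a phenothiazine tricycle with a chlorine
#' substituent and a dimethylaminopropyl side chain, 21 heavy atoms and 23
#' bonds. Built from the embedded edge list; no cheminformatics backend is
#' required.
#'
#' @return a \linkS4class{MolecularGraph} with n = 21, m = 23.
#' @export
chlorpromazineGraph <- function() {
  readEdgeList(.extdata("chlorpromazine.edges"))
}

#' The full chlorpromazine fixture
#'
#' Bundles the graph, its SMILES string, and the published eccentricity
#' partitions so tests can compare the computed structure against the
#' printed one rather than trusting either alone.
#'
#' @return list with elements `graph` (\linkS4class{MolecularGraph}),
#'   `smiles` (character), `vertex_partition` (named integer vector:
#'   eccentricity -> vertex count) and `edge_partition` (data.frame with
#'   columns `ecc1`, `ecc2`, `count`).
#' @export
chlorpromazineFixture <- function() {
  list(
    graph = chlorpromazineGraph(),
    smiles = "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
    vertex_partition = c(`5` = 2L, `6` = 3L, `7` = 5L, `8` = 6L, `9` = 5L),
    edge_partition = data.frame(
      ecc1 = c(5L, 5L, 6L, 7L, 8L),
      ecc2 = c(5L, 6L, 7L, 8L, 9L),
      count = c(1L, 3L, 5L, 7L, 7L)
    )
  )
}

#' Audit the published tables for internal inconsistencies
#'
#' Checks, on the embedded fixtures:
#' \itemize{
#'   \item `avec` consistency: zeta / avec must be (close to) an integer
#'     vertex count for every drug;
#'   \item the edge eccentricity adjacency rule |ecc1 - ecc2| <= 1 on the
#'     published chlorpromazine edge partition;
#'   \item the nested-model ordering: the quadratic correlation must be at
#'     least the linear correlation in the published comparison tables
#'     (violations indicate transcription errors in the source).
#' }
#' Nothing is corrected; the report simply lists violations.
#'
#' @param tol how far zeta / avec may sit from an integer before being
#'   flagged (default 0.01, generous for 4-decimal rounding of avec).
#' @return data.frame with columns `check`, `where`, `detail`; zero rows if
#'   no anomaly is found.
#' @examples
#' validateConsistency()
#' @export
validateConsistency <- function(tol = 0.01) {
  anomalies <- list()
  addAnomaly <- function(check, where, detail) {
    anomalies[[length(anomalies) + 1L]] <<-
      data.frame(check = check, where = where, detail = detail,
                 stringsAsFactors = FALSE)
  }

  idx <- paperIndices()
  nImplied <- idx$zeta / idx$avec
  off <- abs(nImplied - round(nImplied))
  for (i in which(off > tol)) {
    addAnomaly("avec_integer_n", idx$drug[i],
               sprintf("zeta = %g with avec = %g implies n = %.4f (not an integer)",
                       idx$zeta[i], idx$avec[i], nImplied[i]))
  }

  ep <- chlorpromazineFixture()$edge_partition
  for (i in which(abs(ep$ecc1 - ep$ecc2) > 1L)) {
    addAnomaly("edge_ecc_adjacency", "chlorpromazine",
               sprintf("edge class (%d, %d) violates |ecc1 - ecc2| <= 1",
                       ep$ecc1[i], ep$ecc2[i]))
  }

  lin <- paperCorrelations("linear")
  quad <- paperCorrelations("quadratic")
  bad <- which(quad < lin, arr.ind = TRUE)
  for (i in seq_len(nrow(bad))) {
    ix <- rownames(lin)[bad[i, 1L]]
    pr <- colnames(lin)[bad[i, 2L]]
    addAnomaly("nested_r_ordering", paste(ix, pr, sep = "~"),
               sprintf("published quadratic r = %.4f below linear r = %.4f",
                       quad[bad[i, 1L], bad[i, 2L]],
                       lin[bad[i, 1L], bad[i, 2L]]))
  }

  if (length(anomalies)) {
    do.call(rbind, anomalies)
  } else {
    data.frame(check = character(), where = character(),
               detail = character(), stringsAsFactors = FALSE)
  }
}
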