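## Pipeline conveniences behind the command-line script: batch index tables
## and the published-vs-recomputed reproduction report.

#' Index table for a batch of molecular graphs
#'
#' @param graphs a named list of \linkS4class{MolecularGraph} objects; names
#'   become the `drug` id column (unnamed lists get `g1`, `g2`, ...).
#' @param convention index convention passed to [computeIndices()].
#' @return data.frame with one row per graph: `drug`, `n`, `m`, the eight
#'   index columns, and `convention`; the layout of [paperIndices()] plus
#'   size columns, ready for `write.csv()`.
#' @examples
#' indicesTable(list(a = chlorpromazineGraph()), convention = "paper_faithful")
#' @export
indicesTable <- function(graphs, convention = "standard") {
  if (length(graphs) == 0L) stop("no input graphs")
  ids <- names(graphs)
  if (is.null(ids) || any(!nzchar(ids))) {
    ids <- paste0("g", seq_along(graphs))
  }
  rows <- lapply(graphs, computeIndices, convention = convention)
  out <- do.call(rbind, rows)
  cbind(drug = ids, out, stringsAsFactors = FALSE)
}

#' Reproduce the published results from the embedded fixtures
#'
#' Recomputes, deterministically and without any external input:
#' \itemize{
#'   \item the chlorpromazine worked example (all eight indices, both
#'     conventions) side by side with the published row;
#'   \item the full 8 x 8 linear and quadratic correlation tables from the
#'     published index and property tables, side by side with the published
#'     comparison matrices;
#'   \item the complexity ~ GA4 fits, the one published combination that
#'     passes the p and F screens;
#'   \item the [validateConsistency()] anomaly report.
#' }
#'
#' @param dir optional output directory; when given, the report is also
#'   written as CSV/JSON files (`worked_example.csv`,
#'   `correlations_<model>_recomputed.csv`, `anomalies.csv`,
#'   `summary.json`).
#' @return (invisibly when `dir` is given) a list with elements
#'   `worked_example`, `correlations`, `ga4_complexity`, `anomalies`.
#' @export
reproduceReport <- function(dir = NULL) {
  fixture <- chlorpromazineFixture()
  printed <- paperIndices()
  rowA <- printed[printed$drug == "a", .indexColumns]

  recomputed <- lapply(c(paper_faithful = "paper_faithful",
                         standard = "standard"),
                       function(cv) {
    unlist(computeIndices(fixture$graph, convention = cv)[, .indexColumns])
  })
  worked <- data.frame(
    index = .indexColumns,
    published = as.numeric(rowA),
    paper_faithful = round(as.numeric(recomputed$paper_faithful), 4),
    standard = round(as.numeric(recomputed$standard), 4),
    stringsAsFactors = FALSE
  )

  props <- drugProperties()
  correlations <- lapply(c(linear = "linear", quadratic = "quadratic"),
                         function(model) {
    list(published = paperCorrelations(model),
         recomputed = correlationTable(printed, props, model))
  })

  ga4c <- lapply(c(linear = "linear", quadratic = "quadratic"),
                 function(model) {
    fit <- fitPropertyModel(printed$ga4, props$C, model)
    c(fitStats(fit), significance(fit))
  })

  report <- list(
    worked_example = worked,
    correlations = correlations,
    ga4_complexity = ga4c,
    anomalies = validateConsistency()
  )

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    utils::write.csv(worked, file.path(dir, "worked_example.csv"),
                     row.names = FALSE)
    for (model in names(correlations)) {
      utils::write.csv(
        correlations[[model]]$recomputed,
        file.path(dir, sprintf("correlations_%s_recomputed.csv", model))
      )
      utils::write.csv(
        correlations[[model]]$published,
        file.path(dir, sprintf("correlations_%s_published.csv", model))
      )
    }
    utils::write.csv(report$anomalies, file.path(dir, "anomalies.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(worked_example = worked, ga4_complexity = ga4c,
           n_anomalies = nrow(report$anomalies)),
      file.path(dir, "summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
    return(invisible(report))
  }
  report
}

#' Export a batch of QSPR fits as JSON records
#'
#' @param fits data.frame from [fitAllModels()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeFitsJSON <- function(fits, path) {
  jsonlite::write_json(fits, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
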