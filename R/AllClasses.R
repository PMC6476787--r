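## S4 containers for survey data and metacommunity statistics.

#' Binary plot x species community matrix with plot metadata
#'
#' Rows are 1 m^2 survey plots, columns are species; entries are 0/1
#' incidences. \code{plotData} carries one row per plot with the sampling
#' hierarchy (\code{mountain}, \code{transect}, \code{station}, \code{plot})
#' and \code{altitude_m}.
#'
#' @slot incidence binary integer matrix, plots x species. Column names are
#'   species labels, row names plot identifiers.
#' @slot plotData data.frame aligned with the rows of \code{incidence};
#'   must contain columns \code{mountain}, \code{transect}, \code{station},
#'   \code{plot} and \code{altitude_m}.
#'
#' @seealso [buildCommunityMatrix()], [readCommunityMatrix()]
#' @exportClass CommunityMatrix
setClass("CommunityMatrix",
  slots = c(incidence = "matrix", plotData = "data.frame"))

.requiredPlotCols <- c("mountain", "transect", "station", "plot", "altitude_m")

setValidity("CommunityMatrix", function(object) {
  inc <- object@incidence
  pd <- object@plotData
  msgs <- character()
  if (!is.numeric(inc))
    msgs <- c(msgs, "incidence must be numeric")
  else if (length(inc) && !all(inc %in% c(0, 1)))
    msgs <- c(msgs, "incidence entries must be 0 or 1")
  if (nrow(pd) != nrow(inc))
    msgs <- c(msgs, "plotData must have one row per incidence row")
  miss <- setdiff(.requiredPlotCols, names(pd))
  if (length(miss))
    msgs <- c(msgs, paste0("plotData lacks column(s): ",
                           paste(miss, collapse = ", ")))
  if (is.null(colnames(inc)) && ncol(inc) > 0)
    msgs <- c(msgs, "incidence must have species column names")
  if (anyDuplicated(colnames(inc)))
    msgs <- c(msgs, "duplicate species columns")
  if (anyDuplicated(rownames(inc)))
    msgs <- c(msgs, "duplicate plot row names")
  if ("altitude_m" %in% names(pd) && any(!is.finite(pd$altitude_m) |
                                         pd$altitude_m <= 0))
    msgs <- c(msgs, "altitude_m must be finite and > 0")
  if (length(msgs)) msgs else TRUE
})

#' Construct a CommunityMatrix
#'
#' @param incidence binary matrix (plots x species).
#' @param plotData data.frame with columns \code{mountain}, \code{transect},
#'   \code{station}, \code{plot}, \code{altitude_m}, one row per plot.
#' @return A \code{\linkS4class{CommunityMatrix}}.
#' @export
CommunityMatrix <- function(incidence, plotData) {
  incidence <- as.matrix(incidence)
  storage.mode(incidence) <- "integer"
  plotData <- as.data.frame(plotData)
  if (is.null(rownames(incidence)) && nrow(incidence) == nrow(plotData))
    rownames(incidence) <- plotKeys(plotData)
  rownames(plotData) <- rownames(incidence)
  new("CommunityMatrix", incidence = incidence, plotData = plotData)
}

plotKeys <- function(pd)
  paste(pd$mountain, pd$transect, pd$station, pd$plot, sep = ".")

#' Principal-coordinate embedding of a dissimilarity matrix
#'
#' Classical scaling of a (possibly non-Euclidean) dissimilarity matrix.
#' Positive-eigenvalue axes live in \code{real}, negative-eigenvalue axes in
#' \code{imag}; squared dissimilarities are recovered as the sum of squared
#' coordinate differences on the real axes minus the sum on the imaginary
#' axes.
#'
#' @slot real matrix of coordinates on positive-eigenvalue axes (scaled by
#'   the square root of the eigenvalue).
#' @slot imag matrix of coordinates on negative-eigenvalue axes (scaled by
#'   the square root of the eigenvalue magnitude).
#' @slot eigenvalues all retained eigenvalues, descending.
#' @exportClass PCoAEmbedding
setClass("PCoAEmbedding",
  slots = c(real = "matrix", imag = "matrix", eigenvalues = "numeric"))

#' Row/column ordering of a community matrix
#'
#' @slot rows integer permutation of plot rows.
#' @slot cols integer permutation of species columns.
#' @slot kind one of \code{"optimal_nestedness"}, \code{"optimal_modularity"},
#'   \code{"altitude"}, \code{"altitude_within_mountain"}, \code{"identity"}.
#' @exportClass MatrixOrdering
setClass("MatrixOrdering",
  slots = c(rows = "integer", cols = "integer", kind = "character"))

setValidity("MatrixOrdering", function(object) {
  ok <- function(p) length(p) == 0L || identical(sort(p), seq_along(p))
  if (!ok(object@rows)) return("rows is not a permutation")
  if (!ok(object@cols)) return("cols is not a permutation")
  TRUE
})

#' NODF nestedness of an ordered incidence matrix
#'
#' @slot nodf combined NODF in [0, 100] (pair-count-weighted combination of
#'   the row and column components).
#' @slot nodfRows,nodfCols row-pair and column-pair components.
#' @slot ordering the \code{\linkS4class{MatrixOrdering}} the value was
#'   computed under.
#' @exportClass NestednessResult
setClass("NestednessResult",
  slots = c(nodf = "numeric", nodfRows = "numeric", nodfCols = "numeric",
            ordering = "MatrixOrdering"))

#' Barber modularity of a bipartite incidence matrix
#'
#' @slot Q Barber's Q for the stored bipartition.
#' @slot plotModules,speciesModules named integer module assignments.
#' @slot nModules number of non-empty modules.
#' @slot restartsUsed number of optimisation starts examined.
#' @slot seed RNG seed used by the optimiser.
#' @slot kind \code{"optimal"} or \code{"altitude_constrained"}.
#' @slot bandPartitionQ Q of the raw altitude-band partition (NA when not an
#'   altitude-constrained run).
#' @exportClass ModularityResult
setClass("ModularityResult",
  slots = c(Q = "numeric", plotModules = "integer",
            speciesModules = "integer", nModules = "integer",
            restartsUsed = "integer", seed = "integer", kind = "character",
            bandPartitionQ = "numeric"))

#' Null-model test of a matrix statistic
#'
#' @slot statistic label of the statistic tested.
#' @slot observed observed value on the input matrix.
#' @slot expected mean of the null ensemble.
#' @slot nullSd sample (n-1) standard deviation of the null ensemble.
#' @slot z (observed - expected) / nullSd; NA when nullSd is 0.
#' @slot pEmpirical one-tailed empirical p in the direction of the observed
#'   deviation, with add-one correction: (extreme + 1) / (nReps + 1).
#' @slot direction \code{"above"} or \code{"below"}.
#' @slot nullValues the null ensemble.
#' @slot nReps,seed ensemble size and RNG seed.
#' @exportClass NullTestResult
setClass("NullTestResult",
  slots = c(statistic = "character", observed = "numeric",
            expected = "numeric", nullSd = "numeric", z = "numeric",
            pEmpirical = "numeric", direction = "character",
            nullValues = "numeric", nReps = "integer", seed = "integer"))
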