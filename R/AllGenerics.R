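## Accessor generics and show methods.

#' @rdname CommunityMatrix-class
#' @param x,object a \code{CommunityMatrix}.
#' @export
setGeneric("incidence", function(x) standardGeneric("incidence"))

#' @rdname CommunityMatrix-class
#' @export
setMethod("incidence", "CommunityMatrix", function(x) x@incidence)

#' @rdname CommunityMatrix-class
#' @export
setGeneric("plotData", function(x) standardGeneric("plotData"))

#' @rdname CommunityMatrix-class
#' @export
setMethod("plotData", "CommunityMatrix", function(x) x@plotData)

#' @rdname CommunityMatrix-class
#' @export
setGeneric("speciesNames", function(x) standardGeneric("speciesNames"))

#' @rdname CommunityMatrix-class
#' @export
setMethod("speciesNames", "CommunityMatrix", function(x) colnames(x@incidence))

#' Per-plot species richness (row sums)
#' @rdname CommunityMatrix-class
#' @export
setGeneric("plotRichness", function(x) standardGeneric("plotRichness"))

#' @rdname CommunityMatrix-class
#' @export
setMethod("plotRichness", "CommunityMatrix",
          function(x) rowSums(x@incidence))

#' Per-species occurrence frequency (column sums)
#' @rdname CommunityMatrix-class
#' @export
setGeneric("speciesFrequencies",
           function(x) standardGeneric("speciesFrequencies"))

#' @rdname CommunityMatrix-class
#' @export
setMethod("speciesFrequencies", "CommunityMatrix",
          function(x) colSums(x@incidence))

setMethod("dim", "CommunityMatrix", function(x) dim(x@incidence))

#' Subset a CommunityMatrix by plots
#'
#' @param x a \code{CommunityMatrix}.
#' @param i plot (row) index: integer, logical, or row-name character vector.
#' @param dropEmptySpecies drop species with zero occurrences in the subset
#'   (default TRUE; set FALSE to keep the full species set, e.g. for
#'   round-tripping externally supplied matrices).
#' @return A \code{CommunityMatrix} on the selected plots.
#' @export
subsetPlots <- function(x, i, dropEmptySpecies = TRUE) {
  stopifnot(is(x, "CommunityMatrix"))
  inc <- x@incidence[i, , drop = FALSE]
  pd <- x@plotData[i, , drop = FALSE]
  if (dropEmptySpecies && ncol(inc))
    inc <- inc[, colSums(inc) > 0, drop = FALSE]
  new("CommunityMatrix", incidence = inc, plotData = pd)
}

setMethod("show", "CommunityMatrix", function(object) {
  inc <- object@incidence
  cat(sprintf("CommunityMatrix: %d plots x %d species\n",
              nrow(inc), ncol(inc)))
  if (length(inc)) {
    cat(sprintf("  fill: %d presences (%.1f%%)\n", sum(inc),
                100 * mean(inc)))
    alt <- object@plotData$altitude_m
    cat(sprintf("  altitude: %.0f-%.0f m; %d mountain(s), %d transect(s), %d station(s)\n",
                min(alt), max(alt),
                length(unique(object@plotData$mountain)),
                length(unique(paste(object@plotData$mountain,
                                    object@plotData$transect))),
                length(unique(paste(object@plotData$mountain,
                                    object@plotData$transect,
                                    object@plotData$station)))))
  }
  invisible(NULL)
})

setMethod("show", "PCoAEmbedding", function(object) {
  cat(sprintf("PCoAEmbedding: %d items, %d real + %d imaginary axes\n",
              nrow(object@real), ncol(object@real), ncol(object@imag)))
  invisible(NULL)
})

setMethod("show", "NestednessResult", function(object) {
  cat(sprintf("NODF = %.2f (rows %.2f, cols %.2f) under '%s' ordering\n",
              object@nodf, object@nodfRows, object@nodfCols,
              object@ordering@kind))
  invisible(NULL)
})

setMethod("show", "ModularityResult", function(object) {
  cat(sprintf("Barber Q = %.4f with %d modules (%s; %d starts, seed %d)\n",
              object@Q, object@nModules, object@kind, object@restartsUsed,
              object@seed))
  if (!is.na(object@bandPartitionQ))
    cat(sprintf("  altitude-band partition Q = %.4f\n",
                object@bandPartitionQ))
  invisible(NULL)
})

setMethod("show", "NullTestResult", function(object) {
  z <- if (is.na(object@z)) "NA (degenerate null)" else
    sprintf("%.3f", object@z)
  cat(sprintf("%s: obs %.4f vs null %.4f +/- %.4f (n = %d)\n",
              object@statistic, object@observed, object@expected,
              object@nullSd, object@nReps))
  cat(sprintf("  Z = %s, empirical p = %.4g (%s)\n", z, object@pEmpirical,
              object@direction))
  invisible(NULL)
})
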