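## NODF nestedness and matrix orderings.

.asIncidence <- function(x) {
  if (is(x, "CommunityMatrix")) incidence(x) else {
    m <- as.matrix(x)
    if (length(m) && !all(m %in% c(0, 1))) stop("matrix must be binary")
    m
  }
}

#' Identity (as-supplied) ordering
#'
#' @param x a \code{CommunityMatrix} or binary matrix.
#' @return A \code{\linkS4class{MatrixOrdering}} leaving rows and columns
#'   as supplied.
#' @export
identityOrdering <- function(x) {
  m <- .asIncidence(x)
  new("MatrixOrdering", rows = seq_len(nrow(m)), cols = seq_len(ncol(m)),
      kind = "identity")
}

#' Apply a row/column ordering
#'
#' @param x a \code{CommunityMatrix} or binary matrix.
#' @param ordering a \code{\linkS4class{MatrixOrdering}}.
#' @return permuted binary matrix.
#' @export
applyOrdering <- function(x, ordering) {
  m <- .asIncidence(x)
  m[ordering@rows, ordering@cols, drop = FALSE]
}

#' Optimal nestedness ordering
#'
#' Rows by decreasing species richness, columns by decreasing occurrence
#' frequency; ties keep input order (stable).
#'
#' @param x a \code{CommunityMatrix} or binary matrix.
#' @return A \code{\linkS4class{MatrixOrdering}} of kind
#'   \code{"optimal_nestedness"}.
#' @export
optimalNestednessOrdering <- function(x) {
  m <- .asIncidence(x)
  new("MatrixOrdering",
      rows = order(-rowSums(m)), cols = order(-colSums(m)),
      kind = "optimal_nestedness")
}

#' Altitude-imposed row ordering
#'
#' Rows ascending by altitude (ties broken by transect then plot label);
#' with \code{withinMountain = TRUE} mountains keep their input order and
#' rows ascend by altitude inside each. Columns are by decreasing frequency
#' in both cases.
#'
#' @param x a \code{CommunityMatrix} (altitudes come from its plot
#'   metadata).
#' @param withinMountain sort by altitude within each mountain.
#' @param descending sort altitude descending instead (diagnostic; the
#'   default reported direction is ascending).
#' @return A \code{\linkS4class{MatrixOrdering}}.
#' @export
altitudeOrdering <- function(x, withinMountain = FALSE,
                             descending = FALSE) {
  stopifnot(is(x, "CommunityMatrix"))
  pd <- plotData(x)
  if (is.null(pd$altitude_m) || anyNA(pd$altitude_m))
    stop("altitudes missing from plot metadata")
  alt <- if (descending) -pd$altitude_m else pd$altitude_m
  rows <- if (withinMountain) {
    mf <- factor(pd$mountain, levels = unique(pd$mountain))
    order(as.integer(mf), alt, pd$transect, pd$plot)
  } else {
    order(alt, pd$transect, pd$plot)
  }
  new("MatrixOrdering", rows = rows,
      cols = order(-colSums(incidence(x))),
      kind = if (withinMountain) "altitude_within_mountain" else "altitude")
}

.nodfPairs <- function(m) {
  ## sum of pair contributions down the rows of m (as ordered)
  f <- rowSums(m)
  n <- nrow(m)
  if (n < 2) return(c(sum = 0, pairs = 0))
  O <- tcrossprod(m)
  ## pair (i above j): contributes 100 * overlap / f_j when f_j < f_i, f_j > 0
  cond <- outer(f, f, function(fi, fj) fj < fi & fj > 0)
  P <- 100 * sweep(O, 2, pmax(f, 1), "/") * cond
  c(sum = sum(P[upper.tri(P)]), pairs = n * (n - 1) / 2)
}

#' NODF nestedness (overlap and decreasing fill)
#'
#' For each ordered row pair (i above j) the contribution is 100 x
#' |overlap| / fill(j) when fill(j) < fill(i) and fill(j) > 0, else 0;
#' likewise for column pairs left-to-right. The combined NODF divides the
#' summed contributions by the total number of row plus column pairs, giving
#' a value in [0, 100] (0 = no nestedness, 100 = perfectly nested). Because
#' NODF depends on matrix fill it should be interpreted against a null model
#' (see [nullTest()]).
#'
#' Zero-fill rows/columns contribute 0 to every pair they appear in rather
#' than being dropped, keeping plot counts consistent across statistics.
#'
#' @param x a \code{CommunityMatrix} or binary matrix.
#' @param ordering a \code{\linkS4class{MatrixOrdering}}; default is the
#'   optimal (richness/frequency) sorting.
#' @return A \code{\linkS4class{NestednessResult}}.
#' @export
nodf <- function(x, ordering = optimalNestednessOrdering(x)) {
  m <- applyOrdering(x, ordering)
  if (!sum(m)) stop("all-zero matrix")
  r <- .nodfPairs(m)
  cl <- .nodfPairs(t(m))
  tot <- r[["pairs"]] + cl[["pairs"]]
  new("NestednessResult",
      nodf = if (tot > 0) (r[["sum"]] + cl[["sum"]]) / tot else 0,
      nodfRows = if (r[["pairs"]] > 0) r[["sum"]] / r[["pairs"]] else 0,
      nodfCols = if (cl[["pairs"]] > 0) cl[["sum"]] / cl[["pairs"]] else 0,
      ordering = ordering)
}
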