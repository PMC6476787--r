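## Multi-scale beta diversity: binary Bray-Curtis (Sorensen)
## dissimilarities, principal-coordinate embedding with imaginary axes, and
## per-plot distances to station / transect / landscape (altitude-band)
## centroids.

#' Binary Bray-Curtis (Sorensen) dissimilarity between two species sets
#'
#' 1 - 2|a n b| / (|a| + |b|). Two empty sets are defined as identical
#' (dissimilarity 0) with a warning, so barren high-altitude plots do not
#' break the pipeline.
#'
#' @param a,b character vectors of species labels.
#' @return dissimilarity in [0,1].
#' @export
binaryBrayCurtis <- function(a, b) {
  a <- unique(a[!is.na(a) & nzchar(a)])
  b <- unique(b[!is.na(b) & nzchar(b)])
  if (!length(a) && !length(b)) {
    warning("both species sets empty; dissimilarity defined as 0")
    return(0)
  }
  1 - 2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Pairwise Sorensen dissimilarity matrix of a community matrix
#'
#' Binary Bray-Curtis via \code{vegan::vegdist(..., binary = TRUE)}; pairs
#' of empty plots (undefined) are set to 0 with a warning.
#'
#' @param x a \code{\linkS4class{CommunityMatrix}} or binary matrix.
#' @return symmetric dissimilarity matrix with plot labels.
#' @export
sorensenMatrix <- function(x) {
  inc <- if (is(x, "CommunityMatrix")) incidence(x) else as.matrix(x)
  d <- suppressWarnings(
    as.matrix(vegan::vegdist(inc, method = "bray", binary = TRUE)))
  if (anyNA(d)) {
    warning("empty plots present; their mutual dissimilarities set to 0")
    d[is.na(d)] <- 0
  }
  diag(d) <- 0
  d
}

#' Principal coordinates analysis retaining imaginary axes
#'
#' Gower-centres -D^2/2 and eigendecomposes. Axes with eigenvalue magnitude
#' below 1e-10 of the largest are dropped. For non-Euclidean inputs
#' (e.g. Sorensen) the negative-eigenvalue axes are kept as imaginary
#' coordinates, so squared dissimilarities are reconstructed exactly as
#' (sum of squared real differences) - (sum of squared imaginary
#' differences).
#'
#' @param D symmetric non-negative dissimilarity matrix with zero diagonal.
#' @return A \code{\linkS4class{PCoAEmbedding}}.
#' @export
pcoa <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) != ncol(D) || max(abs(D - t(D))) > 1e-8)
    stop("D must be a symmetric square matrix")
  if (any(D < 0)) stop("D must be non-negative")
  if (max(abs(diag(D))) > 1e-12) stop("D must have a zero diagonal")
  n <- nrow(D)
  A <- -0.5 * D^2
  G <- A - matrix(rowMeans(A), n, n) - matrix(colMeans(A), n, n,
                                              byrow = TRUE) + mean(A)
  e <- eigen((G + t(G)) / 2, symmetric = TRUE)
  lam <- e$values
  thr <- 1e-10 * max(abs(lam), 0)
  keep <- abs(lam) > thr
  lam <- lam[keep]
  vec <- e$vectors[, keep, drop = FALSE]
  pos <- lam > 0
  real <- vec[, pos, drop = FALSE] %*% diag(sqrt(lam[pos]),
                                            sum(pos), sum(pos))
  neg <- lam < 0
  imag <- vec[, neg, drop = FALSE] %*% diag(sqrt(-lam[neg]),
                                            sum(neg), sum(neg))
  rownames(real) <- rownames(imag) <- rownames(D)
  new("PCoAEmbedding", real = real, imag = imag,
      eigenvalues = sort(lam, decreasing = TRUE))
}

#' Squared dissimilarities reconstructed from an embedding
#'
#' @param embedding a \code{PCoAEmbedding}.
#' @return matrix of signed squared dissimilarities.
#' @export
reconstructSquaredDissimilarity <- function(embedding) {
  sq <- function(X) {
    if (!ncol(X)) return(matrix(0, nrow(X), nrow(X)))
    s <- rowSums(X^2)
    outer(s, s, "+") - 2 * tcrossprod(X)
  }
  sq(embedding@real) - sq(embedding@imag)
}

#' Distances from items to group centroids in PCoA space
#'
#' Centroids are per-group arithmetic means in both the real and imaginary
#' coordinates; squared distances are the real part minus the imaginary
#' part, with negative values (possible for non-Euclidean dissimilarities)
#' clamped to zero and flagged.
#'
#' @param embedding a \code{PCoAEmbedding}.
#' @param grouping factor/character vector, one group label per item.
#' @return data.frame with columns \code{plot}, \code{group},
#'   \code{distance}, \code{clamped}.
#' @export
centroidDistances <- function(embedding, grouping) {
  X <- embedding@real
  Y <- embedding@imag
  if (length(grouping) != nrow(X))
    stop("grouping must have one label per embedded item")
  grouping <- as.character(grouping)
  if (anyNA(grouping)) stop("every item needs a group")
  sq <- numeric(nrow(X))
  for (g in unique(grouping)) {
    i <- grouping == g
    cx <- colMeans(X[i, , drop = FALSE])
    cy <- colMeans(Y[i, , drop = FALSE])
    sq[i] <- rowSums(sweep(X[i, , drop = FALSE], 2, cx)^2) -
      rowSums(sweep(Y[i, , drop = FALSE], 2, cy)^2)
  }
  clamped <- sq < 0
  data.frame(plot = rownames(X) %||% seq_len(nrow(X)), group = grouping,
             distance = sqrt(pmax(sq, 0)), clamped = clamped,
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Beta diversity at station, transect and landscape scales
#'
#' One shared PCoA embedding of the full plot x plot Sorensen matrix;
#' per-plot centroid distances are computed for three groupings: the
#' station (very local scale), the transect (1 km scale), and all plots of
#' the same altitude band across mountains (landscape scale).
#'
#' @param x a \code{\linkS4class{CommunityMatrix}}.
#' @param bands altitude-band table (see [defaultBands()]).
#' @return data.frame with columns \code{plot}, \code{scale} (factor:
#'   station < transect < landscape), \code{group}, \code{distance},
#'   \code{clamped}, plus the plot hierarchy and \code{altitude_m} for
#'   downstream models.
#' @export
betaDiversityAllScales <- function(x, bands = defaultBands()) {
  stopifnot(is(x, "CommunityMatrix"))
  pd <- plotData(x)
  emb <- pcoa(sorensenMatrix(x))
  groupings <- list(
    station = paste(pd$mountain, pd$transect, pd$station, sep = "."),
    transect = paste(pd$mountain, pd$transect, sep = "."),
    landscape = as.character(assignBand(pd$altitude_m, bands)))
  out <- lapply(names(groupings), function(sc) {
    tab <- centroidDistances(emb, groupings[[sc]])
    tab$scale <- sc
    cbind(tab, pd[, c("mountain", "transect", "station", "altitude_m")])
  })
  out <- do.call(rbind, out)
  out$scale <- factor(out$scale,
                      levels = c("station", "transect", "landscape"))
  rownames(out) <- NULL
  out[, c("plot", "scale", "group", "distance", "clamped", "mountain",
          "transect", "station", "altitude_m")]
}
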