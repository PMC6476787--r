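## Bipartite modularity: reciprocal-averaging ordination scores, Barber's Q,
## BRIM optimisation, altitude-constrained runs, incidence images.

.bipartiteComponents <- function(m) {
  nr <- nrow(m); nc <- ncol(m)
  compR <- integer(nr); compC <- integer(nc); comp <- 0L
  for (start in seq_len(nr)) {
    if (compR[start]) next
    comp <- comp + 1L
    queue <- start
    while (length(queue)) {
      r <- queue[1]; queue <- queue[-1]
      if (compR[r]) next
      compR[r] <- comp
      for (cc in which(m[r, ] > 0 & compC == 0L)) {
        compC[cc] <- comp
        queue <- c(queue, which(m[, cc] > 0 & compR == 0L))
      }
    }
  }
  list(rows = compR, cols = compC, n = comp)
}

.raComponent <- function(m, maxit = 10000, tol = 1e-12) {
  r <- rowSums(m); cl <- colSums(m); tot <- sum(m)
  std <- function(v, w) {
    v <- v - sum(w * v) / tot
    nrm <- sqrt(sum(w * v^2) / tot)
    if (nrm < 1e-14) return(NULL)
    v / nrm
  }
  x <- std(seq_len(nrow(m)), r)
  if (is.null(x))  # single row: no non-trivial axis
    return(list(row = numeric(nrow(m)), col = numeric(ncol(m))))
  for (it in seq_len(maxit)) {
    y <- drop(crossprod(m, x)) / cl
    x2 <- std(drop(m %*% y) / r, r)
    if (is.null(x2))
      return(list(row = numeric(nrow(m)), col = numeric(ncol(m))))
    if (max(abs(x2 - x)) < tol) { x <- x2; break }
    x <- x2
  }
  y <- drop(crossprod(m, x)) / cl
  y <- y - sum(cl * y) / tot
  nrm <- sqrt(sum(cl * y^2) / tot)
  y <- if (nrm < 1e-14) numeric(ncol(m)) else y / nrm
  list(row = x, col = y)
}

#' Reciprocal-averaging (correspondence analysis) scores
#'
#' First non-trivial correspondence-analysis axis, obtained by iterating
#' mutual weighted averaging of row and column scores (renormalising to
#' zero weighted mean and unit weighted variance each pass) to convergence.
#' The sign is fixed so that the highest-altitude plot (or the first row,
#' for a plain matrix) has a non-negative score. A disconnected incidence
#' graph yields per-component scores, offset so components do not overlap,
#' with a warning.
#'
#' @param x a \code{CommunityMatrix} or binary matrix with no all-zero rows
#'   or columns.
#' @return list with \code{rowScores}, \code{colScores} (named numeric) and
#'   \code{components} (row component ids).
#' @export
reciprocalAveraging <- function(x) {
  m <- .asIncidence(x)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("all-zero rows/columns not allowed in reciprocal averaging")
  comp <- .bipartiteComponents(m)
  if (comp$n > 1)
    warning("incidence graph is disconnected (", comp$n,
            " components); scores computed per component")
  rowScores <- numeric(nrow(m)); colScores <- numeric(ncol(m))
  offset <- 0
  for (ci in seq_len(comp$n)) {
    ri <- comp$rows == ci; cj <- comp$cols == ci
    sc <- .raComponent(m[ri, cj, drop = FALSE])
    lo <- min(sc$row, sc$col, 0)
    rowScores[ri] <- sc$row - lo + offset
    colScores[cj] <- sc$col - lo + offset
    offset <- max(rowScores[ri], colScores[cj]) + 1
  }
  if (comp$n == 1) {  # re-standardise (offset shift is cosmetic otherwise)
    rowScores <- rowScores - sum(rowSums(m) * rowScores) / sum(m)
    colScores <- colScores - sum(colSums(m) * colScores) / sum(m)
    v <- sqrt(sum(rowSums(m) * rowScores^2) / sum(m))
    if (v > 1e-14) rowScores <- rowScores / v
    v <- sqrt(sum(colSums(m) * colScores^2) / sum(m))
    if (v > 1e-14) colScores <- colScores / v
  }
  ref <- if (is(x, "CommunityMatrix"))
    which.max(plotData(x)$altitude_m) else 1L
  if (rowScores[ref] < 0) {
    rowScores <- -rowScores
    colScores <- -colScores
  }
  names(rowScores) <- rownames(m)
  names(colScores) <- colnames(m)
  list(rowScores = rowScores, colScores = colScores,
       components = comp$rows)
}

.alignModules <- function(mods, labels, side) {
  if (!is.null(names(mods)) && !is.null(labels)) {
    if (!all(labels %in% names(mods)))
      stop("module assignment missing for some ", side)
    mods <- mods[labels]
  }
  as.integer(as.factor(mods))  # work with integer ids, shared factor space
}

#' Barber's bipartite modularity Q
#'
#' Q = (1/m) sum_ij (B_ij - k_i d_j / m) [module(i) == module(j)], with m
#' the total number of presences, k_i row sums and d_j column sums. A
#' single shared module gives Q = 0; Q <= 1.
#'
#' @param x a \code{CommunityMatrix} or binary matrix.
#' @param plotModules,speciesModules module labels per plot/species (named
#'   vectors are matched to row/column names; otherwise positional). Labels
#'   live in one shared space across the two sides.
#' @return Q.
#' @export
barberQ <- function(x, plotModules, speciesModules) {
  m <- .asIncidence(x)
  tot <- sum(m)
  if (tot == 0) stop("matrix has no presences")
  g <- if (!is.null(names(plotModules)))
    plotModules[rownames(m)] else plotModules
  h <- if (!is.null(names(speciesModules)))
    speciesModules[colnames(m)] else speciesModules
  stopifnot(length(g) == nrow(m), length(h) == ncol(m))
  k <- rowSums(m); d <- colSums(m)
  Q <- 0
  for (mod in union(unique(g), unique(h))) {
    ri <- which(g == mod); cj <- which(h == mod)
    if (length(ri) && length(cj))
      Q <- Q + sum(m[ri, cj]) - sum(k[ri]) * sum(d[cj]) / tot
  }
  Q / tot
}

## One BRIM run from an initial bipartition with at most k modules.
## Alternates Q-maximising reassignment of plots given species modules and
## vice versa until the Q gain drops below tol; Q never decreases.
.brimSweep <- function(Bt, tot, g, h, k, tol = 1e-10, maxIter = 500) {
  nr <- nrow(Bt); nc <- ncol(Bt)
  H <- matrix(0, nc, k); H[cbind(seq_len(nc), h)] <- 1
  G <- matrix(0, nr, k); G[cbind(seq_len(nr), g)] <- 1
  Q <- sum(G * (Bt %*% H)) / tot
  for (it in seq_len(maxIter)) {
    Tmat <- Bt %*% H
    g <- max.col(Tmat, ties.method = "first")
    G <- matrix(0, nr, k); G[cbind(seq_len(nr), g)] <- 1
    S <- crossprod(Bt, G)
    h <- max.col(S, ties.method = "first")
    H <- matrix(0, nc, k); H[cbind(seq_len(nc), h)] <- 1
    Qnew <- sum(S[cbind(seq_len(nc), h)]) / tot
    if (Qnew - Q < tol) { Q <- max(Q, Qnew); break }
    Q <- Qnew
  }
  list(Q = Q, g = g, h = h)
}

#' Maximise Barber's Q with the BRIM algorithm
#'
#' Alternating assignment sweeps (fix plot modules, place each species in
#' its Q-maximising module, then the converse) from multiple starts:
#' \code{nRestarts} random bipartitions, one start binning
#' reciprocal-averaging scores into modules, and an optional supplied
#' initial partition. The allowed module count is searched adaptively
#' (start at 2, double while the best Q improves, then bisect), capped at
#' \code{min(rows, cols, 30)}. Deterministic under a fixed seed.
#'
#' @param x a \code{CommunityMatrix} or binary matrix.
#' @param nRestarts random starts per module count.
#' @param seed RNG seed.
#' @param init optional list(g = plot modules, h = species modules) extra
#'   start.
#' @param kind stored result label.
#' @param bandPartitionQ stored Q of a reference partition (used by
#'   [altitudeConstrainedModularity()]).
#' @return A \code{\linkS4class{ModularityResult}}.
#' @export
brimOptimize <- function(x, nRestarts = 20, seed = 1L, init = NULL,
                         kind = "optimal", bandPartitionQ = NA_real_) {
  m <- .asIncidence(x)
  tot <- sum(m)
  if (tot == 0) stop("matrix has no presences")
  nr <- nrow(m); nc <- ncol(m)
  k <- rowSums(m); d <- colSums(m)
  Bt <- m - outer(k, d) / tot
  cap <- min(nr, nc, 30L)
  set.seed(seed)
  ra <- tryCatch(suppressWarnings(reciprocalAveraging(m)),
                 error = function(e) NULL)
  nStarts <- 0L
  best <- list(Q = 0, g = rep(1L, nr), h = rep(1L, nc))
  evalK <- function(kMod) {
    starts <- replicate(nRestarts, list(
      g = sample.int(kMod, nr, replace = TRUE),
      h = sample.int(kMod, nc, replace = TRUE)), simplify = FALSE)
    if (!is.null(ra)) {
      br <- as.integer(cut(rank(ra$rowScores, ties.method = "first"),
                           kMod, labels = FALSE))
      bc <- as.integer(cut(rank(ra$colScores, ties.method = "first"),
                           kMod, labels = FALSE))
      starts <- c(starts, list(list(g = br, h = bc)))
    }
    if (!is.null(init)) {
      levs <- sort(unique(c(init$g, init$h)))
      gi <- match(init$g, levs)
      hi <- match(init$h, levs)
      if (length(levs) <= kMod)
        starts <- c(starts, list(list(g = gi, h = hi)))
    }
    bk <- list(Q = -Inf)
    for (st in starts) {
      nStarts <<- nStarts + 1L
      res <- .brimSweep(Bt, tot, st$g, st$h, kMod)
      if (res$Q > bk$Q) bk <- res
    }
    bk
  }
  if (cap >= 2) {
    tried <- new.env()
    tryK <- function(kk) {
      key <- as.character(kk)
      if (is.null(tried[[key]])) tried[[key]] <- evalK(kk)
      tried[[key]]
    }
    kCur <- 2L
    best <- tryK(2L)
    while (2L * kCur <= cap) {
      nxt <- tryK(2L * kCur)
      if (nxt$Q > best$Q + 1e-12) {
        best <- nxt; kCur <- 2L * kCur
      } else break
    }
    lo <- kCur; hi <- min(2L * kCur, cap)
    while (hi - lo > 1L) {
      mid <- as.integer((lo + hi) %/% 2)
      cand <- tryK(mid)
      if (cand$Q > best$Q + 1e-12) { best <- cand; lo <- mid }
      else hi <- mid
    }
  }
  used <- sort(unique(c(best$g, best$h)))
  g <- match(best$g, used); h <- match(best$h, used)
  names(g) <- rownames(m); names(h) <- colnames(m)
  new("ModularityResult", Q = best$Q, plotModules = as.integer(g),
      speciesModules = as.integer(h),
      nModules = length(intersect(unique(g), unique(h))),
      restartsUsed = nStarts, seed = as.integer(seed), kind = kind,
      bandPartitionQ = bandPartitionQ)
}

#' Altitude-constrained modularity
#'
#' Runs BRIM with an extra initial partition imposed by the altitude bands:
#' plots are assigned the module of their band (optionally crossed with
#' mountain), species the band module holding most of their occurrences.
#' Barber's Q itself is invariant to row ordering, so this is the
#' operational meaning of "altitude-sorted" modularity; the Q of the raw
#' band partition is reported alongside.
#'
#' @param x a \code{CommunityMatrix}.
#' @param bands altitude-band table.
#' @param withinMountain cross bands with mountains in the imposed
#'   partition.
#' @param nRestarts,seed as in [brimOptimize()].
#' @return A \code{\linkS4class{ModularityResult}} of kind
#'   \code{"altitude_constrained"}.
#' @export
altitudeConstrainedModularity <- function(x, bands = defaultBands(),
                                          withinMountain = FALSE,
                                          nRestarts = 20, seed = 1L) {
  stopifnot(is(x, "CommunityMatrix"))
  pd <- plotData(x)
  bl <- assignBand(pd$altitude_m, bands)
  g <- if (withinMountain)
    as.integer(factor(paste(pd$mountain, bl))) else as.integer(bl)
  g <- as.integer(as.factor(g))  # consecutive ids
  inc <- incidence(x)
  byMod <- rowsum(inc, g)  # modules x species occurrence counts
  h <- as.integer(apply(byMod, 2, which.max))
  bandQ <- barberQ(x, g, h)
  brimOptimize(x, nRestarts = nRestarts, seed = seed,
               init = list(g = g, h = h), kind = "altitude_constrained",
               bandPartitionQ = bandQ)
}

#' Write an incidence image
#'
#' Monochrome raster of the ordered binary matrix (presence = black), one
#' \code{cellSize} x \code{cellSize} pixel block per cell.
#'
#' @param x a \code{CommunityMatrix} or binary matrix.
#' @param ordering a \code{\linkS4class{MatrixOrdering}}.
#' @param path output PNG path.
#' @param cellSize pixels per matrix cell.
#' @return the path, invisibly.
#' @export
renderIncidence <- function(x, ordering = identityOrdering(x), path,
                            cellSize = 1) {
  m <- applyOrdering(x, ordering)
  img <- 1 - m
  if (cellSize > 1)
    img <- kronecker(img, matrix(1, cellSize, cellSize))
  png::writePNG(img, path)
  invisible(path)
}
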