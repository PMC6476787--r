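# Shared fixtures and independent oracles, built in code.

# perfectly nested staircase and 2x2 checkerboard
staircaseMatrix <- function() {
  m <- rbind(c(1, 1, 1, 1), c(1, 1, 1, 0), c(1, 1, 0, 0), c(1, 0, 0, 0))
  dimnames(m) <- list(paste0("p", 1:4), paste0("s", 1:4))
  m
}

checkerboardMatrix <- function() {
  m <- rbind(c(1, 0), c(0, 1))
  dimnames(m) <- list(c("p1", "p2"), c("s1", "s2"))
  m
}

twoBlockMatrix <- function() {
  m <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0), c(0, 0, 1, 1), c(0, 0, 1, 1))
  dimnames(m) <- list(paste0("p", 1:4), paste0("s", 1:4))
  m
}

# random binary matrix with no empty rows/columns
randomIncidence <- function(nr, nc, fill = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    m <- matrix(rbinom(nr * nc, 1, fill), nr, nc)
    if (all(rowSums(m) > 0) && all(colSums(m) > 0)) break
  }
  dimnames(m) <- list(paste0("p", seq_len(nr)), paste0("s", seq_len(nc)))
  m
}

# tiny CommunityMatrix wrapper around a plain incidence matrix
asCM <- function(m, altitude = NULL) {
  n <- nrow(m)
  if (is.null(altitude)) altitude <- seq(800, 1200, length.out = n)
  CommunityMatrix(m, data.frame(
    mountain = rep("M1", n), transect = rep("T1", n),
    station = paste0("S", ceiling(seq_len(n) / 2)),
    plot = paste0("P", seq_len(n)), altitude_m = altitude,
    stringsAsFactors = FALSE))
}

# small, fast synthetic survey for structural tests
tinyConfig <- function(seed = 1, ...) {
  simulationConfig(nMountains = 2, stationsPerTransect = 2,
                   plotsPerStation = 3, poolSize = 40, seed = seed, ...)
}

# Exhaustive Barber-Q maximum over all bipartitions into <= kmax modules.
# For a fixed row partition the optimal column assignment decomposes per
# column, so enumerating row partitions is exact.
exhaustiveBestQ <- function(m, kmax = 3) {
  tot <- sum(m)
  Bt <- m - outer(rowSums(m), colSums(m)) / tot
  nr <- nrow(m)
  gs <- as.matrix(expand.grid(rep(list(seq_len(kmax)), nr)))
  best <- -Inf
  for (i in seq_len(nrow(gs))) {
    G <- matrix(0, nr, kmax)
    G[cbind(seq_len(nr), gs[i, ])] <- 1
    M <- crossprod(G, Bt)
    best <- max(best, sum(apply(M, 2, max)))
  }
  best / tot
}

# Direct (loop-based) NODF recomputation, independent of the package's
# vectorised path.
nodfDirect <- function(m) {
  pairSum <- function(mm) {
    f <- rowSums(mm)
    s <- 0
    n <- nrow(mm)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (f[j] < f[i] && f[j] > 0)
        s <- s + 100 * sum(mm[i, ] * mm[j, ]) / f[j]
    }
    s
  }
  nr <- nrow(m); nc <- ncol(m)
  as.numeric((pairSum(m) + pairSum(t(m))) /
               (nr * (nr - 1) / 2 + nc * (nc - 1) / 2))
}

# First non-trivial correspondence-analysis axis via the SVD of the
# standardised incidence matrix (eigen oracle for reciprocal averaging).
caAxisOracle <- function(m) {
  r <- rowSums(m); cl <- colSums(m); tot <- sum(m)
  S <- diag(1 / sqrt(r)) %*% m %*% diag(1 / sqrt(cl))
  sv <- svd(S)
  u <- sv$u[, 2] / sqrt(r)
  u <- u - sum(r * u) / tot
  u / sqrt(sum(r * u^2) / tot)
}
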