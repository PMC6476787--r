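# Alpha diversity and multi-scale beta diversity.

test_that("scaled Shannon evenness hits its anchors and invariances", {
  expect_equal(scaledShannon(c(a = 10, b = 10, c = 10))$J, 1)
  expect_equal(scaledShannon(c(a = 25))$J, 0)
  ev <- scaledShannon(c(a = 30, b = 10))
  expect_equal(ev$H, 0.5623, tolerance = 1e-4)
  expect_equal(ev$J, 0.8113, tolerance = 1e-4)
  # scale and permutation invariance of J
  set.seed(1)
  cnt <- setNames(rpois(6, 20) + 1, letters[1:6])
  expect_equal(scaledShannon(cnt)$J, scaledShannon(cnt * 7)$J)
  expect_equal(scaledShannon(cnt)$J, scaledShannon(sample(cnt))$J)
  expect_error(scaledShannon(c(a = 0, b = 0)), "zero")
})

test_that("cover logit clamps at half the visual-estimate resolution", {
  expect_equal(as.numeric(logitCover(0.5)), 0)
  expect_equal(as.numeric(logitCover(0.75)), log(3))
  z <- logitCover(0)
  expect_equal(as.numeric(z), log(0.005 / 0.995), tolerance = 1e-6)
  expect_equal(as.numeric(z), -5.293, tolerance = 1e-3)
  expect_true(attr(z, "clamped"))
  expect_false(attr(logitCover(0.3), "clamped"))
  expect_error(logitCover(1.2), "\\[0,1\\]")
})

test_that("binary Bray-Curtis follows the Sorensen formula", {
  expect_equal(binaryBrayCurtis(c("a", "b"), c("a", "b")), 0)
  expect_equal(binaryBrayCurtis(c("a", "b"), c("c", "d")), 1)
  expect_equal(binaryBrayCurtis(c("s1", "s2", "s3"), "s1"), 0.5)
  expect_warning(z <- binaryBrayCurtis(character(), character()), "empty")
  expect_equal(z, 0)
  # symmetry, bounds, identity over random set pairs
  set.seed(7)
  for (i in 1:20) {
    a <- sample(letters, sample(1:10, 1))
    b <- sample(letters, sample(1:10, 1))
    d <- binaryBrayCurtis(a, b)
    expect_equal(d, binaryBrayCurtis(b, a))
    expect_gte(d, 0); expect_lte(d, 1)
    if (setequal(a, b)) expect_equal(d, 0) else expect_gt(d, 0)
  }
})

test_that("sorensenMatrix agrees with the pairwise set formula", {
  m <- randomIncidence(8, 10, seed = 5)
  D <- sorensenMatrix(m)
  sets <- apply(m, 1, function(r) colnames(m)[r == 1], simplify = FALSE)
  for (i in 1:7) for (j in (i + 1):8)
    expect_equal(D[i, j], binaryBrayCurtis(sets[[i]], sets[[j]]))
})

test_that("PCoA of Euclidean points reproduces the distances exactly", {
  set.seed(2)
  pts <- matrix(rnorm(6), 3, 2)
  D <- as.matrix(dist(pts))
  emb <- pcoa(D)
  expect_true(all(emb@eigenvalues > -1e-10))
  expect_equal(ncol(emb@imag), 0)
  rec <- sqrt(pmax(reconstructSquaredDissimilarity(emb), 0))
  diag(rec) <- 0  # diagonal only zero up to floating-point noise
  expect_equal(rec, D, tolerance = 1e-8, ignore_attr = TRUE)
  # degenerate all-zero input: no retained axes
  emb0 <- pcoa(matrix(0, 3, 3))
  expect_equal(length(emb0@eigenvalues), 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("non-Euclidean Sorensen matrices keep imaginary axes and reconstruct", {
  found_negative <- FALSE
  for (s in 1:10) {
    m <- randomIncidence(6, 8, seed = s + 100)
    D <- sorensenMatrix(m)
    emb <- pcoa(D)
    if (ncol(emb@imag) > 0) found_negative <- TRUE
    expect_lt(max(abs(reconstructSquaredDissimilarity(emb) - D^2)), 1e-8)
  }
  expect_true(found_negative)  # Sorensen is routinely non-Euclidean
})

test_that("centroid distances match the brute-force Euclidean oracle", {
  set.seed(4)
  pts <- matrix(rnorm(40), 20, 2)
  rownames(pts) <- paste0("p", 1:20)
  D <- as.matrix(dist(pts))
  emb <- pcoa(D)
  grp <- rep(c("a", "b", "c", "d"), each = 5)
  cd <- centroidDistances(emb, grp)
  brute <- sapply(1:20, function(i) {
    ctr <- colMeans(pts[grp == grp[i], , drop = FALSE])
    sqrt(sum((pts[i, ] - ctr)^2))
  })
  expect_equal(cd$distance, brute, tolerance = 1e-8)
  expect_false(any(cd$clamped))
  # identical-composition group and singleton group give zero distance
  m <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 1, 1))
  colnames(m) <- paste0("s", 1:3)
  emb2 <- pcoa(sorensenMatrix(m))
  cd2 <- centroidDistances(emb2, c("g1", "g1", "g2"))
  expect_equal(cd2$distance[1:2], c(0, 0), tolerance = 1e-8)
  expect_equal(cd2$distance[3], 0, tolerance = 1e-8)  # singleton
})

test_that("centroid distances are invariant to eigenvector indeterminacy", {
  m <- randomIncidence(12, 15, seed = 31)
  D <- sorensenMatrix(m)
  grp <- rep(c("a", "b", "c"), each = 4)
  d1 <- centroidDistances(pcoa(D), grp)$distance
  # an independent decomposition of the permuted matrix must give the same
  # distances (eigenvector signs/rotations differ)
  perm <- sample(12)
  d2 <- centroidDistances(pcoa(D[perm, perm]), grp[perm])$distance
  expect_equal(d2[order(perm)], d1, tolerance = 1e-8)
})

test_that("scale structure shows up in the multi-scale distance table", {
  # two stations, internally identical plots, mutually distinct
  inc <- rbind(matrix(rep(c(1, 1, 0, 0), 5), 5, byrow = TRUE),
               matrix(rep(c(0, 0, 1, 1), 5), 5, byrow = TRUE))
  colnames(inc) <- paste0("s", 1:4)
  pd <- data.frame(mountain = "M1", transect = "T1",
                   station = rep(c("S1", "S2"), each = 5),
                   plot = paste0("P", 1:10),
                   altitude_m = rep(800, 10), stringsAsFactors = FALSE)
  cm <- CommunityMatrix(inc, pd)
  bt <- betaDiversityAllScales(cm)
  expect_equal(bt$distance[bt$scale == "station"], rep(0, 10),
               tolerance = 1e-8)
  expect_true(all(bt$distance[bt$scale == "transect"] > 0.1))
  # all-identical plots: zero at every scale
  inc2 <- matrix(rep(c(1, 1, 0, 0), 10), 10, byrow = TRUE,
                 dimnames = list(NULL, paste0("s", 1:4)))
  bt2 <- betaDiversityAllScales(CommunityMatrix(inc2, pd))
  expect_equal(max(bt2$distance), 0, tolerance = 1e-8)
})
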