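# NODF, matrix orderings, reciprocal averaging, Barber Q, BRIM.

test_that("NODF anchors: perfect staircase 100, checkerboard 0", {
  expect_equal(nodf(staircaseMatrix())@nodf, 100)
  expect_equal(nodf(checkerboardMatrix(),
                    identityOrdering(checkerboardMatrix()))@nodf, 0)
  expect_error(nodf(matrix(0, 2, 2)), "all-zero")
})

test_that("NODF matches both a direct recomputation and vegan", {
  for (s in 1:8) {
    m <- randomIncidence(7, 9, fill = 0.45, seed = s)
    ours <- nodf(m, identityOrdering(m))
    expect_equal(ours@nodf, nodfDirect(m), tolerance = 1e-10)
    veg <- vegan::nestednodf(m, order = FALSE, weighted = FALSE)$statistic
    expect_equal(ours@nodf, unname(veg["NODF"]), tolerance = 1e-8)
    expect_equal(ours@nodfRows, unname(veg["N.rows"]), tolerance = 1e-8)
    expect_equal(ours@nodfCols, unname(veg["N.columns"]), tolerance = 1e-8)
  }
})

test_that("optimal ordering sorts by richness/frequency with stable ties", {
  st <- staircaseMatrix()
  expect_equal(optimalNestednessOrdering(st)@rows, 1:4)
  expect_equal(optimalNestednessOrdering(st[4:1, ])@rows, 4:1)
  tie <- rbind(c(1, 1, 0), c(1, 0, 1), c(1, 1, 1))
  colnames(tie) <- paste0("s", 1:3)
  # rows 1 and 2 tie at richness 2 and keep input order
  expect_equal(optimalNestednessOrdering(tie)@rows, c(3L, 1L, 2L))
})

test_that("no ordering beats the optimal ordering for NODF", {
  set.seed(12)
  for (s in 1:10) {
    m <- randomIncidence(8, 8, fill = 0.4, seed = 200 + s)
    best <- nodf(m)@nodf
    for (k in 1:5) {
      ord <- new("MatrixOrdering", rows = sample(8L), cols = sample(8L),
                 kind = "identity")
      expect_lte(nodf(m, ord)@nodf, best + 1e-10)
    }
  }
})

test_that("altitude ordering ascends, groups bands, and nests within mountains", {
  sv <- simulateSurvey(tinyConfig(seed = 6))
  cm <- buildCommunityMatrix(sv$records)
  ord <- altitudeOrdering(cm)
  alt <- plotData(cm)$altitude_m[ord@rows]
  expect_true(all(diff(alt) >= 0))
  # plots of one band are contiguous after sorting
  bl <- as.character(assignBand(alt))
  expect_equal(length(rle(bl)$values), length(unique(bl)))
  # within-mountain: mountains keep input order, altitude ascends inside
  ordW <- altitudeOrdering(cm, withinMountain = TRUE)
  pd <- plotData(cm)[ordW@rows, ]
  expect_equal(unique(pd$mountain), unique(plotData(cm)$mountain))
  for (m in unique(pd$mountain))
    expect_true(all(diff(pd$altitude_m[pd$mountain == m]) >= 0))
  # already sorted input gives the identity
  o <- order(plotData(cm)$altitude_m, plotData(cm)$transect,
             plotData(cm)$plot)
  cmSorted <- subsetPlots(cm, o, dropEmptySpecies = FALSE)
  expect_equal(altitudeOrdering(cmSorted)@rows, seq_len(nrow(cm)))
})

test_that("reciprocal averaging matches the eigen oracle and is equivariant", {
  # seed chosen so the first non-trivial axis is well-separated (no tie)
  m <- randomIncidence(4, 4, fill = 0.6, seed = 74)
  ra <- reciprocalAveraging(m)
  oracle <- caAxisOracle(m)
  if (sign(oracle[which.max(ra$rowScores)]) != sign(max(ra$rowScores)))
    oracle <- -oracle
  agree <- min(max(abs(unname(ra$rowScores) - oracle)),
               max(abs(unname(ra$rowScores) + oracle)))
  expect_lt(agree, 1e-8)
  # row permutation permutes scores identically (up to the global sign,
  # whose convention is tied to the first row of a plain matrix)
  perm <- c(3, 1, 4, 2)
  ra2 <- reciprocalAveraging(m[perm, ])
  a <- unname(ra2$rowScores); b <- unname(ra$rowScores[perm])
  expect_lt(min(max(abs(a - b)), max(abs(a + b))), 1e-8)
  expect_error(reciprocalAveraging(rbind(c(1, 0), c(0, 0))), "all-zero")
})

test_that("disconnected incidence blocks get separated per-component scores", {
  m <- twoBlockMatrix()
  expect_warning(ra <- reciprocalAveraging(m), "disconnected")
  expect_lt(max(ra$rowScores[1:2]), min(ra$rowScores[3:4]))
  expect_lt(max(ra$colScores[1:2]), min(ra$colScores[3:4]))
})

test_that("Barber Q follows the hand formula", {
  blk <- twoBlockMatrix()
  expect_equal(barberQ(blk, c(1, 1, 2, 2), c(1, 1, 2, 2)), 0.5)
  expect_equal(barberQ(blk, rep(1, 4), rep(1, 4)), 0)  # single module
  # permutation invariance given fixed (named) assignments
  g <- setNames(c(1, 1, 2, 2), rownames(blk))
  h <- setNames(c(1, 1, 2, 2), colnames(blk))
  perm <- c(3, 1, 4, 2)
  expect_equal(barberQ(blk[perm, perm], g, h), 0.5)
  expect_error(barberQ(matrix(0, 2, 2), c(1, 1), c(1, 1)), "presences")
})

test_that("BRIM recovers planted blocks and never degrades its start", {
  br <- brimOptimize(twoBlockMatrix(), nRestarts = 5, seed = 3)
  expect_equal(br@Q, 0.5)
  expect_equal(br@nModules, 2L)
  expect_equal(br@plotModules[1], br@plotModules[2])
  expect_false(br@plotModules[1] == br@plotModules[3])
  # a supplied start is never made worse
  m <- randomIncidence(8, 8, fill = 0.4, seed = 41)
  init <- list(g = rep(1:2, each = 4), h = rep(1:2, each = 4))
  q0 <- barberQ(m, init$g, init$h)
  br2 <- brimOptimize(m, nRestarts = 0, seed = 1, init = init)
  expect_gte(br2@Q, q0 - 1e-12)
  expect_lte(br2@Q, 1)
})

test_that("BRIM equals the exhaustive bipartition maximum on small matrices", {
  hits <- 0
  for (s in 1:6) {
    m <- randomIncidence(5, 5, fill = 0.45, seed = 300 + s)
    br <- brimOptimize(m, nRestarts = 15, seed = s)
    star <- exhaustiveBestQ(m, nrow(m))  # true global maximum
    expect_lte(br@Q, star + 1e-10)
    if (abs(br@Q - star) < 1e-10) hits <- hits + 1
  }
  expect_gte(hits, 5)
})

test_that("altitude-constrained modularity is consistent with the free optimum", {
  # strong turnover: modules align with bands, so both runs agree
  cfg <- simulationConfig(nMountains = 2, stationsPerTransect = 3,
                          plotsPerStation = 3, poolSize = 60,
                          coreFraction = 0, turnoverStrength = 6, seed = 8)
  cm <- buildCommunityMatrix(simulateSurvey(cfg)$records)
  free <- brimOptimize(cm, nRestarts = 10, seed = 2)
  cons <- altitudeConstrainedModularity(cm, nRestarts = 10, seed = 2)
  expect_gte(free@Q + 1e-9, cons@bandPartitionQ)  # optimality
  expect_lt(abs(free@Q - cons@Q), 0.01)
})

test_that("incidence images round-trip the matrix fill", {
  f <- tempfile(fileext = ".png")
  renderIncidence(checkerboardMatrix(), path = f)
  img <- png::readPNG(f)
  expect_equal(dim(img)[1:2], c(2, 2))
  expect_equal(sum(img == 0), 2)  # presences are black
  st <- staircaseMatrix()
  renderIncidence(st, optimalNestednessOrdering(st), f, cellSize = 3)
  img2 <- png::readPNG(f)
  expect_equal(dim(img2)[1:2], c(12, 12))
  expect_equal(sum(img2 == 0) / 9, sum(st))
  # upper-left triangle filled under the optimal ordering
  expect_equal(img2[1, 12], 0)  # top-right: fullest row
  expect_equal(img2[12, 1], 0)  # bottom-left
  expect_equal(img2[12, 12], 1)
})
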