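## Null-model engine: fixed-species-frequency randomisation, Z-score and
## empirical-p inference, and the pooled/per-mountain metacommunity grid.

#' Randomise a matrix preserving species frequencies
#'
#' Each species' d_j presences are placed in d_j distinct plots chosen
#' uniformly at random, independently per species: column sums are exactly
#' conserved, row sums are free (rows may become empty; NODF treats
#' zero-fill rows as contributing 0 and Q is unaffected). Plot metadata is
#' unchanged.
#'
#' @param x a \code{CommunityMatrix}.
#' @return a randomised \code{CommunityMatrix}.
#' @export
randomizeFixedFrequencies <- function(x) {
  stopifnot(is(x, "CommunityMatrix"))
  inc <- incidence(x)
  n <- nrow(inc)
  d <- colSums(inc)
  if (any(d > n)) stop("species frequency exceeds number of plots")
  out <- matrix(0L, n, ncol(inc), dimnames = dimnames(inc))
  for (j in seq_len(ncol(inc)))
    if (d[j] > 0) out[sample.int(n, d[j]), j] <- 1L
  new("CommunityMatrix", incidence = out, plotData = plotData(x))
}

#' Null-model test of a matrix statistic
#'
#' Computes the statistic on the observed matrix and on \code{nReps}
#' fixed-species-frequency randomisations, then reports the null mean and
#' SD, Z = (obs - mean) / sd (sample SD; NA when the null is degenerate),
#' and a one-tailed empirical p in the direction of the observed deviation
#' with the add-one correction (#\{as-or-more-extreme\} + 1)/(nReps + 1).
#'
#' Ordering-dependent statistics should re-derive their ordering inside
#' \code{statistic} (altitude orderings are unchanged by the null since
#' plot metadata and column sums are conserved); optimisation-based
#' statistics (BRIM Q) are re-optimised per null matrix.
#'
#' @param x a \code{CommunityMatrix}.
#' @param statistic function mapping a \code{CommunityMatrix} to a number.
#' @param nReps ensemble size (>= 2; 1000 for publication-grade runs).
#' @param seed RNG seed for the ensemble.
#' @param label statistic label stored in the result.
#' @return A \code{\linkS4class{NullTestResult}} (its \code{nullValues}
#'   slot holds the ensemble).
#' @export
nullTest <- function(x, statistic, nReps = 1000, seed = 1L,
                     label = "statistic") {
  stopifnot(nReps >= 2)
  observed <- statistic(x)
  set.seed(seed)
  nulls <- vapply(seq_len(nReps), function(i)
    statistic(randomizeFixedFrequencies(x)), numeric(1))
  mu <- mean(nulls)
  s <- sd(nulls)
  direction <- if (observed >= mu) "above" else "below"
  extreme <- if (direction == "above") sum(nulls >= observed) else
    sum(nulls <= observed)
  new("NullTestResult", statistic = label, observed = observed,
      expected = mu, nullSd = s,
      z = if (s > 0) (observed - mu) / s else NA_real_,
      pEmpirical = (extreme + 1) / (nReps + 1), direction = direction,
      nullValues = nulls, nReps = as.integer(nReps),
      seed = as.integer(seed))
}

.nullRow <- function(res, subset, sorting, statistic) {
  data.frame(subset = subset, sorting = sorting, statistic = statistic,
             observed = res@observed, expected = res@expected,
             sd = res@nullSd, z = res@z, p_empirical = res@pEmpirical,
             n_reps = res@nReps, seed = res@seed,
             stringsAsFactors = FALSE)
}

#' Pooled and per-mountain nestedness/modularity grid
#'
#' For the pooled matrix and each mountain separately, tests NODF (optimal
#' richness/frequency sorting and altitude sorting) and Barber's Q (BRIM
#' under optimal and altitude-band-constrained starts; for the pooled
#' matrix also the altitude-within-mountain constraint) against the
#' fixed-species-frequency null model. Optimal-sorting statistics are
#' re-sorted / re-optimised on every null matrix.
#'
#' @param x a \code{CommunityMatrix} with mountain and altitude metadata.
#' @param bands altitude-band table.
#' @param nReps null replicates per cell (1000 for publication-grade runs;
#'   smaller values keep exploratory runs fast).
#' @param seed master seed; each cell derives its own.
#' @param brimRestarts BRIM random restarts for observed matrices.
#' @param nullBrimRestarts BRIM restarts per null matrix (the dominant
#'   cost; kept smaller).
#' @return data.frame with one row per (subset, sorting, statistic):
#'   columns \code{subset}, \code{sorting}, \code{statistic},
#'   \code{observed}, \code{expected}, \code{sd}, \code{z},
#'   \code{p_empirical}, \code{n_reps}, \code{seed}.
#' @export
metacommunityAnalysis <- function(x, bands = defaultBands(), nReps = 1000,
                                  seed = 1L, brimRestarts = 20,
                                  nullBrimRestarts = 5) {
  stopifnot(is(x, "CommunityMatrix"))
  subsets <- c(list(all = x),
               lapply(setNames(nm = unique(plotData(x)$mountain)),
                      function(m) subsetPlots(
                        x, plotData(x)$mountain == m)))
  rows <- list()
  cellSeed <- seed
  nextSeed <- function() {
    cellSeed <<- cellSeed + 1L
    cellSeed
  }
  for (nm in names(subsets)) {
    sub <- subsets[[nm]]
    ## NODF, optimal sorting (re-sorted per null matrix)
    rows[[length(rows) + 1L]] <- .nullRow(
      nullTest(sub, function(m) nodf(m)@nodf, nReps, nextSeed(),
               label = "NODF/optimal"),
      nm, "optimal", "NODF")
    ## NODF, altitude sorting (ordering re-derived; identical per null)
    rows[[length(rows) + 1L]] <- .nullRow(
      nullTest(sub, function(m) nodf(m, altitudeOrdering(m))@nodf, nReps,
               nextSeed(), label = "NODF/altitude"),
      nm, "altitude", "NODF")
    ## Q, optimal (BRIM re-optimised per null)
    qStat <- function(restarts) function(m)
      brimOptimize(m, nRestarts = restarts,
                   seed = sample.int(.Machine$integer.max - 1, 1))@Q
    obsQ <- brimOptimize(sub, nRestarts = brimRestarts,
                         seed = nextSeed())@Q
    resQ <- nullTest(sub, qStat(nullBrimRestarts), nReps, nextSeed(),
                     label = "Q/optimal")
    resQ@observed <- obsQ
    resQ@z <- if (resQ@nullSd > 0) (obsQ - resQ@expected) / resQ@nullSd
      else NA_real_
    resQ@direction <- if (obsQ >= resQ@expected) "above" else "below"
    extreme <- if (resQ@direction == "above")
      sum(resQ@nullValues >= obsQ) else sum(resQ@nullValues <= obsQ)
    resQ@pEmpirical <- (extreme + 1) / (nReps + 1)
    rows[[length(rows) + 1L]] <- .nullRow(resQ, nm, "optimal", "Q")
    ## Q, altitude-constrained starts
    constraints <- if (nm == "all") c(FALSE, TRUE) else FALSE
    for (wm in constraints) {
      qAlt <- function(m) altitudeConstrainedModularity(
        m, bands, withinMountain = wm, nRestarts = nullBrimRestarts,
        seed = sample.int(.Machine$integer.max - 1, 1))@Q
      obsQA <- altitudeConstrainedModularity(
        sub, bands, withinMountain = wm, nRestarts = brimRestarts,
        seed = nextSeed())@Q
      resA <- nullTest(sub, qAlt, nReps, nextSeed(),
                       label = "Q/altitude")
      resA@observed <- obsQA
      resA@z <- if (resA@nullSd > 0) (obsQA - resA@expected) / resA@nullSd
        else NA_real_
      resA@direction <- if (obsQA >= resA@expected) "above" else "below"
      extreme <- if (resA@direction == "above")
        sum(resA@nullValues >= obsQA) else sum(resA@nullValues <= obsQA)
      resA@pEmpirical <- (extreme + 1) / (nReps + 1)
      rows[[length(rows) + 1L]] <- .nullRow(
        resA, nm,
        if (wm) "altitude_within_mountain" else "altitude", "Q")
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
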