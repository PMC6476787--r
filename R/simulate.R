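## Synthetic survey generator: Gaussian altitude niches on a logit scale
## with nested random effects, unimodal cover, and ITEX-style
## point-intercept counts.

#' Configuration for the synthetic survey generator
#'
#' Defaults reproduce the survey design this package targets: 3 mountains,
#' one 1 km transect per altitude band (four bands), five stations per
#' transect 250 m apart, five 1 m^2 plots per station, 25 intercept points
#' per plot (125 per station).
#'
#' Species occupancy follows a Gaussian altitude niche passed through a
#' logit link with nested random effects: the niche assigns species s at
#' altitude a the baseline probability
#' \code{maxOcc * exp(-(a - optimum)^2 / (2 tolerance^2))}, and mountain,
#' transect and station intercepts perturb its logit. A fraction
#' \code{coreFraction} of species get 4x inflated tolerances (wide-niche
#' "core" species: the nestedness knob); the rest have tolerances shrunk by
#' \code{turnoverStrength} (the modularity knob).
#'
#' @param nMountains,stationsPerTransect,plotsPerStation,pointsPerPlot survey
#'   design counts.
#' @param bands altitude-band table as from [defaultBands()]; one transect is
#'   simulated per mountain per band.
#' @param poolSize size of the regional species pool.
#' @param nicheToleranceLogMean,nicheToleranceLogSd log-normal parameters of
#'   the baseline niche width (m).
#' @param coreFraction proportion of wide-niche core species in [0,1].
#' @param turnoverStrength tolerance shrink factor (>= 1) for non-core
#'   species; larger values sharpen altitudinal turnover.
#' @param maxOccRange range of the uniform draw for per-species maximum
#'   occupancy.
#' @param optimaCenter,optimaSd if supplied, niche optima are drawn
#'   Normal(optimaCenter, optimaSd) (truncated to the gradient) instead of
#'   uniformly; use to concentrate optima mid-gradient.
#' @param coverPeakAlt,coverPeakValue altitude (m) and value (proportion) of
#'   the cover peak.
#' @param coverCurvature curvature of the cover quadratic on the logit scale
#'   (per m^2).
#' @param coverNoiseSd SD of plot-level Gaussian noise on the cover logit.
#' @param reSdMountain,reSdTransect,reSdStation random-intercept SDs on the
#'   occupancy logit scale.
#' @param dropOneTransect drop the highest-band transect of the last
#'   mountain, mimicking an incomplete field campaign (11 of 12 transects,
#'   275 plots).
#' @param topBandWidth sampled width (m) of the open top band.
#' @param seed integer seed fixing the full survey.
#' @return A `simulationConfig` list.
#' @export
simulationConfig <- function(nMountains = 3, bands = defaultBands(),
                             stationsPerTransect = 5, plotsPerStation = 5,
                             pointsPerPlot = 25, poolSize = 150,
                             nicheToleranceLogMean = log(120),
                             nicheToleranceLogSd = 0.4,
                             coreFraction = 0.3, turnoverStrength = 2,
                             maxOccRange = c(0.1, 0.9),
                             optimaCenter = NULL, optimaSd = NULL,
                             coverPeakAlt = 850, coverPeakValue = 0.8,
                             coverCurvature = 1.1e-5, coverNoiseSd = 0.5,
                             reSdMountain = 0.25, reSdTransect = 0.25,
                             reSdStation = 0.25, dropOneTransect = FALSE,
                             topBandWidth = 200, seed = 1) {
  bands <- .checkBands(bands)
  cfg <- list(nMountains = nMountains, bands = bands,
              stationsPerTransect = stationsPerTransect,
              plotsPerStation = plotsPerStation,
              pointsPerPlot = pointsPerPlot, poolSize = poolSize,
              nicheToleranceLogMean = nicheToleranceLogMean,
              nicheToleranceLogSd = nicheToleranceLogSd,
              coreFraction = coreFraction,
              turnoverStrength = turnoverStrength,
              maxOccRange = maxOccRange, optimaCenter = optimaCenter,
              optimaSd = optimaSd, coverPeakAlt = coverPeakAlt,
              coverPeakValue = coverPeakValue,
              coverCurvature = coverCurvature, coverNoiseSd = coverNoiseSd,
              reSdMountain = reSdMountain, reSdTransect = reSdTransect,
              reSdStation = reSdStation, dropOneTransect = dropOneTransect,
              topBandWidth = topBandWidth, seed = as.integer(seed))
  stopifnot(nMountains >= 1, stationsPerTransect >= 1, plotsPerStation >= 1,
            pointsPerPlot >= 1, poolSize >= 1,
            coreFraction >= 0, coreFraction <= 1, turnoverStrength > 0,
            coverPeakValue > 0, coverPeakValue <= 1)
  class(cfg) <- "simulationConfig"
  cfg
}

.maxSampledAlt <- function(config) {
  top <- max(config$bands$lower)
  max(ifelse(is.finite(config$bands$upper), config$bands$upper,
             top + config$topBandWidth))
}

#' Draw the regional species pool
#'
#' Uses the current RNG state (seeded by [simulateSurvey()]). Core species
#' (the first \code{round(coreFraction * poolSize)}) get tolerances inflated
#' 4x; specialists have tolerances divided by \code{turnoverStrength}.
#' Optima are uniform over [min band lower - 100, max sampled altitude +
#' 100] unless \code{optimaCenter}/\code{optimaSd} are set.
#'
#' @param config a `simulationConfig`.
#' @return data.frame with columns \code{species}, \code{optimum},
#'   \code{tolerance}, \code{maxOcc}, \code{core}, \code{abundanceWeight}.
#' @export
drawNichePool <- function(config) {
  n <- config$poolSize
  lo <- min(config$bands$lower) - 100
  hi <- .maxSampledAlt(config) + 100
  nCore <- round(config$coreFraction * n)
  core <- seq_len(n) <= nCore
  if (!is.null(config$optimaCenter) && !is.null(config$optimaSd)) {
    opt <- rnorm(n, config$optimaCenter, config$optimaSd)
    opt <- pmin(pmax(opt, lo), hi)
  } else {
    opt <- runif(n, lo, hi)
  }
  tol <- exp(rnorm(n, config$nicheToleranceLogMean,
                   config$nicheToleranceLogSd))
  tol[core] <- tol[core] * 4
  tol[!core] <- tol[!core] / config$turnoverStrength
  maxOcc <- runif(n, config$maxOccRange[1], config$maxOccRange[2])
  data.frame(species = sprintf("sp%03d", seq_len(n)),
             optimum = opt, tolerance = tol, maxOcc = maxOcc, core = core,
             abundanceWeight = rlnorm(n, 0, 1),
             stringsAsFactors = FALSE)
}

.nicheProb <- function(pool, altitude) {
  ## baseline occupancy probability, random effects at zero
  vapply(altitude, function(a)
    pool$maxOcc * exp(-(a - pool$optimum)^2 / (2 * pool$tolerance^2)),
    numeric(nrow(pool)))
}

#' Expected per-plot species richness at an altitude
#'
#' Sum over the pool of baseline occupancy probabilities (random effects at
#' zero).
#'
#' @param pool niche pool as from [drawNichePool()] (the survey `truth`).
#' @param altitude numeric vector of altitudes (m).
#' @return numeric vector of expected richness values.
#' @export
expectedRichness <- function(pool, altitude) {
  p <- .nicheProb(pool, altitude)
  if (is.null(dim(p))) sum(p) else colSums(p)
}

.clampP <- function(p, eps = 1e-9) pmin(pmax(p, eps), 1 - eps)

#' Simulate a hierarchical survey
#'
#' Generates transect/station altitudes within bands, species presences from
#' the Gaussian-niche logit model with nested random intercepts, unimodal
#' plot cover, and station point-intercept counts (each point touches a
#' present species with probability proportional to a per-species log-normal
#' abundance weight times plot cover, else records no touch).
#'
#' The full output is a deterministic function of \code{config$seed};
#' per-mountain sub-seeds keep mountains independent of simulation order.
#'
#' @param config a `simulationConfig`.
#' @return list with elements \code{records} (plot records, see
#'   [readPlotRecords()]), \code{intercepts} (per-plot `interceptCounts`),
#'   and \code{truth} (niche pool plus realised random effects).
#' @export
simulateSurvey <- function(config = simulationConfig()) {
  stopifnot(inherits(config, "simulationConfig"))
  set.seed(config$seed)
  pool <- drawNichePool(config)
  mSeeds <- sample.int(.Machine$integer.max - 1, config$nMountains)
  bands <- config$bands[order(config$bands$lower), ]
  nB <- nrow(bands)
  recs <- list(); ints <- list(); reRows <- list()
  for (m in seq_len(config$nMountains)) {
    set.seed(mSeeds[m])
    mnt <- sprintf("M%d", m)
    uM <- rnorm(1, 0, config$reSdMountain)
    for (b in seq_len(nB)) {
      if (config$dropOneTransect && m == config$nMountains && b == nB)
        next
      tr <- sprintf("%sT%d", mnt, b)
      uT <- rnorm(1, 0, config$reSdTransect)
      lo <- bands$lower[b]
      hi <- if (is.finite(bands$upper[b])) bands$upper[b] else
        lo + config$topBandWidth
      trAlt <- runif(1, lo + 25, hi - 25)
      for (s in seq_len(config$stationsPerTransect)) {
        st <- sprintf("%sS%d", tr, s)
        uS <- rnorm(1, 0, config$reSdStation)
        stAlt <- min(max(trAlt + rnorm(1, 0, 15), lo), hi - 1e-6)
        reRows[[length(reRows) + 1L]] <-
          data.frame(mountain = mnt, transect = tr, station = st,
                     uMountain = uM, uTransect = uT, uStation = uS,
                     altitude_m = stAlt, stringsAsFactors = FALSE)
        base <- .clampP(pool$maxOcc *
                          exp(-(stAlt - pool$optimum)^2 /
                                (2 * pool$tolerance^2)))
        pOcc <- stats::plogis(stats::qlogis(base) + uM + uT + uS)
        coverMu <- stats::qlogis(config$coverPeakValue) -
          config$coverCurvature * (stAlt - config$coverPeakAlt)^2
        for (p in seq_len(config$plotsPerStation)) {
          present <- rbinom(nrow(pool), 1, pOcc) == 1
          cov <- stats::plogis(coverMu + rnorm(1, 0, config$coverNoiseSd))
          recs[[length(recs) + 1L]] <-
            data.frame(mountain = mnt, transect = tr, station = st,
                       plot = sprintf("P%d", p), altitude_m = stAlt,
                       cover = cov,
                       species = paste(pool$species[present],
                                       collapse = ";"),
                       stringsAsFactors = FALSE)
          ints[[length(ints) + 1L]] <-
            .simulateIntercepts(pool, present, cov, st,
                                config$pointsPerPlot)
        }
      }
    }
  }
  records <- do.call(rbind, recs)
  list(records = records, intercepts = ints,
       truth = list(pool = pool, randomEffects = do.call(rbind, reRows),
                    config = config))
}

.simulateIntercepts <- function(pool, present, cover, station, nPoints) {
  w <- pool$abundanceWeight[present]
  sp <- pool$species[present]
  if (!length(sp))
    return(interceptCounts(station, setNames(numeric(0), character(0)),
                           nPoints))
  probs <- c(cover * w / sum(w), 1 - cover)  # species..., no touch
  draw <- rmultinom(1, nPoints, probs)[, 1]
  counts <- setNames(draw[seq_along(sp)], sp)
  interceptCounts(station, counts, nPoints)
}

#' Pool a simulated survey's intercepts per station
#'
#' @param intercepts list of per-plot `interceptCounts` (from
#'   [simulateSurvey()]).
#' @return list of station-level `interceptCounts`.
#' @export
poolSurveyIntercepts <- function(intercepts) {
  stations <- vapply(intercepts, `[[`, character(1), "station")
  lapply(split(intercepts, stations), poolStationCounts)
}
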