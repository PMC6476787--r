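## End-to-end orchestration: run every analysis stage on real or simulated
## data and write CSV tables, incidence images, and a run log.

.writeStamped <- function(df, path, seed, stage) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stage=%s seed=%d", stage, seed), con)
  write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full diversity analysis
#'
#' Executes the selected stages on either supplied plot records (plus
#' optional intercept counts) or a synthetic survey, writing results under
#' \code{outDir}:
#' \describe{
#'   \item{alpha}{\code{alpha_plots.csv} (per-plot cover, logit cover,
#'     richness) and \code{alpha_evenness.csv} (per-station scaled Shannon
#'     evenness), when intercept counts exist.}
#'   \item{beta}{\code{beta_distances.csv}: per-plot centroid distances at
#'     the station, transect and landscape scales.}
#'   \item{trends}{\code{trend_lrt.csv} (quadratic-vs-linear tests per
#'     response), \code{trend_coefficients.csv},
#'     \code{beta_scale_contrasts.csv} and
#'     \code{beta_scale_subsets.csv}.}
#'   \item{metacom}{\code{metacommunity.csv} (pooled/per-mountain NODF and
#'     Q against the null model) and incidence images under
#'     \code{images/}.}
#' }
#' A \code{run_log.txt} records the seed, stage outcomes and any warnings
#' (clamped distances, empty-plot conventions, non-convergence).
#'
#' @param outDir output directory (created if needed).
#' @param records plot-record data.frame, or NULL to simulate.
#' @param intercepts list of `interceptCounts` (per plot or station), or
#'   NULL.
#' @param simConfig a [simulationConfig()] used when \code{records} is
#'   NULL.
#' @param bands altitude-band table.
#' @param nReps null-model replicates for the metacommunity stage.
#' @param seed seed for all stochastic stages.
#' @param stages subset of \code{c("alpha", "beta", "trends", "metacom")}.
#' @return invisible list of written paths.
#' @export
runPipeline <- function(outDir, records = NULL, intercepts = NULL,
                        simConfig = NULL, bands = defaultBands(),
                        nReps = 200, seed = 1L,
                        stages = c("alpha", "beta", "trends", "metacom")) {
  if (!is.null(records) && !is.null(simConfig))
    stop("supply records or a simulation config, not both")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(outDir, "run_log.txt")
  logLine <- function(...) cat(sprintf(...), "\n", sep = "",
                               file = log, append = TRUE)
  cat(sprintf("run started %s, seed %d\n",
              format(Sys.time(), "%Y-%m-%dT%H:%M:%S"), seed), file = log)
  if (is.null(records)) {
    if (is.null(simConfig)) simConfig <- simulationConfig(seed = seed)
    sim <- simulateSurvey(simConfig)
    records <- sim$records
    if (is.null(intercepts)) intercepts <- sim$intercepts
    logLine("simulated survey: %d plots, seed %d", nrow(records),
            simConfig$seed)
  }
  paths <- character()
  stage <- function(name, expr) {
    if (!name %in% stages) return(invisible(NULL))
    tryCatch({
      expr
      logLine("stage %s: ok", name)
    }, error = function(e) {
      logLine("stage %s: FAILED (%s)", name, conditionMessage(e))
      stop("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  cm <- buildCommunityMatrix(records)
  betaTab <- NULL

  stage("alpha", {
    alpha <- plotAlphaTable(records)
    p <- .writeStamped(alpha, file.path(outDir, "alpha_plots.csv"), seed,
                       "alpha")
    paths <- c(paths, p)
    if (!is.null(intercepts) && length(intercepts)) {
      pooled <- poolSurveyIntercepts(intercepts)
      ev <- stationEvennessTable(pooled)
      meta <- unique(alpha[c("mountain", "transect", "station",
                             "altitude_m")])
      ev <- merge(ev, meta, by = "station", all.x = TRUE, sort = FALSE)
      p <- .writeStamped(ev, file.path(outDir, "alpha_evenness.csv"),
                         seed, "alpha")
      paths <- c(paths, p)
    }
  })

  stage("beta", {
    betaTab <- withCallingHandlers(
      betaDiversityAllScales(cm, bands),
      warning = function(w) {
        logLine("beta warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    paths <- c(paths, .writeStamped(
      betaTab, file.path(outDir, "beta_distances.csv"), seed, "beta"))
  })

  stage("trends", {
    alpha <- plotAlphaTable(records)
    lrts <- list(
      cover_logit = lrtQuadratic(alpha, "cover_logit", "gaussian",
                                 "station"),
      richness = lrtQuadratic(alpha, "richness", "poisson", "station"))
    if (!is.null(intercepts) && length(intercepts)) {
      pooled <- poolSurveyIntercepts(intercepts)
      ev <- stationEvennessTable(pooled)
      meta <- unique(alpha[c("mountain", "transect", "station",
                             "altitude_m")])
      ev <- merge(ev, meta, by = "station", sort = FALSE)
      ev <- ev[!is.na(ev$J), ]
      lrts$evenness <- lrtQuadratic(ev, "J", "gaussian", "transect")
    }
    lrtTab <- do.call(rbind, lapply(names(lrts), function(r)
      data.frame(response = r, chisq = lrts[[r]]$chisq,
                 df = lrts[[r]]$df, p = lrts[[r]]$p)))
    paths <- c(paths, .writeStamped(
      lrtTab, file.path(outDir, "trend_lrt.csv"), seed, "trends"))
    coefTab <- do.call(rbind, lapply(names(lrts), function(r) {
      f <- lrts[[r]]$quadratic
      if (!f$converged) logLine("trend fit %s: not converged", r)
      cbind(response = r, f$coefficients)
    }))
    paths <- c(paths, .writeStamped(
      coefTab, file.path(outDir, "trend_coefficients.csv"), seed,
      "trends"))
    if (is.null(betaTab)) betaTab <- betaDiversityAllScales(cm, bands)
    sf <- scaleInteractionFit(betaTab)
    paths <- c(paths, .writeStamped(
      tukeyScaleContrasts(sf),
      file.path(outDir, "beta_scale_contrasts.csv"), seed, "trends"))
    subTab <- do.call(rbind, lapply(names(sf$subsets), function(sc)
      cbind(scale = sc, sf$subsets[[sc]]$coefficients)))
    subTab <- rbind(
      cbind(scale = "interaction_lrt",
            data.frame(term = "altitude_sq:scale",
                       estimate = sf$interactionLRT$chisq,
                       se = NA_real_, z = NA_real_,
                       p = sf$interactionLRT$p)),
      subTab)
    paths <- c(paths, .writeStamped(
      subTab, file.path(outDir, "beta_scale_subsets.csv"), seed,
      "trends"))
  })

  stage("metacom", {
    tab <- metacommunityAnalysis(cm, bands, nReps = nReps, seed = seed)
    paths <- c(paths, .writeStamped(
      tab, file.path(outDir, "metacommunity.csv"), seed, "metacom"))
    imgDir <- file.path(outDir, "images")
    dir.create(imgDir, showWarnings = FALSE)
    renderIncidence(cm, optimalNestednessOrdering(cm),
                    file.path(imgDir, "incidence_optimal.png"))
    renderIncidence(cm, altitudeOrdering(cm),
                    file.path(imgDir, "incidence_altitude.png"))
    renderIncidence(cm, altitudeOrdering(cm, withinMountain = TRUE),
                    file.path(imgDir, "incidence_altitude_within.png"))
    paths <- c(paths, file.path(imgDir, c(
      "incidence_optimal.png", "incidence_altitude.png",
      "incidence_altitude_within.png")))
  })

  logLine("run finished")
  invisible(paths)
}
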