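# Mixed-effects altitude trends, LRTs, scale interaction, Tukey contrasts.

# nested design with iid noise (no true random effects)
flatDesign <- function(seed, n_per = 40, sdNoise = 0.1) {
  set.seed(seed)
  d <- data.frame(mountain = rep(sprintf("m%d", 1:6), each = n_per),
                  transect = rep(rep(1:4, each = n_per / 4), 6),
                  station = rep(rep(1:2, each = n_per / 8), 24),
                  altitude_m = runif(6 * n_per, 700, 1500))
  d$y <- 2 + 0.003 * d$altitude_m - 2e-6 * d$altitude_m^2 +
    rnorm(nrow(d), 0, sdNoise)
  d
}

test_that("with zero fitted variance components the fit collapses to OLS", {
  d <- flatDesign(4)
  f <- suppressMessages(fitAltitudeTrend(d, "y", 2, "gaussian", "station"))
  vc <- f$varcomp$variance[f$varcomp$group != "Residual"]
  expect_lt(max(vc), 1e-10)  # the OLS-limit regime really holds here
  ols <- lm(y ~ altitude_m + I(altitude_m^2), d)
  expect_equal(f$coefficients$estimate, unname(coef(ols)),
               tolerance = 1e-6)
  expect_lt(max(abs(f$coefficients$estimate - coef(ols))), 1e-4)
  expect_equal(f$coefficients$se, unname(sqrt(diag(vcov(ols)))),
               tolerance = 0.05)  # ML vs OLS dispersion scaling
})

test_that("the Poisson GLMM collapses to ordinary Poisson regression", {
  set.seed(8)
  d <- flatDesign(8)
  d$y <- rpois(nrow(d), exp(0.5 + 0.0005 * d$altitude_m))
  f <- suppressMessages(fitAltitudeTrend(d, "y", 1, "poisson", "station"))
  expect_lt(max(f$varcomp$variance), 1e-10)
  g <- glm(y ~ altitude_m, poisson, d)
  expect_lt(max(abs(f$coefficients$estimate - coef(g))), 1e-4)
})

test_that("a constant response yields null slopes and vanishing variances", {
  d <- flatDesign(1)
  d$y <- 5
  f <- suppressMessages(suppressWarnings(
    fitAltitudeTrend(d, "y", 2, "gaussian", "station")))
  expect_equal(f$coefficients$estimate[1], 5, tolerance = 1e-6)
  expect_lt(max(abs(f$coefficients$estimate[2:3])), 1e-10)
  expect_lt(max(f$varcomp$variance), 1e-8)
})

test_that("estimates are invariant to relabelling the hierarchy", {
  sv <- simulateSurvey(tinyConfig(seed = 17))
  al <- plotAlphaTable(sv$records)
  f1 <- suppressMessages(fitAltitudeTrend(al, "cover_logit", 2,
                                          "gaussian", "station"))
  al2 <- al
  al2$mountain <- chartr("12", "21", al2$mountain)
  al2$transect <- paste0("X", al2$transect)
  f2 <- suppressMessages(fitAltitudeTrend(al2, "cover_logit", 2,
                                          "gaussian", "station"))
  expect_equal(f1$coefficients$estimate, f2$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-6)
})

test_that("quadratic LRT behaves across signal regimes", {
  # the quadratic never fits worse than the nested linear model
  for (s in 1:3) {
    d <- flatDesign(s + 40, sdNoise = 0.3)
    lr <- suppressMessages(lrtQuadratic(d, "y", "gaussian", "station"))
    expect_gte(lr$chisq, 0)
    expect_equal(lr$df, 1L)
    expect_gte(lr$p, 0); expect_lte(lr$p, 1)
    expect_gte(lr$quadratic$logLik, lr$linear$logLik - 1e-8)
  }
  # strong curvature is detected decisively
  d <- flatDesign(50, sdNoise = 0.05)
  lr <- suppressMessages(lrtQuadratic(d, "y", "gaussian", "station"))
  expect_lt(lr$p, 0.001)
  # no curvature: a purely linear response keeps the quadratic term null
  d$y <- 1 + 0.001 * d$altitude_m + rnorm(nrow(d), 0, 0.05)
  lr0 <- suppressMessages(lrtQuadratic(d, "y", "gaussian", "station"))
  expect_gt(lr0$p, 0.001)
})

test_that("quadratic vertex recovery locates a 1000 m richness peak", {
  set.seed(60)
  errs <- replicate(5, {
    d <- data.frame(mountain = rep(sprintf("m%d", 1:3), each = 100),
                    transect = rep(rep(1:4, each = 25), 3),
                    station = rep(rep(1:5, each = 5), 12))
    stAlt <- runif(60, 700, 1300)
    d$altitude_m <- rep(stAlt, each = 5)
    stRE <- rep(rnorm(60, 0, 0.3), each = 5)
    d$y <- 3 - 8e-6 * (d$altitude_m - 1000)^2 + stRE +
      rnorm(300, 0, 0.3)
    f <- suppressMessages(fitAltitudeTrend(d, "y", 2, "gaussian",
                                           "station"))
    abs(suppressWarnings(trendVertex(f)) - 1000)
  })
  expect_lt(median(errs), 100)
})

simulateScaleData <- function(seed, curvedScale = NULL, shift = 0) {
  set.seed(seed)
  d <- expand.grid(mountain = sprintf("m%d", 1:3), transect = 1:4,
                   station = 1:5, plotid = 1:5,
                   scale = c("station", "transect", "landscape"),
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  key <- paste(d$mountain, d$transect, d$station)
  stAlt <- setNames(runif(60, 700, 1300), unique(key))
  d$altitude_m <- stAlt[key]
  d$distance <- 0.3 + 0.05 * (d$scale == "transect") +
    0.1 * (d$scale == "landscape") + shift * (d$scale == "landscape") +
    rnorm(nrow(d), 0, 0.05)
  if (!is.null(curvedScale))
    d$distance <- d$distance - (d$scale == curvedScale) *
      4e-7 * (d$altitude_m - 1000)^2
  d$scale <- factor(d$scale, levels = c("station", "transect", "landscape"))
  d
}

test_that("the scale interaction model needs three scales and finds curvature", {
  d <- simulateScaleData(3, curvedScale = "transect")
  expect_error(scaleInteractionFit(d[d$scale == "station", ]), "three")
  sf <- suppressMessages(scaleInteractionFit(d))
  ps <- vapply(sf$subsets, function(f)
    f$coefficients$p[f$coefficients$term == "altitude_sq"], numeric(1))
  expect_lt(ps[["transect"]], 0.05)
  expect_gt(min(ps[["station"]], ps[["landscape"]]), 0.05)
  expect_lt(sf$interactionLRT$p, 0.05)
})

test_that("Tukey-adjusted contrasts separate shifted scales and are antisymmetric", {
  d <- simulateScaleData(5, shift = 0)
  # make transect == station, landscape shifted
  d$distance <- d$distance - 0.05 * (d$scale == "transect")
  sf <- suppressMessages(scaleInteractionFit(d))
  ct <- tukeyScaleContrasts(sf)
  expect_equal(nrow(ct), 3)
  expect_equal(ct$df, rep(sf$nObs - sf$rankX, 3))
  sig <- ct$p < 0.05
  names(sig) <- ct$contrast
  expect_false(sig[["transect - station"]])
  expect_true(sig[["landscape - station"]])
  expect_true(sig[["landscape - transect"]])
  # antisymmetry under reversed factor order
  d2 <- d
  d2$scale <- factor(d2$scale, levels = rev(levels(d$scale)))
  ct2 <- tukeyScaleContrasts(suppressMessages(scaleInteractionFit(d2)))
  est <- setNames(ct$estimate, ct$contrast)
  est2 <- setNames(ct2$estimate, ct2$contrast)
  expect_equal(est2[["station - landscape"]],
               -est[["landscape - station"]], tolerance = 1e-5)
  expect_equal(setNames(ct2$p, ct2$contrast)[["station - landscape"]],
               ct$p[ct$contrast == "landscape - station"],
               tolerance = 1e-3)
})

test_that("contrast estimates and t statistics agree with emmeans", {
  d <- simulateScaleData(7)
  sf <- suppressMessages(scaleInteractionFit(d))
  ct <- tukeyScaleContrasts(sf)
  emm <- emmeans::emmeans(sf$full, "scale", lmer.df = "asymptotic",
                          at = list(altc = 0, altc2 = 0))
  prs <- as.data.frame(emmeans::contrast(emm, "revpairwise",
                                         adjust = "none"))
  ours <- setNames(ct$estimate, ct$contrast)
  theirs <- setNames(prs$estimate, prs$contrast)
  for (nm in names(ours))
    expect_equal(ours[[nm]], theirs[[nm]], tolerance = 1e-6)
  expect_equal(setNames(ct$t, ct$contrast)[names(theirs)],
               setNames(prs$z.ratio, prs$contrast), tolerance = 1e-3,
               ignore_attr = TRUE)
})
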