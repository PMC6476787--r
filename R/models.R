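## Altitude trend models: mixed models with nested random intercepts,
## linear-vs-quadratic likelihood-ratio tests, scale x altitude interaction,
## and multivariate-t (Tukey-style) pairwise scale contrasts.
##
## All fits use maximum likelihood (not REML) because the LRTs compare
## fixed-effect structures. Altitude is mean-centred before squaring to
## curb collinearity; reported coefficients are back-transformed to the
## raw-altitude parameterisation.

.prepTrendData <- function(data, response, nesting) {
  need <- c(response, "altitude_m", "mountain", "transect")
  if (nesting == "station") need <- c(need, "station")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("data lacks column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(y = data[[response]],
                  altitude_m = data$altitude_m,
                  g1 = as.character(data$mountain),
                  g2 = paste(data$mountain, data$transect, sep = "."),
                  stringsAsFactors = FALSE)
  if (nesting == "station")
    d$g3 <- paste(d$g2, data$station, sep = ".")
  if ("scale" %in% names(data)) d$scale <- data$scale
  d <- d[complete.cases(d[c("y", "altitude_m")]), , drop = FALSE]
  ## centre and scale altitude so the quadratic term is well-conditioned;
  ## coefficients are back-transformed to the raw scale for reporting
  ctr <- mean(d$altitude_m)
  scl <- sd(d$altitude_m)
  if (!is.finite(scl) || scl == 0) scl <- 1
  d$altc <- (d$altitude_m - ctr) / scl
  d$altc2 <- d$altc^2
  attr(d, "center") <- ctr
  attr(d, "scale") <- scl
  d
}

.reTerms <- function(nesting)
  if (nesting == "station") "(1 | g1) + (1 | g2) + (1 | g3)" else
    "(1 | g1) + (1 | g2)"

.fitOnce <- function(form, d, family, optimizer = NULL) {
  if (family == "gaussian") {
    ctrl <- if (is.null(optimizer)) lme4::lmerControl() else
      lme4::lmerControl(optimizer = optimizer)
    lme4::lmer(form, data = d, REML = FALSE, control = ctrl)
  } else {
    ctrl <- if (is.null(optimizer)) lme4::glmerControl() else
      lme4::glmerControl(optimizer = optimizer)
    lme4::glmer(form, data = d, family = stats::poisson(link = "log"),
                control = ctrl)
  }
}

.isConverged <- function(fit) {
  opt <- fit@optinfo$conv$opt
  if (!is.null(opt) && opt != 0) return(FALSE)
  msgs <- fit@optinfo$conv$lme4$messages
  if (is.null(msgs) || !length(msgs)) return(TRUE)
  ## variance components on the boundary routinely trip the Hessian and
  ## gradient checks; a singular fit with only such messages is usable
  checkOnly <- all(grepl("Hessian|gradient|converge|singular", msgs))
  checkOnly && isTRUE(lme4::isSingular(fit, tol = 1e-5))
}

## raw-altitude reparameterisation of a standardised polynomial fit:
## (b0, b1, b2) on (1, u, u^2) with u = (a - m)/s -> coefficients on
## (1, a, a^2)
.rawTransform <- function(beta, V, center, scale, degree) {
  m <- center; s <- scale
  Tm <- if (degree == 2)
    rbind(c(1, -m / s, (m / s)^2),
          c(0, 1 / s, -2 * m / s^2),
          c(0, 0, 1 / s^2)) else
    rbind(c(1, -m / s), c(0, 1 / s))
  est <- drop(Tm %*% beta)
  cov <- Tm %*% V %*% t(Tm)
  list(estimate = est, se = sqrt(diag(cov)))
}

#' Fit a mixed-effects altitude trend
#'
#' Fits \code{response ~ altitude (+ altitude^2) + nested random
#' intercepts} by maximum likelihood: a Gaussian linear mixed model
#' (\code{lme4::lmer}) or a Poisson log-link GLMM (\code{lme4::glmer}, for
#' richness counts). Random structure is station-in-transect-in-mountain
#' (\code{nesting = "station"}) or transect-in-mountain (\code{nesting =
#' "transect"}, used for station-level evenness). Altitude is centred
#' internally; the coefficient table is reported on the raw altitude scale.
#'
#' @param data data.frame with the response, \code{altitude_m} and the
#'   hierarchy labels.
#' @param response name of the response column.
#' @param degree altitude polynomial degree, 1 or 2.
#' @param family \code{"gaussian"} or \code{"poisson"}.
#' @param nesting \code{"station"} or \code{"transect"}.
#' @return A `gradientFit`: list with \code{coefficients} (term, estimate,
#'   se, z, p — Wald normal approximation), \code{varcomp},
#'   \code{logLik}, \code{nObs}, \code{converged}, and the underlying
#'   \code{model}.
#' @export
fitAltitudeTrend <- function(data, response, degree = 2,
                             family = c("gaussian", "poisson"),
                             nesting = c("station", "transect")) {
  family <- match.arg(family)
  nesting <- match.arg(nesting)
  stopifnot(degree %in% 1:2)
  d <- .prepTrendData(data, response, nesting)
  fixed <- if (degree == 2) "altc + altc2" else "altc"
  form <- stats::as.formula(paste("y ~", fixed, "+", .reTerms(nesting)))
  fit <- .fitOnce(form, d, family)
  conv <- .isConverged(fit)
  if (!conv) {
    fit2 <- tryCatch(.fitOnce(form, d, family, "bobyqa"),
                     error = function(e) NULL)
    if (!is.null(fit2) && as.numeric(logLik(fit2)) >=
          as.numeric(logLik(fit)) - 1e-8) {
      fit <- fit2
      conv <- .isConverged(fit2)
    }
  }
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  raw <- .rawTransform(beta, V, attr(d, "center"), attr(d, "scale"),
                       degree)
  terms <- c("(Intercept)", "altitude", "altitude_sq")[seq_len(degree + 1)]
  z <- raw$estimate / raw$se
  coefs <- data.frame(term = terms, estimate = raw$estimate, se = raw$se,
                      z = z, p = 2 * pnorm(-abs(z)),
                      stringsAsFactors = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(coefficients = coefs,
                 varcomp = data.frame(group = vc$grp, variance = vc$vcov,
                                      sd = vc$sdcor),
                 logLik = as.numeric(logLik(fit)), nObs = nrow(d),
                 converged = conv, degree = degree, family = family,
                 nesting = nesting, center = attr(d, "center"),
                 scale = attr(d, "scale"),
                 altRange = range(d$altitude_m), model = fit),
            class = "gradientFit")
}

#' @export
print.gradientFit <- function(x, ...) {
  cat(sprintf("Altitude trend (%s, degree %d, %s nesting; n = %d, logLik = %.2f%s)\n",
              x$family, x$degree, x$nesting, x$nObs, x$logLik,
              if (x$converged) "" else "; NOT CONVERGED"))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Altitude of the fitted quadratic vertex
#'
#' -b1 / (2 b2) on the raw altitude scale; warns when the vertex lies
#' outside the observed altitude range.
#'
#' @param fit a degree-2 `gradientFit`.
#' @return vertex altitude (m).
#' @export
trendVertex <- function(fit) {
  stopifnot(inherits(fit, "gradientFit"), fit$degree == 2)
  b <- fit$coefficients$estimate
  v <- -b[2] / (2 * b[3])
  rng <- range(fit$altRange)
  if (v < rng[1] || v > rng[2])
    warning(sprintf("vertex %.0f m lies outside the sampled range [%.0f, %.0f]",
                    v, rng[1], rng[2]))
  v
}

#' Likelihood-ratio test of quadratic vs linear altitude
#'
#' Both models are fitted by ML with identical random structure; the
#' statistic is twice the log-likelihood gain, referred to a chi-square with
#' 1 df. A negative gain beyond tolerance triggers refits with alternative
#' optimisers before erroring.
#'
#' @inheritParams fitAltitudeTrend
#' @return An `lrtResult`: list with \code{chisq}, \code{df}, \code{p}, and
#'   the two `gradientFit`s.
#' @export
lrtQuadratic <- function(data, response, family = c("gaussian", "poisson"),
                         nesting = c("station", "transect")) {
  family <- match.arg(family)
  nesting <- match.arg(nesting)
  f1 <- fitAltitudeTrend(data, response, 1, family, nesting)
  f2 <- fitAltitudeTrend(data, response, 2, family, nesting)
  chisq <- 2 * (f2$logLik - f1$logLik)
  if (chisq < -1e-6) {
    for (opt in c("bobyqa", "Nelder_Mead")) {
      refit <- tryCatch(
        .fitOnce(stats::formula(f2$model), f2$model@frame, family, opt),
        error = function(e) NULL)
      if (!is.null(refit) &&
            as.numeric(logLik(refit)) > f2$logLik) {
        f2$logLik <- as.numeric(logLik(refit))
        f2$model <- refit
      }
    }
    chisq <- 2 * (f2$logLik - f1$logLik)
    if (chisq < -1e-6)
      stop("quadratic model log-likelihood below nested linear model ",
           "after restarts (difference ", format(chisq / 2), ")")
  }
  chisq <- max(chisq, 0)
  structure(list(chisq = chisq, df = 1L,
                 p = pchisq(chisq, 1, lower.tail = FALSE),
                 linear = f1, quadratic = f2),
            class = "lrtResult")
}

#' @export
print.lrtResult <- function(x, ...) {
  cat(sprintf("LRT: chisq = %.3f, df = %d, p = %.4g\n",
              x$chisq, x$df, x$p))
  invisible(x)
}

#' Scale x altitude interaction model for beta diversity
#'
#' Fits the full model \code{distance ~ (altitude + altitude^2) * scale}
#' with station-in-transect-in-mountain random intercepts, a
#' likelihood-ratio test of the quadratic-by-scale interaction (df = number
#' of scales - 1), and per-scale subset models reporting linear and
#' quadratic altitude terms.
#'
#' @param betaTab output of [betaDiversityAllScales()] (needs the three
#'   scales).
#' @return A `scaleTrendFit`: list with \code{full} (merMod),
#'   \code{fullCoefficients}, \code{interactionLRT}, \code{subsets}
#'   (named list of `gradientFit`), \code{nObs}, \code{rankX},
#'   \code{center}.
#' @export
scaleInteractionFit <- function(betaTab) {
  if (!"scale" %in% names(betaTab)) stop("scale column required")
  betaTab$scale <- droplevels(factor(betaTab$scale))
  if (nlevels(betaTab$scale) != 3)
    stop("three scales required, got ",
         paste(levels(betaTab$scale), collapse = ", "))
  d <- .prepTrendData(betaTab, "distance", "station")
  full <- .fitOnce(y ~ (altc + altc2) * scale + (1 | g1) + (1 | g2) +
                     (1 | g3), d, "gaussian")
  redQ <- .fitOnce(y ~ altc * scale + altc2 + (1 | g1) + (1 | g2) +
                     (1 | g3), d, "gaussian")
  chisq <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(redQ))))
  dfI <- nlevels(d$scale) - 1L
  interactionLRT <- structure(
    list(chisq = chisq, df = dfI,
         p = pchisq(chisq, dfI, lower.tail = FALSE)),
    class = "lrtResult")
  subsets <- lapply(levels(betaTab$scale), function(sc)
    fitAltitudeTrend(betaTab[betaTab$scale == sc, , drop = FALSE],
                     "distance", 2, "gaussian", "station"))
  names(subsets) <- levels(betaTab$scale)
  b <- lme4::fixef(full)
  se <- sqrt(diag(as.matrix(vcov(full))))
  z <- b / se
  structure(list(full = full,
                 fullCoefficients = data.frame(
                   term = names(b), estimate = unname(b), se = unname(se),
                   z = unname(z), p = unname(2 * pnorm(-abs(z))),
                   stringsAsFactors = FALSE),
                 interactionLRT = interactionLRT, subsets = subsets,
                 nObs = nrow(d),
                 rankX = qr(lme4::getME(full, "X"))$rank,
                 center = attr(d, "center")),
            class = "scaleTrendFit")
}

#' @export
print.scaleTrendFit <- function(x, ...) {
  cat(sprintf("Beta-diversity scale model (n = %d)\n", x$nObs))
  cat(sprintf("quadratic x scale interaction: chisq = %.3f, df = %d, p = %.4g\n",
              x$interactionLRT$chisq, x$interactionLRT$df,
              x$interactionLRT$p))
  for (sc in names(x$subsets)) {
    cat(sprintf("-- subset: %s\n", sc))
    print(x$subsets[[sc]]$coefficients, row.names = FALSE, digits = 4)
  }
  invisible(x)
}

#' Pairwise scale contrasts with multivariate-t (Tukey-style) adjustment
#'
#' Contrasts the estimated marginal means of the three spatial scales at the
#' mean altitude. The adjusted p-value for each contrast is the probability
#' that the maximum absolute component of a trivariate t (with the
#' contrasts' estimated correlation and df = n - rank of the fixed-effect
#' design) exceeds the observed |t|.
#'
#' @param x a `scaleTrendFit`.
#' @return data.frame with columns \code{contrast}, \code{estimate},
#'   \code{se}, \code{t}, \code{df}, \code{p}. Swapping the two levels of a
#'   pair flips the sign of the estimate and t.
#' @export
tukeyScaleContrasts <- function(x) {
  stopifnot(inherits(x, "scaleTrendFit"))
  fit <- x$full
  beta <- lme4::fixef(fit)
  V <- as.matrix(vcov(fit))
  lv <- levels(fit@frame$scale)
  ## marginal mean of level s at the mean altitude (altc = 0, altc2 = 0)
  L <- matrix(0, length(lv), length(beta),
              dimnames = list(lv, names(beta)))
  L[, "(Intercept)"] <- 1
  for (s in lv[-1]) L[s, paste0("scale", s)] <- 1
  pairs <- utils::combn(lv, 2)
  C <- t(apply(pairs, 2, function(pr) L[pr[2], ] - L[pr[1], ]))
  est <- drop(C %*% beta)
  Vc <- C %*% V %*% t(C)
  se <- sqrt(diag(Vc))
  tval <- est / se
  df <- x$nObs - x$rankX
  corr <- stats::cov2cor(Vc)
  padj <- vapply(abs(tval), function(tt)
    1 - mvtnorm::pmvt(lower = rep(-tt, length(tval)),
                      upper = rep(tt, length(tval)),
                      df = as.integer(df), corr = corr,
                      algorithm = mvtnorm::GenzBretz(abseps = 1e-8))[1],
    numeric(1))
  data.frame(contrast = paste(pairs[2, ], "-", pairs[1, ]),
             estimate = est, se = se, t = tval, df = df,
             p = pmin(pmax(padj, 0), 1), stringsAsFactors = FALSE)
}
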