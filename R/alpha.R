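## Alpha diversity: scaled Shannon evenness and the cover logit.

#' Scaled Shannon evenness of a count vector
#'
#' Shannon entropy H = -sum p_i ln p_i over species with positive counts,
#' scaled by its maximum ln S so that 1 is complete evenness and a
#' single-species community scores 0.
#'
#' @param counts named non-negative numeric vector (e.g. pooled
#'   point-intercept touches per species).
#' @return list with \code{H} (nats), \code{S} (species count) and \code{J}
#'   (scaled evenness in [0,1]).
#' @examples
#' scaledShannon(c(a = 30, b = 10))  # J = 0.811
#' @export
scaledShannon <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all counts are zero")
  p <- counts / sum(counts)
  H <- -sum(p * log(p))
  S <- length(p)
  J <- if (S == 1) 0 else H / log(S)
  list(H = H, S = S, J = J)
}

#' Station evenness table from intercept counts
#'
#' @param stationCounts list of station-level `interceptCounts` (see
#'   [poolStationCounts()]); stations with no touches are returned with NA
#'   evenness.
#' @return data.frame with columns \code{station}, \code{H}, \code{S},
#'   \code{J}.
#' @export
stationEvennessTable <- function(stationCounts) {
  rows <- lapply(stationCounts, function(ic) {
    if (!length(ic$counts) || sum(ic$counts) == 0)
      return(data.frame(station = ic$station, H = NA_real_, S = 0L,
                        J = NA_real_, stringsAsFactors = FALSE))
    ev <- scaledShannon(ic$counts)
    data.frame(station = ic$station, H = ev$H, S = ev$S, J = ev$J,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Logit-transform a cover proportion
#'
#' Proportions are clamped to [eps, 1 - eps] before the logit so that bare
#' (0) and fully covered (1) plots remain finite; eps defaults to 0.005,
#' half the 1% resolution of a visual cover estimate.
#'
#' @param p cover proportion(s) in [0,1].
#' @param eps clamp width.
#' @return numeric vector of logits, with a logical \code{clamped} attribute
#'   flagging values that were clamped.
#' @export
logitCover <- function(p, eps = 0.005) {
  if (any(p < 0 | p > 1 | !is.finite(p)))
    stop("cover must lie in [0,1]")
  clamped <- p < eps | p > 1 - eps
  pc <- pmin(pmax(p, eps), 1 - eps)
  structure(log(pc / (1 - pc)), clamped = clamped)
}

#' Per-plot alpha-diversity table
#'
#' Plot-level richness and logit cover together with the sampling hierarchy,
#' ready for the altitude trend models.
#'
#' @param records plot-record data.frame.
#' @return data.frame with \code{mountain}, \code{transect}, \code{station},
#'   \code{plot}, \code{altitude_m}, \code{cover}, \code{cover_logit},
#'   \code{richness}.
#' @export
plotAlphaTable <- function(records) {
  records$species <- .normaliseSpecies(records$species)
  sets <- speciesSets(records)
  rich <- vapply(sets, function(x) sum(!is.na(x)), integer(1))
  out <- records[, c("mountain", "transect", "station", "plot",
                     "altitude_m", "cover")]
  out$cover_logit <- as.numeric(logitCover(records$cover))
  out$richness <- rich
  out
}
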