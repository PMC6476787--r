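## Survey data model: altitude bands, long-format record I/O, matrix
## construction, point-intercept pooling.

#' Default altitude bands
#'
#' The four survey elevation bands. Bands are lower-inclusive and
#' upper-exclusive; the top band is open above.
#'
#' @return data.frame with columns \code{lower}, \code{upper} (metres) and
#'   \code{label}.
#' @export
defaultBands <- function() {
  data.frame(lower = c(700, 900, 1100, 1300),
             upper = c(900, 1100, 1300, Inf),
             label = c("700-900", "900-1100", "1100-1300", ">1300"),
             stringsAsFactors = FALSE)
}

.checkBands <- function(bands) {
  stopifnot(is.data.frame(bands), all(c("lower", "upper") %in% names(bands)))
  if (any(bands$lower >= bands$upper))
    stop("each band must have lower < upper")
  o <- order(bands$lower)
  b <- bands[o, ]
  if (nrow(b) > 1 && any(b$upper[-nrow(b)] > b$lower[-1]))
    stop("bands overlap")
  if (is.null(bands$label))
    bands$label <- ifelse(is.finite(bands$upper),
                          paste0(bands$lower, "-", bands$upper),
                          paste0(">", bands$lower))
  bands
}

#' Assign altitudes to elevation bands
#'
#' Band membership is lower-inclusive, upper-exclusive, so e.g. 900 m falls
#' in the 900-1100 band.
#'
#' @param altitude numeric vector of altitudes (m a.s.l.).
#' @param bands band table as from [defaultBands()].
#' @return character vector of band labels (factor-ordered by lower edge).
#' @export
assignBand <- function(altitude, bands = defaultBands()) {
  bands <- .checkBands(bands)
  out <- rep(NA_character_, length(altitude))
  for (k in seq_len(nrow(bands))) {
    hit <- altitude >= bands$lower[k] & altitude < bands$upper[k]
    out[hit] <- bands$label[k]
  }
  if (anyNA(out))
    stop("altitude(s) outside all bands: ",
         paste(unique(altitude[is.na(out)]), collapse = ", "))
  factor(out, levels = bands$label[order(bands$lower)])
}

.normaliseSpecies <- function(s) {
  ## ";"-separated species string -> sorted, de-duplicated set string
  sets <- strsplit(ifelse(is.na(s), "", s), ";", fixed = TRUE)
  vapply(sets, function(x) {
    x <- sort(unique(trimws(x)))
    paste(x[nzchar(x)], collapse = ";")
  }, character(1))
}

speciesSets <- function(records)
  strsplit(ifelse(records$species == "", NA_character_, records$species),
           ";", fixed = TRUE)

.validateRecords <- function(rec) {
  need <- c("mountain", "transect", "station", "plot", "altitude_m",
            "cover", "species")
  miss <- setdiff(need, names(rec))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  for (col in c("mountain", "transect", "station", "plot"))
    if (any(!nzchar(as.character(rec[[col]]))))
      stop("empty labels in column '", col, "'")
  if (any(!is.finite(rec$altitude_m) | rec$altitude_m <= 0))
    stop("altitude_m must be finite and > 0")
  if (any(rec$cover < 0 | rec$cover > 1))
    stop("cover outside [0,1] after dialect conversion")
  key <- plotKeys(rec)
  if (anyDuplicated(key))
    stop("duplicated (mountain, transect, station, plot) key: ",
         key[anyDuplicated(key)])
  invisible(rec)
}

#' Read long-format plot records
#'
#' Accepts the long form (`mountain,transect,station,plot,altitude_m,cover,
#' species` with a ";"-separated species list) or the wide binary form
#' (one 0/1 column per species after `cover`). Cover may be recorded as a
#' percentage (0-100, optionally with a trailing `%`) or a proportion (0-1);
#' by default the dialect is detected from the maximum value.
#'
#' @param path CSV file.
#' @param cover one of \code{"auto"}, \code{"percent"}, \code{"proportion"}.
#' @return data.frame of validated plot records (cover as a proportion,
#'   species as a normalised ";"-separated set string).
#' @export
readPlotRecords <- function(path, cover = c("auto", "percent", "proportion")) {
  cover <- match.arg(cover)
  if (!file.exists(path)) stop("no such file: ", path)
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 comment.char = "#")
  need <- c("mountain", "transect", "station", "plot", "altitude_m", "cover")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  cv <- df$cover
  if (is.character(cv)) cv <- as.numeric(sub("%$", "", trimws(cv)))
  if (anyNA(cv)) stop("non-numeric cover values")
  dialect <- switch(cover,
    auto = if (max(cv) > 1) "percent" else "proportion",
    cover)
  if (dialect == "percent") {
    if (any(cv < 0 | cv > 100)) stop("cover outside [0,100] (percent dialect)")
    cv <- cv / 100
  } else if (any(cv < 0 | cv > 1)) {
    stop("cover outside [0,1] (proportion dialect)")
  }
  if ("species" %in% names(df)) {
    sp <- .normaliseSpecies(as.character(df$species))
  } else {
    spCols <- setdiff(names(df), need)
    if (!length(spCols))
      stop("missing column(s): species (or wide binary species columns)")
    bin <- as.matrix(df[spCols])
    if (!all(bin %in% c(0, 1))) stop("wide species columns must be 0/1")
    sp <- apply(bin, 1, function(r) paste(sort(spCols[r == 1]),
                                          collapse = ";"))
  }
  rec <- data.frame(mountain = as.character(df$mountain),
                    transect = as.character(df$transect),
                    station = as.character(df$station),
                    plot = as.character(df$plot),
                    altitude_m = as.numeric(df$altitude_m),
                    cover = cv, species = sp,
                    stringsAsFactors = FALSE)
  .validateRecords(rec)
  rec
}

#' Write plot records (long form, proportion cover)
#'
#' Inverse of [readPlotRecords()]; reading the written file recovers the
#' records exactly.
#'
#' @param records plot-record data.frame.
#' @param path output CSV path.
#' @export
writePlotRecords <- function(records, path) {
  records$species <- .normaliseSpecies(records$species)
  .validateRecords(records)
  write.csv(records[, c("mountain", "transect", "station", "plot",
                        "altitude_m", "cover", "species")],
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Build a binary community matrix from plot records
#'
#' One row per plot record; species columns are sorted by decreasing
#' occurrence frequency, ties broken by label. Species observed nowhere do
#' not appear.
#'
#' @param records plot-record data.frame (see [readPlotRecords()]).
#' @return A \code{\linkS4class{CommunityMatrix}}.
#' @export
buildCommunityMatrix <- function(records) {
  if (!nrow(records)) stop("empty record list")
  records$species <- .normaliseSpecies(records$species)
  .validateRecords(records)
  sets <- speciesSets(records)
  sets <- lapply(sets, function(x) x[!is.na(x)])
  allSp <- sort(unique(unlist(sets)))
  inc <- matrix(0L, nrow(records), length(allSp),
                dimnames = list(plotKeys(records), allSp))
  for (i in seq_along(sets))
    inc[i, sets[[i]]] <- 1L
  freq <- colSums(inc)
  ord <- order(-freq, colnames(inc))
  inc <- inc[, ord, drop = FALSE]
  CommunityMatrix(inc, records[, c("mountain", "transect", "station",
                                   "plot", "altitude_m")])
}

#' Recover plot records from a community matrix
#'
#' Inverse of [buildCommunityMatrix()] on incidence content (cover is not
#' stored in the matrix and is returned as NA unless supplied).
#'
#' @param x a \code{CommunityMatrix}.
#' @param cover optional per-plot cover proportions.
#' @return plot-record data.frame.
#' @export
matrixToRecords <- function(x, cover = NA_real_) {
  pd <- plotData(x)
  inc <- incidence(x)
  sp <- apply(inc, 1, function(r) paste(sort(colnames(inc)[r == 1]),
                                        collapse = ";"))
  data.frame(mountain = pd$mountain, transect = pd$transect,
             station = pd$station, plot = pd$plot,
             altitude_m = pd$altitude_m, cover = cover, species = unname(sp),
             stringsAsFactors = FALSE)
}

#' Read / write a community matrix as CSV
#'
#' Format: columns `mountain,transect,station,plot,altitude_m` followed by
#' one 0/1 column per species. Externally supplied presence-absence matrices
#' can be adapted to this shape by prepending the metadata columns.
#'
#' @param path CSV file.
#' @param keepEmptySpecies keep all-zero species columns (default FALSE).
#' @return A \code{\linkS4class{CommunityMatrix}}.
#' @export
readCommunityMatrix <- function(path, keepEmptySpecies = FALSE) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                 comment.char = "#")
  meta <- c("mountain", "transect", "station", "plot", "altitude_m")
  miss <- setdiff(meta, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  spCols <- setdiff(names(df), meta)
  inc <- as.matrix(df[spCols])
  if (!all(inc %in% c(0, 1))) stop("species columns must be 0/1")
  if (!keepEmptySpecies)
    inc <- inc[, colSums(inc) > 0, drop = FALSE]
  pd <- df[meta]
  pd$mountain <- as.character(pd$mountain)
  pd$transect <- as.character(pd$transect)
  pd$station <- as.character(pd$station)
  pd$plot <- as.character(pd$plot)
  CommunityMatrix(inc, pd)
}

#' @rdname readCommunityMatrix
#' @param x a \code{CommunityMatrix}.
#' @export
writeCommunityMatrix <- function(x, path) {
  df <- cbind(plotData(x)[, c("mountain", "transect", "station", "plot",
                              "altitude_m")],
              as.data.frame(incidence(x), check.names = FALSE))
  write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Point-intercept counts for one sampling unit
#'
#' @param station station label.
#' @param counts named non-negative integer vector of touches per species.
#' @param nPoints number of intercept points examined (25 per plot in the
#'   survey design; pooling five plots gives 125 per station).
#' @return An `interceptCounts` list.
#' @export
interceptCounts <- function(station, counts, nPoints) {
  counts <- counts[counts > 0]
  stopifnot(nPoints >= 1, all(counts >= 0))
  if (length(counts) && is.null(names(counts)))
    stop("counts must be named by species")
  structure(list(station = as.character(station),
                 counts = counts, nPoints = as.integer(nPoints)),
            class = "interceptCounts")
}

#' Pool point-intercept counts to the station level
#'
#' Sums per-species touch counts and point totals across sampling units of
#' one station (the survey design pools five 25-point plots to 125 points).
#'
#' @param countsList list of `interceptCounts`, all for the same station.
#' @param station optional station label to check against.
#' @return A pooled `interceptCounts`.
#' @export
poolStationCounts <- function(countsList, station = NULL) {
  stopifnot(length(countsList) >= 1)
  stations <- vapply(countsList, `[[`, character(1), "station")
  if (is.null(station)) station <- stations[1]
  if (any(stations != station))
    stop("mixed stations in pooled counts: ",
         paste(unique(stations), collapse = ", "))
  all <- unlist(lapply(countsList, `[[`, "counts"))
  counts <- if (length(all)) {
    tp <- tapply(all, names(all), sum)
    setNames(as.numeric(tp), names(tp))[order(names(tp))]
  } else numeric()
  interceptCounts(station, counts,
                  sum(vapply(countsList, `[[`, integer(1), "nPoints")))
}

#' Read long-form intercept counts (`station,species,count` CSV)
#'
#' @param path CSV file; an optional `n_points` column gives the point total
#'   per station (else the summed counts are used as a lower bound).
#' @return list of `interceptCounts`, one per station.
#' @export
readInterceptCounts <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("station", "species", "count")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  lapply(split(df, df$station), function(d) {
    np <- if ("n_points" %in% names(d)) d$n_points[1] else sum(d$count)
    interceptCounts(d$station[1], setNames(d$count, d$species), np)
  })
}
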