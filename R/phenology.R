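#' Ice/water index of a classified raster
#'
#' The proportion of ice to open water over a water mask:
#' `(n_ice - n_water) / (n_ice + n_water)`. Extreme values of -1.0 and +1.0
#' represent open water and completely frozen water bodies. LAND and CLOUD
#' cells are null: excluded from both counts. If every masked cell is null
#' the index is undefined (flagged, not an error).
#'
#' @param raster An `ice_raster`.
#' @param mask Logical matrix with the raster's dimensions selecting the
#'   water-body cells (e.g. from [water_mask()]); must select at least one
#'   cell.
#' @return A list with `index` (NA when undefined), `n_ice`, `n_water`,
#'   and `undefined`.
#' @examples
#' g <- matrix(c(1, 1, 2, 0), 2, 2)
#' r <- structure(list(year = 2010, doy = 33, grid = g, cellsize = 500),
#'                class = "ice_raster")
#' ice_index(r, g != 0)
#' @export
ice_index <- function(raster, mask) {
  stopifnot(is.logical(mask), all(dim(mask) == dim(raster$grid)))
  if (!any(mask)) stop("empty water mask: no cells selected")
  cls <- raster$grid[mask]
  n_ice <- sum(cls == CLASS_ICE)
  n_water <- sum(cls == CLASS_WATER)
  if (n_ice + n_water == 0L) {
    return(list(index = NA_real_, n_ice = 0L, n_water = 0L, undefined = TRUE))
  }
  list(index = (n_ice - n_water) / (n_ice + n_water),
       n_ice = n_ice, n_water = n_water, undefined = FALSE)
}

#' Ice-index time series over a raster series
#'
#' Applies [ice_index()] to every raster, restricted to a water mask.
#'
#' @param series An `ice_series`.
#' @param mask Logical water mask (see [ice_index()]).
#' @return Data frame `year`, `doy`, `index`, `n_ice`, `n_water`,
#'   `undefined`, sorted by time.
#' @export
ice_index_series <- function(series, mask) {
  out <- do.call(rbind, lapply(series, function(r) {
    v <- ice_index(r, mask)
    data.frame(year = r$year, doy = r$doy, index = v$index,
               n_ice = v$n_ice, n_water = v$n_water, undefined = v$undefined)
  }))
  out[order(out$year, out$doy), ]
}

# locate sign crossings of one kind in a (doy, index) series and keep the
# last one after which the sign persists for >= `persist` records (or all
# remaining records when fewer are left)
find_crossing <- function(doy, index, from_positive, persist = 2L) {
  n <- length(index)
  if (n < 2L) return(NULL)
  cand <- NULL
  for (i in seq_len(n - 1L)) {
    s1 <- index[i]; s2 <- index[i + 1L]
    hit <- if (from_positive) s1 > 0 && s2 <= 0 else s1 < 0 && s2 >= 0
    if (!hit) next
    ahead <- index[(i + 1L):min(n, i + persist)]
    stable <- if (from_positive) all(ahead <= 0) else all(ahead >= 0)
    if (!stable) next
    day <- doy[i] + (0 - s1) * (doy[i + 1L] - doy[i]) / (s2 - s1)
    cand <- day
  }
  cand
}

#' Breakup and freeze dates from an ice-index series
#'
#' Dates the x-intercepts of the ice/water index within one year. With ice
#' counted positively, breakup is a positive-to-negative crossing searched
#' before mid-year (day 183) and freeze-up a negative-to-positive crossing
#' searched from mid-year on. Crossings are located by linear interpolation
#' between the bracketing 8-day records; undefined (all-cloud) periods are
#' skipped; among multiple crossings the last one whose sign persists for at
#' least two subsequent records is taken (robust to single-period flickers).
#'
#' @param series Data frame from [ice_index_series()].
#' @param year Year to date.
#' @return List with `breakup_doy` and `freeze_doy` (fractional day-of-year;
#'   NA with the corresponding flag set when no qualifying crossing exists)
#'   and logical flags `breakup_missing`, `freeze_missing`.
#' @export
phenology_dates <- function(series, year) {
  s <- series[series$year == year & !series$undefined & !is.na(series$index), ]
  s <- s[order(s$doy), ]
  if (nrow(s) < 3L) stop("need >= 3 valid index records in year ", year)
  first_half <- s[s$doy <= 191, ]   # include the record bracketing day 183
  second_half <- s[s$doy >= 175, ]
  breakup <- find_crossing(first_half$doy, first_half$index, from_positive = TRUE)
  freeze <- find_crossing(second_half$doy, second_half$index, from_positive = FALSE)
  if (!is.null(breakup) && breakup > 183) breakup <- NULL
  if (!is.null(freeze) && freeze < 183) freeze <- NULL
  list(breakup_doy = if (is.null(breakup)) NA_real_ else breakup,
       freeze_doy = if (is.null(freeze)) NA_real_ else freeze,
       breakup_missing = is.null(breakup),
       freeze_missing = is.null(freeze))
}

#' Per-year phenology table from an index series
#'
#' Runs [phenology_dates()] for every year in the series and derives the
#' ice-availability window of each winter via [ice_window()].
#'
#' @param series Data frame from [ice_index_series()].
#' @return Data frame of class `phenology_series`: `year`, `breakup_doy`,
#'   `freeze_doy`, `window_days`, `flags` (comma-separated missing-date
#'   markers, empty when complete).
#' @export
phenology_series <- function(series) {
  years <- sort(unique(series$year))
  rows <- lapply(years, function(y) {
    d <- phenology_dates(series, y)
    flags <- c(if (d$breakup_missing) "breakup_missing",
               if (d$freeze_missing) "freeze_missing")
    data.frame(year = y, breakup_doy = d$breakup_doy, freeze_doy = d$freeze_doy,
               window_days = NA_real_, flags = paste(flags, collapse = ","))
  })
  out <- do.call(rbind, rows)
  for (i in seq_len(nrow(out))) {
    out$window_days[i] <- ice_window(out, out$year[i])
  }
  class(out) <- c("phenology_series", "data.frame")
  out
}

#' Ice-availability window of a winter
#'
#' Days between freeze-up of year `year - 1` and breakup of `year` — the
#' window during which ice supports travel, labelled by its breakup year.
#' NA (flagged missing) when either endpoint is missing.
#'
#' @param phenology Data frame with `year`, `breakup_doy`, `freeze_doy`
#'   (e.g. from [phenology_series()]).
#' @param year Breakup year labelling the winter.
#' @return Window length in days, or NA.
#' @export
ice_window <- function(phenology, year) {
  b <- phenology$breakup_doy[phenology$year == year]
  f <- phenology$freeze_doy[phenology$year == year - 1]
  if (length(b) != 1L || length(f) != 1L || is.na(b) || is.na(f)) return(NA_real_)
  (days_in_year(year - 1) - f) + b
}

#' Linear trend of phenology dates across years
#'
#' Ordinary least-squares regression of a date (day-of-year) on calendar
#' year, with the F test of zero slope on `n - 2` denominator df.
#'
#' @param year Numeric vector of years.
#' @param date Numeric vector of dates (day-of-year), NAs dropped pairwise.
#' @return List with `slope`, `intercept`, `F`, `df` (denominator), `p`,
#'   and the fitted `lm` object as `fit`.
#' @export
trend_regression <- function(year, date) {
  keep <- !is.na(year) & !is.na(date)
  fit <- stats::lm(date ~ year, data = data.frame(year = year[keep], date = date[keep]))
  if (stats::var(date[keep]) < .Machine$double.eps * mean(date[keep])^2) {
    # constant response: zero model sum of squares by definition
    return(list(slope = 0, intercept = mean(date[keep]), F = 0,
                df = sum(keep) - 2L, p = 1, fit = fit))
  }
  an <- suppressWarnings(stats::anova(fit))
  Fv <- an$`F value`[1]
  p <- an$`Pr(>F)`[1]
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       F = Fv, df = an$Df[2], p = p, fit = fit)
}

#' Write a phenology table to CSV
#'
#' @param phenology A [phenology_series()] data frame.
#' @param path Output path for `year,breakup_doy,freeze_doy,window_days,flags`.
#' @export
write_phenology_csv <- function(phenology, path) {
  utils::write.csv(as.data.frame(phenology), path, row.names = FALSE)
  invisible(path)
}
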