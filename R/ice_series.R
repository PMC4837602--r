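#' Ground-truth phenology for the ice-raster generator
#'
#' Per-year true breakup and freeze dates plus the observation model of the
#' classified product: a logistic transition of the per-cell ice probability
#' around the true dates, symmetric classification noise, and cloud gaps.
#'
#' @param breakup_doy,freeze_doy True day-of-year of breakup (ice to open
#'   water) and freeze-up (open water to ice); recycled over years. Freeze
#'   must exceed breakup within the calendar year. Defaults 148 (late May)
#'   and 323 (mid November), typical of large subarctic lakes.
#' @param steepness Logistic transition scale in days (default 3).
#' @param noise Probability in `[0, 1)` that a classified water cell is
#'   flipped ICE<->WATER.
#' @param cloud Probability in `[0, 1)` that a water cell is masked CLOUD.
#' @return A list of class `phenology_truth`.
#' @export
phenology_truth <- function(breakup_doy = 148, freeze_doy = 323,
                            steepness = 3, noise = 0, cloud = 0) {
  stopifnot(all(freeze_doy > breakup_doy), steepness > 0,
            noise >= 0, noise < 1, cloud >= 0, cloud < 1)
  structure(list(breakup_doy = breakup_doy, freeze_doy = freeze_doy,
                 steepness = steepness, noise = noise, cloud = cloud),
            class = "phenology_truth")
}

# per-year truth value, recycled
truth_for_year <- function(truth, years, field) {
  v <- rep_len(truth[[field]], length(years))
  v
}

# Expected per-cell probability of ICE on day-of-year d given true dates.
# Frozen in winter on both sides of the open-water season; the mid-year split
# at day 183 separates the thaw and freeze limbs.
ice_probability <- function(doy, breakup, freeze, steepness) {
  ifelse(doy <= 183,
         stats::plogis((breakup - doy) / steepness),
         stats::plogis((doy - freeze) / steepness))
}

#' Day-of-year starts of the 8-day raster periods
#'
#' Periods are indexed from day-of-year 33 (start of February) in 8-day
#' windows, mirroring the cadence of the classified ice product; the period
#' timestamp is the first day of its window.
#'
#' @return Integer vector of period start days (33, 41, ..., 361).
#' @export
period_starts <- function() seq(33L, 361L, by = 8L)

#' Generate a seasonal series of classified ice rasters
#'
#' For every 8-day period of every year, each WATER cell of the landscape is
#' classified ICE with a probability following a logistic curve of day-of-year
#' around the year's true breakup/freeze dates, then flipped ICE<->WATER with
#' the noise rate and masked CLOUD with the gap probability. LAND cells are
#' always LAND. Deterministic for a given seed.
#'
#' @param landscape A [generate_landscape()] result.
#' @param truth A [phenology_truth()].
#' @param years Integer vector of years to simulate.
#' @param seed Integer RNG seed.
#' @return A list of class `ice_series`: one `ice_raster` per period per year,
#'   each a list with `year`, `doy` (period start), `grid` (integer matrix of
#'   class codes) and `cellsize`.
#' @examples
#' ls <- generate_landscape(landscape_config(), seed = 1)
#' series <- generate_ice_series(ls, phenology_truth(), years = 2011, seed = 1)
#' length(series)  # one raster per 8-day period
#' @export
generate_ice_series <- function(landscape, truth, years, seed = 1) {
  stopifnot(inherits(landscape, "landscape"), inherits(truth, "phenology_truth"))
  set.seed(seed)
  wmask <- landscape$grid == CLASS_WATER
  nwater <- sum(wmask)
  breakups <- truth_for_year(truth, years, "breakup_doy")
  freezes <- truth_for_year(truth, years, "freeze_doy")
  out <- list()
  for (yi in seq_along(years)) {
    for (doy in period_starts()) {
      p <- ice_probability(doy, breakups[yi], freezes[yi], truth$steepness)
      cls <- ifelse(stats::runif(nwater) < p, CLASS_ICE, CLASS_WATER)
      if (truth$noise > 0) {
        flip <- stats::runif(nwater) < truth$noise
        cls[flip] <- ifelse(cls[flip] == CLASS_ICE, CLASS_WATER, CLASS_ICE)
      }
      if (truth$cloud > 0) {
        cls[stats::runif(nwater) < truth$cloud] <- CLASS_CLOUD
      }
      grid <- landscape$grid
      grid[wmask] <- cls
      out[[length(out) + 1L]] <- structure(
        list(year = years[yi], doy = doy, grid = grid,
             cellsize = landscape$cellsize),
        class = "ice_raster")
    }
  }
  structure(out, class = "ice_series")
}

# Find the raster whose 8-day window contains (year, doy); days before the
# first February period fall in the last window of the previous year.
raster_for_date <- function(series, year, doy) {
  if (doy < 33) { year <- year - 1L; doy <- doy + days_in_year(year) }
  pstart <- 33L + 8L * ((as.integer(doy) - 33L) %/% 8L)
  pstart <- min(pstart, 361L)
  for (r in series) if (r$year == year && r$doy == pstart) return(r)
  NULL
}

#' Write an ice-raster series as plain gridded text
#'
#' Writes one whitespace-separated integer grid per raster (rows north to
#' south) plus a sidecar period-index CSV `year,period_start_doy,filename`.
#'
#' @param series An `ice_series`.
#' @param dir Output directory (created if needed).
#' @return The path of the index CSV, invisibly.
#' @export
write_ice_series <- function(series, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- data.frame(year = integer(), period_start_doy = integer(),
                    filename = character())
  for (r in series) {
    fn <- sprintf("ice_%d_%03d.txt", r$year, r$doy)
    utils::write.table(r$grid[rev(seq_len(nrow(r$grid))), , drop = FALSE],
                       file.path(dir, fn), row.names = FALSE,
                       col.names = FALSE)
    idx <- rbind(idx, data.frame(year = r$year, period_start_doy = r$doy,
                                 filename = fn))
  }
  ipath <- file.path(dir, "period_index.csv")
  utils::write.csv(idx, ipath, row.names = FALSE)
  invisible(ipath)
}

#' Read an ice-raster series written by [write_ice_series()]
#'
#' @param dir Directory holding the gridded text files and `period_index.csv`.
#' @param cellsize Cell size in metres of the grids.
#' @return An `ice_series`.
#' @export
read_ice_series <- function(dir, cellsize) {
  idx <- utils::read.csv(file.path(dir, "period_index.csv"))
  out <- lapply(seq_len(nrow(idx)), function(i) {
    g <- as.matrix(utils::read.table(file.path(dir, idx$filename[i])))
    dimnames(g) <- NULL
    g <- g[rev(seq_len(nrow(g))), , drop = FALSE]
    structure(list(year = idx$year[i], doy = idx$period_start_doy[i],
                   grid = g, cellsize = cellsize),
              class = "ice_raster")
  })
  structure(out, class = "ice_series")
}
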