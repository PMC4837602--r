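# Grid class codes shared by landscape grids and ice rasters.
CLASS_LAND  <- 0L
CLASS_ICE   <- 1L
CLASS_WATER <- 2L
CLASS_CLOUD <- 3L

#' Grid class codes
#'
#' The fixed integer codes used in landscape grids and classified ice rasters:
#' `LAND = 0`, `ICE = 1`, `WATER = 2`, `CLOUD = 3`. Landscape grids only use
#' LAND/WATER; ice rasters use all four.
#'
#' @return Named integer vector of the four class codes.
#' @export
ice_classes <- function() {
  c(LAND = CLASS_LAND, ICE = CLASS_ICE, WATER = CLASS_WATER, CLOUD = CLASS_CLOUD)
}

days_in_year <- function(year) {
  ifelse((year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0, 366L, 365L)
}

#' @noRd
wrap_angle <- function(a) {
  # wrap degrees into (-180, 180]
  w <- a %% 360
  w[!is.na(w) & w > 180] <- w[!is.na(w) & w > 180] - 360
  w
}

doy_of <- function(time) as.POSIXlt(time, tz = "UTC")$yday + 1L
year_of <- function(time) as.POSIXlt(time, tz = "UTC")$year + 1900L

# Run-length style grouping of a logical vector: returns integer group ids for
# TRUE runs, NA elsewhere.
true_runs <- function(flag) {
  r <- rle(flag)
  grp <- rep(NA_integer_, length(flag))
  idx <- cumsum(r$lengths)
  start <- idx - r$lengths + 1L
  gid <- cumsum(r$values)
  for (k in seq_along(r$values)) {
    if (r$values[k]) grp[start[k]:idx[k]] <- gid[k]
  }
  grp
}
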