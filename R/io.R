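#' Write telemetry to CSV
#'
#' Writes `id,timestamp,x,y,interval_h` with ISO-8601 UTC timestamps; any
#' extra columns (e.g. the simulator's ground-truth `state`) are dropped.
#'
#' @param fixes Telemetry data frame.
#' @param path Output path.
#' @export
write_telemetry_csv <- function(fixes, path) {
  out <- data.frame(
    id = fixes$id,
    timestamp = format(fixes$timestamp, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
    x = fixes$x, y = fixes$y, interval_h = fixes$interval_h)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read telemetry from CSV
#'
#' @param path CSV with columns `id,timestamp,x,y,interval_h` (ISO-8601 UTC
#'   timestamps).
#' @return Telemetry data frame with POSIXct timestamps.
#' @export
read_telemetry_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  d
}

#' Write a segment table to CSV
#'
#' @param segments Data frame from [classify_segments()].
#' @param path Output path.
#' @export
write_segments_csv <- function(segments, path) {
  seg <- segments
  seg$start <- format(seg$start, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  seg$end <- format(seg$end, "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  utils::write.csv(seg, path, row.names = FALSE)
  invisible(path)
}

#' Write per-draw validation correlations to CSV
#'
#' @param validation An `ssf_validation` from [kfold_validate()].
#' @param path Output path for `draw,r_s`.
#' @export
write_validation_csv <- function(validation, path) {
  utils::write.csv(validation$per_draw, path, row.names = FALSE)
  invisible(path)
}
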