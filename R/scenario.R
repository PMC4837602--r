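#' Scenario configuration
#'
#' Parameters of the phenology-shift scenario analysis: breakup advances and
#' freeze delays are applied in 1-day increments up to `max_shift`; the named
#' `projections` are literature day-shift ranges for the 2041-2070 horizon
#' (defaults: spring breakup advance 10-15 days, fall freeze delay 7.8-13.8
#' days); `window` is the span of days after freeze-up / before breakup used
#' for the travel-distance comparison.
#'
#' @param max_shift Maximum phenology shift in days (default 30).
#' @param increment Shift increment in days (default 1).
#' @param window Analysis window in days around freeze/breakup (default 15,
#'   closed at both ends).
#' @param projections Named list; each element a list with numeric `advance`
#'   and/or `delay` day-shift ranges.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(max_shift = 30, increment = 1, window = 15,
                            projections = list(
                              horizon_2041_2070 = list(advance = c(10, 15),
                                                       delay = c(7.8, 13.8)))) {
  stopifnot(max_shift >= 0, increment > 0, window > 0)
  structure(list(max_shift = max_shift, increment = increment,
                 window = window, projections = projections),
            class = "scenario_config")
}

#' Proportion as a percentage
#'
#' Reporting helper used throughout the scenario summaries.
#'
#' @param n Count (numerator).
#' @param total Total (denominator).
#' @return `100 * n / total`.
#' @export
proportion_pct <- function(n, total) 100 * n / total

#' Percent change between observed and projected totals
#'
#' @param observed,projected Totals on the same scale (e.g. km travelled).
#' @return `100 * (projected - observed) / observed`.
#' @export
percent_change <- function(observed, projected) {
  100 * (projected - observed) / observed
}

#' Flag ice crossings made impossible by a phenology shift
#'
#' A spring crossing is impossible when breakup advanced by `d` days
#' precedes it (`doy > breakup - d`); a fall crossing is impossible when
#' freeze-up delayed by `d` days postdates it (`doy < freeze + d`).
#' Crossings whose year has no phenology estimate are excluded and counted.
#'
#' @param crossings Data frame of ice crossings with `year`, `doy` and
#'   `season` (`"spring"`/`"fall"`) columns (e.g. the `ice_crossing` rows of
#'   [classify_segments()]).
#' @param phenology Phenology table with `year`, `breakup_doy`, `freeze_doy`.
#' @param kind `"advance_breakup"` (applies to spring crossings) or
#'   `"delay_freeze"` (fall crossings).
#' @param d Shift in days (>= 0; fractional allowed).
#' @return List with `crossings` (the season's crossings plus an
#'   `impossible` flag), `n`, `n_impossible`, `pct_impossible`,
#'   `prop_possible`, `n_excluded`.
#' @export
impossible_crossings <- function(crossings, phenology,
                                 kind = c("advance_breakup", "delay_freeze"), d) {
  kind <- match.arg(kind)
  stopifnot(d >= 0)
  season <- if (kind == "advance_breakup") "spring" else "fall"
  cr <- crossings[crossings$season == season, , drop = FALSE]
  i <- match(cr$year, phenology$year)
  ref <- if (kind == "advance_breakup") phenology$breakup_doy[i] else
    phenology$freeze_doy[i]
  excl <- is.na(ref)
  n_excluded <- sum(excl)
  cr <- cr[!excl, , drop = FALSE]; ref <- ref[!excl]
  cr$impossible <- if (kind == "advance_breakup") cr$doy > ref - d else
    cr$doy < ref + d
  n <- nrow(cr); ni <- sum(cr$impossible)
  list(crossings = cr, n = n, n_impossible = ni,
       pct_impossible = proportion_pct(ni, n),
       prop_possible = 1 - ni / n, n_excluded = n_excluded)
}

#' Lost-crossing curve over 1-day phenology shifts
#'
#' Evaluates [impossible_crossings()] for both seasons at every shift from 0
#' to `max_shift` in `increment`-day steps.
#'
#' @inheritParams impossible_crossings
#' @param config A [scenario_config()].
#' @return Data frame `season`, `shift_days`, `n_crossings`, `n_impossible`,
#'   `prop_possible`.
#' @export
scenario_curve <- function(crossings, phenology, config = scenario_config()) {
  shifts <- seq(0, config$max_shift, by = config$increment)
  rows <- lapply(c("advance_breakup", "delay_freeze"), function(kind) {
    do.call(rbind, lapply(shifts, function(d) {
      r <- impossible_crossings(crossings, phenology, kind, d)
      data.frame(season = if (kind == "advance_breakup") "spring" else "fall",
                 shift_days = d, n_crossings = r$n,
                 n_impossible = r$n_impossible,
                 prop_possible = r$prop_possible)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Weighted 8-connected lattice over traversable cells; vertex i = linear
# index of cell [iy, ix] in the grid matrix.
detour_graph <- function(landscape, excluded_classes = CLASS_WATER) {
  g <- landscape$grid
  ny <- nrow(g); nx <- ncol(g)
  land <- !(g %in% excluded_classes)
  dim(land) <- dim(g)
  cs <- landscape$cellsize
  idx <- function(iy, ix) (ix - 1L) * ny + iy
  edges <- list(); weights <- list()
  add <- function(iy1, ix1, iy2, ix2, w) {
    ok <- land[cbind(iy1, ix1)] & land[cbind(iy2, ix2)]
    if (!any(ok)) return()
    edges[[length(edges) + 1L]] <<- rbind(idx(iy1, ix1)[ok], idx(iy2, ix2)[ok])
    weights[[length(weights) + 1L]] <<- rep(w, sum(ok))
  }
  ys <- rep(seq_len(ny), nx); xs <- rep(seq_len(nx), each = ny)
  right <- xs < nx; up <- ys < ny
  add(ys[right], xs[right], ys[right], xs[right] + 1L, cs)
  add(ys[up], xs[up], ys[up] + 1L, xs[up], cs)
  dr <- right & up
  add(ys[dr], xs[dr], ys[dr] + 1L, xs[dr] + 1L, cs * sqrt(2))
  dl <- up & xs > 1L
  add(ys[dl], xs[dl], ys[dl] + 1L, xs[dl] - 1L, cs * sqrt(2))
  gr <- igraph::make_empty_graph(n = nx * ny, directed = FALSE)
  if (length(edges)) {
    gr <- igraph::add_edges(gr, as.vector(do.call(cbind, edges)),
                            weight = unlist(weights))
  }
  gr
}

#' Shortest land detour between two points
#'
#' Minimal-length path over traversable cells of the landscape grid
#' (8-connected, straight moves cost one cell size and diagonal moves
#' `sqrt(2)` cell sizes), avoiding water-body surfaces. Endpoints are
#' snapped to their containing cells and must be on land; endpoints enclosed
#' by water (no land-connected route) are an error.
#'
#' @param start,end Numeric `c(x, y)` endpoints (m), both on land.
#' @param landscape A `landscape`.
#' @param excluded_classes Grid classes that block the path (default WATER).
#' @param graph Optional prebuilt graph from a previous call (reuse when
#'   routing many detours over one landscape).
#' @return List with `length_m`, `path` (data frame of cell-centre vertices
#'   `x`, `y`), and `n_cells`.
#' @export
shortest_detour <- function(start, end, landscape,
                            excluded_classes = CLASS_WATER, graph = NULL) {
  cells <- cell_of(landscape, c(start[1], end[1]), c(start[2], end[2]))
  if (any(is.na(cells$ix))) stop("detour endpoint outside the landscape")
  cls <- landscape$grid[cbind(cells$iy, cells$ix)]
  if (any(cls %in% excluded_classes)) {
    stop("detour endpoint is not on land")
  }
  ny <- nrow(landscape$grid)
  v <- (cells$ix - 1L) * ny + cells$iy
  if (is.null(graph)) graph <- detour_graph(landscape, excluded_classes)
  dist <- igraph::distances(graph, v = v[1], to = v[2])[1, 1]
  if (!is.finite(dist)) {
    stop("no land route between detour endpoints (enclosed by water)")
  }
  vp <- igraph::shortest_paths(graph, from = v[1], to = v[2],
                               output = "vpath")$vpath[[1]]
  vi <- as.integer(vp)
  ix <- (vi - 1L) %/% ny + 1L
  iy <- (vi - 1L) %% ny + 1L
  cs <- landscape$cellsize
  list(length_m = dist,
       path = data.frame(x = landscape$origin[1] + (ix - 0.5) * cs,
                         y = landscape$origin[2] + (iy - 0.5) * cs),
       n_cells = length(vi))
}

# TRUE when a point lies inside any island polygon
on_island <- function(landscape, x, y) {
  for (isl in landscape$islands) {
    if (any(point_in_polygon(x, y, isl$poly))) return(TRUE)
  }
  FALSE
}

#' Projected travel-distance change when ice crossings become impossible
#'
#' Restricts the segment table to crossings and detours performed within the
#' first `window` days following freeze-up or preceding breakup, replaces
#' each replaceable ice crossing with its shortest land detour (crossings of
#' rivers or leading to islands, and crossings without a land route, are
#' kept at their original distance and counted separately), and reports
#' observed and projected totals, the percent change, per-crossing
#' detour-to-crossing distance ratios, and a paired t test of detour vs
#' crossing distances.
#'
#' @param segments Segment table from [classify_segments()].
#' @param phenology Phenology table (`year`, `breakup_doy`, `freeze_doy`).
#' @param landscape A `landscape`.
#' @param config A [scenario_config()].
#' @return List of class `scenario_result`: `totals` (`observed_km`,
#'   `projected_km`, `percent_change`), `replaced` (per-crossing table with
#'   `crossing_km`, `detour_km`, `ratio`), `paired_t` (`t`, `df`, `p`,
#'   `mean_ratio`), and `counts`.
#' @export
projected_distance_change <- function(segments, phenology, landscape,
                                      config = scenario_config()) {
  keep_class <- segments$class %in% c("ice_crossing", "water_crossing", "detour")
  seg <- segments[keep_class, , drop = FALSE]
  i <- match(seg$year, phenology$year)
  b <- phenology$breakup_doy[i]; f <- phenology$freeze_doy[i]
  w <- config$window
  in_window <- (seg$season == "spring" & !is.na(b) &
                  seg$doy >= b - w & seg$doy <= b) |
               (seg$season == "fall" & !is.na(f) &
                  seg$doy >= f & seg$doy <= f + w)
  seg <- seg[in_window, , drop = FALSE]
  observed_m <- sum(seg$distance_m)
  ice <- seg$class == "ice_crossing"
  graph <- NULL
  replaced <- list(); n_unreplaceable <- 0L
  for (r in which(ice)) {
    if (seg$body_type[r] == "river" ||
        on_island(landscape, c(seg$x1[r], seg$x2[r]), c(seg$y1[r], seg$y2[r]))) {
      n_unreplaceable <- n_unreplaceable + 1L
      next
    }
    if (is.null(graph)) graph <- detour_graph(landscape)
    det <- tryCatch(
      shortest_detour(c(seg$x1[r], seg$y1[r]), c(seg$x2[r], seg$y2[r]),
                      landscape, graph = graph),
      error = function(e) NULL)
    if (is.null(det)) { n_unreplaceable <- n_unreplaceable + 1L; next }
    replaced[[length(replaced) + 1L]] <- data.frame(
      segment_id = seg$segment_id[r],
      crossing_km = seg$distance_m[r] / 1000,
      detour_km = det$length_m / 1000,
      ratio = det$length_m / seg$distance_m[r])
  }
  replaced <- if (length(replaced)) do.call(rbind, replaced) else
    data.frame(segment_id = character(), crossing_km = numeric(),
               detour_km = numeric(), ratio = numeric())
  projected_m <- observed_m +
    sum(replaced$detour_km - replaced$crossing_km) * 1000
  paired <- if (nrow(replaced) >= 2L) {
    ht <- stats::t.test(replaced$detour_km, replaced$crossing_km, paired = TRUE)
    list(t = unname(ht$statistic), df = unname(ht$parameter),
         p = unname(ht$p.value), mean_ratio = mean(replaced$ratio))
  } else {
    list(t = NA_real_, df = NA_real_, p = NA_real_,
         mean_ratio = if (nrow(replaced)) mean(replaced$ratio) else NA_real_)
  }
  structure(list(
    totals = list(observed_km = observed_m / 1000,
                  projected_km = projected_m / 1000,
                  percent_change = percent_change(observed_m, projected_m)),
    replaced = replaced, paired_t = paired,
    counts = list(n_window_segments = nrow(seg),
                  n_detours = sum(seg$class == "detour"),
                  n_ice_crossings = sum(ice),
                  n_water_crossings = sum(seg$class == "water_crossing"),
                  n_replaced = nrow(replaced),
                  n_unreplaceable = n_unreplaceable),
    window_segments = seg), class = "scenario_result")
}

#' Lost-crossing proportions under literature phenology projections
#'
#' Evaluates [impossible_crossings()] at each named projection's advance
#' (spring) and delay (fall) shifts and combines the two seasonal maxima
#' into an overall lost-crossing proportion.
#'
#' @inheritParams impossible_crossings
#' @param config A [scenario_config()] carrying the projections.
#' @return List with `per_season` (projection x season x shift results) and
#'   `overall` (per projection: combined `n_lost`, `n_total`, `pct_lost`).
#' @export
apply_projections <- function(crossings, phenology, config = scenario_config()) {
  per <- list(); overall <- list()
  for (nm in names(config$projections)) {
    pr <- config$projections[[nm]]
    res <- list()
    for (season in c("spring", "fall")) {
      shifts <- if (season == "spring") pr$advance else pr$delay
      if (is.null(shifts)) next
      kind <- if (season == "spring") "advance_breakup" else "delay_freeze"
      for (d in shifts) {
        r <- impossible_crossings(crossings, phenology, kind, d)
        res[[length(res) + 1L]] <- data.frame(
          projection = nm, season = season, shift_days = d,
          n = r$n, n_impossible = r$n_impossible,
          pct_impossible = r$pct_impossible)
      }
    }
    res <- do.call(rbind, res)
    per[[nm]] <- res
    mx <- stats::aggregate(cbind(n_impossible, n) ~ season, data = res,
                           FUN = max)
    overall[[nm]] <- data.frame(
      projection = nm,
      n_lost = sum(mx$n_impossible), n_total = sum(mx$n),
      pct_lost = proportion_pct(sum(mx$n_impossible), sum(mx$n)))
  }
  list(per_season = do.call(rbind, per),
       overall = do.call(rbind, overall))
}

#' Write the lost-crossing curve to CSV
#'
#' @param curve Data frame from [scenario_curve()].
#' @param path Output path.
#' @export
write_scenario_curve_csv <- function(curve, path) {
  utils::write.csv(curve, path, row.names = FALSE)
  invisible(path)
}
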