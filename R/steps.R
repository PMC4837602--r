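#' Build steps from GPS fixes
#'
#' A step is the straight line between two successive locations of one
#' individual: Euclidean length (m), duration (h), movement rate (m/h),
#' heading (deg), and from the second step on, the signed turning angle
#' relative to the previous step (deg in (-180, 180]) with its absolute
#' value.
#'
#' @param fixes Data frame with columns `id`, `timestamp` (POSIXct),
#'   `x`, `y`, and optionally `interval_h`; two or more fixes per individual,
#'   strictly increasing timestamps.
#' @return Data frame with one row per step: `id`, `step` (index within
#'   individual), `x1`, `y1`, `x2`, `y2`, `t1`, `t2`, `interval_h`,
#'   `length_m`, `duration_h`, `rate_mh`, `heading_deg`, `turn_deg`,
#'   `abs_turn_deg`.
#' @examples
#' f <- data.frame(id = "a",
#'                 timestamp = as.POSIXct("2011-01-01", tz = "UTC") + 3600 * (0:2),
#'                 x = c(0, 3000, 6000), y = c(0, 4000, 8000))
#' build_steps(f)
#' @export
build_steps <- function(fixes) {
  stopifnot(all(c("id", "timestamp", "x", "y") %in% names(fixes)))
  fixes <- fixes[order(fixes$id, fixes$timestamp), ]
  out <- lapply(split(fixes, fixes$id, drop = TRUE), function(f) {
    n <- nrow(f)
    if (n < 2L) return(NULL)
    dup <- duplicated(f$timestamp)
    if (any(dup)) {
      stop(sprintf("duplicate timestamp for individual '%s' at %s",
                   f$id[1], format(f$timestamp[which(dup)[1]], tz = "UTC")))
    }
    dx <- diff(f$x); dy <- diff(f$y)
    dur <- as.numeric(difftime(f$timestamp[-1], f$timestamp[-n], units = "hours"))
    if (any(dur <= 0)) stop("non-positive step duration for individual ", f$id[1])
    len <- sqrt(dx^2 + dy^2)
    heading <- atan2(dy, dx) * 180 / pi
    turn <- c(NA_real_, wrap_angle(diff(heading)))
    data.frame(id = f$id[-n], step = seq_len(n - 1L),
               x1 = f$x[-n], y1 = f$y[-n], x2 = f$x[-1], y2 = f$y[-1],
               t1 = f$timestamp[-n], t2 = f$timestamp[-1],
               interval_h = if ("interval_h" %in% names(f)) f$interval_h[-n] else dur,
               length_m = len, duration_h = dur, rate_mh = len / dur,
               heading_deg = heading, turn_deg = turn,
               abs_turn_deg = abs(turn))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Clip fixes to the vicinity of large water bodies
#'
#' Keeps maximal runs of consecutive fixes lying on a water-body surface or
#' within its buffer (closed boundary: a fix exactly at the buffer distance
#' is included). Each fix is assigned to its nearest body; a run touching two
#' bodies is split at the change of nearest-body assignment. Runs of fewer
#' than three locations are dropped (turning angles need three).
#'
#' @param fixes Telemetry data frame (`id`, `timestamp`, `x`, `y`, ...).
#' @param landscape A `landscape` (its `waterbodies` are used).
#' @param buffer_m Buffer distance in metres (default 5000).
#' @return The candidate-segment fixes: input rows plus `segment_id`,
#'   `waterbody_id`, `body_type`; zero rows when nothing is in the vicinity.
#' @export
clip_to_vicinity <- function(fixes, landscape, buffer_m = 5000) {
  fixes <- fixes[order(fixes$id, fixes$timestamp), ]
  bodies <- landscape$waterbodies
  D <- vapply(bodies, function(b) dist_to_polygon(fixes$x, fixes$y, b$poly),
              numeric(nrow(fixes)))
  D <- matrix(D, nrow = nrow(fixes))
  nearest <- max.col(-D, ties.method = "first")
  near <- D[cbind(seq_len(nrow(fixes)), nearest)] <= buffer_m
  key <- paste(fixes$id, ifelse(near, nearest, NA))
  newrun <- c(TRUE, key[-1] != key[-length(key)])
  run <- cumsum(newrun)
  keep <- near
  seg_rows <- split(which(keep), run[keep])
  seg_rows <- Filter(function(r) length(r) >= 3L, seg_rows)
  if (!length(seg_rows)) {
    out <- fixes[0, ]
    out$segment_id <- character(0); out$waterbody_id <- character(0)
    out$body_type <- character(0)
    return(out)
  }
  out <- do.call(rbind, lapply(seq_along(seg_rows), function(k) {
    r <- seg_rows[[k]]
    f <- fixes[r, ]
    b <- bodies[[nearest[r[1]]]]
    f$segment_id <- sprintf("S%03d", k)
    f$waterbody_id <- b$id
    f$body_type <- b$type
    f
  }))
  rownames(out) <- NULL
  out
}

#' Remove stopovers from segment fixes
#'
#' Collapses runs of at least `min_fixes` consecutive fixes on land (including
#' islands) whose pairwise maximum displacement does not exceed `radius_m` to
#' their final fix. Clumps on ice or open water are never removed. The
#' operation is applied until a fixed point is reached, so it is idempotent.
#'
#' @param segfixes Segment fixes (e.g. from [clip_to_vicinity()]), with a
#'   `segment_id` column; a plain fix table is treated as one segment.
#' @param landscape A `landscape` (land/water grid).
#' @param radius_m Clump radius in metres (default 1000).
#' @param min_fixes Minimum clump size (default 4).
#' @return The fixes with stopover rows removed.
#' @export
remove_stopovers <- function(segfixes, landscape, radius_m = 1000, min_fixes = 4) {
  if (!"segment_id" %in% names(segfixes)) segfixes$segment_id <- "S001"
  pieces <- lapply(split(segfixes, segfixes$segment_id, drop = TRUE), function(f) {
    repeat {
      n <- nrow(f)
      on_land <- class_at(landscape$grid, landscape, f$x, f$y) == CLASS_LAND
      drop <- logical(n)
      i <- 1L
      while (i <= n) {
        if (!on_land[i]) { i <- i + 1L; next }
        j <- i
        while (j < n && on_land[j + 1L] &&
               all(sqrt((f$x[i:j] - f$x[j + 1L])^2 +
                        (f$y[i:j] - f$y[j + 1L])^2) <= radius_m)) {
          j <- j + 1L
        }
        if (j - i + 1L >= min_fixes) drop[i:(j - 1L)] <- TRUE
        i <- j + 1L
      }
      if (!any(drop)) break
      f <- f[!drop, , drop = FALSE]
    }
    f
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

# sample points along a chord at half-cell spacing (endpoints included)
chord_points <- function(x1, y1, x2, y2, cellsize) {
  len <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  npt <- max(2L, as.integer(ceiling(len / (cellsize / 2))) + 1L)
  tt <- seq(0, 1, length.out = npt)
  list(x = x1 + tt * (x2 - x1), y = y1 + tt * (y2 - y1))
}

# TRUE for points on the body's surface (inside polygon, outside its islands)
on_surface <- function(x, y, waterbody, landscape) {
  inside <- point_in_polygon(x, y, waterbody$poly)
  for (isl in landscape$islands) {
    if (isl$waterbody_id == waterbody$id) {
      inside <- inside & !point_in_polygon(x, y, isl$poly)
    }
  }
  inside
}

#' Classify a movement segment as crossing, detour, or vicinity-only
#'
#' A segment is a crossing when any of its steps intersects the water-body
#' surface for at least `crossing_threshold` of the step length (sampled at
#' half-cell spacing); its substrate (ice vs water crossing) is the majority
#' class of the on-surface sample points on the date-matched 8-day raster
#' (a step uses the raster whose window contains the step's start time).
#' Otherwise the segment is a detour when its net displacement is at least
#' `detour_min_disp` (it passes the body rather than lingering); otherwise
#' it is vicinity-only.
#'
#' @param segfixes Fixes of one segment (with `waterbody_id`).
#' @param series An `ice_series` covering the segment's dates (an error lists
#'   any missing periods).
#' @param landscape A `landscape`.
#' @param crossing_threshold Minimum intersected fraction of a step length
#'   (default 0.1) for the step to count as on-surface.
#' @param detour_min_disp Net displacement (m) required to call a
#'   non-crossing segment a detour; default the smaller side of the body's
#'   bounding box.
#' @return List with `class` (one of `"ice_crossing"`, `"water_crossing"`,
#'   `"detour"`, `"vicinity_only"`), `max_surface_frac`, `n_ice`, `n_water`
#'   (sampled surface points), `net_displacement_m`, and `surface_time`
#'   (time of the first fix on the surface, NA if none).
#' @export
classify_segment <- function(segfixes, series, landscape,
                             crossing_threshold = 0.1, detour_min_disp = NULL) {
  wb <- Find(function(b) b$id == segfixes$waterbody_id[1], landscape$waterbodies)
  if (is.null(wb)) stop("segment has unknown waterbody_id")
  if (is.null(detour_min_disp)) {
    detour_min_disp <- min(diff(range(wb$poly$x)), diff(range(wb$poly$y)))
  }
  steps <- build_steps(segfixes)
  n_ice <- 0L; n_water <- 0L
  max_frac <- 0
  missing <- character(0)
  for (i in seq_len(nrow(steps))) {
    pts <- chord_points(steps$x1[i], steps$y1[i], steps$x2[i], steps$y2[i],
                        landscape$cellsize)
    surf <- on_surface(pts$x, pts$y, wb, landscape)
    frac <- mean(surf)
    max_frac <- max(max_frac, frac)
    if (frac >= crossing_threshold) {
      yr <- year_of(steps$t1[i]); dd <- doy_of(steps$t1[i])
      r <- raster_for_date(series, yr, dd)
      if (is.null(r)) {
        missing <- c(missing, sprintf("%d/doy %d", yr, dd))
        next
      }
      cls <- resolve_classes(series, landscape, yr, dd, pts$x[surf], pts$y[surf])
      n_ice <- n_ice + sum(cls == CLASS_ICE, na.rm = TRUE)
      n_water <- n_water + sum(cls == CLASS_WATER, na.rm = TRUE)
    }
  }
  if (length(missing)) {
    stop("no date-matched ice raster for period(s): ",
         paste(unique(missing), collapse = ", "))
  }
  surf_fix <- on_surface(segfixes$x, segfixes$y, wb, landscape)
  net <- sqrt((segfixes$x[nrow(segfixes)] - segfixes$x[1])^2 +
              (segfixes$y[nrow(segfixes)] - segfixes$y[1])^2)
  cls <- if (max_frac >= crossing_threshold) {
    if (n_water > n_ice) "water_crossing" else "ice_crossing"
  } else if (net >= detour_min_disp) "detour" else "vicinity_only"
  list(class = cls, max_surface_frac = max_frac, n_ice = n_ice,
       n_water = n_water, net_displacement_m = net,
       surface_time = if (any(surf_fix)) segfixes$timestamp[which(surf_fix)[1]]
                      else as.POSIXct(NA))
}

#' Classify all segments and tabulate them
#'
#' Runs [classify_segment()] and [segment_metrics()] over every segment and
#' returns the segment table used downstream (scenario analysis, exports).
#' The crossing date is the first fix on the water-body surface (first fix
#' for non-crossings); season is spring for dates up to day-of-year 183,
#' fall after.
#'
#' @param segfixes Segment fixes from [clip_to_vicinity()] (after
#'   [remove_stopovers()]).
#' @inheritParams classify_segment
#' @return Data frame with one row per segment: `segment_id`, `id`, `class`,
#'   `waterbody_id`, `body_type`, `n_fixes`, `mean_rate_mh`, `mean_turn_deg`,
#'   `start`, `end`, `distance_m`, `year`, `doy`, `season`, and endpoints
#'   `x1`, `y1`, `x2`, `y2`.
#' @export
classify_segments <- function(segfixes, series, landscape,
                              crossing_threshold = 0.1, detour_min_disp = NULL) {
  rows <- lapply(split(segfixes, segfixes$segment_id, drop = TRUE), function(f) {
    cl <- classify_segment(f, series, landscape, crossing_threshold, detour_min_disp)
    met <- segment_metrics(f)
    when <- if (!is.na(cl$surface_time)) cl$surface_time else f$timestamp[1]
    data.frame(segment_id = f$segment_id[1], id = f$id[1], class = cl$class,
               waterbody_id = f$waterbody_id[1], body_type = f$body_type[1],
               n_fixes = nrow(f), mean_rate_mh = met$mean_rate_mh,
               mean_turn_deg = met$mean_abs_turn_deg,
               start = f$timestamp[1], end = f$timestamp[nrow(f)],
               distance_m = met$total_length_m,
               year = year_of(when), doy = doy_of(when),
               season = if (doy_of(when) <= 183) "spring" else "fall",
               x1 = f$x[1], y1 = f$y[1],
               x2 = f$x[nrow(f)], y2 = f$y[nrow(f)])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Movement metrics of a segment
#'
#' Arithmetic means over the segment's steps: movement rate (each step
#' weighted equally) and absolute turning angle (defined from the second
#' step on).
#'
#' @param segfixes Fixes of one segment (>= 3 locations).
#' @return List with `mean_rate_mh`, `mean_abs_turn_deg`, `total_length_m`,
#'   `n_steps`.
#' @export
segment_metrics <- function(segfixes) {
  steps <- build_steps(segfixes)
  list(mean_rate_mh = mean(steps$rate_mh),
       mean_abs_turn_deg = mean(steps$abs_turn_deg, na.rm = TRUE),
       total_length_m = sum(steps$length_m),
       n_steps = nrow(steps))
}

#' Compare movement metrics across substrates with a group random intercept
#'
#' Method-of-moments analogue of a random-intercept comparison: within each
#' individual-by-fix-interval group that holds both a focal substrate and the
#' reference, the group-level mean difference is computed, and the substrate
#' contrast is the mean of those group differences with its between-group
#' standard error (t reference distribution on `groups - 1` df). With fewer
#' than two informative groups the function falls back to a pooled Welch
#' comparison, with a warning.
#'
#' @param values Numeric metric values (e.g. movement rates in m/h).
#' @param substrate Character vector of substrate labels per value.
#' @param group Group labels (individual x interval class) per value.
#' @param reference Reference substrate level (default `"control"`).
#' @return Data frame with one row per non-reference substrate: `substrate`,
#'   `adjusted_mean` (mean over groups of group means), `contrast`, `se`,
#'   `t`, `df`, `p`, `n_groups`, `method`.
#' @export
compare_metrics <- function(values, substrate, group, reference = "control") {
  stopifnot(length(values) == length(substrate), length(values) == length(group))
  d <- data.frame(v = values, s = substrate, g = group)
  levels_s <- setdiff(unique(d$s), reference)
  gm <- stats::aggregate(v ~ s + g, data = d, FUN = mean)
  adj <- stats::aggregate(v ~ s, data = gm, FUN = mean)
  out <- lapply(levels_s, function(s) {
    a <- gm[gm$s == s, c("g", "v")]
    b <- gm[gm$s == reference, c("g", "v")]
    m <- merge(a, b, by = "g", suffixes = c("_s", "_r"))
    if (nrow(m) >= 2L) {
      dg <- m$v_s - m$v_r
      est <- mean(dg)
      se <- stats::sd(dg) / sqrt(length(dg))
      tv <- if (se == 0) 0 else est / se
      df <- length(dg) - 1L
      p <- if (se == 0 && est == 0) 1 else 2 * stats::pt(-abs(tv), df)
      data.frame(substrate = s, adjusted_mean = adj$v[adj$s == s],
                 contrast = est, se = se, t = tv, df = df, p = p,
                 n_groups = length(dg), method = "group_differences")
    } else {
      warning("fewer than 2 groups with both '", s, "' and '", reference,
              "'; falling back to pooled Welch comparison")
      w <- welch_t(d$v[d$s == s], d$v[d$s == reference])
      data.frame(substrate = s, adjusted_mean = adj$v[adj$s == s],
                 contrast = mean(d$v[d$s == s]) - mean(d$v[d$s == reference]),
                 se = NA_real_, t = w$t, df = w$df, p = w$p,
                 n_groups = nrow(m), method = "welch_pooled")
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ice and water composition of a buffer around a location
#'
#' Proportions of ICE and WATER cells among all cells whose centres fall
#' within the disc of radius `radius_m` around the location. LAND and CLOUD
#' cells stay in the denominator, so the two proportions need not sum to one
#' (land-inclusive percentages).
#'
#' @param raster An `ice_raster` (or the landscape grid wrapped as one).
#' @param landscape The `landscape` providing the coordinate frame.
#' @param x,y Location (m).
#' @param radius_m Buffer radius in metres (1000 and 2500 are the
#'   conventional zones of influence).
#' @return List with `prop_ice`, `prop_water`, `n_cells`.
#' @export
buffer_composition <- function(raster, landscape, x, y, radius_m = 1000) {
  cs <- landscape$cellsize
  ny <- nrow(raster$grid); nx <- ncol(raster$grid)
  ix0 <- max(1L, floor((x - radius_m - landscape$origin[1]) / cs) + 1L)
  ix1 <- min(nx, floor((x + radius_m - landscape$origin[1]) / cs) + 1L)
  iy0 <- max(1L, floor((y - radius_m - landscape$origin[2]) / cs) + 1L)
  iy1 <- min(ny, floor((y + radius_m - landscape$origin[2]) / cs) + 1L)
  if (ix0 > ix1 || iy0 > iy1) return(list(prop_ice = NA_real_, prop_water = NA_real_, n_cells = 0L))
  ix <- ix0:ix1; iy <- iy0:iy1
  cx <- landscape$origin[1] + (ix - 0.5) * cs
  cy <- landscape$origin[2] + (iy - 0.5) * cs
  gx <- matrix(cx, nrow = length(iy), ncol = length(ix), byrow = TRUE)
  gy <- matrix(cy, nrow = length(iy), ncol = length(ix))
  inside <- (gx - x)^2 + (gy - y)^2 <= radius_m^2
  cls <- raster$grid[iy, ix, drop = FALSE][inside]
  n <- length(cls)
  if (n == 0L) return(list(prop_ice = NA_real_, prop_water = NA_real_, n_cells = 0L))
  list(prop_ice = sum(cls == CLASS_ICE) / n,
       prop_water = sum(cls == CLASS_WATER) / n,
       n_cells = n)
}

#' Welch two-sample t test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p value.
#'
#' @param a,b Numeric samples.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    eq <- mean(a) == mean(b)
    return(list(t = if (eq) 0 else Inf * sign(mean(a) - mean(b)),
                df = length(a) + length(b) - 2, p = if (eq) 1 else 0))
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}
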