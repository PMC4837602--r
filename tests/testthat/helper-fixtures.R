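# Shared fixtures and independent oracles, all built in code.

CL <- ice_classes()

# small landscape with one 20x10-cell lake, deterministically placed
tiny_landscape <- function(seed = 1, lake = c(20, 10), nx = 60, ny = 50,
                           type = "lake", island = NULL) {
  wb <- list(type = type, width = lake[1], height = lake[2])
  if (!is.null(island)) wb$island <- island
  generate_landscape(landscape_config(nx = nx, ny = ny, cellsize = 500,
                                      waterbodies = list(wb)), seed = seed)
}

# raster with every water cell of the landscape set to one class
uniform_raster <- function(landscape, class, year = 2011, doy = 33) {
  g <- landscape$grid
  g[g == CL["WATER"]] <- class
  structure(list(year = year, doy = doy, grid = g,
                 cellsize = landscape$cellsize),
            class = "ice_raster")
}

# short series of uniform rasters spanning several 8-day periods
uniform_series <- function(landscape, class, year = 2011, doys = c(33, 41, 49)) {
  structure(lapply(doys, function(d) uniform_raster(landscape, class, year, d)),
            class = "ice_series")
}

# a full-year ice series where each water cell has the given class schedule;
# frozen before breakup/after freeze, open between (hard transitions, no noise)
hard_series <- function(landscape, year = 2011, breakup = 148, freeze = 323) {
  structure(lapply(period_starts(), function(doy) {
    cls <- if (doy < breakup || doy >= freeze) CL["ICE"] else CL["WATER"]
    uniform_raster(landscape, cls, year = year, doy = doy)
  }), class = "ice_series")
}

lake_center <- function(landscape, i = 1) {
  p <- landscape$waterbodies[[i]]$poly
  c(mean(range(p$x)), mean(range(p$y)))
}

# fixes along a straight transect at constant speed
transect_fixes <- function(from, to, n, id = "a", interval_h = 2,
                           t0 = as.POSIXct("2011-02-10 00:00:00", tz = "UTC")) {
  tt <- seq(0, 1, length.out = n)
  data.frame(id = id,
             timestamp = t0 + 3600 * interval_h * (seq_len(n) - 1),
             x = from[1] + tt * (to[1] - from[1]),
             y = from[2] + tt * (to[2] - from[2]),
             interval_h = interval_h)
}

# Independent shortest-path oracle: Bellman relaxation (value iteration) on
# the 8-connected land grid, vectorized over the whole distance field. Same
# metric as the package's Dijkstra route but an entirely different algorithm.
oracle_grid_distance <- function(landscape, start, end,
                                 excluded = CL["WATER"]) {
  g <- landscape$grid
  land <- !(g %in% excluded)
  dim(land) <- dim(g)
  cs <- landscape$cellsize
  sc <- cell_of_pub(landscape, start[1], start[2])
  ec <- cell_of_pub(landscape, end[1], end[2])
  ny <- nrow(g); nx <- ncol(g)
  D <- matrix(Inf, ny, nx)
  D[sc$iy, sc$ix] <- 0
  D[!land] <- Inf
  shifts <- list(c(1, 0, cs), c(-1, 0, cs), c(0, 1, cs), c(0, -1, cs),
                 c(1, 1, cs * sqrt(2)), c(1, -1, cs * sqrt(2)),
                 c(-1, 1, cs * sqrt(2)), c(-1, -1, cs * sqrt(2)))
  repeat {
    Dold <- D
    for (s in shifts) {
      dy <- s[1]; dx <- s[2]; w <- s[3]
      src_y <- max(1, 1 - dy):min(ny, ny - dy)
      src_x <- max(1, 1 - dx):min(nx, nx - dx)
      cand <- D[src_y, src_x, drop = FALSE] + w
      tgt_y <- src_y + dy; tgt_x <- src_x + dx
      blk <- D[tgt_y, tgt_x, drop = FALSE]
      upd <- cand < blk
      blk[upd] <- cand[upd]
      blk[!land[tgt_y, tgt_x]] <- Inf
      D[tgt_y, tgt_x] <- blk
    }
    if (identical(D, Dold)) break
  }
  D[ec$iy, ec$ix]
}

# re-derive the containing cell the same way the package does (public info:
# origin + cellsize), kept separate from package internals
cell_of_pub <- function(landscape, x, y) {
  cs <- landscape$cellsize
  list(ix = floor((x - landscape$origin[1]) / cs) + 1L,
       iy = floor((y - landscape$origin[2]) / cs) + 1L)
}

# tie-corrected Spearman via explicit midranks (reference formula)
spearman_midrank <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
}
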