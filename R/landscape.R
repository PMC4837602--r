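#' Landscape configuration
#'
#' Describes the synthetic landscape to generate: grid dimensions, cell size,
#' origin, and the water bodies to place. Each water body is a rectangle
#' aligned to cell boundaries, so its surface cell count is exactly
#' `width_cells * height_cells`.
#'
#' @param nx,ny Grid dimensions in cells (x/east and y/north); both >= 50.
#' @param cellsize Cell edge length in metres (default 500, the resolution of
#'   8-day classified ice products).
#' @param origin Numeric length-2, projected coordinates (m) of the grid's
#'   lower-left corner.
#' @param waterbodies List of water-body requests, each a list with `type`
#'   (one of `"lake"`, `"river"`, `"reservoir"`), `width` and `height` in
#'   cells, and optionally `island = c(width, height)` in cells for a land
#'   island centred in the body.
#' @return A list of class `landscape_config`.
#' @export
landscape_config <- function(nx = 150, ny = 120, cellsize = 500,
                             origin = c(0, 0),
                             waterbodies = list(
                               list(type = "lake", width = 40, height = 20),
                               list(type = "river", width = 3, height = 60),
                               list(type = "reservoir", width = 20, height = 15)
                             )) {
  stopifnot(nx >= 50, ny >= 50, cellsize > 0, length(waterbodies) >= 1)
  types <- vapply(waterbodies, `[[`, "", "type")
  if (!all(types %in% c("lake", "river", "reservoir"))) {
    stop("water-body type must be one of 'lake', 'river', 'reservoir'")
  }
  structure(list(nx = nx, ny = ny, cellsize = cellsize, origin = origin,
                 waterbodies = waterbodies),
            class = "landscape_config")
}

#' Generate a synthetic landscape
#'
#' Places the requested rectangular water bodies at random, non-overlapping
#' positions on a LAND grid and records each body as a polygon with an `id`
#' and a `type` attribute. Islands are carved back to LAND inside their body.
#' Deterministic for a given seed.
#'
#' @param config A [landscape_config()].
#' @param seed Integer RNG seed.
#' @return An object of class `landscape`: a list with `grid` (integer matrix,
#'   `ny` rows x `nx` columns, row 1 = southernmost row; codes from
#'   [ice_classes()]), `cellsize`, `origin`, `waterbodies` (list of
#'   `list(id, type, poly, area_m2)`), and `islands` (list of
#'   `list(waterbody_id, poly)`).
#' @examples
#' ls <- generate_landscape(landscape_config(), seed = 1)
#' table(ls$grid)
#' @export
generate_landscape <- function(config = landscape_config(), seed = 1) {
  stopifnot(inherits(config, "landscape_config"))
  set.seed(seed)
  nx <- config$nx; ny <- config$ny; cs <- config$cellsize
  x0 <- config$origin[1]; y0 <- config$origin[2]
  grid <- matrix(CLASS_LAND, nrow = ny, ncol = nx)

  margin <- 2L
  placed <- list()   # occupied cell bounding boxes c(ix0, iy0, ix1, iy1)
  bodies <- list()
  islands <- list()
  for (b in seq_along(config$waterbodies)) {
    wb <- config$waterbodies[[b]]
    w <- as.integer(wb$width); h <- as.integer(wb$height)
    if (w < 1 || h < 1 || w > nx - 2 * margin || h > ny - 2 * margin) {
      stop(sprintf("water body %d (%dx%d cells) cannot fit in a %dx%d grid",
                   b, w, h, nx, ny))
    }
    ok <- FALSE
    for (try in 1:500) {
      ix0 <- sample.int(nx - w - 2 * margin + 1L, 1L) + margin - 1L
      iy0 <- sample.int(ny - h - 2 * margin + 1L, 1L) + margin - 1L
      box <- c(ix0, iy0, ix0 + w, iy0 + h)
      clash <- any(vapply(placed, function(p) {
        !(box[3] + 1L < p[1] || p[3] + 1L < box[1] ||
          box[4] + 1L < p[2] || p[4] + 1L < box[2])
      }, logical(1)))
      if (!clash) { ok <- TRUE; break }
    }
    if (!ok) stop(sprintf("could not place water body %d without overlap", b))
    placed[[length(placed) + 1L]] <- box
    grid[(iy0 + 1L):(iy0 + h), (ix0 + 1L):(ix0 + w)] <- CLASS_WATER

    poly <- data.frame(
      x = x0 + cs * c(ix0, ix0 + w, ix0 + w, ix0),
      y = y0 + cs * c(iy0, iy0, iy0 + h, iy0 + h)
    )
    id <- sprintf("wb%02d", b)
    bodies[[b]] <- list(id = id, type = wb$type, poly = poly,
                        area_m2 = w * h * cs^2)
    if (!is.null(wb$island)) {
      iw <- as.integer(wb$island[1]); ih <- as.integer(wb$island[2])
      if (iw >= w - 2 || ih >= h - 2) stop("island does not fit inside its water body")
      jx0 <- ix0 + (w - iw) %/% 2L; jy0 <- iy0 + (h - ih) %/% 2L
      grid[(jy0 + 1L):(jy0 + ih), (jx0 + 1L):(jx0 + iw)] <- CLASS_LAND
      islands[[length(islands) + 1L]] <- list(
        waterbody_id = id,
        poly = data.frame(x = x0 + cs * c(jx0, jx0 + iw, jx0 + iw, jx0),
                          y = y0 + cs * c(jy0, jy0, jy0 + ih, jy0 + ih)))
    }
  }
  structure(list(grid = grid, cellsize = cs, origin = c(x0, y0),
                 waterbodies = bodies, islands = islands),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("landscape: %d x %d cells @ %g m, %d water bodies (%s), %d islands\n",
              ncol(x$grid), nrow(x$grid), x$cellsize,
              length(x$waterbodies),
              paste(vapply(x$waterbodies, `[[`, "", "type"), collapse = ", "),
              length(x$islands)))
  invisible(x)
}

# Column/row indices of the cells containing points; NA outside the grid.
cell_of <- function(landscape, x, y) {
  cs <- landscape$cellsize
  ix <- floor((x - landscape$origin[1]) / cs) + 1L
  iy <- floor((y - landscape$origin[2]) / cs) + 1L
  bad <- ix < 1L | ix > ncol(landscape$grid) | iy < 1L | iy > nrow(landscape$grid)
  ix[bad] <- NA_integer_; iy[bad] <- NA_integer_
  list(ix = as.integer(ix), iy = as.integer(iy))
}

# Class codes of a grid (landscape grid or raster grid) at point coordinates;
# points outside the grid are returned as LAND.
class_at <- function(grid, landscape, x, y) {
  cells <- cell_of(landscape, x, y)
  cls <- rep(CLASS_LAND, length(x))
  ok <- !is.na(cells$ix)
  cls[ok] <- grid[cbind(cells$iy[ok], cells$ix[ok])]
  cls
}

#' Water mask of a landscape
#'
#' @param landscape A `landscape`.
#' @param waterbody_id Optional body id; if given, the mask is restricted to
#'   cells whose centres fall inside that body's polygon (excluding islands).
#' @return Logical matrix with the grid's dimensions.
#' @export
water_mask <- function(landscape, waterbody_id = NULL) {
  m <- landscape$grid == CLASS_WATER
  if (!is.null(waterbody_id)) {
    wb <- Find(function(b) b$id == waterbody_id, landscape$waterbodies)
    if (is.null(wb)) stop("unknown waterbody_id: ", waterbody_id)
    idx <- which(m, arr.ind = TRUE)
    cs <- landscape$cellsize
    cx <- landscape$origin[1] + (idx[, 2] - 0.5) * cs
    cy <- landscape$origin[2] + (idx[, 1] - 0.5) * cs
    keep <- point_in_polygon(cx, cy, wb$poly)
    m[,] <- FALSE
    m[idx[keep, , drop = FALSE]] <- TRUE
  }
  m
}

#' Write water bodies to GeoJSON
#'
#' Writes the landscape's water-body polygons as a GeoJSON FeatureCollection
#' with `id` and `type` properties (planar coordinates in metres).
#'
#' @param landscape A `landscape`.
#' @param path Output file path.
#' @export
write_waterbodies_geojson <- function(landscape, path) {
  features <- lapply(landscape$waterbodies, function(b) {
    ring <- rbind(as.matrix(b$poly), as.matrix(b$poly[1, , drop = FALSE]))
    list(type = "Feature",
         properties = list(id = b$id, type = b$type, area_m2 = b$area_m2),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(split(ring, row(ring)[, 1])))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read water bodies from GeoJSON
#'
#' @param path GeoJSON FeatureCollection file written by
#'   [write_waterbodies_geojson()] or equivalent: Polygon features with `id`
#'   and `type` properties.
#' @return List of `list(id, type, poly)` water bodies.
#' @export
read_waterbodies_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  lapply(fc$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]], function(p) {
      c(x = as.numeric(p[[1]]), y = as.numeric(p[[2]]))
    }))
    ring <- as.data.frame(ring)
    if (nrow(ring) > 1 &&
        isTRUE(all.equal(unlist(ring[1, ]), unlist(ring[nrow(ring), ])))) {
      ring <- ring[-nrow(ring), , drop = FALSE]
    }
    list(id = f$properties$id, type = f$properties$type, poly = ring,
         area_m2 = f$properties$area_m2)
  })
}
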