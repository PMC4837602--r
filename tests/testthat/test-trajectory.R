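utc <- function(s) as.POSIXct(s, tz = "UTC")

test_that("steps carry Euclidean length, rate, heading and turning angle", {
  f <- data.frame(id = "a", timestamp = utc("2011-01-01") + 3600 * 2 * (0:1),
                  x = c(0, 3000), y = c(0, 4000))
  s <- build_steps(f)
  expect_equal(s$length_m, 5000)      # 3-4-5 triangle
  expect_equal(s$rate_mh, 2500)
  expect_true(is.na(s$turn_deg))

  collinear <- data.frame(id = "a", timestamp = utc("2011-01-01") + 3600 * (0:2),
                          x = c(0, 1000, 2000), y = c(0, 500, 1000))
  expect_equal(build_steps(collinear)$turn_deg[2], 0)

  reversal <- data.frame(id = "a", timestamp = utc("2011-01-01") + 3600 * (0:2),
                         x = c(0, 1000, 0), y = 0)
  expect_equal(build_steps(reversal)$abs_turn_deg[2], 180)
})

test_that("duplicate timestamps are an error naming the individual", {
  f <- data.frame(id = "crb07", timestamp = utc("2011-01-01") + c(0, 0, 3600),
                  x = 1:3, y = 1:3)
  expect_error(build_steps(f), "crb07")
})

test_that("step lengths and turning angles are rigid-motion invariant", {
  set.seed(4)
  f <- data.frame(id = "a", timestamp = utc("2011-01-01") + 3600 * (0:19),
                  x = cumsum(rnorm(20, 0, 800)), y = cumsum(rnorm(20, 0, 800)))
  s0 <- build_steps(f)
  th <- 0.7
  g <- f
  g$x <- cos(th) * f$x - sin(th) * f$y + 1e5
  g$y <- sin(th) * f$x + cos(th) * f$y - 2e4
  s1 <- build_steps(g)
  expect_equal(s1$length_m, s0$length_m)
  expect_equal(s1$abs_turn_deg, s0$abs_turn_deg)
  expect_equal(nrow(s1), nrow(s0))
})

test_that("vicinity clipping keeps buffered runs with a closed 5-km boundary", {
  ls <- tiny_landscape()
  wb <- ls$waterbodies[[1]]
  rng <- apply(as.matrix(wb$poly), 2, range)
  cy <- mean(rng[, 2])

  far <- transect_fixes(c(rng[1, 1] - 8000, rng[2, 2] + 8000),
                        c(rng[1, 1] - 6500, rng[2, 2] + 6500), 5)
  expect_equal(nrow(clip_to_vicinity(far, ls)), 0)

  cross <- transect_fixes(c(rng[1, 1] - 9000, cy), c(rng[2, 1] + 9000, cy), 25)
  seg <- clip_to_vicinity(cross, ls)
  expect_equal(length(unique(seg$segment_id)), 1)
  # oracle: exactly the fixes within 5 km of the body
  d <- dist_to_polygon(cross$x, cross$y, wb$poly)
  expect_setequal(seg$timestamp, cross$timestamp[d <= 5000])
  expect_equal(unique(seg$waterbody_id), wb$id)

  at_edge <- transect_fixes(c(rng[1, 1] - 5000, cy), c(rng[1, 1] - 5000, cy + 400), 3)
  expect_equal(nrow(clip_to_vicinity(at_edge, ls)), 3)  # exactly 5 000 m: included
})

test_that("stopover clumps on land collapse to their final fix", {
  ls <- tiny_landscape()
  wb <- ls$waterbodies[[1]]
  rng <- apply(as.matrix(wb$poly), 2, range)
  cy <- mean(rng[, 2])
  x0 <- rng[1, 1] - 4000   # on land, inside the buffer, 4 km from shore
  base <- transect_fixes(c(x0 - 8000, cy), c(x0, cy), 5)
  clump <- data.frame(id = "a",
                      timestamp = max(base$timestamp) + 3600 * 2 * (1:6),
                      x = x0 + 1000 + c(0, 120, 60, 180, 90, 150),
                      y = cy + c(0, 80, 150, 40, 110, 20), interval_h = 2)
  tail <- data.frame(id = "a",
                     timestamp = max(clump$timestamp) + 3600 * 2 * (1:2),
                     x = x0 + c(3000, 3800), y = cy, interval_h = 2)
  f <- rbind(base, clump, tail)
  f$segment_id <- "S001"
  out <- remove_stopovers(f, ls, radius_m = 500, min_fixes = 4)
  expect_equal(nrow(out), nrow(base) + 1 + nrow(tail))
  expect_true(clump$timestamp[6] %in% out$timestamp)      # final clump fix kept
  expect_false(any(clump$timestamp[1:5] %in% out$timestamp))

  # a clump of 3 with min_fixes 4 is untouched
  out3 <- remove_stopovers(rbind(base, clump[1:3, ], tail), ls,
                           radius_m = 500, min_fixes = 4)
  expect_equal(nrow(out3), nrow(base) + 3 + nrow(tail))

  # clumps on the water-body surface are never removed
  ctr <- lake_center(ls)
  on_ice <- data.frame(id = "a", timestamp = utc("2011-02-01") + 3600 * (0:5),
                       x = ctr[1] + c(0, 50, 100, 20, 70, 40),
                       y = ctr[2] + c(0, 40, 90, 10, 60, 30), interval_h = 1)
  expect_equal(nrow(remove_stopovers(on_ice, ls, 500, 4)), 6)
})

test_that("stopover removal is idempotent", {
  ls <- tiny_landscape()
  set.seed(8)
  f <- data.frame(id = "a", timestamp = utc("2011-01-01") + 3600 * (0:59),
                  x = cumsum(rnorm(60, 200, 400)),
                  y = 2000 + cumsum(rnorm(60, 0, 300)), interval_h = 1)
  once <- remove_stopovers(f, ls, radius_m = 1000, min_fixes = 4)
  twice <- remove_stopovers(once, ls, radius_m = 1000, min_fixes = 4)
  expect_identical(once, twice)
})

test_that("segments are classified as ice crossing, water crossing or detour", {
  ls <- tiny_landscape()
  wb <- ls$waterbodies[[1]]
  rng <- apply(as.matrix(wb$poly), 2, range)
  cy <- mean(rng[, 2])
  frozen <- uniform_series(ls, CL["ICE"])
  open <- uniform_series(ls, CL["WATER"])
  cross <- transect_fixes(c(rng[1, 1] - 3000, cy), c(rng[2, 1] + 3000, cy), 15)
  cross$waterbody_id <- wb$id

  expect_equal(classify_segment(cross, frozen, ls)$class, "ice_crossing")
  expect_equal(classify_segment(cross, open, ls)$class, "water_crossing")

  # shoreline walker: around the south shore, cross-lake net displacement
  south <- rng[1, 2] - 1500
  around <- rbind(
    transect_fixes(c(rng[1, 1] - 2000, cy), c(rng[1, 1] - 1500, south), 4),
    transect_fixes(c(rng[1, 1] - 1000, south), c(rng[2, 1] + 1000, south), 10,
                   t0 = utc("2011-02-10 10:00:00")),
    transect_fixes(c(rng[2, 1] + 1500, south), c(rng[2, 1] + 2000, cy), 4,
                   t0 = utc("2011-02-11 00:00:00")))
  around$timestamp <- utc("2011-02-10") + 3600 * 2 * seq_len(nrow(around))
  around$waterbody_id <- wb$id
  det <- classify_segment(around, frozen, ls)
  expect_equal(det$class, "detour")
  expect_lt(det$max_surface_frac, 0.1)

  # lingering near the shore: vicinity-only
  linger <- transect_fixes(c(rng[1, 1] - 3000, cy), c(rng[1, 1] - 2500, cy + 300), 5)
  linger$waterbody_id <- wb$id
  expect_equal(classify_segment(linger, frozen, ls)$class, "vicinity_only")

  # a missing date-matched raster is an error naming the period
  late <- cross
  late$timestamp <- utc("2012-06-01") + 3600 * 2 * seq_len(nrow(late))
  expect_error(classify_segment(late, frozen, ls), "2012")
})

test_that("segment metrics are per-step arithmetic means", {
  f <- data.frame(id = "a", timestamp = utc("2011-01-01") + 3600 * (0:2),
                  x = c(0, 1000, 3000), y = 0)
  m <- segment_metrics(f)
  expect_equal(m$mean_rate_mh, 1500)   # 1000 and 2000 m/h
  expect_equal(m$mean_abs_turn_deg, 0)

  # constant 30-degree turns
  ang <- cumsum(c(0, rep(30, 4))) * pi / 180
  xy <- apply(cbind(cos(ang), sin(ang)) * 1000, 2, cumsum)
  f2 <- data.frame(id = "a", timestamp = utc("2011-01-01") + 3600 * (0:5),
                   x = c(0, xy[, 1]), y = c(0, xy[, 2]))
  expect_equal(segment_metrics(f2)$mean_abs_turn_deg, 30)
})

test_that("substrate contrasts are recovered through the group structure", {
  set.seed(21)
  groups <- sprintf("g%02d", 1:30)
  sim_one <- function(offset) {
    d <- do.call(rbind, lapply(groups, function(g) {
      mu <- rnorm(1, 500, 150)     # group random intercept
      data.frame(g = g,
                 v = c(mu + rnorm(8, 0, 100), mu + offset + rnorm(8, 0, 100)),
                 s = rep(c("control", "ice"), each = 8))
    }))
    compare_metrics(d$v, d$s, d$g)
  }
  r <- sim_one(1000)
  expect_lt(abs(r$contrast - 1000), 2 * r$se)
  expect_lt(r$p, 0.01)

  # identical per-group means give a zero contrast
  d0 <- data.frame(g = rep(groups[1:4], each = 4),
                   v = rep(c(1, 2, 3, 4), each = 4),
                   s = rep(c("control", "ice"), 8))
  r0 <- compare_metrics(d0$v, d0$s, d0$g)
  expect_equal(r0$contrast, 0)
  expect_equal(r0$p, 1)
})

test_that("the group comparison holds its nominal type-I error", {
  set.seed(31)
  groups <- sprintf("g%02d", 1:30)
  pvals <- replicate(1000, {
    d <- do.call(rbind, lapply(groups, function(g) {
      mu <- rnorm(1, 0, 1)
      data.frame(g = g, v = mu + rnorm(8), s = rep(c("control", "ice"), 4))
    }))
    compare_metrics(d$v, d$s, d$g)$p
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.03)
  expect_lt(rate, 0.07)
})

test_that("pooled Welch fallback engages below two informative groups", {
  d <- data.frame(g = "g01", v = c(rnorm(10), rnorm(10, 2)),
                  s = rep(c("control", "ice"), each = 10))
  expect_warning(r <- compare_metrics(d$v, d$s, d$g), "Welch")
  expect_equal(r$method, "welch_pooled")
})

test_that("buffer composition counts land in the denominator", {
  ls <- tiny_landscape()
  wb <- ls$waterbodies[[1]]
  rng <- apply(as.matrix(wb$poly), 2, range)
  frozen <- uniform_raster(ls, CL["ICE"])

  ctr <- lake_center(ls)
  mid <- buffer_composition(frozen, ls, ctr[1], ctr[2], radius_m = 1000)
  expect_equal(mid$prop_ice, 1)
  expect_equal(mid$prop_water, 0)

  # land cell farthest from the lake, guaranteed inside the grid
  idx <- which(ls$grid == CL["LAND"], arr.ind = TRUE)
  lx <- (idx[, 2] - 0.5) * 500; ly <- (idx[, 1] - 0.5) * 500
  far <- which.max(dist_to_polygon(lx, ly, wb$poly))
  onland <- buffer_composition(frozen, ls, lx[far], ly[far], 1000)
  expect_equal(onland$prop_ice, 0)
  expect_equal(onland$prop_water, 0)

  # disc centred on the shoreline: half ice within cell quantization
  edge <- buffer_composition(frozen, ls, rng[1, 1], mean(rng[, 2]), 2500)
  expect_lt(abs(edge$prop_ice - 0.5), 0.05)

  melt <- uniform_raster(ls, CL["WATER"])
  edge_w <- buffer_composition(melt, ls, rng[1, 1], mean(rng[, 2]), 2500)
  expect_lt(abs(edge_w$prop_water - 0.5), 0.05)
  expect_equal(edge_w$prop_ice, 0)
})

test_that("Welch statistic has its closed-form df and nominal size", {
  x <- rnorm(15)
  expect_equal(welch_t(x, x)$t, 0)
  expect_equal(welch_t(x, x)$p, 1)
  # equal n and equal sample variance: df = 2n - 2 exactly
  y <- x + 3
  w <- welch_t(x, y)
  expect_equal(w$df, 28)

  set.seed(13)
  rej <- replicate(2000, welch_t(rnorm(20), rnorm(20, 0, 3))$p < 0.05)
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})
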