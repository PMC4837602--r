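utc <- function(s) as.POSIXct(s, tz = "UTC")
suppressPackageStartupMessages(library(survival))  # independent cross-check

fake_steps <- function(lengths, id = "a", interval_h = 2) {
  n <- length(lengths)
  data.frame(id = id, interval_h = interval_h, length_m = lengths,
             turn_deg = c(NA, runif(n - 1, -180, 180)))
}

test_that("availability distributions trim the longest step lengths", {
  set.seed(1)
  d <- build_distributions(fake_steps(1:100), trim = 0.05)
  entry <- d[["a|2"]]
  expect_equal(max(entry$lengths), 95)
  expect_length(entry$lengths, 95)

  d0 <- build_distributions(fake_steps(1:100), trim = 0)
  expect_length(d0[["a|2"]]$lengths, 100)
  expect_equal(max(d0[["a|2"]]$lengths), 100)

  # keyed by individual x interval class
  two <- rbind(fake_steps(1:50, "a", 2), fake_steps(1:50, "b", 7))
  d2 <- build_distributions(two)
  expect_setequal(names(d2), c("a|2", "b|7"))
})

test_that("resampling reproduces the stored empirical distribution", {
  set.seed(2)
  d <- build_distributions(fake_steps(rgamma(400, 2, scale = 300)), trim = 0.05)
  stored <- d[["a|2"]]$lengths
  draws <- sample(stored, 10000, replace = TRUE)
  ks <- max(abs(ecdf(draws)(stored) - ecdf(stored)(stored)))
  expect_lt(ks, 0.02)
})

test_that("control steps follow the matched-availability construction", {
  dg <- list(lengths = 750, angles = 0)
  set.seed(3)
  ctl <- generate_controls(100, 200, prev_heading = 90, dist = dg, n = 10)
  expect_equal(nrow(ctl), 10)
  expect_equal(unique(ctl$length_m), 750)
  expect_equal(unique(round(ctl$x2 - 100, 9)), 0)   # straight ahead: due north
  expect_equal(unique(ctl$y2), 950)

  d2 <- list(lengths = c(400, 800), angles = c(-90, 0, 90))
  set.seed(7); a <- generate_controls(0, 0, 45, d2, 10)
  set.seed(7); b <- generate_controls(0, 0, 45, d2, 10)
  expect_identical(a, b)
  expect_error(generate_controls(0, 0, NA, d2, 10), "heading")
})

test_that("control headings inherit the sampled angle distribution", {
  set.seed(4)
  d <- list(lengths = 500, angles = runif(5000, -180, 180))
  ctl <- generate_controls(0, 0, prev_heading = 30, dist = d, n = 10000)
  counts <- table(cut(ctl$heading_deg, breaks = seq(-180, 180, by = 30)))
  expect_gt(chisq.test(counts)$p.value, 0.01)
})

test_that("step composition is sampled at half-cell spacing with cloud fallback", {
  ls <- tiny_landscape()
  wb <- ls$waterbodies[[1]]
  rng <- apply(as.matrix(wb$poly), 2, range)
  cy <- mean(rng[, 2])
  frozen <- structure(list(uniform_raster(ls, CL["ICE"], doy = 41)),
                      class = "ice_series")
  t0 <- utc("2011-02-12")

  land <- step_covariates(rng[1, 1] - 5000, cy, rng[1, 1] - 1000, cy, t0, frozen, ls)
  expect_equal(land$prop_water, 0); expect_equal(land$prop_ice, 0)

  onlake <- step_covariates(rng[1, 1] + 500, cy, rng[1, 1] + 4500, cy, t0, frozen, ls)
  expect_equal(onlake$prop_water, 0); expect_equal(onlake$prop_ice, 1)

  # chord half on land, half on open lake
  open <- structure(list(uniform_raster(ls, CL["WATER"], doy = 41)),
                    class = "ice_series")
  half <- step_covariates(rng[1, 1] - 4000, cy, rng[1, 1] + 4000, cy, t0, open, ls)
  expect_lt(abs(half$prop_water - 0.5), 250 / 8000 + 1e-9)
  expect_equal(half$prop_ice, 0)

  # fully clouded period falls back to the nearest-in-time clear raster
  cloudy <- uniform_raster(ls, CL["CLOUD"], doy = 41)
  ser <- structure(list(cloudy, uniform_raster(ls, CL["ICE"], doy = 49)),
                   class = "ice_series")
  cc <- step_covariates(rng[1, 1] + 500, cy, rng[1, 1] + 4500, cy, t0, ser, ls)
  expect_equal(cc$prop_ice, 1)
})

test_that("the conditional likelihood is maximized and matches survival::clogit", {
  st <- simulate_ssf_strata(400, seed = 10)
  fit <- fit_clogit(st)
  expect_true(fit$converged)
  expect_gte(fit$loglik, fit$loglik_null)

  sv <- survival::clogit(observed ~ prop_water + prop_ice +
                           survival::strata(stratum), data = st)
  expect_equal(unname(coef(fit)), unname(coef(sv)), tolerance = 1e-6)
  expect_equal(unname(fit$se), unname(sqrt(diag(vcov(sv)))), tolerance = 1e-5)
  expect_equal(fit$loglik, unname(sv$loglik[2]), tolerance = 1e-8)
})

test_that("the likelihood is invariant to stratum-constant covariate shifts", {
  st <- simulate_ssf_strata(200, seed = 11)
  fit <- fit_clogit(st)
  shifted <- st
  shifted$prop_water <- st$prop_water + st$stratum * 0.37  # constant per stratum
  fit2 <- fit_clogit(shifted)
  expect_equal(coef(fit2), coef(fit), tolerance = 1e-6)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-8)
})

test_that("degenerate designs are refused or flagged", {
  st <- simulate_ssf_strata(50, seed = 12)
  flat <- st
  flat$prop_water <- ave(flat$prop_water, flat$stratum)  # stratum-constant
  expect_error(fit_clogit(flat, covars = "prop_water"), "prop_water")

  # complete separation: observed step maximal in every stratum
  sep <- st
  sep$sepcov <- ifelse(sep$observed, 1, 0)
  fsep <- fit_clogit(sep, covars = "sepcov")
  expect_false(fsep$converged)
})

test_that("interaction models nest the base model and AICc penalizes them", {
  st <- simulate_ssf_strata(300, seed = 13)
  base <- fit_clogit(st)
  inter <- fit_clogit(st, interactions = TRUE)
  expect_equal(inter$k, 6)
  expect_gte(inter$loglik, base$loglik - 1e-8)
  # no true interaction: the simpler model usually wins on AICc
  set.seed(14)
  wins <- replicate(20, {
    s <- simulate_ssf_strata(300, seed = sample.int(1e6, 1))
    fit_clogit(s)$aicc < fit_clogit(s, interactions = TRUE)$aicc
  })
  expect_gte(mean(wins), 0.8)
})

test_that("AICc applies the small-sample correction on strata", {
  expect_equal(aicc(list(loglik = -3809.01, k = 2, n_strata = 1203)), 7622.03,
               tolerance = 1e-5)
  expect_equal(aicc(list(loglik = 0, k = 1, n_strata = 100)), 2 + 4 / 98)
  big <- aicc(list(loglik = -500, k = 3, n_strata = 1e9))
  expect_equal(big, 2 * 500 + 6, tolerance = 1e-6)
})

test_that("rank counts feed a tie-corrected Spearman correlation", {
  counts <- c(rep(0, 10), 40)       # observed step always in the top rank
  expect_equal(spearman_counts(counts), spearman_midrank(counts, 1:11))
  expect_equal(spearman_counts(counts), 0.5)
  expect_equal(spearman_counts(rep(3, 11)), 0)
  expect_equal(spearman_counts(1:11), 1)
})

test_that("k-fold validation separates strong selection from the null", {
  strong <- simulate_ssf_strata(500, beta = c(prop_water = -2, prop_ice = 2),
                                seed = 15)
  vs <- kfold_validate(strong, seed = 1)
  expect_gte(vs$mean_rs, 0.5)
  expect_equal(nrow(vs$per_draw), 10)
  expect_true(all(rowSums(vs$counts) == length(unique(strong$stratum)) -
                    floor(0.8 * length(unique(strong$stratum)))))

  null <- simulate_ssf_strata(800, beta = c(prop_water = 0, prop_ice = 0),
                              seed = 16)
  vn <- kfold_validate(null, seed = 1)
  expect_lt(abs(vn$mean_rs), 0.2)
})

test_that("grouped fits recover group-specific coefficients and flag small groups", {
  a <- simulate_ssf_strata(400, beta = c(prop_water = -1.5, prop_ice = 0.2),
                           seed = 17)
  b <- simulate_ssf_strata(400, beta = c(prop_water = 0.2, prop_ice = 1.5),
                           seed = 18)
  b$stratum <- b$stratum + 400
  st <- rbind(a, b)
  grp <- rep(c("short_ice", "long_ice"), each = nrow(a))
  gf <- grouped_fits(st, grp)
  expect_setequal(names(gf$fits), c("short_ice", "long_ice"))
  fa <- gf$fits[["short_ice"]]; fb <- gf$fits[["long_ice"]]
  expect_lt(abs(coef(fa)[["prop_water"]] + 1.5), 3 * fa$se[["prop_water"]])
  expect_lt(abs(coef(fb)[["prop_ice"]] - 1.5), 3 * fb$se[["prop_ice"]])

  # single group: identical to the global fit; tiny group: flagged not fitted
  g1 <- grouped_fits(a, rep("all", nrow(a)))
  expect_equal(coef(g1$fits[["all"]]), coef(fit_clogit(a)))
  tiny <- grouped_fits(a, ifelse(a$stratum <= 5, "tiny", "rest"))
  expect_named(tiny$skipped, "tiny")
  expect_false("tiny" %in% names(tiny$fits))
})

test_that("strata assembled from telemetry carry composition covariates", {
  ls <- tiny_landscape()
  wb <- ls$waterbodies[[1]]
  rng <- apply(as.matrix(wb$poly), 2, range)
  cy <- mean(rng[, 2])
  frozen <- structure(list(uniform_raster(ls, CL["ICE"], doy = 41)),
                      class = "ice_series")
  set.seed(19)
  fixes <- transect_fixes(c(rng[1, 1] - 6000, cy), c(rng[2, 1] + 6000, cy), 30)
  fixes$x <- fixes$x + rnorm(30, 0, 300)
  fixes$y <- fixes$y + rnorm(30, 0, 300)
  steps <- build_steps(fixes)
  steps$body_type <- "lake"
  dists <- build_distributions(steps, trim = 0.05)
  st <- build_ssf_strata(steps, dists, frozen, ls, n_controls = 10, seed = 1)
  expect_true(all(table(st$stratum) == 11))
  expect_true(all(tapply(st$observed, st$stratum, sum) == 1))
  expect_true(all(st$prop_ice >= 0 & st$prop_ice <= 1))
  expect_gt(max(st$prop_ice), 0)   # the transect crosses the frozen lake
  # deterministic under the seed
  st2 <- build_ssf_strata(steps, dists, frozen, ls, n_controls = 10, seed = 1)
  expect_identical(st, st2)
})
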