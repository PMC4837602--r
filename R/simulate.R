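#' Behaviour parameters for the trajectory simulator
#'
#' The biased correlated random walk used to emulate migratory movement around
#' large water bodies. Candidate headings are weighted by the substrate ahead
#' through `exp(beta_ice * ice + beta_water * water)` plus a directional bias
#' toward the current seasonal goal; realized speed on ice is multiplied by
#' `speed_mult`.
#'
#' Defaults for the selection coefficients are the log relative selection
#' strengths the step-selection analysis is expected to recover
#' (water -0.733, ice 0.475), and the on-ice speed multiplier of 3 matches
#' the roughly threefold movement-rate contrast between ice and ordinary
#' terrain seen in migrating caribou.
#'
#' @param beta_ice,beta_water Log relative selection weight of ice / open
#'   water in the heading choice.
#' @param speed_mult Multiplier (> 0) applied to step length when the chosen
#'   heading's substrate is ice.
#' @param step_shape,step_scale Gamma shape and scale of the hourly base step
#'   length (m/h); the mean hourly displacement is `step_shape * step_scale`.
#' @param kappa_goal Strength of the directional bias toward the current goal.
#' @param n_headings Number of equally spaced candidate headings (default 24).
#' @param stopover_rate Per-step probability of starting a stopover bout when
#'   on land.
#' @param stopover_mean_h Mean stopover bout duration in hours (> 0).
#' @param stopover_sd_m Positional jitter (m) of fixes within a stopover.
#' @param goal_radius Distance (m) at which a goal counts as reached.
#' @return A list of class `behaviour_params`.
#' @export
behaviour_params <- function(beta_ice = 0.475, beta_water = -0.733,
                             speed_mult = 3, step_shape = 2, step_scale = 270,
                             kappa_goal = 1.5, n_headings = 24,
                             stopover_rate = 0.02, stopover_mean_h = 24,
                             stopover_sd_m = 150, goal_radius = 2000) {
  stopifnot(speed_mult > 0, stopover_mean_h > 0, step_shape > 0,
            step_scale > 0, n_headings >= 4)
  structure(as.list(environment()), class = "behaviour_params")
}

# Effective substrate grid for a raster: CLOUD cells replaced by the raster's
# majority non-cloud water-cell class (ICE on ties / all-cloud).
effective_grid <- function(raster, landscape) {
  g <- raster$grid
  cl <- g == CLASS_CLOUD
  if (any(cl)) {
    known <- g[landscape$grid == CLASS_WATER]
    known <- known[known != CLASS_CLOUD]
    fill <- if (length(known) && sum(known == CLASS_WATER) > sum(known == CLASS_ICE))
      CLASS_WATER else CLASS_ICE
    g[cl] <- fill
  }
  g
}

landscape_extent <- function(landscape) {
  c(xmin = landscape$origin[1], ymin = landscape$origin[2],
    xmax = landscape$origin[1] + ncol(landscape$grid) * landscape$cellsize,
    ymax = landscape$origin[2] + nrow(landscape$grid) * landscape$cellsize)
}

random_land_point <- function(landscape) {
  idx <- which(landscape$grid == CLASS_LAND, arr.ind = TRUE)
  i <- idx[sample.int(nrow(idx), 1L), ]
  cs <- landscape$cellsize
  c(landscape$origin[1] + (i[2] - 0.5) * cs,
    landscape$origin[2] + (i[1] - 0.5) * cs)
}

#' Simulate multi-individual GPS trajectories
#'
#' Each individual follows a biased correlated random walk toward its goal
#' points: at every step a base length is drawn from a gamma distribution
#' scaled by the fix interval, candidate headings probe the substrate at the
#' prospective step's midpoint and endpoint on the date-matched ice raster
#' (open water at either probe marks the candidate as water), and one heading
#' is sampled with weight `exp(beta_ice*ice + beta_water*water +
#' kappa*cos(heading - goal bearing))`. Steps whose chosen substrate is ice
#' are stretched by the speed multiplier. Stopover bouts (clustered jittered
#' fixes) are inserted at the stopover rate while on land.
#'
#' @param landscape A `landscape`.
#' @param ice_series An `ice_series` covering the simulated dates.
#' @param params A [behaviour_params()].
#' @param n_individuals Number of individuals.
#' @param fix_schedule Integer vector of nominal fix intervals (h) to sample
#'   from, one per individual; default the mixed 1, 2, 7, 11, 13 h schedule.
#' @param schedule_weights Sampling weights for `fix_schedule`.
#' @param n_steps Travel steps per individual.
#' @param start Optional list of `c(x, y)` start points (recycled); default
#'   random land cells.
#' @param goals Optional list of goal sequences, each a list of `c(x, y)`
#'   points visited in order (recycled across individuals); default one
#'   random land goal per individual. Goals outside the landscape are an
#'   error.
#' @param start_time POSIXct (UTC) of the first fix.
#' @param seed Integer RNG seed; identical seeds reproduce identical tables.
#' @return A data frame with columns `id`, `timestamp` (POSIXct UTC), `x`,
#'   `y`, `interval_h`, and `state` (`"travel"` or `"stopover"`; ground truth
#'   for stopover-removal checks, dropped by [write_telemetry_csv()]).
#' @export
simulate_trajectories <- function(landscape, ice_series, params = behaviour_params(),
                                  n_individuals = 5,
                                  fix_schedule = c(1, 2, 7, 11, 13),
                                  schedule_weights = c(0.3, 0.3, 0.15, 0.15, 0.1),
                                  n_steps = 200, start = NULL, goals = NULL,
                                  start_time = as.POSIXct("2011-10-01 00:00:00", tz = "UTC"),
                                  seed = 1) {
  stopifnot(inherits(landscape, "landscape"), inherits(params, "behaviour_params"))
  ext <- landscape_extent(landscape)
  if (!is.null(goals)) {
    for (gs in goals) for (g in gs) {
      if (g[1] < ext["xmin"] || g[1] > ext["xmax"] ||
          g[2] < ext["ymin"] || g[2] > ext["ymax"]) {
        stop("goal point lies outside the landscape")
      }
    }
  }
  set.seed(seed)
  cs <- landscape$cellsize
  headings <- seq(0, 360, length.out = params$n_headings + 1)[-(params$n_headings + 1)]
  hr <- headings * pi / 180
  eff_cache <- new.env(parent = emptyenv())
  eff_for <- function(year, doy) {
    r <- raster_for_date(ice_series, year, doy)
    if (is.null(r)) {
      # outside series coverage: nearest raster in time
      key <- vapply(ice_series, function(s) abs((s$year - year) * 365 + s$doy - doy),
                    numeric(1))
      r <- ice_series[[which.min(key)]]
    }
    k <- sprintf("%d_%d", r$year, r$doy)
    if (is.null(eff_cache[[k]])) eff_cache[[k]] <- effective_grid(r, landscape)
    eff_cache[[k]]
  }

  rows <- vector("list", n_individuals)
  for (ind in seq_len(n_individuals)) {
    interval <- fix_schedule[sample.int(length(fix_schedule), 1L,
                                        prob = schedule_weights)]
    pos <- if (is.null(start)) random_land_point(landscape) else
      as.numeric(start[[(ind - 1L) %% length(start) + 1L]])
    goal_seq <- if (is.null(goals)) list(random_land_point(landscape)) else
      goals[[(ind - 1L) %% length(goals) + 1L]]
    gi <- 1L
    t <- start_time + 3600 * stats::runif(1, 0, 24)  # stagger deployments
    xs <- numeric(0); ys <- numeric(0); ts <- numeric(0); st <- character(0)
    push <- function(x, y, tt, state) {
      xs[length(xs) + 1L] <<- x; ys[length(ys) + 1L] <<- y
      ts[length(ts) + 1L] <<- as.numeric(tt); st[length(st) + 1L] <<- state
    }
    push(pos[1], pos[2], t, "travel")
    step <- 0L
    while (step < n_steps) {
      here_land <- class_at(landscape$grid, landscape, pos[1], pos[2]) == CLASS_LAND
      if (here_land && stats::runif(1) < params$stopover_rate) {
        nb <- max(1L, round(stats::rgamma(1, 2, scale = params$stopover_mean_h / 2) / interval))
        nb <- min(nb, 12L)
        for (k in seq_len(nb)) {
          t <- t + 3600 * interval
          push(pos[1] + stats::rnorm(1, 0, params$stopover_sd_m),
               pos[2] + stats::rnorm(1, 0, params$stopover_sd_m), t, "stopover")
        }
        step <- step + nb
        next
      }
      L <- stats::rgamma(1, params$step_shape, scale = params$step_scale) * interval
      eg <- eff_for(year_of(t), doy_of(t))
      # probe the candidate step at its midpoint and endpoint: a candidate is
      # "water" if either probe hits open water (so strong avoidance keeps the
      # whole step dry), "ice" if it touches ice without water, else land
      sub_mid <- class_at(eg, landscape, pos[1] + (L / 2) * cos(hr),
                          pos[2] + (L / 2) * sin(hr))
      sub_end <- class_at(eg, landscape, pos[1] + L * cos(hr),
                          pos[2] + L * sin(hr))
      is_water <- sub_mid == CLASS_WATER | sub_end == CLASS_WATER
      is_ice <- !is_water & (sub_mid == CLASS_ICE | sub_end == CLASS_ICE)
      sub <- ifelse(is_water, CLASS_WATER, ifelse(is_ice, CLASS_ICE, CLASS_LAND))
      goal <- goal_seq[[gi]]
      bearing <- atan2(goal[2] - pos[2], goal[1] - pos[1])
      w <- exp(params$beta_ice * (sub == CLASS_ICE) +
               params$beta_water * (sub == CLASS_WATER) +
               params$kappa_goal * cos(hr - bearing))
      h <- sample.int(length(hr), 1L, prob = w)
      Lr <- L * if (sub[h] == CLASS_ICE) params$speed_mult else 1
      pos <- c(pos[1] + Lr * cos(hr[h]), pos[2] + Lr * sin(hr[h]))
      pos[1] <- min(max(pos[1], ext["xmin"] + cs / 2), ext["xmax"] - cs / 2)
      pos[2] <- min(max(pos[2], ext["ymin"] + cs / 2), ext["ymax"] - cs / 2)
      t <- t + 3600 * interval
      push(pos[1], pos[2], t, "travel")
      if (gi < length(goal_seq) &&
          sqrt(sum((pos - goal_seq[[gi]])^2)) < params$goal_radius) gi <- gi + 1L
      step <- step + 1L
    }
    rows[[ind]] <- data.frame(
      id = sprintf("ind%02d", ind),
      timestamp = as.POSIXct(ts, origin = "1970-01-01", tz = "UTC"),
      x = xs, y = ys, interval_h = interval, state = st)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate ground-truth step-selection strata
#'
#' Draws matched used-available strata exactly from the conditional-logit
#' data-generating process: each stratum holds `n_controls + 1` candidate
#' steps with water/ice step-composition covariates drawn from an
#' availability mixture (a land-only mass plus beta-distributed water-surface
#' fractions split between ice and open water), and the observed step is
#' chosen with probability proportional to `exp(x' beta)`. Used for
#' estimator-recovery checks with known truth.
#'
#' @param n_strata Number of strata.
#' @param beta Named numeric: true coefficients for `prop_water` and
#'   `prop_ice` (defaults -0.733 and 0.475, the generating truth the global
#'   step-selection model is expected to recover).
#' @param n_controls Control steps per stratum (default 10).
#' @param p_land Probability that a candidate step is entirely on land.
#' @param seed Integer RNG seed.
#' @return Data frame with columns `stratum`, `observed`, `prop_water`,
#'   `prop_ice`, `body_type` (stratum-level, `lake`/`river`/`reservoir`).
#' @export
simulate_ssf_strata <- function(n_strata, beta = c(prop_water = -0.733, prop_ice = 0.475),
                                n_controls = 10, p_land = 0.4, seed = 1) {
  set.seed(seed)
  m <- n_controls + 1L
  n <- n_strata * m
  land <- stats::runif(n) < p_land
  f <- stats::rbeta(n, 1.2, 1.2)      # water-surface fraction of the step
  z <- rep(stats::rbeta(n_strata, 2, 2), each = m)  # frozen fraction, stratum-level season
  prop_ice <- ifelse(land, 0, f * z)
  prop_water <- ifelse(land, 0, f * (1 - z))
  eta <- beta[["prop_water"]] * prop_water + beta[["prop_ice"]] * prop_ice
  stratum <- rep(seq_len(n_strata), each = m)
  observed <- logical(n)
  for (s in seq_len(n_strata)) {
    i <- (s - 1L) * m
    w <- exp(eta[(i + 1L):(i + m)])
    observed[i + sample.int(m, 1L, prob = w)] <- TRUE
  }
  data.frame(stratum = stratum, observed = observed,
             prop_water = prop_water, prop_ice = prop_ice,
             body_type = rep(sample(c("lake", "river", "reservoir"), n_strata,
                                    replace = TRUE, prob = c(0.6, 0.2, 0.2)),
                             each = m))
}
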