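#' Empirical availability distributions of step lengths and turning angles
#'
#' Builds per individual-by-fix-interval empirical samples of step lengths
#' and signed turning angles, from which control steps are drawn. The top
#' `trim` fraction of step lengths is removed (`floor(n * trim)` largest
#' values) to prevent overly long random steps.
#'
#' @param steps Step table from [build_steps()].
#' @param trim Fraction of the longest step lengths to discard (default 0.05).
#' @return Object of class `ssf_dists`: a named list keyed
#'   `"<id>|<interval_h>"`, each entry holding `lengths` (trimmed) and
#'   `angles` (signed turning angles, NAs dropped).
#' @export
build_distributions <- function(steps, trim = 0.05) {
  stopifnot(trim >= 0, trim < 1)
  keys <- paste(steps$id, steps$interval_h, sep = "|")
  out <- lapply(split(steps, keys), function(s) {
    len <- sort(s$length_m)
    k <- floor(length(len) * trim)
    if (k > 0) len <- len[seq_len(length(len) - k)]
    ang <- s$turn_deg[!is.na(s$turn_deg)]
    if (!length(len) || !length(ang)) return(NULL)
    list(lengths = len, angles = ang)
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) stop("no usable steps to build availability distributions")
  structure(out, class = "ssf_dists")
}

#' Generate matched control steps for one observed step
#'
#' Each control starts at the observed step's origin; its heading is the
#' previous observed heading plus a signed turning angle sampled from the
#' availability distribution, and its length is sampled independently from
#' the trimmed step-length distribution. Controls may land on any substrate,
#' including outside any buffer.
#'
#' @param x,y Origin of the observed step (m).
#' @param prev_heading Heading (deg) of the previous observed step; an
#'   observed step without one cannot be matched (callers skip and count it).
#' @param dist One entry of an [build_distributions()] object.
#' @param n Number of controls (default 10).
#' @return Data frame with `x1`, `y1`, `x2`, `y2`, `heading_deg`,
#'   `length_m`, one row per control. Uses the current RNG state; seed for
#'   reproducibility.
#' @export
generate_controls <- function(x, y, prev_heading, dist, n = 10) {
  if (is.na(prev_heading)) stop("observed step has no previous heading")
  len <- dist$lengths[sample.int(length(dist$lengths), n, replace = TRUE)]
  ang <- dist$angles[sample.int(length(dist$angles), n, replace = TRUE)]
  heading <- wrap_angle(prev_heading + ang)
  data.frame(x1 = x, y1 = y,
             x2 = x + len * cos(heading * pi / 180),
             y2 = y + len * sin(heading * pi / 180),
             heading_deg = heading, length_m = len)
}

# Resolve classified-raster values at points for a date, replacing CLOUD by
# the nearest-in-time non-cloud class of the same cell (NA if none).
resolve_classes <- function(series, landscape, year, doy, xs, ys) {
  r <- raster_for_date(series, year, doy)
  if (is.null(r)) {
    stop(sprintf("no date-matched ice raster for %d/doy %d", year, doy))
  }
  cls <- class_at(r$grid, landscape, xs, ys)
  cloudy <- which(cls == CLASS_CLOUD)
  if (length(cloudy)) {
    tdist <- vapply(series, function(s) abs((s$year - r$year) * 365 + (s$doy - r$doy)),
                    numeric(1))
    ord <- order(tdist)
    for (i in cloudy) {
      cls[i] <- NA_integer_
      for (j in ord[-1]) {
        v <- class_at(series[[j]]$grid, landscape, xs[i], ys[i])
        if (v != CLASS_CLOUD) { cls[i] <- v; break }
      }
    }
  }
  cls
}

#' Water and ice composition along a step
#'
#' Samples the step's chord at half-cell spacing and returns the fractions of
#' sample points classified WATER and ICE on the date-matched raster. CLOUD
#' points fall back to the nearest-in-time non-cloud class for their cell and
#' are excluded from the denominator if none exists; points beyond the grid
#' count as land.
#'
#' @param x1,y1,x2,y2 Step endpoints (m).
#' @param time POSIXct start time of the step (selects the 8-day raster).
#' @param series An `ice_series`.
#' @param landscape A `landscape`.
#' @return List with `prop_water` and `prop_ice`, each in `[0, 1]`.
#' @export
step_covariates <- function(x1, y1, x2, y2, time, series, landscape) {
  pts <- chord_points(x1, y1, x2, y2, landscape$cellsize)
  cls <- resolve_classes(series, landscape, year_of(time), doy_of(time),
                         pts$x, pts$y)
  cls <- cls[!is.na(cls)]
  if (!length(cls)) return(list(prop_water = NA_real_, prop_ice = NA_real_))
  list(prop_water = mean(cls == CLASS_WATER), prop_ice = mean(cls == CLASS_ICE))
}

#' Assemble step-selection strata from observed steps
#'
#' For every observed step with a defined previous heading, draws `n_controls`
#' matched random steps from the individual-by-interval availability
#' distributions and computes the water/ice composition of the observed and
#' control steps. Steps without a previous heading, or whose individual and
#' interval have no availability entry, are skipped and counted.
#'
#' @param steps Step table (from [build_steps()] applied to segment fixes);
#'   a `body_type` column, if present, is carried onto the strata.
#' @param dists An [build_distributions()] object.
#' @param series An `ice_series`.
#' @param landscape A `landscape`.
#' @param n_controls Controls per stratum (default 10).
#' @param seed Integer RNG seed.
#' @return Data frame with `stratum`, `observed`, `prop_water`, `prop_ice`,
#'   `body_type`; attribute `n_skipped` counts unmatched observed steps.
#' @export
build_ssf_strata <- function(steps, dists, series, landscape,
                             n_controls = 10, seed = 1) {
  set.seed(seed)
  has_prev <- !is.na(steps$turn_deg)
  skipped <- 0L
  rows <- list()
  sid <- 0L
  for (i in which(has_prev)) {
    key <- paste(steps$id[i], steps$interval_h[i], sep = "|")
    if (is.null(dists[[key]])) { skipped <- skipped + 1L; next }
    prev_heading <- wrap_angle(steps$heading_deg[i] - steps$turn_deg[i])
    ctl <- generate_controls(steps$x1[i], steps$y1[i], prev_heading,
                             dists[[key]], n = n_controls)
    sid <- sid + 1L
    xs <- c(steps$x2[i], ctl$x2); ys <- c(steps$y2[i], ctl$y2)
    cov <- lapply(seq_along(xs), function(j) {
      step_covariates(steps$x1[i], steps$y1[i], xs[j], ys[j], steps$t1[i],
                      series, landscape)
    })
    rows[[sid]] <- data.frame(
      stratum = sid,
      observed = c(TRUE, rep(FALSE, n_controls)),
      prop_water = vapply(cov, `[[`, 0, "prop_water"),
      prop_ice = vapply(cov, `[[`, 0, "prop_ice"),
      body_type = if ("body_type" %in% names(steps)) steps$body_type[i] else NA_character_)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(stratum = integer(), observed = logical(),
               prop_water = numeric(), prop_ice = numeric(),
               body_type = character())
  rownames(out) <- NULL
  attr(out, "n_skipped") <- skipped
  out
}

# Design matrix for the conditional-logistic model; interactions add
# covariate x body-type dummies (lake is the reference level).
ssf_design <- function(strata, covars, interactions) {
  X <- as.matrix(strata[, covars, drop = FALSE])
  if (interactions) {
    for (ty in c("reservoir", "river")) {
      d <- as.numeric(strata$body_type == ty)
      for (cv in covars) {
        X <- cbind(X, strata[[cv]] * d)
        colnames(X)[ncol(X)] <- paste0(cv, ":", ty)
      }
    }
  }
  X
}

# log-likelihood, gradient and Hessian of the conditional logit
clogit_core <- function(beta, X, stratum, obs) {
  eta <- drop(X %*% beta)
  mx <- stats::ave(eta, stratum, FUN = max)
  ee <- exp(eta - mx)
  denom <- rowsum(ee, stratum)                    # one row per stratum
  smax <- mx[!duplicated(stratum)]
  ll <- sum(eta[obs]) - sum(log(denom) + smax)
  sidx <- match(stratum, sort(unique(stratum)))
  p <- ee / denom[sidx]
  grad <- colSums(X[obs, , drop = FALSE]) - colSums(X * p)
  M <- rowsum(X * p, stratum)
  H <- -(t(X * p) %*% X - t(M) %*% M)
  list(ll = ll, grad = grad, hess = H, p = p)
}

#' Fit a step-selection function by conditional logistic regression
#'
#' Maximizes the conditional log-likelihood
#' `sum_s [ x_obs,s' beta - log sum_j exp(x_j,s' beta) ]`
#' by Newton-Raphson from `beta = 0` with step-halving, stopping when the
#' gradient max-norm falls below `tol` (or flagging non-convergence after
#' `max_iter` iterations or a diverging estimate, as under complete
#' separation). Standard errors come from the inverse observed information.
#' Strata without covariate contrast between the observed step and its
#' controls are retained (zero gradient contribution) and counted.
#'
#' @param strata Strata data frame (`stratum`, `observed`, covariates,
#'   optionally `body_type`), e.g. from [build_ssf_strata()] or
#'   [simulate_ssf_strata()].
#' @param covars Covariate column names (default `prop_water`, `prop_ice`).
#' @param interactions If `TRUE`, adds covariate-by-body-type interaction
#'   terms (reservoir and river against the lake reference).
#' @param tol Gradient max-norm convergence tolerance (default 1e-8).
#' @param max_iter Newton iteration cap (default 50).
#' @return Object of class `ssf_fit`: `coefficients`, `se`, `z`, `p`,
#'   `loglik`, `loglik_null`, `k`, `n_strata`, `aicc`, `converged`,
#'   `iterations`, `n_zero_contrast`.
#' @export
fit_clogit <- function(strata, covars = c("prop_water", "prop_ice"),
                       interactions = FALSE, tol = 1e-8, max_iter = 50) {
  stopifnot(nrow(strata) > 0, all(c("stratum", "observed") %in% names(strata)))
  ok <- stats::complete.cases(strata[, c("stratum", "observed", covars)])
  strata <- strata[ok, , drop = FALSE]
  X <- ssf_design(strata, covars, interactions)
  stratum <- strata$stratum
  obs <- strata$observed
  if (!all(tapply(obs, stratum, sum) == 1L)) {
    stop("every stratum must contain exactly one observed step")
  }
  # identifiability: each covariate needs within-stratum variation somewhere
  for (j in seq_len(ncol(X))) {
    rng <- tapply(X[, j], stratum, function(v) diff(range(v)))
    if (all(rng == 0)) {
      stop("covariate '", colnames(X)[j],
           "' is constant within every stratum (non-identifiable)")
    }
  }
  zero_contrast <- tapply(seq_along(stratum), stratum, function(i) {
    all(apply(X[i, , drop = FALSE], 2, function(v) diff(range(v)) == 0))
  })
  beta <- rep(0, ncol(X))
  core <- clogit_core(beta, X, stratum, obs)
  ll0 <- core$ll
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    if (max(abs(core$grad)) < tol) { converged <- TRUE; break }
    delta <- tryCatch(solve(core$hess, -core$grad),
                      error = function(e) NULL)
    if (is.null(delta)) break
    step <- 1
    repeat {
      cand <- beta + step * delta
      core_new <- clogit_core(cand, X, stratum, obs)
      if (core_new$ll >= core$ll - 1e-12 || step < 1e-10) break
      step <- step / 2
    }
    beta <- beta + step * delta
    core <- core_new
  }
  if (max(abs(core$grad)) < tol && all(abs(beta) < 15)) converged <- TRUE
  # a diverging estimate (no finite maximizer, e.g. complete separation) is
  # flagged rather than silently reported
  if (any(abs(beta) >= 15)) converged <- FALSE
  info <- -core$hess
  se <- tryCatch(sqrt(diag(solve(info))), error = function(e) rep(NA_real_, length(beta)))
  names(beta) <- colnames(X); names(se) <- colnames(X)
  z <- beta / se
  n_strata <- length(unique(stratum))
  k <- length(beta)
  fit <- structure(list(
    coefficients = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    loglik = core$ll, loglik_null = ll0, k = k, n_strata = n_strata,
    aicc = NA_real_, converged = converged, iterations = iter,
    n_zero_contrast = sum(unlist(zero_contrast)),
    covars = colnames(X), interactions = interactions),
    class = "ssf_fit")
  fit$aicc <- aicc(fit)
  fit
}

#' @export
print.ssf_fit <- function(x, ...) {
  cat(sprintf("Step-selection fit: %d strata, k = %d, LL = %.2f, AICc = %.2f%s\n",
              x$n_strata, x$k, x$loglik, x$aicc,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  print(data.frame(beta = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Small-sample corrected AIC of a step-selection fit
#'
#' `AICc = -2 LL + 2k + 2k(k + 1) / (n - k - 1)` with `n` the number of
#' strata (the independent units of the conditional likelihood).
#'
#' @param fit An `ssf_fit`, or any list with `loglik`, `k`, `n_strata`.
#' @return The AICc value.
#' @examples
#' aicc(list(loglik = -3809.01, k = 2, n_strata = 1203))
#' @export
aicc <- function(fit) {
  -2 * fit$loglik + 2 * fit$k + 2 * fit$k * (fit$k + 1) / (fit$n_strata - fit$k - 1)
}

#' Linear predictor scores of a step-selection fit
#'
#' @param object An `ssf_fit`.
#' @param strata Strata data frame with the fit's covariates.
#' @param ... Unused.
#' @return Numeric vector of linear scores `x' beta`.
#' @export
predict.ssf_fit <- function(object, strata, ...) {
  X <- ssf_design(strata, setdiff(object$covars, grep(":", object$covars, value = TRUE)),
                  object$interactions)
  drop(X %*% object$coefficients)
}

#' Rank-based k-fold validation of a step-selection model
#'
#' For each of `draws` random splits, the model is fitted on `train_frac` of
#' the strata and evaluated on the rest: within each test stratum the 11
#' steps are ranked by predicted score (rank 11 = highest, ties broken by
#' seeded random order), the rank of the observed step is tallied over test
#' strata, and the Spearman correlation between ranks 1..11 and the
#' observed-step counts is computed with the standard tie-corrected
#' (midrank) formula. The mean correlation over draws is reported.
#'
#' @param strata Strata data frame.
#' @param covars,interactions Model specification passed to [fit_clogit()].
#' @param train_frac Training fraction of strata (default 0.8).
#' @param draws Number of random splits (default 10).
#' @param seed Integer RNG seed.
#' @return List of class `ssf_validation`: `per_draw` data frame
#'   (`draw`, `r_s`), `mean_rs`, `counts` (matrix draws x 11).
#' @export
kfold_validate <- function(strata, covars = c("prop_water", "prop_ice"),
                           interactions = FALSE, train_frac = 0.8,
                           draws = 10, seed = 1) {
  set.seed(seed)
  ids <- unique(strata$stratum)
  m <- max(table(strata$stratum))
  rs <- numeric(draws)
  counts <- matrix(0L, draws, m)
  for (d in seq_len(draws)) {
    train_ids <- sample(ids, size = floor(train_frac * length(ids)))
    fit <- fit_clogit(strata[strata$stratum %in% train_ids, ],
                      covars = covars, interactions = interactions)
    test <- strata[!(strata$stratum %in% train_ids), ]
    score <- predict(fit, test)
    obs_rank <- unlist(lapply(split(seq_len(nrow(test)), test$stratum), function(i) {
      r <- rank(score[i], ties.method = "random")
      r[test$observed[i]]
    }))
    counts[d, ] <- tabulate(obs_rank, nbins = m)
    rs[d] <- spearman_counts(counts[d, ])
  }
  structure(list(per_draw = data.frame(draw = seq_len(draws), r_s = rs),
                 mean_rs = mean(rs), counts = counts),
            class = "ssf_validation")
}

#' Spearman correlation between rank positions and observed-step counts
#'
#' Tie-corrected (midrank) Spearman correlation of a count vector against the
#' rank positions `1..length(counts)`.
#'
#' @param counts Observed-step counts per rank.
#' @return Correlation in `[-1, 1]` (0 when the counts are constant).
#' @export
spearman_counts <- function(counts) {
  if (stats::sd(counts) == 0) return(0)
  stats::cor(counts, seq_along(counts), method = "spearman")
}

#' Independent step-selection fits per group
#'
#' Fits [fit_clogit()] separately per group (e.g. year, or short vs long
#' ice-availability class). Groups with fewer than `min_strata` strata are
#' flagged and not fitted.
#'
#' @param strata Strata data frame.
#' @param group Group label per stratum row.
#' @param covars,interactions Model specification.
#' @param min_strata Minimum strata per fitted group (default 30).
#' @return List with `fits` (named list of `ssf_fit`) and `skipped`
#'   (named integer vector of stratum counts of unfitted groups).
#' @export
grouped_fits <- function(strata, group, covars = c("prop_water", "prop_ice"),
                         interactions = FALSE, min_strata = 30) {
  stopifnot(length(group) == nrow(strata))
  fits <- list(); skipped <- integer(0)
  for (g in unique(group)) {
    sub <- strata[group == g, , drop = FALSE]
    n <- length(unique(sub$stratum))
    if (n < min_strata) {
      skipped[as.character(g)] <- n
    } else {
      fits[[as.character(g)]] <- fit_clogit(sub, covars = covars,
                                            interactions = interactions)
    }
  }
  list(fits = fits, skipped = skipped)
}

#' Write a step-selection fit to JSON
#'
#' @param fit An `ssf_fit`.
#' @param path Output path.
#' @export
write_ssf_fit_json <- function(fit, path) {
  jsonlite::write_json(list(
    beta = as.list(fit$coefficients), se = as.list(fit$se),
    p = as.list(fit$p), LL = fit$loglik, k = fit$k, n = fit$n_strata,
    AICc = fit$aicc, converged = fit$converged), path,
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}
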