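#' Specification of a synthetic study region
#'
#' Describes one region of the synthetic world: its survey years, number of
#' research points (one observation per point-year slot), mean field area,
#' target land-use composition, and the minimum spacing between research
#' points. The shipped defaults ([default_region_specs()]) mirror the three
#' study regions.
#'
#' @param name Region name.
#' @param years Integer vector of survey years; points are assigned to
#'   years round-robin so every region-year level is populated.
#' @param n_points Number of research points (= observations) in the region.
#' @param mean_field_area_ha Target mean parcel area in hectares.
#' @param target_composition Named fractions over the seven land-use
#'   categories, summing to 1.
#' @param source_habitat_pct_range Descriptive (low, high) percent range of
#'   source habitat around the points; recorded metadata, not enforced.
#' @param min_point_spacing_m Minimum pairwise distance between research
#'   points in meters.
#' @return Object of class `region_spec`.
#' @export
region_spec <- function(name, years, n_points, mean_field_area_ha,
                        target_composition,
                        source_habitat_pct_range = c(0, 100),
                        min_point_spacing_m = 300) {
  stopifnot(n_points >= 1, mean_field_area_ha > 0, min_point_spacing_m > 0)
  tc <- target_composition
  if (is.null(names(tc)) || !setequal(names(tc), land_use_categories())) {
    missing <- setdiff(land_use_categories(), names(tc))
    tc[missing] <- 0
    extra <- setdiff(names(tc), land_use_categories())
    if (length(extra)) stop("unknown category in composition: ", extra[1L])
  }
  tc <- tc[land_use_categories()]
  if (any(tc < 0) || any(tc > 1) || abs(sum(tc) - 1) > 1e-9) {
    stop("composition fractions must lie in [0,1] and sum to 1")
  }
  if (source_habitat_pct_range[1L] > source_habitat_pct_range[2L]) {
    stop("source_habitat_pct_range must be (low, high)")
  }
  structure(
    list(name = name, years = as.integer(years), n_points = as.integer(n_points),
         mean_field_area_ha = mean_field_area_ha, target_composition = tc,
         source_habitat_pct_range = source_habitat_pct_range,
         min_point_spacing_m = min_point_spacing_m),
    class = "region_spec"
  )
}

#' Default region specifications emulating the three study regions
#'
#' Maesawa (2011-2013, 47 points, 0.15-ha fields, ~14.7% source habitat),
#' Otomo (2018 and 2020, 18 points, 0.11-ha fields, ~0.3% source habitat,
#' forest-dominated coastal landscape) and Semine (2016-2018, 28 points,
#' 0.16-ha fields, ~9.3% source habitat); 93 observations over 8
#' region-years in total.
#'
#' @return Named list of three [region_spec()] objects.
#' @export
default_region_specs <- function() {
  list(
    Maesawa = region_spec(
      "Maesawa", 2011:2013, 47, 0.15,
      c(paddy = 0.42, source_habitat = 0.1465, soybean = 0.02,
        other_crop = 0.06, forest = 0.20, open_water = 0.03, other = 0.1235),
      source_habitat_pct_range = c(3.55, 28.68)
    ),
    Otomo = region_spec(
      "Otomo", c(2018L, 2020L), 18, 0.11,
      c(paddy = 0.38, source_habitat = 0.0032, soybean = 0.01,
        other_crop = 0.03, forest = 0.45, open_water = 0.04, other = 0.0868),
      source_habitat_pct_range = c(0.13, 0.53)
    ),
    Semine = region_spec(
      "Semine", 2016:2018, 28, 0.16,
      c(paddy = 0.45, source_habitat = 0.0934, soybean = 0.03,
        other_crop = 0.05, forest = 0.25, open_water = 0.02, other = 0.1066),
      source_habitat_pct_range = c(0.84, 29.09)
    )
  )
}

#' Generating truth for synthetic damage observations
#'
#' Defaults reuse the extended prediction equation as the data-generating
#' fixed part, with region / year-in-region / residual standard deviations
#' of 0.3 / 0.5 / 0.6 arcsine degrees (unpublished in the source study;
#' chosen so the simulated between-year spread resembles the observed one).
#'
#' @param fixed_intercept,beta_source,beta_soybean,beta_paddy Fixed part
#'   (arcsine degrees; slopes per km2).
#' @param sd_region,sd_year,sd_resid Standard deviations of the region
#'   intercepts, year-in-region intercepts and residual noise.
#' @param seed Integer seed used by [generate_damage()].
#' @return Object of class `generator_params`.
#' @export
generator_params <- function(fixed_intercept = 0.03, beta_source = 32.07,
                             beta_soybean = 44.5, beta_paddy = 2.6,
                             sd_region = 0.3, sd_year = 0.5, sd_resid = 0.6,
                             seed = 1L) {
  if (any(c(sd_region, sd_year, sd_resid) < 0)) {
    stop("standard deviations must be nonnegative")
  }
  structure(
    list(fixed_intercept = fixed_intercept, beta_source = beta_source,
         beta_soybean = beta_soybean, beta_paddy = beta_paddy,
         sd_region = sd_region, sd_year = sd_year, sd_resid = sd_resid,
         seed = as.integer(seed)),
    class = "generator_params"
  )
}

#' Default extent for a region specification
#'
#' A square sized so the requested number of points fits at the requested
#' spacing with slack, plus a 500-m rim so no buffer leaves the landscape.
#'
#' @param spec A [region_spec()].
#' @return Numeric `c(xmin, ymin, xmax, ymax)` in meters.
#' @export
default_extent <- function(spec) {
  # 4x slack: points are confined to clustered paddies, so random
  # sequential placement saturates well below lattice packing
  side <- spec$min_point_spacing_m * ceiling(sqrt(4 * spec$n_points)) + 1000
  c(0, 0, side, side)
}

#' Generate a synthetic field mosaic
#'
#' Tiles the extent gap-free with rectangular parcels by recursive binary
#' splitting (stochastic stopping around the target mean area), then
#' assigns land-use categories in spatial clumps (nearest-centroid growth
#' around random seed parcels) so that the realized composition matches the
#' target within a few percentage points and source habitat occurs in
#' pasture-like patches.
#'
#' @param spec A [region_spec()].
#' @param extent `c(xmin, ymin, xmax, ymax)` in meters; defaults to
#'   [default_extent()].
#' @param seed Integer seed; identical seeds reproduce identical mosaics.
#' @return A [landscape()].
#' @export
generate_landscape <- function(spec, extent = NULL, seed = 1L) {
  if (is.null(extent)) extent <- default_extent(spec)
  stopifnot(length(extent) == 4L, extent[3L] > extent[1L],
            extent[4L] > extent[2L])
  withr::local_seed(seed)
  a_mean <- spec$mean_field_area_ha * 1e4

  # binary space partition; stop each branch when area falls under a
  # lognormal threshold (factor calibrated so the realized mean ~ a_mean)
  stack <- list(extent)
  leaves <- vector("list", 4096L)
  nl <- 0L
  while (length(stack)) {
    r <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    w <- r[3L] - r[1L]
    h <- r[4L] - r[2L]
    thr <- stats::rlnorm(1L, log(1.7 * a_mean), 0.45)
    if (w * h > thr && max(w, h) > 12) {
      f <- stats::runif(1L, 0.35, 0.65)
      if (w >= h) {
        xc <- r[1L] + f * w
        stack <- c(stack, list(c(r[1L], r[2L], xc, r[4L]),
                               c(xc, r[2L], r[3L], r[4L])))
      } else {
        yc <- r[2L] + f * h
        stack <- c(stack, list(c(r[1L], r[2L], r[3L], yc),
                               c(r[1L], yc, r[3L], r[4L])))
      }
    } else {
      nl <- nl + 1L
      if (nl > length(leaves)) leaves <- c(leaves, vector("list", length(leaves)))
      leaves[[nl]] <- r
    }
  }
  leaves <- leaves[seq_len(nl)]
  rect <- do.call(rbind, leaves)
  area <- (rect[, 3L] - rect[, 1L]) * (rect[, 4L] - rect[, 2L])
  cx <- (rect[, 1L] + rect[, 3L]) / 2
  cy <- (rect[, 2L] + rect[, 4L]) / 2
  n <- nrow(rect)

  # clumped category assignment: the dominant category takes the remainder
  tc <- spec$target_composition
  total <- sum(area)
  dominant <- names(tc)[which.max(tc)]
  assigned <- rep(NA_character_, n)
  for (cat in setdiff(names(tc)[tc > 0], dominant)) {
    target <- tc[[cat]] * total
    clump_mean <- max(target / 5, 20 * a_mean)
    acc <- 0
    while (acc < target) {
      free <- which(is.na(assigned))
      if (!length(free)) break
      seed_i <- free[sample.int(length(free), 1L)]
      clump_target <- min(target - acc, stats::rexp(1L, 1 / clump_mean))
      ord <- free[order((cx[free] - cx[seed_i])^2 + (cy[free] - cy[seed_i])^2)]
      got <- 0
      for (j in ord) {
        assigned[j] <- cat
        got <- got + area[j]
        if (got >= clump_target) break
      }
      acc <- acc + got
    }
  }
  assigned[is.na(assigned)] <- dominant

  geoms <- lapply(seq_len(n), function(i) {
    rect_ring(rect[i, 1L], rect[i, 2L], rect[i, 3L], rect[i, 4L])
  })
  landscape(sprintf("%s-f%05d", spec$name, seq_len(n)), assigned, geoms,
            validate = FALSE)
}

#' Sample research points inside paddy fields
#'
#' Picks `n_points` distinct paddy parcels and places one point per parcel,
#' 10 m inside a randomly chosen corner (toward the centroid), enforcing
#' the minimum pairwise spacing by greedy rejection. Points are assigned to
#' the region's survey years round-robin. Parcels within 400 m of the
#' extent boundary are excluded so every buffer is fully covered.
#'
#' @param fields A [landscape()] generated for this region.
#' @param spec A [region_spec()].
#' @param seed Integer seed.
#' @param extent The extent the landscape was generated on (for the rim
#'   exclusion); defaults to the landscape bounding box.
#' @return Tibble of points: `point_id`, `region`, `year`, `x_m`, `y_m`.
#' @export
sample_research_points <- function(fields, spec, seed = 1L, extent = NULL) {
  if (is.null(extent)) {
    extent <- c(min(fields$xmin), min(fields$ymin),
                max(fields$xmax), max(fields$ymax))
  }
  paddy <- which(fields$category == "paddy")
  if (length(paddy) < spec$n_points) {
    stop("landscape has fewer paddy fields (", length(paddy),
         ") than requested points (", spec$n_points, ")")
  }
  rim <- 400
  ok_rim <- fields$xmin[paddy] >= extent[1L] + rim &
    fields$xmax[paddy] <= extent[3L] - rim &
    fields$ymin[paddy] >= extent[2L] + rim &
    fields$ymax[paddy] <= extent[4L] - rim
  cand <- paddy[ok_rim]
  if (length(cand) < spec$n_points) cand <- paddy
  withr::local_seed(seed)
  pts <- matrix(NA_real_, spec$n_points, 2L)
  ids <- integer(spec$n_points)
  taken <- 0L
  for (attempt in 1:8) {
    cand_try <- cand[sample.int(length(cand))]
    taken <- 0L
    for (i in cand_try) {
      ring <- fields$geometry[[i]][[1L]]
      corner <- ring[sample.int(nrow(ring), 1L), ]
      cen <- ring_centroid(ring)
      v <- cen - corner
      len <- sqrt(sum(v^2))
      p <- if (len > 10) corner + 10 * v / len else cen
      if (taken > 0L) {
        d2 <- (pts[seq_len(taken), 1L] - p[1L])^2 +
          (pts[seq_len(taken), 2L] - p[2L])^2
        if (min(d2) < spec$min_point_spacing_m^2) next
      }
      taken <- taken + 1L
      pts[taken, ] <- p
      ids[taken] <- i
      if (taken == spec$n_points) break
    }
    if (taken == spec$n_points) break
  }
  if (taken < spec$n_points) {
    stop("could not place ", spec$n_points, " points at ",
         spec$min_point_spacing_m, " m spacing; use a larger extent")
  }
  years <- sort(rep_len(spec$years, spec$n_points))
  tibble::tibble(
    point_id = sprintf("%s-p%02d", spec$name, seq_len(spec$n_points)),
    region = spec$name,
    year = years,
    x_m = pts[, 1L],
    y_m = pts[, 2L],
    field_id = fields$id[ids]
  )
}

#' Simulate pecky-rice damage observations
#'
#' Draws region intercepts `u ~ N(0, sd_region^2)`, year-in-region
#' intercepts `w ~ N(0, sd_year^2)` and residual noise, adds them to the
#' fixed linear predictor over the buffer features, truncates the
#' arcsine-scale response to \[0, 90\], and back-transforms to percent
#' damage. Grain counts are simulated with totals uniform on
#' 18498..46049 and `damaged = round(total * pct / 100)`; the stored
#' `pct_damage` is the exact model value (the counts are its quantized
#' shadow).
#'
#' @param points Research points (see [sample_research_points()]); several
#'   regions may be concatenated.
#' @param features Buffer feature table ([feature_table()]) keyed by
#'   `point_id`.
#' @param params A [generator_params()].
#' @return Tibble of observations; the drawn random effects are attached as
#'   attribute `"effects"`.
#' @export
generate_damage <- function(points, features, params = generator_params()) {
  miss <- setdiff(points$point_id, features$point_id)
  if (length(miss)) stop("no buffer composition for point '", miss[1L], "'")
  dat <- dplyr::left_join(points, features, by = "point_id")
  rcol <- if ("region.x" %in% names(dat)) "region.x" else "region"
  ycol <- if ("year.x" %in% names(dat)) "year.x" else "year"
  dat <- dat[order(dat[[rcol]], dat[[ycol]], dat$point_id), ]
  region <- dat[[rcol]]
  year <- dat[[ycol]]
  withr::local_seed(params$seed)
  regions <- sort(unique(region))
  u <- stats::setNames(stats::rnorm(length(regions), 0, params$sd_region),
                       regions)
  ry <- paste(region, year, sep = ":")
  rys <- sort(unique(ry))
  w <- stats::setNames(stats::rnorm(length(rys), 0, params$sd_year), rys)
  eta <- params$fixed_intercept +
    params$beta_source * dat$source_habitat_km2 +
    params$beta_soybean * dat$soybean_km2 +
    params$beta_paddy * dat$paddy_km2
  y <- eta + u[region] + w[ry] + stats::rnorm(nrow(dat), 0, params$sd_resid)
  y <- pmin(pmax(y, 0), 90)
  pct <- inverse_arcsine(y)
  total <- sample(18498:46049, nrow(dat), replace = TRUE)
  damaged <- as.integer(round(total * pct / 100))
  out <- tibble::tibble(
    point_id = dat$point_id,
    region = region,
    year = as.integer(year),
    grains_total = as.integer(total),
    grains_damaged = damaged,
    pct_damage = unname(pct),
    arcsine_damage = unname(y)
  )
  attr(out, "effects") <- list(u = u, w = w)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
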