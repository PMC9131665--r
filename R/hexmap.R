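#' Hexagonal grid covering an extent
#'
#' Flat-top regular hexagons with the given side length (default 300 m,
#' the largest hexagon fitting in a 300-m-radius circle, so each cell
#' approximates a 600-m-diameter buffer). Adjacent cells share edges
#' exactly; the grid is anchored at the extent's lower-left corner and
#' extends far enough to cover it completely.
#'
#' @param extent `c(xmin, ymin, xmax, ymax)` in meters.
#' @param side_m Hexagon side = circumradius in meters.
#' @return Tibble of cells: `id`, `cx`, `cy`, `geometry` (6-vertex ring),
#'   bounding-box columns, `area_m2`.
#' @export
hex_grid <- function(extent, side_m = 300) {
  if (side_m <= 0) stop("side_m must be positive")
  stopifnot(length(extent) == 4L, extent[3L] > extent[1L],
            extent[4L] > extent[2L])
  s <- side_m
  dx <- 1.5 * s
  dy <- sqrt(3) * s
  i0 <- floor((extent[1L] - extent[1L]) / dx) - 1L
  imax <- ceiling((extent[3L] - extent[1L]) / dx) + 1L
  jmax <- ceiling((extent[4L] - extent[2L]) / dy) + 1L
  th <- pi * (0:5) / 3
  hx <- s * cos(th)
  hy <- s * sin(th)
  cells <- list()
  n <- 0L
  for (i in i0:imax) {
    cx <- extent[1L] + i * dx
    yoff <- if (i %% 2L == 0L) 0 else dy / 2
    for (j in (-1L):jmax) {
      cy <- extent[2L] + j * dy + yoff
      n <- n + 1L
      cells[[n]] <- list(id = sprintf("hex-%d-%d", i, j), cx = cx, cy = cy)
    }
  }
  cx <- vapply(cells, `[[`, numeric(1), "cx")
  cy <- vapply(cells, `[[`, numeric(1), "cy")
  # keep cells that can touch the extent
  keep <- cx + s >= extent[1L] - 1e-9 & cx - s <= extent[3L] + 1e-9 &
    cy + dy / 2 >= extent[2L] - 1e-9 & cy - dy / 2 <= extent[4L] + 1e-9
  cells <- cells[keep]
  cx <- cx[keep]
  cy <- cy[keep]
  geoms <- lapply(seq_along(cells), function(k) {
    cbind(cx[k] + hx, cy[k] + hy)
  })
  tibble::tibble(
    id = vapply(cells, `[[`, character(1), "id"),
    cx = cx, cy = cy,
    geometry = geoms,
    xmin = cx - s, ymin = cy - dy / 2, xmax = cx + s, ymax = cy + dy / 2,
    area_m2 = 3 * sqrt(3) / 2 * s^2
  )
}

#' Land-use composition of hexagon cells
#'
#' Intersects every field polygon with every (bounding-box-overlapping)
#' cell and accumulates per-category areas in km2, with the field-margin
#' correction prorated by the in-cell area fraction exactly as in
#' [buffer_composition()]. Cells containing no agricultural area are
#' dropped.
#'
#' @param grid A [hex_grid()].
#' @param fields A [landscape()].
#' @param margin A [margin_model()].
#' @param include_margin Add prorated margins into `source_habitat`.
#' @param drop_empty Drop cells without agricultural area (the published
#'   map keeps only hexagons containing agricultural fields); set to
#'   `FALSE` to keep every intersected cell, e.g. for area-conservation
#'   audits.
#' @return Tibble of agricultural cells with `<category>_km2` columns,
#'   `margin_km2` and `contains_agriculture`.
#' @export
populate_cells <- function(grid, fields, margin = margin_model(),
                           include_margin = TRUE, drop_empty = TRUE) {
  if (nrow(grid) == 0L) stop("empty grid")
  ag <- agricultural_categories()
  rows <- lapply(seq_len(nrow(grid)), function(k) {
    hexring <- grid$geometry[[k]]
    cand <- which(fields$xmax > grid$xmin[k] & fields$xmin < grid$xmax[k] &
                    fields$ymax > grid$ymin[k] & fields$ymin < grid$ymax[k])
    if (!length(cand)) return(NULL)
    # a field is fully inside if all 4 bbox corners are inside all 6 edges
    inside <- vapply(cand, function(i) {
      corners <- rect_ring(fields$xmin[i], fields$ymin[i],
                           fields$xmax[i], fields$ymax[i])
      all(vapply(1:6, function(e) {
        a <- hexring[e, ]
        b <- hexring[if (e == 6L) 1L else e + 1L, ]
        all((b[1L] - a[1L]) * (corners[, 2L] - a[2L]) -
              (b[2L] - a[2L]) * (corners[, 1L] - a[1L]) >= 0)
      }, logical(1)))
    }, logical(1))
    comp <- clip_composition(fields, hexring, inside, cand,
                             margin, include_margin)
    has_ag <- sum(comp$cat_area[ag]) > 0
    if (!has_ag && drop_empty) return(NULL)
    if (sum(comp$cat_area) == 0) return(NULL)
    out <- tibble::tibble(id = grid$id[k], cx = grid$cx[k], cy = grid$cy[k],
                          geometry = list(hexring))
    areas <- comp$cat_area / 1e6
    if (include_margin) {
      areas[["source_habitat"]] <- areas[["source_habitat"]] +
        comp$margin_m2 / 1e6
    }
    for (cat in land_use_categories()) {
      out[[paste0(cat, "_km2")]] <- areas[[cat]]
    }
    out$margin_km2 <- comp$margin_m2 / 1e6
    out$contains_agriculture <- has_ag
    out
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(tibble::tibble())
  }
  dplyr::bind_rows(rows)
}

#' Predict damage for hexagon cells and flag priority areas
#'
#' Applies the population-level linear predictor (no region- or
#' year-specific effects, as on the published priority map) to each cell's
#' land-use composition, back-transforms to percent damage, grades the
#' cells, and flags those whose predicted grade is worse than first grade
#' (prediction above `threshold` percent).
#'
#' @param cells Output of [populate_cells()].
#' @param model A [damage_model()].
#' @param threshold Priority boundary in percent (default 0.1, the
#'   first-grade limit).
#' @param thresholds A [grade_thresholds()].
#' @return `cells` with `predicted_arcsine`, `predicted_pct`, `grade`,
#'   `priority`; priority/total counts in attribute `"summary"`.
#' @export
map_predict <- function(cells, model, threshold = 0.1,
                        thresholds = grade_thresholds()) {
  if (nrow(cells) == 0L) stop("no cells to predict")
  eta <- stats::predict(model, cells)
  cells$predicted_arcsine <- eta
  cells$predicted_pct <- inverse_arcsine(pmin(pmax(eta, 0), 90))
  cells$grade <- classify_grade(cells$predicted_pct, thresholds)
  cells$priority <- cells$predicted_pct > threshold
  attr(cells, "summary") <- list(n_priority = sum(cells$priority),
                                 n_total = nrow(cells))
  cells
}

#' Scenario sensitivity table for the prediction equation
#'
#' Evaluates the model over the min/average/max source-habitat and soybean
#' areas at the average paddy area (all in km2; the defaults are the
#' study's values: source 0.37/3.12/8.32 ha, soybean 0/0.33/2.90 ha, paddy
#' 9.42 ha), for a low-risk and a high-risk random-intercept case.
#'
#' @param model A [damage_model()].
#' @param source_levels,soybean_levels Named numeric `c(min=, avg=, max=)`
#'   in km2.
#' @param paddy_avg Average paddy area in km2.
#' @param intercept_cases Named numeric of random-intercept offsets
#'   (arcsine degrees), e.g. `c(lowest = ..., highest = ...)`.
#' @param thresholds A [grade_thresholds()].
#' @return Tibble over case x source level x soybean level with arcsine and
#'   percent predictions and grades.
#' @export
scenario_table <- function(model,
                           source_levels = c(min = 0.0037, avg = 0.0312,
                                             max = 0.0832),
                           soybean_levels = c(min = 0, avg = 0.0033,
                                              max = 0.0290),
                           paddy_avg = 0.0942,
                           intercept_cases = c(lowest = 0, highest = 0),
                           thresholds = grade_thresholds()) {
  grid <- expand.grid(case = names(intercept_cases),
                      source_level = names(source_levels),
                      soybean_level = names(soybean_levels),
                      stringsAsFactors = FALSE)
  feats <- tibble::tibble(
    source_habitat = source_levels[grid$source_level],
    soybean = soybean_levels[grid$soybean_level],
    paddy = paddy_avg
  )
  eta <- stats::predict(model, feats) + intercept_cases[grid$case]
  pct <- inverse_arcsine(pmin(pmax(eta, 0), 90))
  tibble::tibble(
    case = grid$case,
    intercept = unname(intercept_cases[grid$case]),
    source_level = grid$source_level,
    source_km2 = unname(source_levels[grid$source_level]),
    soybean_level = grid$soybean_level,
    soybean_km2 = unname(soybean_levels[grid$soybean_level]),
    paddy_km2 = paddy_avg,
    arcsine = unname(eta),
    pct = unname(pct),
    grade = classify_grade(unname(pct), thresholds)
  )
}

#' Random-intercept offset for a named risk case
#'
#' Sum of a model's stored region intercept and year-in-region intercept
#' for a region-year; missing labels contribute zero with a warning.
#'
#' @param model A [damage_model()].
#' @param region,year Labels of the case.
#' @return Scalar offset in arcsine degrees.
#' @export
risk_case_offset <- function(model, region, year) {
  ri <- model$random_intercepts
  u <- ri$region[as.character(region)]
  w <- ri$region_year[paste(region, year, sep = ":")]
  if (is.null(ri$region) || is.na(u)) {
    warning("no stored region intercept for '", region, "'; using 0")
    u <- 0
  }
  if (is.null(ri$region_year) || is.na(w)) {
    warning("no stored region-year intercept for '", region, ":", year,
            "'; using 0")
    w <- 0
  }
  unname(u + w)
}

#' Write a predicted hexagon map to GeoJSON
#'
#' @param cells Output of [map_predict()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_map <- function(cells, path) {
  if (nrow(cells) == 0L) stop("no cells to write")
  feats <- lapply(seq_len(nrow(cells)), function(i) {
    r <- cells$geometry[[i]]
    r <- rbind(r, r[1L, ])
    props <- list(id = cells$id[i])
    for (cat in land_use_categories()) {
      nm <- paste0(cat, "_km2")
      props[[nm]] <- cells[[nm]][i]
    }
    props$predicted_pct <- cells$predicted_pct[i]
    props$grade <- as.character(cells$grade[i])
    props$priority <- cells$priority[i]
    list(
      type = "Feature",
      properties = props,
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(r)),
                                  function(j) c(r[j, 1L], r[j, 2L])))
      )
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a hexagon map written by [write_map()]
#'
#' @param path GeoJSON path.
#' @return Tibble of cells with geometry and properties.
#' @export
read_map <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1L]],
                                  function(p) c(p[[1L]], p[[2L]])))
    ring <- ring[-nrow(ring), , drop = FALSE]
    p <- f$properties
    out <- tibble::tibble(id = p$id, geometry = list(ring))
    for (nm in setdiff(names(p), "id")) out[[nm]] <- p[[nm]]
    out
  })
  dplyr::bind_rows(rows)
}
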