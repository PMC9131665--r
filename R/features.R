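#' Field-margin area model
#'
#' Linear model predicting the grassy field-margin area (m2) of an
#' agricultural parcel from its perimeter: `area = 0.3978 * perimeter -
#' 25.173`, clamped at zero below the root perimeter (about 63.3 m).
#' Margins are graminoid-dominated and count as source habitat.
#'
#' @param slope Slope in m2 per m of perimeter.
#' @param intercept Intercept in m2.
#' @return Object of class `margin_model`.
#' @export
margin_model <- function(slope = 0.3978, intercept = -25.173) {
  structure(list(slope = slope, intercept = intercept),
            class = "margin_model")
}

#' Predicted field-margin area
#'
#' @param perimeter_m Nonnegative field perimeter(s) in meters.
#' @param margin A [margin_model()].
#' @return Margin area(s) in m2, clamped at zero.
#' @export
margin_area <- function(perimeter_m, margin = margin_model()) {
  if (any(perimeter_m < 0)) stop("perimeter must be nonnegative")
  pmax(0, margin$slope * perimeter_m + margin$intercept)
}

# Shared clipping core: per-category intersection areas (m2) between a
# convex clip ring and a landscape, plus prorated margin area (m2). The
# `inside_fun(fields_idx)` shortcut marks fields wholly inside the clip.
clip_composition <- function(fields, clip, fully_inside, candidates,
                             margin, include_margin) {
  cat_area <- stats::setNames(rep(0, 7L), land_use_categories())
  margin_m2 <- 0
  ag <- agricultural_categories()
  for (i in candidates) {
    if (fully_inside[match(i, candidates)]) {
      a <- fields$area_m2[i]
    } else {
      a <- clip_area_polygon(fields$geometry[[i]], clip,
                             rings_convex = fields$convex[i])
      if (a <= 0) next
    }
    cat <- fields$category[i]
    cat_area[[cat]] <- cat_area[[cat]] + a
    if (include_margin && cat %in% ag) {
      margin_m2 <- margin_m2 +
        margin_area(fields$perimeter_m[i], margin) * a / fields$area_m2[i]
    }
  }
  list(cat_area = cat_area, margin_m2 = margin_m2)
}

#' Land-use composition within a circular buffer
#'
#' Intersects a circular buffer (approximated by a regular polygon) around a
#' research point with every field polygon and sums the intersection areas
#' per land-use category, in km2. When `include_margin` is on, the predicted
#' field-margin area of every agricultural field touching the buffer is
#' added to the source-habitat total, prorated by the fraction of the
#' field's area lying inside the buffer.
#'
#' @param point One-row data frame (or list) with `point_id`, `x_m`, `y_m`.
#' @param fields A [landscape()].
#' @param radius_m Buffer radius in meters (default 300).
#' @param margin A [margin_model()].
#' @param include_margin Add prorated margins into `source_habitat`.
#' @param segments Number of segments approximating the circle (>= 256
#'   keeps the relative area error below 1e-4).
#' @return One-row tibble with `point_id`, `radius_m`, one `<category>_km2`
#'   column per category, and `margin_km2`.
#' @export
buffer_composition <- function(point, fields, radius_m = 300,
                               margin = margin_model(),
                               include_margin = TRUE, segments = 256L) {
  if (radius_m <= 0) stop("radius_m must be positive")
  px <- point$x_m[1L]
  py <- point$y_m[1L]
  circle <- regular_polygon(c(px, py), radius_m, segments)
  dmin <- bbox_min_dist(px, py, fields$xmin, fields$ymin,
                        fields$xmax, fields$ymax)
  cand <- which(dmin < radius_m)
  dmax <- bbox_max_dist(px, py, fields$xmin[cand], fields$ymin[cand],
                        fields$xmax[cand], fields$ymax[cand])
  comp <- clip_composition(fields, circle, dmax <= radius_m, cand,
                           margin, include_margin)
  areas <- comp$cat_area / 1e6
  if (include_margin) {
    areas[["source_habitat"]] <- areas[["source_habitat"]] + comp$margin_m2 / 1e6
  }
  out <- tibble::tibble(point_id = as.character(point$point_id[1L]),
                        radius_m = radius_m)
  for (cat in land_use_categories()) {
    out[[paste0(cat, "_km2")]] <- areas[[cat]]
  }
  out$margin_km2 <- comp$margin_m2 / 1e6
  out
}

#' Buffer feature table for a set of research points
#'
#' Runs [buffer_composition()] for every research point and returns one row
#' per point with the per-category km2 areas plus the point's region and
#' year, ready to join with damage observations on `point_id`.
#'
#' @param points Tibble of research points (`point_id`, `region`, `year`,
#'   `x_m`, `y_m`).
#' @param fields A [landscape()].
#' @inheritParams buffer_composition
#' @return Tibble with one row per point.
#' @export
feature_table <- function(points, fields, radius_m = 300,
                          margin = margin_model(), include_margin = TRUE) {
  if (nrow(points) == 0L) stop("points must be nonempty")
  if (anyDuplicated(points$point_id)) {
    stop("duplicate point ids: ",
         points$point_id[duplicated(points$point_id)][1L])
  }
  rows <- lapply(seq_len(nrow(points)), function(i) {
    buffer_composition(points[i, ], fields, radius_m = radius_m,
                       margin = margin, include_margin = include_margin)
  })
  out <- dplyr::bind_rows(rows)
  out$region <- points$region
  out$year <- points$year
  out
}
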