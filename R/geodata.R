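#' The seven land-use categories
#'
#' The landscape classification used throughout the package: forest, rice
#' paddy fields (`paddy`), soybean fields, other agricultural crops
#' (`other_crop`), source habitat of the sorghum plant bug (pastures and
#' graminoid-dominated fallow fields, `source_habitat`), open water, and
#' everything else (`other`).
#'
#' @return Character vector of the seven category codes.
#' @export
land_use_categories <- function() {
  c("forest", "paddy", "soybean", "other_crop", "source_habitat",
    "open_water", "other")
}

agricultural_categories <- function() {
  c("paddy", "soybean", "other_crop", "source_habitat")
}

#' Build a validated landscape of field polygons
#'
#' A landscape is a tibble with one row per land parcel: an id, one of the
#' seven land-use categories, a polygon geometry (list of rings in planar
#' meters; the first ring is the exterior, later rings are holes whose area
#' is subtracted), and derived `area_m2` / `perimeter_m`. Bounding boxes and
#' a convexity flag are cached for fast buffer clipping.
#'
#' @param id Character vector of parcel ids (unique).
#' @param category Character vector of land-use categories (see
#'   [land_use_categories()]).
#' @param geometry List of polygons; each polygon is a list of open
#'   2-column coordinate matrices (meters), or a single matrix for a
#'   hole-free polygon.
#' @param validate Run the (quadratic) self-intersection check per ring.
#'   Enabled for user input, disabled by the synthetic generator whose
#'   rectangles are simple by construction.
#' @return A `landscape` tibble.
#' @export
landscape <- function(id, category, geometry, validate = TRUE) {
  stopifnot(length(id) == length(category), length(id) == length(geometry))
  if (length(id) == 0L) stop("landscape must contain at least one field")
  id <- as.character(id)
  if (anyDuplicated(id)) stop("duplicate field ids: ", id[duplicated(id)][1L])
  bad <- setdiff(unique(category), land_use_categories())
  if (length(bad)) {
    off <- id[match(bad[1L], category)]
    stop("unknown land-use category '", bad[1L], "' (feature id '", off, "')")
  }
  geometry <- lapply(geometry, function(g) {
    if (is.matrix(g)) g <- list(g)
    lapply(g, function(r) {
      r <- as.matrix(r)
      storage.mode(r) <- "double"
      if (nrow(r) >= 2L && all(r[1L, ] == r[nrow(r), ])) {
        r <- r[-nrow(r), , drop = FALSE]  # drop GeoJSON closing vertex
      }
      if (nrow(r) < 3L) stop("ring with fewer than 3 vertices")
      r
    })
  })
  if (validate) {
    for (i in seq_along(geometry)) {
      for (r in geometry[[i]]) {
        if (ring_self_intersects(r)) {
          stop("self-intersecting geometry in feature id '", id[i], "'")
        }
      }
    }
  }
  area <- vapply(geometry, function(g) {
    ring_area(g[[1L]]) - if (length(g) > 1L) {
      sum(vapply(g[-1L], ring_area, numeric(1)))
    } else 0
  }, numeric(1))
  if (any(area <= 0)) {
    stop("non-positive polygon area in feature id '", id[which(area <= 0)[1L]], "'")
  }
  perim <- vapply(geometry, function(g) {
    sum(vapply(g, ring_perimeter, numeric(1)))
  }, numeric(1))
  bb <- t(vapply(geometry, rings_bbox, numeric(4)))
  convex <- vapply(geometry, function(g) {
    length(g) == 1L && ring_is_convex(g[[1L]])
  }, logical(1))
  out <- tibble::tibble(
    id = id,
    category = as.character(category),
    geometry = geometry,
    area_m2 = area,
    perimeter_m = perim,
    xmin = bb[, 1L], ymin = bb[, 2L], xmax = bb[, 3L], ymax = bb[, 4L],
    convex = convex
  )
  class(out) <- c("landscape", class(out))
  out
}

#' Read a landscape from GeoJSON
#'
#' Coordinates are interpreted as planar meters (no CRS handling). Every
#' feature must be a `Polygon` carrying a `category` property naming one of
#' the seven land-use categories.
#'
#' @param path Path to a GeoJSON FeatureCollection.
#' @return A `landscape` tibble (see [landscape()]).
#' @export
read_landscape <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  if (length(feats) == 0L) stop("empty FeatureCollection")
  ids <- character(length(feats))
  cats <- character(length(feats))
  geoms <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    ids[i] <- as.character(
      if (!is.null(f$properties$id)) f$properties$id
      else if (!is.null(f$id)) f$id
      else paste0("feature-", i)
    )
    if (is.null(f$properties$category)) {
      stop("feature id '", ids[i], "' has no 'category' property")
    }
    cats[i] <- f$properties$category
    if (is.null(f$geometry) || f$geometry$type != "Polygon") {
      stop("feature id '", ids[i], "' is not a Polygon")
    }
    geoms[[i]] <- lapply(f$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]])))
      m
    })
  }
  landscape(ids, cats, geoms, validate = TRUE)
}

#' Write a landscape to GeoJSON
#'
#' @param fields A `landscape` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(fields, path) {
  if (nrow(fields) == 0L) stop("refusing to write an empty landscape")
  feats <- lapply(seq_len(nrow(fields)), function(i) {
    rings <- lapply(fields$geometry[[i]], function(r) {
      r <- rbind(r, r[1L, ])  # close ring per GeoJSON
      lapply(seq_len(nrow(r)), function(j) c(r[j, 1L], r[j, 2L]))
    })
    list(
      type = "Feature",
      properties = list(
        id = fields$id[i],
        category = fields$category[i],
        area_m2 = fields$area_m2[i],
        perimeter_m = fields$perimeter_m[i]
      ),
      geometry = list(type = "Polygon", coordinates = rings)
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read damage observations (and research points) from CSV
#'
#' Expects columns for the point id, region, year and either grain counts
#' (`grains_total`, `grains_damaged`) or a percent-damage column. When counts
#' are present and no percent column is given, the percentage is recomputed
#' as `100 * damaged / total`; when both are present the stated percentage is
#' kept but validated against the counts (0.01 percentage-point tolerance,
#' covering count quantization). Coordinates (`x_m`, `y_m`) are optional.
#'
#' @param path CSV path (comma-separated, header row, UTF-8).
#' @param col_map Optional named list remapping the expected column names
#'   (`point_id`, `region`, `year`, `x_m`, `y_m`, `grains_total`,
#'   `grains_damaged`, `pct_damage`) onto the file's columns.
#' @return Tibble of observations with `pct_damage` and `arcsine_damage`.
#' @export
read_observations <- function(path, col_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  std <- c("point_id", "region", "year", "x_m", "y_m",
           "grains_total", "grains_damaged", "pct_damage")
  map <- stats::setNames(as.list(std), std)
  if (!is.null(col_map)) map[names(col_map)] <- col_map
  get_col <- function(nm) {
    cn <- map[[nm]]
    if (cn %in% names(raw)) raw[[cn]] else NULL
  }
  for (req in c("point_id", "region", "year")) {
    if (is.null(get_col(req))) stop("missing required column: ", map[[req]])
  }
  total <- get_col("grains_total")
  damaged <- get_col("grains_damaged")
  pct <- get_col("pct_damage")
  if (is.null(pct) && is.null(total)) {
    stop("need either a pct_damage column or grain-count columns")
  }
  if (!is.null(total)) {
    if (is.null(damaged)) stop("grains_total present without grains_damaged")
    if (any(total <= 0)) stop("grains_total must be positive")
    if (any(damaged < 0)) stop("grains_damaged must be nonnegative")
    if (any(damaged > total)) {
      i <- which(damaged > total)[1L]
      stop("grains_damaged > grains_total for point '",
           as.character(get_col("point_id"))[i], "'")
    }
    count_pct <- 100 * damaged / total
    if (is.null(pct)) {
      pct <- count_pct
    } else if (any(abs(pct - count_pct) > 0.01)) {
      i <- which(abs(pct - count_pct) > 0.01)[1L]
      stop("pct_damage inconsistent with grain counts for point '",
           as.character(get_col("point_id"))[i], "'")
    }
  }
  if (any(pct < 0 | pct > 100)) stop("pct_damage outside [0, 100]")
  out <- tibble::tibble(
    point_id = as.character(get_col("point_id")),
    region = as.character(get_col("region")),
    year = as.integer(get_col("year")),
    pct_damage = as.numeric(pct),
    arcsine_damage = arcsine_transform(as.numeric(pct))
  )
  if (!is.null(total)) {
    out$grains_total <- as.integer(total)
    out$grains_damaged <- as.integer(damaged)
  }
  if (!is.null(get_col("x_m"))) out$x_m <- as.numeric(get_col("x_m"))
  if (!is.null(get_col("y_m"))) out$y_m <- as.numeric(get_col("y_m"))
  if (anyDuplicated(out[c("point_id", "region", "year")])) {
    stop("duplicate (region, year, point_id) rows")
  }
  out
}

#' Write observations to CSV
#'
#' @param observations Tibble as returned by [read_observations()] or
#'   [generate_damage()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_observations <- function(observations, path) {
  utils::write.csv(observations, path, row.names = FALSE)
  invisible(path)
}
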