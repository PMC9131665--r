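# Shared synthetic worlds, built once per test run and cached.

.world_cache <- new.env(parent = emptyenv())

# small single-region world for feature / fit mechanics
small_spec <- function(n_points = 10, years = 2020:2021,
                       spacing = 250) {
  peckyrice::region_spec(
    "Small", years, n_points, 0.15,
    c(paddy = 0.5, source_habitat = 0.15, soybean = 0.05, other_crop = 0.05,
      forest = 0.15, open_water = 0.02, other = 0.08),
    min_point_spacing_m = spacing
  )
}

small_world <- function() {
  if (!exists("small", .world_cache)) {
    spec <- small_spec()
    extent <- peckyrice::default_extent(spec)
    fields <- peckyrice::generate_landscape(spec, extent, seed = 42)
    points <- peckyrice::sample_research_points(fields, spec, seed = 43,
                                                extent = extent)
    features <- peckyrice::feature_table(points, fields)
    assign("small", list(spec = spec, extent = extent, fields = fields,
                         points = points, features = features),
           .world_cache)
  }
  get("small", .world_cache)
}

# the full three-region, 93-point study world
study_world <- function() {
  if (!exists("study", .world_cache)) {
    specs <- peckyrice::default_region_specs()
    pts <- list()
    fts <- list()
    for (i in seq_along(specs)) {
      spec <- specs[[i]]
      extent <- peckyrice::default_extent(spec)
      fields <- peckyrice::generate_landscape(spec, extent, seed = 100 + i)
      pts[[spec$name]] <- peckyrice::sample_research_points(
        fields, spec, seed = 200 + i, extent = extent
      )
      fts[[spec$name]] <- peckyrice::feature_table(pts[[spec$name]], fields)
    }
    assign("study",
           list(points = dplyr::bind_rows(pts),
                features = dplyr::bind_rows(fts)),
           .world_cache)
  }
  get("study", .world_cache)
}

# joined observation-feature table from the study world
study_data <- function(params = peckyrice::generator_params(seed = 5)) {
  w <- study_world()
  obs <- peckyrice::generate_damage(w$points, w$features, params)
  dplyr::left_join(
    obs,
    w$features[setdiff(names(w$features), c("region", "year"))],
    by = "point_id"
  )
}

# three tiny regions for fast end-to-end mechanics
tiny_specs <- function() {
  list(
    A = peckyrice::region_spec(
      "A", 2011:2012, 8, 0.15,
      c(paddy = 0.45, source_habitat = 0.14, soybean = 0.03, other_crop = 0.05,
        forest = 0.2, open_water = 0.03, other = 0.1),
      min_point_spacing_m = 250),
    B = peckyrice::region_spec(
      "B", c(2018L, 2020L), 6, 0.11,
      c(paddy = 0.4, source_habitat = 0.01, soybean = 0.01, other_crop = 0.03,
        forest = 0.42, open_water = 0.04, other = 0.09),
      min_point_spacing_m = 250),
    C = peckyrice::region_spec(
      "C", 2016:2017, 6, 0.16,
      c(paddy = 0.45, source_habitat = 0.09, soybean = 0.03, other_crop = 0.05,
        forest = 0.25, open_water = 0.02, other = 0.11),
      min_point_spacing_m = 250)
  )
}

# direct profiled REML log-likelihood on a variance-ratio grid: the
# independent oracle for fit_lmm (region + year-in-region structure)
reml_profile_oracle <- function(y, X, region, region_year, gamma_u, gamma_w) {
  n <- length(y)
  p <- ncol(X)
  Zu <- stats::model.matrix(~ 0 + factor(region))
  Zw <- stats::model.matrix(~ 0 + factor(region_year))
  ZuZut <- tcrossprod(Zu)
  ZwZwt <- tcrossprod(Zw)
  eval_node <- function(gu, gw) {
    V0 <- diag(n) + gu * ZuZut + gw * ZwZwt
    Vi <- solve(V0)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
    -0.5 * ((n - p) * (log(2 * pi) + 1) + (n - p) * log(s2) +
              as.numeric(determinant(V0)$modulus) +
              as.numeric(determinant(XtVX)$modulus))
  }
  best <- -Inf
  for (gu in gamma_u) {
    for (gw in gamma_w) {
      ll <- eval_node(gu, gw)
      if (ll > best) best <- ll
    }
  }
  best
}
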