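#' Pipeline configuration
#'
#' Bundles every setting of a seeded end-to-end run: region specifications,
#' buffer radius, model choice, cross-validation settings, generator truth,
#' and optional output directory. All defaults are the canonical study
#' settings (300-m radius, 0.1/0.3/0.7% grades, extended random structure).
#'
#' @param seed Integer master seed; every stochastic stage derives its seed
#'   from it.
#' @param region_specs Named list of [region_spec()] objects.
#' @param radius_m Buffer radius in meters.
#' @param model_choice `"refit"` (REML refit on the synthetic data),
#'   `"extended"` (printed extended equation) or `"original"` (printed
#'   original equation).
#' @param cv_k Cross-validation folds (used when `fold_rule` is
#'   `"stratified"`; `"by_region"` uses one fold per region).
#' @param fold_rule Passed to [cross_validate()].
#' @param threshold Positive-class / priority boundary in percent.
#' @param generator A [generator_params()]; its seed is overridden by
#'   `seed`.
#' @param map_region Name of the region to map (default: fewest points).
#' @param out_dir Optional directory for artifacts (GeoJSON, CSV, JSON).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            region_specs = default_region_specs(),
                            radius_m = 300,
                            model_choice = c("refit", "extended", "original"),
                            cv_k = 3L,
                            fold_rule = "by_region",
                            threshold = 0.1,
                            generator = generator_params(),
                            map_region = NULL,
                            out_dir = NULL) {
  model_choice <- match.arg(model_choice)
  if (is.null(map_region)) {
    np <- vapply(region_specs, `[[`, integer(1), "n_points")
    map_region <- names(region_specs)[which.min(np)]
  }
  generator$seed <- as.integer(seed) + 977L
  structure(
    list(seed = as.integer(seed), region_specs = region_specs,
         radius_m = radius_m, model_choice = model_choice, cv_k = cv_k,
         fold_rule = fold_rule, threshold = threshold, generator = generator,
         map_region = map_region, out_dir = out_dir),
    class = "pipeline_config"
  )
}

#' Run the full synthetic-landscape damage pipeline
#'
#' Chains every stage: generate one field mosaic and set of research points
#' per region, extract buffer features, simulate damage observations from
#' the generator truth, fit (or select) the prediction model, evaluate it
#' (observed-vs-predicted mixed model, confusion statistics, ROC/AUC,
#' cross-validation), and build the hexagon priority map for one region.
#' Identical seeds yield identical reports apart from timings.
#'
#' @param config A [pipeline_config()].
#' @return A report list with `seed`, `metrics`, `map`, `model`,
#'   per-stage `timings_s`, and the intermediate `data`; artifacts are
#'   written when `config$out_dir` is set.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  timings <- list()
  tick <- function() Sys.time()
  tock <- function(t0) as.numeric(difftime(Sys.time(), t0, units = "secs"))

  t0 <- tick()
  landscapes <- list()
  points_list <- list()
  extents <- list()
  for (i in seq_along(config$region_specs)) {
    spec <- config$region_specs[[i]]
    extent <- default_extent(spec)
    ls_seed <- config$seed + 101L * i
    landscapes[[spec$name]] <- generate_landscape(spec, extent, seed = ls_seed)
    points_list[[spec$name]] <- sample_research_points(
      landscapes[[spec$name]], spec, seed = ls_seed + 13L, extent = extent
    )
    extents[[spec$name]] <- extent
  }
  points <- dplyr::bind_rows(points_list)
  timings$synth <- tock(t0)

  t0 <- tick()
  features <- dplyr::bind_rows(lapply(names(landscapes), function(rn) {
    feature_table(points_list[[rn]], landscapes[[rn]],
                  radius_m = config$radius_m)
  }))
  timings$features <- tock(t0)

  t0 <- tick()
  observations <- generate_damage(points, features, config$generator)
  data <- dplyr::left_join(
    observations,
    features[setdiff(names(features), c("region", "year"))],
    by = "point_id"
  )
  timings$damage <- tock(t0)

  t0 <- tick()
  fit <- NULL
  model <- switch(config$model_choice,
    refit = {
      fit <- fit_lmm(data)
      fit$model
    },
    extended = extended_model(),
    original = original_model()
  )
  timings$fit <- tock(t0)

  t0 <- tick()
  pred <- stats::predict(model, data)
  ovp <- obs_vs_pred(data$arcsine_damage, pred, data$region, data$year)
  pred_pct <- inverse_arcsine(pmin(pmax(pred, 0), 90))
  conf <- confusion(data$pct_damage, pred_pct, config$threshold)
  obs_pos <- data$pct_damage > config$threshold
  auc <- if (length(unique(obs_pos)) == 2L) roc_auc(obs_pos, pred)$auc
  else NA_real_
  cv <- cross_validate(data, k = config$cv_k, fold_rule = config$fold_rule,
                       seed = config$seed + 7L,
                       threshold = config$threshold)
  timings$evaluate <- tock(t0)

  t0 <- tick()
  map_ls <- landscapes[[config$map_region]]
  grid <- hex_grid(extents[[config$map_region]])
  cells <- populate_cells(grid, map_ls)
  cells <- map_predict(cells, model, threshold = config$threshold)
  map_summary <- attr(cells, "summary")
  timings$map <- tock(t0)

  report <- list(
    seed = config$seed,
    model_choice = config$model_choice,
    n_obs = nrow(data),
    metrics = list(
      r2_conditional = ovp$r2_conditional,
      r2_marginal = ovp$r2_marginal,
      rmse = ovp$rmse,
      slope = ovp$slope,
      wald_chisq = ovp$wald_chisq,
      accuracy = conf$accuracy,
      sensitivity = conf$sensitivity,
      specificity = conf$specificity,
      auc = auc,
      cv_r2_mean = cv$r2_mean, cv_r2_sd = cv$r2_sd,
      cv_auc_mean = cv$auc_mean, cv_auc_sd = cv$auc_sd
    ),
    map = list(region = config$map_region,
               n_priority = map_summary$n_priority,
               n_total = map_summary$n_total),
    model = model,
    fit = fit,
    cv = cv,
    confusion = conf,
    data = data,
    cells = cells,
    timings_s = timings
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    for (rn in names(landscapes)) {
      write_landscape(landscapes[[rn]],
                      file.path(config$out_dir,
                                paste0("landscape_", rn, ".geojson")))
    }
    utils::write.csv(features, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    write_observations(observations,
                       file.path(config$out_dir, "observations.csv"))
    write_model(model, file.path(config$out_dir, "model.json"))
    write_map(cells, file.path(config$out_dir, "priority_map.geojson"))
    jsonlite::write_json(
      list(seed = report$seed, model_choice = report$model_choice,
           n_obs = report$n_obs, metrics = report$metrics,
           map = report$map, timings_s = timings),
      file.path(config$out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, na = "null"
    )
  }
  report
}
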