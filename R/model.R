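#' Arcsine square-root transform of a damage percentage
#'
#' Maps percent pecky rice damage `p` in \[0, 100\] to
#' `asin(sqrt(p / 100))` expressed in degrees, the response scale of all
#' prediction equations in this package. The observed damage ceiling of
#' 0.27 percent maps to about 2.98 on this scale.
#'
#' @param pct Numeric vector of percentages in \[0, 100\].
#' @return Numeric vector in \[0, 90\] (degrees).
#' @export
arcsine_transform <- function(pct) {
  if (any(!is.finite(pct)) || any(pct < 0 | pct > 100)) {
    stop("pct must lie in [0, 100]")
  }
  asin(sqrt(pct / 100)) * 180 / pi
}

#' Inverse of the arcsine square-root transform
#'
#' @param y Numeric vector in \[0, 90\] (degrees).
#' @return Percent damage in \[0, 100\]; exact inverse of
#'   [arcsine_transform()] to 1e-10.
#' @export
inverse_arcsine <- function(y) {
  if (any(!is.finite(y)) || any(y < 0 | y > 90)) {
    stop("y must lie in [0, 90]")
  }
  100 * sin(y * pi / 180)^2
}

#' Construct a predictive damage model
#'
#' Container for a linear predictor on the arcsine-degree scale: a fixed
#' intercept, per-km2 coefficients for land-use covariates, and optional
#' random-intercept maps at the `region`, `year` and `region_year` levels
#' (labels of the latter are `"region:year"`).
#'
#' @param intercept Fixed intercept (arcsine degrees).
#' @param coefficients Named numeric vector, one entry per covariate
#'   (per km2).
#' @param random_intercepts Named list of named numeric vectors; allowed
#'   names: `region`, `year`, `region_year`.
#' @param variance_components Named numeric vector of random-effect
#'   variances (may be empty for the printed equations).
#' @param residual_sd Residual standard deviation (NA for the printed
#'   equations).
#' @param year_mode For models with year intercepts only: `"population"`
#'   predicts with year effect 0 when no year is supplied; `"conservative"`
#'   adds the largest stored year intercept instead (the precautionary
#'   choice for unlabelled extrapolation).
#' @return Object of class `damage_model`.
#' @export
damage_model <- function(intercept, coefficients, random_intercepts = list(),
                         variance_components = numeric(),
                         residual_sd = NA_real_,
                         year_mode = c("population", "conservative")) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L,
            is.numeric(coefficients), !is.null(names(coefficients)))
  bad <- setdiff(names(random_intercepts), c("region", "year", "region_year"))
  if (length(bad)) stop("unknown random-intercept level: ", bad[1L])
  if (length(variance_components) && any(variance_components < 0)) {
    stop("variance components must be nonnegative")
  }
  structure(
    list(intercept = intercept,
         coefficients = coefficients,
         random_intercepts = random_intercepts,
         variance_components = variance_components,
         residual_sd = residual_sd,
         year_mode = match.arg(year_mode)),
    class = "damage_model"
  )
}

#' @export
print.damage_model <- function(x, ...) {
  cat("<damage_model> y (arcsine degrees) =", format(x$intercept), "+\n")
  for (nm in names(x$coefficients)) {
    cat(sprintf("  %+.4g * %s (km2)\n", x$coefficients[[nm]], nm))
  }
  if (length(x$random_intercepts)) {
    cat("random intercepts:",
        paste(names(x$random_intercepts), collapse = ", "), "\n")
  }
  invisible(x)
}

#' The original prediction equation (single-region study)
#'
#' `y = -0.09 + 40.05 * source_habitat + 52.7 * soybean - 1.12 * paddy +
#' RI_year`, with year-specific random intercepts for 2011-2013 (largest in
#' 2011). The published intercept values are not printed, so they default
#' to zero and can be supplied.
#'
#' @param year_intercepts Named numeric vector of year intercepts.
#' @param year_mode See [damage_model()]; `"conservative"` reproduces the
#'   original study's precaution of mapping with the highest (2011) year
#'   intercept.
#' @return A `damage_model`.
#' @export
original_model <- function(year_intercepts = c("2011" = 0, "2012" = 0,
                                               "2013" = 0),
                           year_mode = c("population", "conservative")) {
  damage_model(
    intercept = -0.09,
    coefficients = c(source_habitat = 40.05, soybean = 52.7, paddy = -1.12),
    random_intercepts = list(year = year_intercepts),
    year_mode = match.arg(year_mode)
  )
}

#' The extended prediction equation (three-region study)
#'
#' `y = 0.03 + 32.07 * source_habitat + 44.5 * soybean + 2.6 * paddy +
#' RI_region&year`, where the random part is the sum of a region intercept
#' and a year-within-region intercept. Intercept values are unpublished and
#' default to zero (population-level prediction, as used for hazard maps).
#'
#' @param precise Use the higher-precision coefficient table values
#'   (44.52, 2.61) instead of the printed equation's 44.5 and 2.6.
#' @param region_intercepts,region_year_intercepts Optional named numeric
#'   vectors of stored random-intercept values (region-year labels are
#'   `"region:year"`).
#' @return A `damage_model`.
#' @export
extended_model <- function(precise = FALSE,
                           region_intercepts = c(Maesawa = 0, Otomo = 0,
                                                 Semine = 0),
                           region_year_intercepts = NULL) {
  if (is.null(region_year_intercepts)) {
    labs <- c(paste0("Maesawa:", 2011:2013), paste0("Otomo:", c(2018, 2020)),
              paste0("Semine:", 2016:2018))
    region_year_intercepts <- stats::setNames(rep(0, length(labs)), labs)
  }
  damage_model(
    intercept = 0.03,
    coefficients = c(source_habitat = 32.07,
                     soybean = if (precise) 44.52 else 44.5,
                     paddy = if (precise) 2.61 else 2.6),
    random_intercepts = list(region = region_intercepts,
                             region_year = region_year_intercepts)
  )
}

# resolve a covariate name to a column of `data`: exact match or `<name>_km2`
resolve_covariate <- function(data, nm) {
  if (nm %in% names(data)) return(data[[nm]])
  alt <- paste0(nm, "_km2")
  if (alt %in% names(data)) return(data[[alt]])
  stop("covariate '", nm, "' not found in feature data")
}

lookup_ri <- function(map, labels, strict, level) {
  v <- map[as.character(labels)]
  if (anyNA(v)) {
    if (strict) {
      stop("unknown ", level, " label: ",
           as.character(labels)[which(is.na(v))[1L]])
    }
    v[is.na(v)] <- 0
  }
  unname(v)
}

#' Predict arcsine-scale damage from land-use features
#'
#' Computes the linear predictor of a [damage_model()] over a feature table.
#' Random-intercept labels that are not supplied contribute zero, i.e. the
#' default is the population-level prediction used for hazard mapping.
#'
#' @param object A `damage_model`.
#' @param newdata Data frame with one column per model covariate (either the
#'   covariate name itself or `<name>_km2`), areas in km2.
#' @param region,year Optional label vectors (length 1 or `nrow(newdata)`)
#'   activating stored random intercepts.
#' @param strict Error on unknown labels instead of treating them as 0.
#' @param ... Unused.
#' @return Numeric vector of arcsine-degree predictions.
#' @export
predict.damage_model <- function(object, newdata, region = NULL, year = NULL,
                                 strict = FALSE, ...) {
  eta <- rep(object$intercept, nrow(newdata))
  for (nm in names(object$coefficients)) {
    eta <- eta + object$coefficients[[nm]] * resolve_covariate(newdata, nm)
  }
  ri <- object$random_intercepts
  if (!is.null(region) && !is.null(ri$region)) {
    eta <- eta + lookup_ri(ri$region, region, strict, "region")
  }
  if (!is.null(year) && !is.null(ri$year)) {
    eta <- eta + lookup_ri(ri$year, year, strict, "year")
  } else if (is.null(year) && !is.null(ri$year) &&
             object$year_mode == "conservative" && length(ri$year)) {
    eta <- eta + max(ri$year)
  }
  if (!is.null(region) && !is.null(year) && !is.null(ri$region_year)) {
    eta <- eta + lookup_ri(ri$region_year, paste(region, year, sep = ":"),
                           strict, "region-year")
  }
  eta
}

#' Serialize a damage model to JSON
#'
#' All constants are written at full precision so a model file round trips
#' exactly.
#'
#' @param model A `damage_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(
    list(intercept = model$intercept,
         coefficients = as.list(model$coefficients),
         random_intercepts = lapply(model$random_intercepts, as.list),
         variance_components = as.list(model$variance_components),
         residual_sd = model$residual_sd,
         year_mode = model$year_mode),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' Read a damage model from JSON
#'
#' @param path Path written by [write_model()].
#' @return A `damage_model`.
#' @export
read_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  damage_model(
    intercept = j$intercept,
    coefficients = unlist(j$coefficients),
    random_intercepts = lapply(j$random_intercepts, unlist),
    variance_components = if (length(j$variance_components)) {
      unlist(j$variance_components)
    } else numeric(),
    residual_sd = if (is.null(j$residual_sd)) NA_real_ else j$residual_sd,
    year_mode = j$year_mode
  )
}
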