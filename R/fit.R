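#' Fit a random-intercept linear mixed model for arcsine damage
#'
#' REML (default) estimation of the damage model on a joined
#' observation-feature table, with either the extended random structure
#' (region intercepts plus year-within-region intercepts) or the original
#' one (year intercepts only). Fitting is delegated to [lme4::lmer()];
#' fixed effects, BLUPs, variance components and Nakagawa-Schielzeth R2
#' values are extracted into a [damage_model()] plus fit summaries.
#'
#' @param data Data frame holding the response column plus the covariate
#'   columns (either plain covariate names or `<name>_km2`), `region` and
#'   `year`.
#' @param fixed_terms Character vector of covariate names.
#' @param random_spec `c("region", "year_in_region")` (extended structure)
#'   or `"year"` (original structure).
#' @param reml Use REML (TRUE, estimation) or ML (FALSE, used for AICc
#'   comparison across fixed-effect sets).
#' @param response Name of the response column (arcsine degrees).
#' @return Object of class `damage_fit`: `model` (a `damage_model`),
#'   `std_errors`, `log_reml`, `aic`, `aicc`, `n_obs`, `k_params`, `vif`,
#'   `r2_marginal`, `r2_conditional`, and the underlying `lme4` fit.
#' @export
fit_lmm <- function(data, fixed_terms = c("source_habitat", "soybean", "paddy"),
                    random_spec = c("region", "year_in_region"),
                    reml = TRUE, response = "arcsine_damage") {
  random_spec <- match.arg(random_spec,
                           c("region", "year_in_region", "year"),
                           several.ok = TRUE)
  if (!response %in% names(data)) stop("missing response column: ", response)
  n <- nrow(data)
  df <- data.frame(.y = data[[response]])
  for (nm in fixed_terms) df[[nm]] <- resolve_covariate(data, nm)

  # rank check on the fixed design before handing off to lme4
  X <- as.matrix(cbind(1, df[fixed_terms]))
  colnames(X) <- c("(Intercept)", fixed_terms)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("singular fixed-effect design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }

  re_terms <- character()
  if ("region" %in% random_spec) {
    df$region <- factor(data$region)
    if (nlevels(df$region) < 2L) stop("need >= 2 region labels")
    re_terms <- c(re_terms, "(1 | region)")
  }
  if ("year_in_region" %in% random_spec) {
    df$region_year <- factor(paste(data$region, data$year, sep = ":"))
    if (nlevels(df$region_year) < 2L) stop("need >= 2 region-year labels")
    re_terms <- c(re_terms, "(1 | region_year)")
  }
  if ("year" %in% random_spec) {
    df$year <- factor(data$year)
    if (nlevels(df$year) < 2L) stop("need >= 2 year labels")
    re_terms <- c(re_terms, "(1 | year)")
  }
  if (!length(re_terms)) stop("random_spec selected no random terms")

  k <- ncol(X) + length(re_terms) + 1L  # fixed + variance components + resid
  if (n <= k + 1L) stop("too few observations (n = ", n, ") for k = ", k)

  form <- stats::as.formula(paste(".y ~", paste(fixed_terms, collapse = " + "),
                                  "+", paste(re_terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
  )
  fit <- tryCatch(
    suppressMessages(lme4::lmer(form, data = df, REML = reml, control = ctrl)),
    error = function(e) stop("mixed-model fit failed: ", conditionMessage(e))
  )

  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  re_vc <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                           vc$grp[vc$grp != "Residual"])
  ll <- as.numeric(stats::logLik(fit))
  aic <- -2 * ll + 2 * k
  aicc <- aic + 2 * k * (k + 1) / (n - k - 1)

  ran <- lme4::ranef(fit)
  ri <- list()
  if ("region" %in% names(ran)) {
    ri$region <- stats::setNames(ran$region[[1L]], rownames(ran$region))
  }
  if ("region_year" %in% names(ran)) {
    ri$region_year <- stats::setNames(ran$region_year[[1L]],
                                      rownames(ran$region_year))
  }
  if ("year" %in% names(ran)) {
    ri$year <- stats::setNames(ran$year[[1L]], rownames(ran$year))
  }

  var_fixed <- stats::var(as.vector(X %*% beta))
  denom <- var_fixed + sum(re_vc) + sigma2
  r2m <- if (denom > 0) var_fixed / denom else NA_real_
  r2c <- if (denom > 0) (var_fixed + sum(re_vc)) / denom else NA_real_

  vifs <- if (length(fixed_terms) >= 2L) {
    tryCatch(vif(df, fixed_terms), error = function(e) NULL)
  } else NULL

  model <- damage_model(
    intercept = unname(beta[1L]),
    coefficients = beta[-1L],
    random_intercepts = ri,
    variance_components = re_vc,
    residual_sd = sqrt(sigma2)
  )
  structure(
    list(model = model, fit = fit, std_errors = se, log_reml = ll,
         reml = reml, aic = aic, aicc = aicc, n_obs = n, k_params = k,
         vif = vifs, r2_marginal = r2m, r2_conditional = r2c,
         fixed_terms = fixed_terms, random_spec = random_spec),
    class = "damage_fit"
  )
}

#' @export
print.damage_fit <- function(x, ...) {
  cat("<damage_fit> n =", x$n_obs, if (x$reml) "(REML)" else "(ML)",
      " logLik =", format(x$log_reml), " AICc =", format(x$aicc), "\n")
  print(x$model)
  invisible(x)
}

#' Rank candidate fixed-effect sets by AICc
#'
#' Refits each candidate covariate set with maximum likelihood (REML
#' likelihoods are not comparable across fixed-effect sets), computes the
#' small-sample corrected AICc, Akaike weights, and flags near-ties
#' (delta AICc < 2). Candidates too large for the sample size are flagged
#' invalid rather than dropped.
#'
#' @param candidate_sets List of character vectors of covariate names; an
#'   empty vector denotes the intercept-only model.
#' @param data As in [fit_lmm()].
#' @param random_spec,response As in [fit_lmm()].
#' @return Tibble sorted by AICc with columns `terms`, `k`, `aic`, `aicc`,
#'   `delta_aicc`, `weight`, `tied`, `invalid` and a list column `fit`.
#' @export
rank_models <- function(candidate_sets, data,
                        random_spec = c("region", "year_in_region"),
                        response = "arcsine_damage") {
  if (length(candidate_sets) < 2L) stop("need >= 2 candidate sets")
  rows <- lapply(candidate_sets, function(terms) {
    if (length(terms) == 0L) terms <- character()
    res <- tryCatch({
      f <- if (length(terms)) {
        fit_lmm(data, fixed_terms = terms, random_spec = random_spec,
                reml = FALSE, response = response)
      } else {
        fit_intercept_only(data, random_spec, response)
      }
      list(fit = f, invalid = FALSE, msg = NA_character_)
    }, error = function(e) list(fit = NULL, invalid = TRUE,
                                msg = conditionMessage(e)))
    tibble::tibble(
      terms = paste(if (length(terms)) terms else "(intercept)",
                    collapse = "+"),
      k = if (res$invalid) NA_integer_ else res$fit$k_params,
      aic = if (res$invalid) NA_real_ else res$fit$aic,
      aicc = if (res$invalid) NA_real_ else res$fit$aicc,
      invalid = res$invalid,
      note = res$msg,
      fit = list(res$fit)
    )
  })
  out <- dplyr::bind_rows(rows)
  out <- out[order(out$aicc), ]
  valid <- !out$invalid
  out$delta_aicc <- NA_real_
  out$weight <- NA_real_
  if (any(valid)) {
    out$delta_aicc <- out$aicc - min(out$aicc[valid])
    w <- exp(-out$delta_aicc[valid] / 2)
    out$weight[valid] <- w / sum(w)
  }
  out$tied <- !out$invalid & !is.na(out$delta_aicc) & out$delta_aicc < 2
  out
}

# intercept-only mixed model, same accounting as fit_lmm
fit_intercept_only <- function(data, random_spec, response) {
  n <- nrow(data)
  df <- data.frame(.y = data[[response]])
  re_terms <- character()
  if ("region" %in% random_spec) {
    df$region <- factor(data$region)
    re_terms <- c(re_terms, "(1 | region)")
  }
  if ("year_in_region" %in% random_spec) {
    df$region_year <- factor(paste(data$region, data$year, sep = ":"))
    re_terms <- c(re_terms, "(1 | region_year)")
  }
  if ("year" %in% random_spec) {
    df$year <- factor(data$year)
    re_terms <- c(re_terms, "(1 | year)")
  }
  k <- 1L + length(re_terms) + 1L
  if (n <= k + 1L) stop("too few observations for intercept-only model")
  form <- stats::as.formula(paste(".y ~ 1 +", paste(re_terms, collapse = " + ")))
  ctrl <- lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4)
  )
  fit <- suppressMessages(lme4::lmer(form, data = df, REML = FALSE,
                                     control = ctrl))
  ll <- as.numeric(stats::logLik(fit))
  aic <- -2 * ll + 2 * k
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma2 <- vc$vcov[vc$grp == "Residual"]
  re_vc <- stats::setNames(vc$vcov[vc$grp != "Residual"],
                           vc$grp[vc$grp != "Residual"])
  model <- damage_model(
    intercept = unname(lme4::fixef(fit)[1L]),
    coefficients = stats::setNames(numeric(0), character(0)),
    variance_components = re_vc,
    residual_sd = sqrt(sigma2)
  )
  structure(
    list(model = model, fit = fit,
         std_errors = sqrt(diag(as.matrix(stats::vcov(fit)))),
         log_reml = ll, reml = FALSE, aic = aic,
         aicc = aic + 2 * k * (k + 1) / (n - k - 1),
         n_obs = n, k_params = k, vif = NULL,
         r2_marginal = 0, r2_conditional = sum(re_vc) / (sum(re_vc) + sigma2),
         fixed_terms = character(), random_spec = random_spec),
    class = "damage_fit"
  )
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R2_j)` where `R2_j` is from regressing covariate `j`
#' on the remaining covariates. Perfectly collinear covariates are reported
#' as `Inf` with a collinearity flag (attribute `"collinear"`).
#'
#' @param features Data frame holding the covariate columns.
#' @param covariates Character vector (>= 2) of covariate names.
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(features, covariates) {
  if (length(covariates) < 2L) stop("need >= 2 covariates")
  M <- sapply(covariates, function(nm) resolve_covariate(features, nm))
  if (any(apply(M, 2L, stats::sd) == 0)) {
    stop("constant covariate column: ",
         covariates[which(apply(M, 2L, stats::sd) == 0)[1L]])
  }
  out <- stats::setNames(numeric(length(covariates)), covariates)
  for (j in seq_along(covariates)) {
    r2 <- suppressWarnings(
      summary(stats::lm(M[, j] ~ M[, -j, drop = FALSE]))$r.squared
    )
    out[j] <- if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }
  attr(out, "collinear") <- names(out)[!is.finite(out)]
  out
}

#' Marginal and conditional R-squared of a mixed-model fit
#'
#' Nakagawa-Schielzeth decomposition: the marginal R2 is the variance of
#' the fixed linear predictor over the total (fixed + random + residual)
#' variance; the conditional R2 additionally credits the random-intercept
#' variances.
#'
#' @param fit A `damage_fit` from [fit_lmm()].
#' @return Named numeric `c(marginal, conditional)`.
#' @export
r_squared <- function(fit) {
  stopifnot(inherits(fit, "damage_fit"))
  X <- stats::model.matrix(fit$fit)
  var_fixed <- stats::var(as.vector(X %*% lme4::fixef(fit$fit)))
  re_vc <- fit$model$variance_components
  sigma2 <- fit$model$residual_sd^2
  denom <- var_fixed + sum(re_vc) + sigma2
  if (denom <= 0) stop("zero total variance")
  c(marginal = var_fixed / denom,
    conditional = (var_fixed + sum(re_vc)) / denom)
}
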