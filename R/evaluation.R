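#' Japanese brown-rice grade thresholds
#'
#' Percent pecky rice defining the regulatory grades: first <= 0.1%,
#' 0.1% < second <= 0.3%, 0.3% < third <= 0.7%, substandard above 0.7%.
#' Boundaries are inclusive on the lower (better) grade.
#'
#' @param first_max,second_max,third_max Upper bounds (percent) of the
#'   first, second and third grades.
#' @return Object of class `grade_thresholds`.
#' @export
grade_thresholds <- function(first_max = 0.1, second_max = 0.3,
                             third_max = 0.7) {
  if (!(first_max < second_max && second_max < third_max)) {
    stop("grade thresholds must be strictly increasing")
  }
  structure(list(first_max = first_max, second_max = second_max,
                 third_max = third_max), class = "grade_thresholds")
}

#' Classify percent damage into brown-rice grades
#'
#' @param pct Nonnegative percent damage.
#' @param thresholds A [grade_thresholds()].
#' @return Factor with levels `first`, `second`, `third`, `substandard`.
#' @export
classify_grade <- function(pct, thresholds = grade_thresholds()) {
  if (any(!is.finite(pct)) || any(pct < 0)) stop("pct must be nonnegative")
  cut(pct,
      breaks = c(-Inf, thresholds$first_max, thresholds$second_max,
                 thresholds$third_max, Inf),
      labels = c("first", "second", "third", "substandard"),
      right = TRUE)
}

#' Confusion statistics at the first-grade boundary
#'
#' Binarizes observed and predicted percent damage at the first-grade
#' threshold (positive = damage exceeds it, i.e. the field fails first
#' grade) and tabulates counts and rates. Rates with an empty denominator
#' are returned as `NA` and named in `$undefined` instead of being
#' silently zero-filled.
#'
#' @param observed_pct,predicted_pct Equal-length percent vectors.
#' @param threshold Positive-class boundary in percent (default 0.1).
#' @return List of class `confusion_stats`: `tp`, `fp`, `tn`, `fn`, `n`,
#'   `accuracy`, `sensitivity`, `specificity`, `ppv`, `npv`, `undefined`.
#' @export
confusion <- function(observed_pct, predicted_pct, threshold = 0.1) {
  if (length(observed_pct) != length(predicted_pct)) {
    stop("observed and predicted vectors differ in length")
  }
  obs <- observed_pct > threshold
  pred <- predicted_pct > threshold
  tp <- sum(obs & pred)
  fp <- sum(!obs & pred)
  tn <- sum(!obs & !pred)
  fn <- sum(obs & !pred)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    tp = tp, fp = fp, tn = tn, fn = fn, n = length(obs),
    accuracy = rate(tp + tn, length(obs)),
    sensitivity = rate(tp, tp + fn),
    specificity = rate(tn, tn + fp),
    ppv = rate(tp, tp + fp),
    npv = rate(tn, tn + fn)
  )
  out$undefined <- names(which(vapply(
    out[c("accuracy", "sensitivity", "specificity", "ppv", "npv")],
    is.na, logical(1))))
  class(out) <- "confusion_stats"
  out
}

#' @export
print.confusion_stats <- function(x, ...) {
  cat(sprintf("<confusion_stats> n=%d tp=%d fp=%d tn=%d fn=%d\n",
              x$n, x$tp, x$fp, x$tn, x$fn))
  cat(sprintf("  accuracy=%.3f sens=%.3f spec=%.3f ppv=%.3f npv=%.3f\n",
              x$accuracy, x$sensitivity, x$specificity, x$ppv, x$npv))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC is the Mann-Whitney concordance probability with ties counted one
#' half (midranks); the returned curve integrates to the same value by the
#' trapezoidal rule.
#'
#' @param observed_binary Logical (or 0/1) vector; both classes must be
#'   present.
#' @param scores Numeric scores, larger = more positive.
#' @return List of class `roc_curve`: `thresholds` (descending),
#'   `tpr`, `fpr`, `auc`.
#' @export
roc_auc <- function(observed_binary, scores) {
  obs <- as.logical(observed_binary)
  if (length(obs) != length(scores)) stop("length mismatch")
  n1 <- sum(obs)
  n0 <- sum(!obs)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks
  auc <- (sum(r[obs]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  ths <- sort(unique(scores), decreasing = TRUE)
  tp <- vapply(ths, function(t) sum(obs & scores >= t), numeric(1))
  fp <- vapply(ths, function(t) sum(!obs & scores >= t), numeric(1))
  tpr <- c(0, tp / n1)
  fpr <- c(0, fp / n0)
  structure(list(thresholds = c(Inf, ths), tpr = tpr, fpr = fpr, auc = auc),
            class = "roc_curve")
}

#' Observed-versus-predicted comparison
#'
#' Post hoc mixed-model regression of observed on predicted arcsine-scale
#' damage with region and year-within-region random intercepts, reporting
#' the conditional R2, the RMSE of the raw differences, and a Wald
#' chi-square test of the slope.
#'
#' @param observed,predicted Arcsine-scale vectors (length n >= 3).
#' @param region,year Grouping labels per observation.
#' @return List: `r2_conditional`, `r2_marginal`, `rmse`, `slope`,
#'   `slope_se`, `wald_chisq`, `p_value`, and the underlying `damage_fit`.
#' @export
obs_vs_pred <- function(observed, predicted, region, year) {
  n <- length(observed)
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(predicted) == 0) stop("constant predictions")
  rmse <- sqrt(mean((observed - predicted)^2))
  # exact linear relation: the mixed model is degenerate (zero residual
  # variance); report the closed-form limit instead of forcing REML
  ols <- stats::lm(observed ~ predicted)
  if (suppressWarnings(summary(ols)$sigma) < 1e-10) {
    return(list(r2_conditional = 1, r2_marginal = 1, rmse = rmse,
                slope = unname(stats::coef(ols)[2L]), slope_se = 0,
                wald_chisq = Inf, p_value = 0, fit = NULL))
  }
  dat <- tibble::tibble(arcsine_damage = observed, predicted = predicted,
                        region = region, year = year)
  fit <- fit_lmm(dat, fixed_terms = "predicted",
                 random_spec = c("region", "year_in_region"))
  slope <- fit$model$coefficients[["predicted"]]
  se <- fit$std_errors[["predicted"]]
  wald <- (slope / se)^2
  list(
    r2_conditional = fit$r2_conditional,
    r2_marginal = fit$r2_marginal,
    rmse = rmse,
    slope = slope,
    slope_se = se,
    wald_chisq = wald,
    p_value = stats::pchisq(wald, df = 1, lower.tail = FALSE),
    fit = fit
  )
}

#' K-fold cross-validation of the damage model
#'
#' Refits the mixed model on the training folds and scores the held-out
#' fold with population-level predictions (no random-intercept labels, the
#' "unknown data" setting). Per-fold metrics are the squared Pearson
#' correlation between observed and predicted arcsine damage and the AUC
#' for failing first grade; folds where a metric is undefined (single
#' class, too few rows) carry `NA`.
#'
#' @param data Joined observation-feature table (needs `arcsine_damage`,
#'   `pct_damage`, covariates, `region`, `year`).
#' @param k Number of folds (>= 2); under `by_region` the folds are the
#'   regions and `k` is overridden by their count.
#' @param fold_rule `"by_region"` (hold out one region at a time) or
#'   `"stratified"` (random folds stratified on the positive class).
#' @param seed Integer seed (stratified folds only).
#' @param fixed_terms,random_spec Passed to [fit_lmm()] on each training
#'   set.
#' @param threshold Positive-class boundary in percent.
#' @return List of class `cv_result`: per-fold tibble `folds` plus
#'   `r2_mean`, `r2_sd`, `auc_mean`, `auc_sd`.
#' @export
cross_validate <- function(data, k = 3, fold_rule = c("by_region", "stratified"),
                           seed = 1L,
                           fixed_terms = c("source_habitat", "soybean", "paddy"),
                           random_spec = c("region", "year_in_region"),
                           threshold = 0.1) {
  fold_rule <- match.arg(fold_rule)
  n <- nrow(data)
  if (fold_rule == "by_region") {
    regions <- sort(unique(data$region))
    if (length(regions) < 2L) stop("by_region folds need >= 2 regions")
    k <- length(regions)
    fold_id <- match(data$region, regions)
  } else {
    if (k < 2L) stop("k must be >= 2")
    withr::local_seed(seed)
    pos <- data$pct_damage > threshold
    fold_id <- integer(n)
    for (cls in unique(pos)) {
      idx <- which(pos == cls)
      idx <- idx[sample.int(length(idx))]
      fold_id[idx] <- rep_len(seq_len(k), length(idx))
    }
  }
  rows <- lapply(seq_len(k), function(f) {
    test <- data[fold_id == f, ]
    train <- data[fold_id != f, ]
    fit <- fit_lmm(train, fixed_terms = fixed_terms,
                   random_spec = random_spec)
    pred <- stats::predict(fit$model, test)
    r2 <- if (nrow(test) >= 3L && stats::sd(pred) > 0 &&
              stats::sd(test$arcsine_damage) > 0) {
      stats::cor(test$arcsine_damage, pred)^2
    } else NA_real_
    obs_pos <- test$pct_damage > threshold
    auc <- if (length(unique(obs_pos)) == 2L) {
      roc_auc(obs_pos, pred)$auc
    } else NA_real_
    tibble::tibble(fold = f, n_test = nrow(test), r2 = r2, auc = auc)
  })
  folds <- dplyr::bind_rows(rows)
  structure(
    list(folds = folds, fold_rule = fold_rule, k = k, seed = seed,
         r2_mean = mean(folds$r2, na.rm = TRUE),
         r2_sd = stats::sd(folds$r2[!is.na(folds$r2)]),
         auc_mean = mean(folds$auc, na.rm = TRUE),
         auc_sd = stats::sd(folds$auc[!is.na(folds$auc)])),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %d folds (%s): R2 %.3f +/- %.3f, AUC %.3f +/- %.3f\n",
              x$k, x$fold_rule, x$r2_mean, x$r2_sd, x$auc_mean, x$auc_sd))
  invisible(x)
}
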