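make_lmm_data <- function(n = 24, seed = 11, sd_u = 0.4, sd_w = 0.5,
                          sd_e = 0.6, beta = c(1, 2)) {
  set.seed(seed)
  region <- rep(c("A", "B", "C"), length.out = n)
  year <- rep(rep(2001:2002, each = 3), length.out = n)
  x <- runif(n)
  ry <- paste(region, year, sep = ":")
  u <- setNames(rnorm(3, 0, sd_u), c("A", "B", "C"))
  w <- setNames(rnorm(length(unique(ry)), 0, sd_w), unique(ry))
  y <- beta[1] + beta[2] * x + u[region] + w[ry] + rnorm(n, 0, sd_e)
  tibble::tibble(arcsine_damage = unname(y), source_habitat = x,
                 region = region, year = year)
}

test_that("zero-variance truth reduces REML fixed effects to OLS", {
  set.seed(21)
  n <- 40
  dat <- tibble::tibble(
    region = rep(c("A", "B", "C", "D"), each = 10),
    year = rep(rep(2001:2002, each = 5), 4),
    source_habitat = runif(n),
    soybean = runif(n)
  )
  e <- rnorm(n, 0, 0.3)
  e <- unname(resid(lm(e ~ factor(paste(dat$region, dat$year)))))
  dat$arcsine_damage <- 0.5 + 3 * dat$source_habitat - 1 * dat$soybean + e
  fit <- fit_lmm(dat, fixed_terms = c("source_habitat", "soybean"))
  ols <- lm(arcsine_damage ~ source_habitat + soybean, dat)
  expect_equal(unname(c(fit$model$intercept, fit$model$coefficients)),
               unname(coef(ols)), tolerance = 1e-4)
})

test_that("REML estimates are permutation invariant and GLS-consistent", {
  dat <- make_lmm_data()
  fit <- fit_lmm(dat, fixed_terms = "source_habitat")
  perm <- dat[sample(nrow(dat)), ]
  fit2 <- fit_lmm(perm, fixed_terms = "source_habitat")
  expect_equal(fit$model$coefficients, fit2$model$coefficients,
               tolerance = 1e-8)
  expect_equal(fit$log_reml, fit2$log_reml, tolerance = 1e-8)

  # with variance components frozen at their estimates, the fixed effects
  # must solve the GLS normal equations
  n <- nrow(dat)
  X <- cbind(1, dat$source_habitat)
  Zu <- model.matrix(~ 0 + factor(dat$region))
  Zw <- model.matrix(~ 0 + factor(paste(dat$region, dat$year, sep = ":")))
  vc <- fit$model$variance_components
  V <- fit$model$residual_sd^2 * diag(n) +
    vc[["region"]] * tcrossprod(Zu) + vc[["region_year"]] * tcrossprod(Zw)
  Vi <- solve(V)
  beta_gls <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% dat$arcsine_damage)
  expect_equal(unname(c(fit$model$intercept, fit$model$coefficients)),
               as.numeric(beta_gls), tolerance = 1e-6)
})

test_that("fit matches the nlme implementation on the same data", {
  skip_if_not_installed("nlme")
  dat <- make_lmm_data(n = 30, seed = 5)
  fit <- fit_lmm(dat, fixed_terms = "source_habitat")
  nl <- nlme::lme(arcsine_damage ~ source_habitat,
                  random = ~ 1 | region / year,
                  data = as.data.frame(dat), method = "REML")
  expect_equal(unname(c(fit$model$intercept, fit$model$coefficients)),
               unname(nlme::fixef(nl)), tolerance = 1e-4)
  expect_equal(fit$log_reml, as.numeric(logLik(nl)), tolerance = 1e-4)
})

test_that("singular designs are rejected with the collinear columns named", {
  dat <- make_lmm_data()
  dat$copy <- dat$source_habitat
  expect_error(fit_lmm(dat, fixed_terms = c("source_habitat", "copy")),
               "collinear.*copy")
})

test_that("AICc ranking normalizes weights and flags invalid candidates", {
  dat <- make_lmm_data(n = 30, seed = 8)
  rk <- rank_models(list("source_habitat", "source_habitat"), dat)
  expect_equal(rk$aicc[1], rk$aicc[2])
  expect_equal(rk$weight, c(0.5, 0.5))
  expect_true(all(rk$tied))

  rk2 <- rank_models(list("source_habitat", character(0)), dat)
  expect_equal(sum(rk2$weight), 1)
  expect_true(all(rk2$aicc >= rk2$aic, na.rm = TRUE))

  tiny <- make_lmm_data(n = 6, seed = 3)
  rk3 <- rank_models(list("source_habitat", character(0)), tiny)
  expect_true(any(rk3$invalid))
  expect_equal(nrow(rk3), 2)  # flagged, not dropped
})

test_that("VIF matches its closed form and flags exact collinearity", {
  set.seed(99)
  n <- 200
  a <- rnorm(n)
  b_orth <- rnorm(n)
  b_orth <- residuals(lm(b_orth ~ a))  # numerically orthogonal
  feats <- tibble::tibble(a = a, b = b_orth + mean(a) * 0)
  v <- vif(feats, c("a", "b"))
  expect_equal(as.numeric(v), c(1, 1), tolerance = 1e-9)

  rho <- 0.8
  c2 <- rho * scale(a)[, 1] + sqrt(1 - rho^2) * scale(b_orth)[, 1]
  feats2 <- tibble::tibble(a = a, c = c2)
  r2 <- cor(feats2$a, feats2$c)^2
  v2 <- vif(feats2, c("a", "c"))
  expect_equal(as.numeric(v2), rep(1 / (1 - r2), 2), tolerance = 1e-9)

  feats3 <- tibble::tibble(a = a, dup = a)
  v3 <- vif(feats3, c("a", "dup"))
  expect_true(all(!is.finite(v3)))
  expect_setequal(attr(v3, "collinear"), c("a", "dup"))

  expect_error(vif(tibble::tibble(a = a, k = 1), c("a", "k")), "constant")
  expect_error(vif(feats, "a"), ">= 2 covariates")
})

test_that("R-squared decomposition matches a direct recomputation", {
  dat <- make_lmm_data(n = 36, seed = 13)
  fit <- fit_lmm(dat, fixed_terms = "source_habitat")
  r2 <- r_squared(fit)
  # independent recomputation from the lme4 components
  m <- fit$fit
  vf <- var(as.vector(model.matrix(m) %*% lme4::fixef(m)))
  vcdf <- as.data.frame(lme4::VarCorr(m))
  vr <- sum(vcdf$vcov[vcdf$grp != "Residual"])
  ve <- vcdf$vcov[vcdf$grp == "Residual"]
  expect_equal(unname(r2["marginal"]), vf / (vf + vr + ve), tolerance = 1e-12)
  expect_equal(unname(r2["conditional"]), (vf + vr) / (vf + vr + ve),
               tolerance = 1e-12)
  expect_lte(r2[["marginal"]], r2[["conditional"]])
  expect_equal(r2[["marginal"]], fit$r2_marginal, tolerance = 1e-12)

  # near-noiseless linear data drives both toward 1
  clean <- dat
  clean$arcsine_damage <- 1 + 2 * clean$source_habitat +
    rnorm(nrow(clean), 0, 1e-4)
  fitc <- fit_lmm(clean, fixed_terms = "source_habitat")
  expect_gt(r_squared(fitc)[["marginal"]], 0.999)

  # intercept-only candidates have zero marginal R2
  rk <- rank_models(list("source_habitat", character(0)), dat)
  int_fit <- rk$fit[[which(rk$terms == "(intercept)")]]
  expect_equal(int_fit$r2_marginal, 0)
})
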