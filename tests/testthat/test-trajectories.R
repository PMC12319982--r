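test_that("a noiseless linear model is recovered to near machine precision", {
  truth <- longitudinal_truth(
    beta = c(intercept = 70, age = -0.8, nonlinear = 0, sex = 1.5, segments = 0.02),
    sigma_u = 0, sigma_e = 1e-6, n_subjects = 40L, missingness = 0
  )
  sim <- simulate_longitudinal_features(truth, "linear", seed = 2)
  expect_warning(fit <- fit_random_intercept_lmm(sim$features, "linear"),
                 "boundary")
  est <- setNames(fit$beta$estimate, fit$beta$term)
  expect_equal(est[["(Intercept)"]], 70, tolerance = 1e-4)
  expect_equal(est[["age_months"]], -0.8, tolerance = 1e-6)
  expect_equal(est[["sex"]], 1.5, tolerance = 1e-5)
  expect_equal(est[["retained_segments"]], 0.02, tolerance = 1e-6)
  expect_lt(fit$sigma_e2, 1e-6)
})

test_that("the ML log-likelihood equals the block-covariance MVN density", {
  truth <- longitudinal_truth(
    beta = c(intercept = 60, age = 0.3, nonlinear = 0, sex = 1, segments = 0),
    sigma_u = 3, sigma_e = 2, n_subjects = 3L, missingness = 0,
    visit_age_mean = c(4, 9), visit_age_sd = c(0.5, 0.5)
  )
  sim <- simulate_longitudinal_features(truth, "linear", seed = 6)
  fit <- suppressWarnings(fit_random_intercept_lmm(sim$features, "linear"))
  oracle <- lmm_loglik_oracle(
    sim$features, setNames(fit$beta$estimate, fit$beta$term),
    fit$sigma_u2, fit$sigma_e2,
    ~ age_months + sex + retained_segments
  )
  expect_lt(abs(fit$loglik - oracle), 1e-8)
  # BIC identity
  expect_equal(fit$bic, -2 * fit$loglik + fit$n_params * log(fit$n_obs),
               tolerance = 1e-10)
})

test_that("coefficients are recovered on average across simulated cohorts", {
  truth <- longitudinal_truth(
    beta = c(intercept = 85, age = -0.5, nonlinear = 0, sex = 1, segments = 0),
    sigma_u = 5, sigma_e = 5, n_subjects = 200L
  )
  est <- vapply(1:30, function(r) {
    sim <- simulate_longitudinal_features(truth, "linear", seed = 400 + r)
    fit <- fit_random_intercept_lmm(sim$features, "linear")
    fit$beta$estimate[fit$beta$term == "age_months"]
  }, numeric(1))
  expect_lt(abs(mean(est) - (-0.5)), 0.05)
})

test_that("richer age models never lose log-likelihood", {
  truth <- longitudinal_truth(n_subjects = 80L)
  sim <- simulate_longitudinal_features(truth, "log", seed = 9)
  fits <- fit_three(sim$features)
  expect_gte(fits$quadratic$loglik, fits$linear$loglik - 1e-8)
  expect_gte(fits$log$loglik, fits$linear$loglik - 1e-8)
})

test_that("one observation per subject degenerates to ordinary least squares", {
  truth <- longitudinal_truth(
    beta = c(intercept = 50, age = 1, nonlinear = 0, sex = 2, segments = 0),
    sigma_u = 0, sigma_e = 3, n_subjects = 150L,
    visit_age_mean = 8, visit_age_sd = 2, missingness = 0
  )
  sim <- simulate_longitudinal_features(truth, "linear", seed = 12)
  fit <- suppressWarnings(fit_random_intercept_lmm(sim$features, "linear"))
  ols <- stats::lm(value ~ age_months + sex + retained_segments,
                   data = sim$features)
  expect_equal(setNames(fit$beta$estimate, fit$beta$term), coef(ols),
               tolerance = 1e-5)
  # only the total variance is identified; it must equal the ML residual
  # variance of the ordinary regression (SSR / n)
  expect_equal(fit$sigma_u2 + fit$sigma_e2,
               sum(stats::residuals(ols)^2) / fit$n_obs, tolerance = 1e-4)
})

test_that("rank-deficient designs fail with the collinear column named", {
  truth <- longitudinal_truth(n_subjects = 20L, p_male = 0)   # sex constant
  sim <- simulate_longitudinal_features(truth, "linear", seed = 3)
  expect_error(fit_random_intercept_lmm(sim$features, "linear"), "sex")
})

test_that("BIC gating retains parsimony and honours the six-point rule", {
  fake <- function(model, bic) {
    structure(list(age_model = model, bic = bic, n_obs = 100L),
              class = "trajectory_fit")
  }
  # all BICs within one point: linear retained
  s1 <- select_age_model(list(linear = fake("linear", 500),
                              quadratic = fake("quadratic", 499.5),
                              log = fake("log", 499.2)))
  expect_equal(s1$age_model[s1$selected], "linear")
  # a gain of exactly six points qualifies
  s2 <- select_age_model(list(linear = fake("linear", 500),
                              quadratic = fake("quadratic", 497),
                              log = fake("log", 494)))
  expect_equal(s2$age_model[s2$selected], "log")
  # both qualify: the lower BIC wins
  s3 <- select_age_model(list(linear = fake("linear", 510),
                              quadratic = fake("quadratic", 502),
                              log = fake("log", 503)))
  expect_equal(s3$age_model[s3$selected], "quadratic")
  # mismatched observation counts are rejected
  bad <- list(linear = fake("linear", 500), quadratic = fake("quadratic", 490),
              log = fake("log", 495))
  bad$log$n_obs <- 99L
  expect_error(select_age_model(bad), "differing")
})

test_that("effect sizes follow the marginal-R2 bookkeeping and thresholds", {
  # strong age effect, null-but-present sex effect
  truth <- longitudinal_truth(
    beta = c(intercept = 85, age = -0.9, nonlinear = 0, sex = 0, segments = 0),
    sigma_u = 3, sigma_e = 3, n_subjects = 250L
  )
  sim <- simulate_longitudinal_features(truth, "linear", seed = 21)
  fit <- fit_random_intercept_lmm(sim$features, "linear")
  es <- effect_sizes(fit)
  f2 <- setNames(es$f2, es$term)
  expect_lt(abs(f2[["sex"]]), 0.01)
  expect_gt(f2[["age_months"]], 0.35)
  expect_equal(as.character(es$magnitude[es$term == "age_months"]), "large")
  # hand bookkeeping for one predictor
  red <- fit_random_intercept_lmm(sim$features, "linear")
  r2_full <- fit$marginal_r2
  red_fit <- lme4::lmer(value ~ sex + retained_segments + (1 | subject),
                        data = sim$features, REML = FALSE)
  X <- stats::model.matrix(~ sex + retained_segments, data = sim$features)
  fitted_fixed <- drop(X %*% lme4::fixef(red_fit))
  vc <- as.data.frame(lme4::VarCorr(red_fit))
  r2_red <- var(fitted_fixed) /
    (var(fitted_fixed) + vc$vcov[vc$grp == "subject"] + vc$vcov[vc$grp == "Residual"])
  expect_equal(f2[["age_months"]], (r2_full - r2_red) / (1 - r2_full),
               tolerance = 1e-8)
})

test_that("tidy, glance and autoplot work on a trajectory fit", {
  truth <- longitudinal_truth(n_subjects = 40L)
  sim <- simulate_longitudinal_features(truth, "log", seed = 30)
  fit <- fit_random_intercept_lmm(sim$features, "log")
  td <- tidy(fit)
  expect_true(all(c("term", "estimate", "std_error", "p_value") %in% names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$bic, fit$bic)
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
  p2 <- plot_prototypes(make_prototype_maps(make_montage(16, 1), 3, 2),
                        make_montage(16, 1))
  expect_s3_class(p2, "ggplot")
})
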