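age_formula <- function(age_model, center_age = FALSE) {
  age <- if (center_age) "I(age_months - mean(age_months))" else "age_months"
  nonlin <- switch(age_model,
    linear = NULL,
    quadratic = if (center_age) "I((age_months - mean(age_months))^2)" else "I(age_months^2)",
    log = "log(age_months)"
  )
  stats::reformulate(
    c(age, nonlin, "sex", "retained_segments", "(1 | subject)"),
    response = "value"
  )
}

#' Fit a random-intercept trajectory model by maximum likelihood
#'
#' Fits `value ~ age (+ age^2 | log(age)) + sex + retained_segments +
#' (1 | subject)` with ML (not REML) so that log-likelihoods and BIC are
#' comparable across the three candidate age models. Fixed-effect inference
#' is Wald-z. BIC is computed as `-2 logLik + n_params log(n_obs)` with
#' `n_params` counting the fixed effects plus the two variance components.
#'
#' @param table A feature tibble holding one response series (one class and
#'   feature); filter with `class`/`feature` if the table holds several.
#' @param age_model `"linear"`, `"quadratic"` or `"log"`.
#' @param class,feature Optional filters applied to `table` first.
#' @param center_age Center age before building the quadratic term (off by
#'   default so coefficients stay on the raw month scale).
#'
#' @return A `trajectory_fit` object; see [tidy.trajectory_fit()] and
#'   [glance.trajectory_fit()].
#' @export
fit_random_intercept_lmm <- function(table,
                                     age_model = c("linear", "quadratic", "log"),
                                     class = NULL, feature = NULL,
                                     center_age = FALSE) {
  age_model <- match.arg(age_model)
  if (!is.null(class)) table <- dplyr::filter(table, .data$class == !!class)
  if (!is.null(feature)) table <- dplyr::filter(table, .data$feature == !!feature)
  if (dplyr::n_distinct(table$class) > 1L || dplyr::n_distinct(table$feature) > 1L) {
    abort("Multiple classes/features in `table`; pass `class` and `feature`.")
  }
  if (dplyr::n_distinct(table$subject) < 2L) {
    abort("At least 2 subjects are required.")
  }
  form <- age_formula(age_model, center_age)
  fixed_form <- lme4::nobars(form)
  X <- stats::model.matrix(fixed_form, data = table)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[setdiff(seq_len(ncol(X)), qrX$pivot[seq_len(qrX$rank)])]
    abort(paste0("Design matrix is rank deficient; collinear columns: ",
                 paste(bad, collapse = ", ")))
  }
  # with a single observation per subject only the total variance is
  # identified; lme4's count check is relaxed so the fit degenerates to OLS
  fit <- lme4::lmer(form, data = table, REML = FALSE,
                    control = lme4::lmerControl(
                      check.nobs.vs.nlev = "ignore",
                      check.nobs.vs.nRE = "ignore"
                    ))
  if (lme4::isSingular(fit, tol = 1e-6)) {
    warn("Random-intercept variance estimated at the boundary (sigma_u^2 = 0).")
  }
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u2 <- vc$vcov[vc$grp == "subject"]
  sigma_e2 <- vc$vcov[vc$grp == "Residual"]
  beta <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(vcov(fit))))
  zval <- beta / se
  pval <- 2 * stats::pnorm(-abs(zval))
  ll <- as.numeric(logLik(fit))
  n_obs <- nrow(table)
  n_params <- length(beta) + 2L
  fitted_fixed <- drop(X %*% beta)
  marg_r2 <- var(fitted_fixed) / (var(fitted_fixed) + sigma_u2 + sigma_e2)
  structure(
    list(
      model = fit, age_model = age_model, center_age = center_age,
      data = table,
      beta = tibble::tibble(term = names(beta), estimate = unname(beta),
                            std_error = unname(se), statistic = unname(zval),
                            p_value = unname(pval)),
      sigma_u2 = sigma_u2, sigma_e2 = sigma_e2,
      loglik = ll, n_obs = n_obs, n_params = n_params,
      bic = -2 * ll + n_params * log(n_obs),
      marginal_r2 = marg_r2
    ),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf(
    "<trajectory_fit> age model: %s | n = %d | logLik = %.2f | BIC = %.2f | marginal R2 = %.3f\n",
    x$age_model, x$n_obs, x$loglik, x$bic, x$marginal_r2
  ))
  print(x$beta)
  invisible(x)
}

#' @describeIn fit_random_intercept_lmm Tidy the fixed-effect table.
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @export
tidy.trajectory_fit <- function(x, ...) x$beta

#' @describeIn fit_random_intercept_lmm One-row model summary.
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble::tibble(
    age_model = x$age_model, n_obs = x$n_obs, n_params = x$n_params,
    loglik = x$loglik, bic = x$bic, sigma_u2 = x$sigma_u2,
    sigma_e2 = x$sigma_e2, marginal_r2 = x$marginal_r2
  )
}

#' Select the age model by BIC
#'
#' Applies the parsimony rule used for developmental trajectories: a
#' nonlinear model (quadratic or log age) is preferred over the linear model
#' only when it improves BIC by at least `delta` points; when both nonlinear
#' models qualify, the one with the lower BIC wins; otherwise the linear
#' model is retained.
#'
#' @param fits Named list with elements `linear`, `quadratic`, `log`, each a
#'   `trajectory_fit` on the identical observations.
#' @param delta BIC improvement required to prefer a nonlinear model
#'   (default 6).
#'
#' @return A tibble with one row per model: `age_model`, `bic`,
#'   `delta_bic_vs_linear` (BIC_linear - BIC_model) and logical `selected`.
#' @export
select_age_model <- function(fits, delta = 6) {
  required <- c("linear", "quadratic", "log")
  if (!all(required %in% names(fits))) {
    abort("`fits` must contain 'linear', 'quadratic' and 'log' models.")
  }
  n_obs <- vapply(fits[required], `[[`, numeric(1), "n_obs")
  if (length(unique(n_obs)) != 1L) {
    abort("The three fits were made on differing numbers of observations.")
  }
  bic <- vapply(fits[required], `[[`, numeric(1), "bic")
  gain <- bic[["linear"]] - bic
  qualifying <- required[-1][gain[-1] >= delta]
  chosen <- if (!length(qualifying)) {
    "linear"
  } else {
    qualifying[which.min(bic[qualifying])]
  }
  tibble::tibble(
    age_model = required, bic = unname(bic),
    delta_bic_vs_linear = unname(gain),
    selected = required == chosen
  )
}

#' Cohen's f-squared and marginal R-squared per predictor
#'
#' Refits the model dropping each fixed-effect predictor in turn (same
#' random-effects structure, same observations, ML throughout) and computes
#' `f2 = (R2_full - R2_reduced) / (1 - R2_full)` on marginal R-squared
#' values, with the conventional small/medium/large labels at 0.02, 0.15
#' and 0.35.
#'
#' @param fit_full A `trajectory_fit`.
#'
#' @return A tibble: `term`, `f2`, `magnitude`, plus the full model's
#'   marginal R-squared as attribute `marginal_r2_full`.
#' @export
effect_sizes <- function(fit_full) {
  stopifnot(inherits(fit_full, "trajectory_fit"))
  r2_full <- fit_full$marginal_r2
  if (r2_full >= 1 - 1e-12) abort("Marginal R^2 is 1; f^2 is degenerate.")
  terms_full <- attr(stats::terms(lme4::nobars(stats::formula(fit_full$model))),
                     "term.labels")
  table <- fit_full$data
  f2 <- vapply(terms_full, function(tm) {
    reduced_terms <- setdiff(terms_full, tm)
    rhs <- c(reduced_terms, "(1 | subject)")
    if (!length(reduced_terms)) rhs <- c("1", "(1 | subject)")
    form <- stats::reformulate(rhs, response = "value")
    red <- lme4::lmer(form, data = table, REML = FALSE)
    beta <- lme4::fixef(red)
    Xr <- stats::model.matrix(lme4::nobars(form), data = table)
    fitted_fixed <- drop(Xr %*% beta)
    vc <- as.data.frame(lme4::VarCorr(red))
    r2_red <- var(fitted_fixed) /
      (var(fitted_fixed) + vc$vcov[vc$grp == "subject"] +
         vc$vcov[vc$grp == "Residual"])
    (r2_full - r2_red) / (1 - r2_full)
  }, numeric(1))
  out <- tibble::tibble(
    term = terms_full,
    f2 = unname(f2),
    magnitude = cut(f2, c(-Inf, 0.02, 0.15, 0.35, Inf),
                    labels = c("negligible", "small", "medium", "large"),
                    right = FALSE)
  )
  attr(out, "marginal_r2_full") <- r2_full
  out
}

#' Plot a fitted developmental trajectory
#'
#' Observed feature values against age with the model-implied population
#' trajectory per sex (segments held at their mean).
#'
#' @param object A `trajectory_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.trajectory_fit <- function(object, ...) {
  table <- object$data
  grid <- tidyr::expand_grid(
    age_months = seq(min(table$age_months), max(table$age_months),
                     length.out = 200),
    sex = sort(unique(table$sex))
  ) |>
    dplyr::mutate(retained_segments = mean(table$retained_segments),
                  subject = NA_character_, value = 0)
  beta <- lme4::fixef(object$model)
  X <- stats::model.matrix(lme4::nobars(stats::formula(object$model)),
                           data = grid)
  grid$value <- drop(X %*% beta)
  ggplot2::ggplot(table, ggplot2::aes(x = .data$age_months, y = .data$value,
                                      colour = factor(.data$sex))) +
    ggplot2::geom_point(alpha = 0.3, size = 0.8) +
    ggplot2::geom_line(data = grid, linewidth = 1) +
    ggplot2::labs(x = "Age (months)", y = "Feature value",
                  colour = "Sex (1 = male)",
                  title = sprintf("Trajectory (%s age model)", object$age_model)) +
    ggplot2::theme_minimal()
}

#' Plot microstate prototype topographies
#'
#' Simple 2-d projection of the montage colored by map value, one facet per
#' prototype. A quick-look rendering, not a full topographic interpolation.
#'
#' @param prototypes A [prototype_set()].
#' @param positions Channels x 3 montage.
#' @return A ggplot object.
#' @export
plot_prototypes <- function(prototypes, positions) {
  stopifnot(inherits(prototypes, "prototype_set"))
  positions <- as.matrix(positions)
  df <- purrr::map_dfr(seq_len(prototypes$K), function(k) {
    tibble::tibble(
      map = paste0("map ", k), x = positions[, 1], y = positions[, 2],
      value = prototypes$maps[k, ]
    )
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_colour_gradient2(low = "blue", mid = "white", high = "red") +
    ggplot2::facet_wrap(~map) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "left-right", y = "posterior-anterior", colour = "a.u.") +
    ggplot2::theme_minimal()
}
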