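#' Ground truth for a simulated longitudinal cohort
#'
#' Bundles the generating parameters of a longitudinal feature table:
#' fixed-effect coefficients, the random-intercept and residual SDs, the
#' per-visit age distributions and missingness, and the retained-segment
#' count distribution. Defaults mirror a four-visit infant cohort: visit ages
#' averaging 3.74, 8.72, 14.1 and 21.5 months (SDs 0.879, 1.49, 1.24, 1.20),
#' roughly one fifth of visits missed, and 16-91 retained two-second
#' segments per recording.
#'
#' @param beta Named fixed effects: `intercept`, `age` (per month), `nonlinear`
#'   (coefficient of the quadratic or log term; ignored for a linear model),
#'   `sex` (female = 0, male = 1), `segments` (per retained segment).
#' @param sigma_u Random-intercept SD (>= 0).
#' @param sigma_e Residual SD (>= 0; zero gives deterministic responses).
#' @param n_subjects Number of subjects.
#' @param visit_age_mean,visit_age_sd Per-visit age means/SDs in months.
#' @param missingness Per-visit probability a subject skips the visit.
#' @param segments_range Inclusive range of retained-segment counts.
#' @param p_male Probability a subject is male.
#'
#' @return A `longitudinal_truth` list.
#' @export
longitudinal_truth <- function(beta = c(intercept = 95, age = 0.36,
                                        nonlinear = -5.9, sex = 1.2,
                                        segments = 0.012),
                               sigma_u = 5, sigma_e = 5, n_subjects = 318L,
                               visit_age_mean = c(3.74, 8.72, 14.1, 21.5),
                               visit_age_sd = c(0.879, 1.49, 1.24, 1.20),
                               missingness = c(0.24, 0.22, 0.18, 0.31),
                               segments_range = c(16L, 91L),
                               p_male = 0.51) {
  stopifnot(sigma_u >= 0, sigma_e >= 0, all(visit_age_mean > 0),
            length(visit_age_mean) == length(visit_age_sd))
  required <- c("intercept", "age", "nonlinear", "sex", "segments")
  if (!all(required %in% names(beta))) {
    abort(paste0("`beta` must name: ", paste(required, collapse = ", ")))
  }
  structure(
    list(
      beta = beta, sigma_u = sigma_u, sigma_e = sigma_e,
      n_subjects = as.integer(n_subjects),
      visit_age_mean = visit_age_mean, visit_age_sd = visit_age_sd,
      missingness = rep_len(missingness, length(visit_age_mean)),
      segments_range = as.integer(segments_range), p_male = p_male
    ),
    class = "longitudinal_truth"
  )
}

#' Simulate a longitudinal microstate feature table
#'
#' Generates observations from the random-intercept model
#' `y_ij = b0 + b1 age_ij + b2 g(age_ij) + b3 sex_i + b4 segments_ij + u_i + e_ij`
#' with `u_i ~ N(0, sigma_u^2)` and `e_ij ~ N(0, sigma_e^2)`, where `g` is
#' `age^2` (quadratic), `log(age)` (log), or absent (linear). Visit ages are
#' drawn per visit from the stated normal distributions (truncated at 0.5
#' months), segment counts uniformly over the stated range, and visits are
#' dropped independently at the per-visit missingness rate (every subject
#' keeps at least one visit).
#'
#' @param truth A [longitudinal_truth()].
#' @param age_model `"linear"`, `"quadratic"` or `"log"`.
#' @param seed Integer seed.
#' @param cohort,class,feature Labels stamped on the output rows.
#'
#' @return List with `features` (a feature tibble; see [persist_features()])
#'   and `intercepts` (per-subject `u_i`).
#' @export
simulate_longitudinal_features <- function(truth,
                                           age_model = c("linear", "quadratic", "log"),
                                           seed = 1L, cohort = "synthetic",
                                           class = "A", feature = "duration") {
  stopifnot(inherits(truth, "longitudinal_truth"))
  age_model <- match.arg(age_model)
  g <- switch(age_model,
    linear = function(a) 0,
    quadratic = function(a) a^2,
    log = function(a) log(a)
  )
  b <- truth$beta
  n_visits <- length(truth$visit_age_mean)
  withr::with_seed(as.integer(seed), {
    sex <- rbinom(truth$n_subjects, 1L, truth$p_male)
    u <- rnorm(truth$n_subjects, 0, truth$sigma_u)
    rows <- vector("list", truth$n_subjects)
    for (i in seq_len(truth$n_subjects)) {
      present <- runif(n_visits) >= truth$missingness
      if (!any(present)) present[sample.int(n_visits, 1L)] <- TRUE
      v <- which(present)
      age <- pmax(0.5, rnorm(length(v), truth$visit_age_mean[v],
                             truth$visit_age_sd[v]))
      segments <- sample(seq(truth$segments_range[1], truth$segments_range[2]),
                         length(v), replace = TRUE)
      y <- b[["intercept"]] + b[["age"]] * age +
        if (age_model == "linear") 0 else b[["nonlinear"]] * g(age)
      y <- y + b[["sex"]] * sex[i] + b[["segments"]] * segments + u[i] +
        rnorm(length(v), 0, truth$sigma_e)
      rows[[i]] <- tibble::tibble(
        subject = sprintf("S%04d", i), cohort = cohort, visit = as.integer(v),
        age_months = age, sex = sex[i],
        retained_segments = as.integer(segments),
        class = class, feature = feature, value = y
      )
    }
    list(
      features = dplyr::bind_rows(rows),
      intercepts = tibble::tibble(subject = sprintf("S%04d", seq_len(truth$n_subjects)),
                                  u = u)
    )
  })
}
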