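# Parameter container for the sex-stratified Weibull proportional-hazards
# model on the age timescale:
#   h_s(t | x) = exp(alpha_s) * p_s * t^(p_s - 1) * exp(beta' x)
#   H0_s(t)    = exp(alpha_s) * t^(p_s)
# Age is the timescale (no age coefficient); covariates enter untransformed.

#' Construct a Weibull proportional-hazards model from known parameters
#'
#' Container for a sex-stratified Weibull PH model on the age timescale, with
#' cumulative baseline hazard `H0_s(t) = exp(alpha_s) * t^p_s` and shared
#' log-hazard-ratio coefficients `beta`.  Use this to build a model from
#' published coefficients; [weibull_ph()] returns the same structure from a
#' maximum-likelihood fit.
#'
#' @param alpha named numeric, log-scale intercept per stratum
#'   (`c(male = ..., female = ...)`).
#' @param shape named numeric, Weibull shape `p_s > 0` per stratum.
#' @param beta named numeric, per-unit log hazard ratios; names must be
#'   cohort covariate columns (`smoking`, `sbp`, `glucose`, `cholesterol`,
#'   `diabetes`).
#' @param label provenance label.
#' @return An object of class `weibull_ph_model`.
#' @export
weibull_ph_model <- function(alpha, shape, beta, label = "manual") {
  stopifnot(is.numeric(alpha), is.numeric(shape), is.numeric(beta))
  if (is.null(names(alpha)) || is.null(names(shape)))
    stopf("alpha and shape must be named by stratum")
  if (!identical(sort(names(alpha)), sort(names(shape))))
    stopf("alpha and shape strata differ")
  if (any(shape <= 0)) stopf("Weibull shape must be strictly positive")
  if (length(beta) && (is.null(names(beta)) || anyDuplicated(names(beta))))
    stopf("beta must have unique names")
  allowed <- c("smoking", "sbp", "glucose", "cholesterol", "diabetes")
  if (length(setdiff(names(beta), allowed)))
    stopf("unknown covariate(s) in beta: %s",
          paste(setdiff(names(beta), allowed), collapse = ", "))
  structure(list(strata = names(alpha),
                 alpha = alpha[names(alpha)],
                 shape = shape[names(alpha)],
                 beta = beta,
                 label = label),
            class = "weibull_ph_model")
}

#' @export
print.weibull_ph_model <- function(x, ...) {
  cat("Sex-stratified Weibull proportional-hazards model (age timescale)\n")
  cat(sprintf("  H0_s(t) = exp(alpha_s) * t^p_s   [%s]\n", x$label))
  for (s in x$strata)
    cat(sprintf("  %-7s alpha = %8.3f   p = %6.3f\n", s, x$alpha[s], x$shape[s]))
  if (length(x$beta)) {
    cat("  log hazard ratios:\n")
    for (k in names(x$beta)) cat(sprintf("    %-12s %8.4f\n", k, x$beta[k]))
  }
  invisible(x)
}

#' Published NRP1A risk-model coefficients
#'
#' The sex-stratified Weibull PH parameter sets reported for the Swiss NRP1A
#' cohort analysis: a model with fasting glucose and a model with total
#' cholesterol (both also containing current smoking and systolic blood
#' pressure).  These printed values serve as reference models for risk
#' charts and as the data-generating truth of the synthetic-cohort module.
#'
#' Note that the coefficients are printed at coarse precision (the SBP
#' coefficient to a single significant figure), which limits how closely
#' chart cells computed from them can match the originally published chart.
#'
#' @return Named list with elements `glucose` and `cholesterol`, each a
#'   [weibull_ph_model()].
#' @export
nrp1a_models <- function() {
  list(
    glucose = weibull_ph_model(
      alpha = c(male = -47.7, female = -58.8),
      shape = c(male = 9.9, female = 12.4),
      beta  = c(smoking = 0.37, sbp = 0.01, glucose = 0.10),
      label = "NRP1A published, glucose model"),
    cholesterol = weibull_ph_model(
      alpha = c(male = -47.5, female = -58.5),
      shape = c(male = 9.9, female = 12.5),
      beta  = c(smoking = 0.34, sbp = 0.01, cholesterol = 0.10),
      label = "NRP1A published, cholesterol model")
  )
}

#' Linear predictor of a Weibull PH model
#'
#' `lp = sum_k beta_k x_k` over the model's covariates; age does not appear
#' (it is the timescale).  Smoking and diabetes indicators contribute their
#' coefficient for `TRUE` and 0 for `FALSE`.
#'
#' @param model a `weibull_ph_model` (or a [weibull_ph()] fit).
#' @param profiles data.frame (or coercible named list) with one row per
#'   subject supplying every covariate named in `beta`.
#' @return Numeric vector of linear predictors.
#' @export
linear_predictor <- function(model, profiles) {
  model <- as_weibull_ph_model(model)
  profiles <- as.data.frame(profiles)
  if (!length(model$beta)) return(rep(0, nrow(profiles)))
  miss <- setdiff(names(model$beta), names(profiles))
  if (length(miss))
    stopf("profile lacks covariate(s): %s", paste(miss, collapse = ", "))
  lp <- rep(0, nrow(profiles))
  for (k in names(model$beta)) {
    x <- profiles[[k]]
    if (is.logical(x)) x <- as.numeric(x)
    if (anyNA(x)) stopf("missing value in covariate '%s'", k)
    lp <- lp + model$beta[[k]] * x
  }
  lp
}

#' Cumulative baseline hazard of the Weibull model
#'
#' `H0(t) = exp(alpha) * t^p`, evaluated in log space to stay finite for the
#' large shapes typical of age-timescale CVD models.
#'
#' @param alpha log-scale intercept.
#' @param shape Weibull shape `p > 0`.
#' @param t age in years, `t > 0`.
#' @return `H0(t)`.
#' @export
cumulative_baseline_hazard <- function(alpha, shape, t) {
  stopifnot(shape > 0)
  if (any(t <= 0)) stopf("cumulative hazard requires t > 0")
  exp(alpha + shape * log(t))
}

#' Absolute risk of fatal CVD over a horizon
#'
#' The probability of dying from CVD within `horizon` years given event-free
#' survival to the baseline age `a0`:
#' `risk = 1 - exp(-(H0(a0 + horizon) - H0(a0)) * exp(lp))`,
#' equivalently `1 - S(a0 + horizon) / S(a0)`.
#'
#' @param model a `weibull_ph_model` or `weibull_ph` fit.
#' @param profiles data.frame with columns `sex`, `age`, and the model's
#'   covariates; one row per subject.
#' @param horizon prediction horizon in years (10 by default; 20 and 30 are
#'   the usual sensitivity settings).
#' @return Numeric vector of risks in `[0, 1)`.
#' @export
predict_absolute_risk <- function(model, profiles, horizon = 10) {
  model <- as_weibull_ph_model(model)
  stopifnot(horizon > 0)
  profiles <- as.data.frame(profiles)
  if (!"age" %in% names(profiles)) stopf("profiles need an 'age' column")
  if (!"sex" %in% names(profiles)) stopf("profiles need a 'sex' column")
  a0 <- profiles$age
  if (any(is.na(a0) | a0 < 16)) stopf("baseline age must be >= 16")
  sex <- as.character(profiles$sex)
  bad <- setdiff(unique(sex), model$strata)
  if (length(bad)) stopf("no stratum for sex value(s): %s",
                         paste(bad, collapse = ", "))
  lp <- linear_predictor(model, profiles)
  alpha <- model$alpha[sex]
  shape <- model$shape[sex]
  dH <- cumulative_baseline_hazard(alpha, shape, a0 + horizon) -
    cumulative_baseline_hazard(alpha, shape, a0)
  unname(1 - exp(-dH * exp(lp)))
}

#' Wald test for a single parameter
#'
#' @param estimate point estimate.
#' @param se standard error, `> 0`.
#' @return list with `z = estimate / se` and two-sided `p = 2 (1 - Phi(|z|))`.
#' @export
wald_test <- function(estimate, se) {
  if (any(se <= 0)) stopf("standard error must be positive")
  z <- estimate / se
  list(z = z, p = 2 * pnorm(-abs(z)))
}

# Accept either a bare parameter container or a fitted model object.
as_weibull_ph_model <- function(model) {
  if (inherits(model, "weibull_ph_model")) return(model)
  if (inherits(model, "weibull_ph")) return(model$model)
  stopf("expected a 'weibull_ph_model' or 'weibull_ph' object")
}
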