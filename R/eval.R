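# Censoring-aware model comparison at a fixed horizon: IPCW Brier score
# (with cross-validation), time-dependent AUC, discrimination slopes and IDI
# with a Wald test, and a paired permutation test for Brier differences.

#' Subject status at a prediction horizon
#'
#' @param table a `cohort_table`.
#' @param horizon horizon in years after entry.
#' @return factor with levels `event` (CVD death within `horizon` years of
#'   entry), `event_free` (under observation at entry + horizon, or event
#'   after the horizon), `censored` (lost before the horizon without event).
#' @export
status_at_horizon <- function(table, horizon) {
  stopifnot(inherits(table, "cohort_table"), horizon > 0)
  time <- table$exit_age - table$age
  out <- rep("censored", nrow(table))
  out[time >= horizon] <- "event_free"
  out[table$event & time <= horizon] <- "event"
  factor(out, levels = c("event", "event_free", "censored"))
}

#' Inverse-probability-of-censoring weights at a horizon
#'
#' Kaplan-Meier estimate `G` of the censoring distribution on the follow-up
#' timescale; weights are `1/G(T-)` for subjects with an event before the
#' horizon, `1/G(horizon)` for subjects event-free at the horizon, and 0 for
#' subjects censored before the horizon.
#'
#' @param table a `cohort_table`.
#' @param horizon horizon in years.
#' @return Numeric weight vector (non-negative; zero exactly for the
#'   censored-before-horizon subjects).
#' @export
ipcw_weights <- function(table, horizon) {
  st <- status_at_horizon(table, horizon)
  time <- table$exit_age - table$age
  cens <- 1 - as.numeric(table$event)
  G_fit <- survival::survfit(survival::Surv(time, cens) ~ 1)
  surv_at <- function(t, left_limit) {
    i <- findInterval(t, G_fit$time, left.open = left_limit)
    c(1, G_fit$surv)[i + 1L]
  }
  w <- numeric(nrow(table))
  ie <- st == "event"
  if (any(ie)) {
    g <- surv_at(time[ie], left_limit = TRUE)  # G(T-)
    if (any(g <= 0))
      stopf("censoring survival is 0 at event time(s) %s; weights undefined",
            paste(signif(time[ie][g <= 0], 4), collapse = ", "))
    w[ie] <- 1 / g
  }
  ifree <- st == "event_free"
  if (any(ifree)) {
    g <- surv_at(horizon, left_limit = TRUE)   # G(horizon-)
    if (g <= 0)
      stopf("censoring survival is 0 at the horizon (%g years); weights undefined",
            horizon)
    w[ifree] <- 1 / g
  }
  w
}

#' IPCW Brier score at a horizon
#'
#' Mean squared difference between the predicted risk and the horizon event
#' indicator, weighted by [ipcw_weights()] and normalized by the cohort size.
#' With no censoring before the horizon this reduces exactly to the plain
#' mean squared error.
#'
#' @param risks predicted risks in `[0, 1]`, aligned with `table`.
#' @param table a `cohort_table`.
#' @param horizon horizon in years.
#' @return Brier score in `[0, 1]`.
#' @export
brier_score <- function(risks, table, horizon = 10) {
  stopifnot(length(risks) == nrow(table), all(risks >= 0 & risks <= 1))
  st <- status_at_horizon(table, horizon)
  w <- ipcw_weights(table, horizon)
  y <- as.numeric(st == "event")
  sum(w * (y - risks)^2) / nrow(table)
}

#' Cross-validated Brier score
#'
#' Refits the Weibull PH model with each subject (or fold) held out, predicts
#' the held-out risks at the horizon, and scores them with the IPCW Brier
#' score on the full table.  `mode = "exact"` is leave-one-out (n refits,
#' warm-started at the full-data optimum); `mode = "kfold"` is the fast
#' approximation.
#'
#' @param table a `cohort_table`.
#' @param covariates model covariates.
#' @param horizon horizon in years.
#' @param mode `"exact"` (leave-one-out) or `"kfold"`.
#' @param K folds for `mode = "kfold"`.
#' @param seed seed for the fold assignment.
#' @return list: `brier_cv`, per-subject cross-validated `risks`, `mode`,
#'   and `failed` (indices whose held-out refit did not converge; the score
#'   is computed over converged predictions with a warning).
#' @export
loocv_brier <- function(table, covariates, horizon = 10,
                        mode = c("exact", "kfold"), K = 10, seed = NULL) {
  mode <- match.arg(mode)
  n <- nrow(table)
  full <- suppressMessages(weibull_ph(table, covariates))
  risks <- rep(NA_real_, n)
  failed <- integer(0)
  folds <- if (mode == "exact") as.list(seq_len(n))
           else with_seed(seed, split(seq_len(n), sample(rep_len(seq_len(K), n))))
  for (fold in folds) {
    fit_i <- tryCatch(
      suppressWarnings(suppressMessages(
        weibull_ph(table[-fold, , drop = FALSE], covariates,
                   start = full$par))),
      error = function(e) NULL)
    if (is.null(fit_i) ||
        fit_i$diagnostics$optim_convergence != 0L ||
        !is.finite(fit_i$loglik)) {
      failed <- c(failed, fold)
      next
    }
    risks[fold] <- predict(fit_i, table[fold, , drop = FALSE], horizon)
  }
  if (length(failed)) {
    warning(sprintf("%d held-out refit(s) failed to converge; scored over the rest",
                    length(failed)), call. = FALSE)
    ok <- setdiff(seq_len(n), failed)
    bs <- brier_score(risks[ok], table[ok, , drop = FALSE], horizon)
  } else {
    bs <- brier_score(risks, table, horizon)
  }
  list(brier_cv = bs, risks = risks, mode = if (mode == "kfold")
    sprintf("kfold(K=%d)", K) else "exact (leave-one-out)", failed = failed)
}

#' Time-dependent AUC at a horizon
#'
#' IPCW-weighted probability that a subject with an event by the horizon is
#' assigned a higher risk than a subject event-free at the horizon; ties in
#' risk count one half.  With `weighted = FALSE` the naive (unweighted)
#' binary-outcome AUC over non-censored subjects is returned.
#'
#' @param risks predicted risks, aligned with `table`.
#' @param table a `cohort_table`.
#' @param horizon horizon in years.
#' @param weighted use IPCW weights (default).
#' @return AUC in `[0, 1]`.
#' @export
auc_at_horizon <- function(risks, table, horizon = 10, weighted = TRUE) {
  stopifnot(length(risks) == nrow(table))
  st <- status_at_horizon(table, horizon)
  w <- if (weighted) ipcw_weights(table, horizon)
       else as.numeric(st != "censored")
  case <- st == "event"
  ctrl <- st == "event_free"
  if (!any(case) || !any(ctrl))
    stopf("AUC undefined: need at least one event and one event-free subject at the horizon")
  rc <- risks[case]; wc <- w[case]
  rk <- risks[ctrl]; wk <- w[ctrl]
  o <- order(rk)
  rk <- rk[o]; wk <- wk[o]
  cw <- c(0, cumsum(wk))
  W_less <- cw[findInterval(rc, rk, left.open = TRUE) + 1L]
  W_leq <- cw[findInterval(rc, rk) + 1L]
  sum(wc * (W_less + 0.5 * (W_leq - W_less))) / (sum(wc) * sum(wk))
}

#' Discrimination slope of a prediction set
#'
#' Mean predicted risk among horizon events minus mean predicted risk among
#' horizon event-free subjects; subjects censored before the horizon are
#' excluded.
#'
#' @param risks predicted risks.
#' @param table a `cohort_table`.
#' @param horizon horizon in years.
#' @return The slope (scalar).
#' @export
discrimination_slope <- function(risks, table, horizon = 10) {
  st <- status_at_horizon(table, horizon)
  if (!any(st == "event")) stopf("no events by the horizon")
  mean(risks[st == "event"]) - mean(risks[st == "event_free"])
}

#' Integrated discrimination improvement
#'
#' `IDI = slope_new - slope_old`, the difference in discrimination slopes of
#' two prediction sets on the same subjects.  The standard error follows the
#' paired construction: per-subject prediction differences `d = new - old`
#' are averaged within the event and event-free groups, and
#' `se = sqrt(var(d_event)/n_event + var(d_free)/n_free)`; the Wald p-value
#' is two-sided.
#'
#' @param risks_new,risks_old predicted risks of the two models, aligned
#'   with `table`.
#' @param table a `cohort_table`.
#' @param horizon horizon in years.
#' @return list: `idi`, `se`, `wald_p`, `slope_new`, `slope_old`.
#' @export
idi <- function(risks_new, risks_old, table, horizon = 10) {
  stopifnot(length(risks_new) == nrow(table),
            length(risks_old) == nrow(table))
  st <- status_at_horizon(table, horizon)
  if (!any(st == "event")) stopf("no events by the horizon")
  slope_new <- discrimination_slope(risks_new, table, horizon)
  slope_old <- discrimination_slope(risks_old, table, horizon)
  d <- risks_new - risks_old
  de <- d[st == "event"]; df_ <- d[st == "event_free"]
  se <- sqrt(var(de) / length(de) + var(df_) / length(df_))
  est <- slope_new - slope_old
  if (!is.finite(se) || se == 0) {
    p <- if (est == 0) 1 else 0
  } else {
    p <- wald_test(est, se)$p
  }
  list(idi = est, se = se, wald_p = p,
       slope_new = slope_new, slope_old = slope_old)
}

#' Paired permutation test for a Brier-score difference
#'
#' Observed statistic `|Brier_a - Brier_b|`; the null distribution swaps each
#' subject's pair of predicted risks independently with probability 1/2
#' (exchangeability of the two models on the same subjects), and
#' `p = (1 + #(null >= observed)) / (n_perm + 1)`.
#'
#' @param risks_a,risks_b predicted risks of the two models.
#' @param table a `cohort_table`.
#' @param horizon horizon in years.
#' @param n_perm number of permutations (at least 99).
#' @param seed integer seed for reproducibility.
#' @return list: `p`, `observed`, `n_perm`.
#' @export
permutation_test_brier <- function(risks_a, risks_b, table, horizon = 10,
                                   n_perm = 1999, seed = NULL) {
  stopifnot(length(risks_a) == nrow(table),
            length(risks_b) == nrow(table), n_perm >= 99)
  st <- status_at_horizon(table, horizon)
  w <- ipcw_weights(table, horizon)
  y <- as.numeric(st == "event")
  n <- nrow(table)
  # Brier_a - Brier_b = mean(s_i * d_i) with d_i the per-subject weighted
  # squared-error difference; swapping a subject's pair flips the sign of d_i.
  d <- (w * ((y - risks_a)^2 - (y - risks_b)^2)) / n
  observed <- abs(sum(d))
  exceed <- with_seed(seed, {
    total <- 0L
    done <- 0L
    while (done < n_perm) {
      b <- min(500L, n_perm - done)
      signs <- matrix(sample(c(-1, 1), n * b, replace = TRUE), n, b)
      nullstat <- abs(colSums(signs * d))
      total <- total + sum(nullstat >= observed - 1e-15)
      done <- done + b
    }
    total
  })
  list(p = (1 + exceed) / (n_perm + 1), observed = observed, n_perm = n_perm)
}

#' Compare two Weibull PH covariate sets on one cohort
#'
#' Fits both models, computes cross-validated predictions, and reports the
#' comparison block: apparent and cross-validated Brier scores, AUC on the
#' cross-validated predictions, discrimination slopes, IDI with Wald test,
#' and the paired permutation p-value for the Brier difference.
#'
#' @param table a `cohort_table`.
#' @param covariates_a,covariates_b covariate sets of models A and B
#'   (model A is "new" in the IDI).
#' @param horizon horizon in years.
#' @param cv_mode `"kfold"` (default) or `"exact"` cross-validation.
#' @param K folds for k-fold mode.
#' @param n_perm permutations for the Brier test.
#' @param seed integer seed (folds + permutations).
#' @return An object of class `cvd_model_comparison`.
#' @export
compare_models <- function(table, covariates_a, covariates_b, horizon = 10,
                           cv_mode = c("kfold", "exact"), K = 10,
                           n_perm = 1999, seed = NULL) {
  cv_mode <- match.arg(cv_mode)
  fit_a <- suppressMessages(weibull_ph(table, covariates_a))
  fit_b <- suppressMessages(weibull_ph(table, covariates_b))
  pred_a <- predict(fit_a, table, horizon)
  pred_b <- predict(fit_b, table, horizon)
  cv_a <- loocv_brier(table, covariates_a, horizon, mode = cv_mode, K = K,
                      seed = seed)
  cv_b <- loocv_brier(table, covariates_b, horizon, mode = cv_mode, K = K,
                      seed = if (is.null(seed)) NULL else seed + 1L)
  st <- status_at_horizon(table, horizon)
  res <- list(
    horizon = horizon,
    models = list(a = covariates_a, b = covariates_b),
    fit_a = fit_a, fit_b = fit_b,
    brier = c(a = brier_score(pred_a, table, horizon),
              b = brier_score(pred_b, table, horizon)),
    brier_cv = c(a = cv_a$brier_cv, b = cv_b$brier_cv),
    cv_mode = cv_a$mode,
    auc = c(a = auc_at_horizon(cv_a$risks, table, horizon),
            b = auc_at_horizon(cv_b$risks, table, horizon)),
    idi = idi(cv_a$risks, cv_b$risks, table, horizon),
    perm = permutation_test_brier(cv_a$risks, cv_b$risks, table, horizon,
                                  n_perm = n_perm,
                                  seed = if (is.null(seed)) NULL else seed + 2L),
    n = nrow(table),
    events_by_horizon = sum(st == "event"))
  class(res) <- "cvd_model_comparison"
  res
}

#' @export
print.cvd_model_comparison <- function(x, ...) {
  lab <- function(cv) paste(cv, collapse = "+")
  cat(sprintf("Model comparison at %d-year horizon (n = %d, %d events by horizon)\n",
              x$horizon, x$n, x$events_by_horizon))
  cat(sprintf("  A: %s   vs   B: %s\n", lab(x$models$a), lab(x$models$b)))
  cat(sprintf("  Brier score x 1e-5 (mean, cross-validated, %s):  A %.0f   B %.0f   perm p = %.3f\n",
              x$cv_mode, 1e5 * x$brier_cv["a"], 1e5 * x$brier_cv["b"], x$perm$p))
  cat(sprintf("  AUC (cross-validated):  A %.4f   B %.4f\n",
              x$auc["a"], x$auc["b"]))
  cat(sprintf("  IDI (A vs B): %.4f (Wald p = %.3g)\n", x$idi$idi, x$idi$wald_p))
  invisible(x)
}

#' External validation of fitted models
#'
#' Applies the *fitted coefficients* to an external cohort without any
#' refitting: predicts each subject's risk at the horizon from both models,
#' then computes the (non-cross-validated) IPCW Brier scores, AUCs, IDI and
#' the permutation p-value on the external table.
#'
#' @param fit a `weibull_ph` fit (or `weibull_ph_model`), the "new" model.
#' @param table external `cohort_table`; must contain both models'
#'   covariates.
#' @param comparison_fit the competing model.
#' @param horizon horizon in years.
#' @param n_perm,seed permutation-test settings.
#' @return An object of class `cvd_external_validation`.
#' @export
external_validate <- function(fit, table, comparison_fit, horizon = 10,
                              n_perm = 1999, seed = NULL) {
  m_a <- as_weibull_ph_model(fit)
  m_b <- as_weibull_ph_model(comparison_fit)
  for (m in list(m_a, m_b)) {
    miss <- setdiff(names(m$beta), names(table))
    if (length(miss))
      stopf("external table lacks covariate(s): %s",
            paste(miss, collapse = ", "))
    ok <- complete.cases(as.data.frame(table)[, names(m$beta), drop = FALSE])
    if (!any(ok)) stopf("no external records with complete covariates")
  }
  pred_a <- predict_absolute_risk(m_a, table, horizon)
  pred_b <- predict_absolute_risk(m_b, table, horizon)
  st <- status_at_horizon(table, horizon)
  res <- list(
    horizon = horizon,
    brier = c(a = brier_score(pred_a, table, horizon),
              b = brier_score(pred_b, table, horizon)),
    auc = c(a = auc_at_horizon(pred_a, table, horizon),
            b = auc_at_horizon(pred_b, table, horizon)),
    idi = idi(pred_a, pred_b, table, horizon),
    perm = permutation_test_brier(pred_a, pred_b, table, horizon,
                                  n_perm = n_perm, seed = seed),
    n = nrow(table),
    events_by_horizon = sum(st == "event"))
  class(res) <- "cvd_external_validation"
  res
}

#' @export
print.cvd_external_validation <- function(x, ...) {
  cat(sprintf("External validation at %d-year horizon (n = %d, %d events by horizon)\n",
              x$horizon, x$n, x$events_by_horizon))
  cat(sprintf("  Brier score x 1e-5 (mean):  A %.0f   B %.0f   perm p = %.3f\n",
              1e5 * x$brier["a"], 1e5 * x$brier["b"], x$perm$p))
  cat(sprintf("  AUC:  A %.4f   B %.4f\n", x$auc["a"], x$auc["b"]))
  cat(sprintf("  IDI (A vs B): %.4f (Wald p = %.3g)\n", x$idi$idi, x$idi$wald_p))
  invisible(x)
}
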