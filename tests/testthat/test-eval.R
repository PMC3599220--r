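test_that("horizon status separates events, survivors and censored", {
  tab <- make_cohort(entry = c(40, 40, 40, 50), exit = c(45, 55, 45, 60),
                     event = c(TRUE, FALSE, FALSE, TRUE))
  st <- status_at_horizon(tab, 10)
  expect_equal(as.character(st), c("event", "event_free", "censored", "event"))
  # a death exactly at the horizon counts as an event
  tab2 <- make_cohort(entry = 40, exit = 50, event = TRUE)
  expect_equal(as.character(status_at_horizon(tab2, 10)), "event")
})

test_that("IPCW weights reproduce a hand-computed censoring KM", {
  # 6 subjects, follow-up times 2,3,4,6,11,12; censoring at 3 and 4
  tab <- make_cohort(entry = rep(40, 6),
                     exit = 40 + c(2, 3, 4, 6, 11, 12),
                     event = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  # censoring KM: drops at t=3 (5 at risk) and t=4 (4 at risk)
  # G(t) = 1 for t < 3; 4/5 on [3,4); 4/5 * 3/4 = 3/5 on [4, ...)
  w <- ipcw_weights(tab, 10)
  expect_equal(w, c(1 / 1,      # event at 2: G(2-) = 1
                    0, 0,       # censored before horizon
                    1 / (3 / 5),  # event at 6: G(6-) = 3/5
                    1 / (3 / 5),  # event-free at 10: G(10-) = 3/5
                    1 / (3 / 5)))
  expect_true(all(w[as.character(status_at_horizon(tab, 10)) == "censored"] == 0))
  # no censoring before horizon: all non-zero weights are 1
  tab2 <- make_cohort(entry = rep(40, 4), exit = 40 + c(2, 12, 11, 5),
                      event = c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(ipcw_weights(tab2, 10), c(1, 1, 1, 1))
})

test_that("Brier score reduces to mean squared error without censoring", {
  tab <- make_cohort(entry = rep(40, 4), exit = 40 + c(2, 12, 11, 5),
                     event = c(TRUE, FALSE, FALSE, TRUE))
  y <- c(1, 0, 0, 1)
  expect_equal(brier_score(y, tab, 10), 0)
  expect_equal(brier_score(rep(0.5, 4), tab, 10), 0.25)
  r <- c(0.8, 0.1, 0.3, 0.4)
  expect_equal(brier_score(r, tab, 10), mean((y - r)^2))
})

test_that("censored Brier score equals the brute-force weighted sum", {
  tab <- make_cohort(entry = rep(40, 6), exit = 40 + c(2, 3, 4, 6, 11, 12),
                     event = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE))
  r <- c(0.9, 0.2, 0.3, 0.6, 0.1, 0.4)
  w <- c(1, 0, 0, 5 / 3, 5 / 3, 5 / 3)
  y <- c(1, 0, 0, 1, 0, 0)   # subject 6 dies after the horizon
  expect_equal(brier_score(r, tab, 10), sum(w * (y - r)^2) / 6)
})

test_that("AUC equals exhaustive concordant-pair counting", {
  tab <- make_cohort(entry = rep(40, 8), exit = 40 + c(3, 5, 8, 12, 11, 13, 2, 14),
                     event = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE))
  r <- c(0.9, 0.4, 0.4, 0.2, 0.4, 0.1, 0.7, 0.3)
  st <- status_at_horizon(tab, 10)
  cases <- which(st == "event"); ctrls <- which(st == "event_free")
  num <- 0
  for (i in cases) for (j in ctrls)
    num <- num + (r[i] > r[j]) + 0.5 * (r[i] == r[j])
  oracle <- num / (length(cases) * length(ctrls))
  expect_equal(auc_at_horizon(r, tab, 10), oracle)
  # perfectly separating risks and constant risks
  sep <- ifelse(st == "event", 0.9, 0.1)
  expect_equal(auc_at_horizon(sep, tab, 10), 1)
  expect_equal(auc_at_horizon(rep(0.3, 8), tab, 10), 0.5)
  # invariance under strictly monotone transforms
  expect_equal(auc_at_horizon(plogis(5 * r - 2), tab, 10),
               auc_at_horizon(r, tab, 10))
  expect_error(auc_at_horizon(r[st == "event"],
                              tab[st == "event", ], 10), "undefined")
})

test_that("IDI is the hand-computed discrimination-slope difference", {
  tab <- make_cohort(entry = rep(40, 10),
                     exit = 40 + c(3, 6, 12, 11, 14, 13, 12, 15, 2, 9),
                     event = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE,
                               FALSE, FALSE, FALSE, TRUE))
  new <- c(0.8, 0.7, 0.2, 0.1, 0.15, 0.25, 0.3, 0.05, 0.5, 0.6)
  old <- c(0.6, 0.5, 0.3, 0.2, 0.25, 0.35, 0.4, 0.15, 0.5, 0.4)
  st <- status_at_horizon(tab, 10)
  ev <- st == "event"; fr <- st == "event_free"
  slope_new <- mean(new[ev]) - mean(new[fr])
  slope_old <- mean(old[ev]) - mean(old[fr])
  got <- idi(new, old, tab, 10)
  expect_equal(got$idi, slope_new - slope_old)
  expect_equal(got$slope_new, slope_new)
  d <- new - old
  expect_equal(got$se, sqrt(var(d[ev]) / sum(ev) + var(d[fr]) / sum(fr)))
  # antisymmetry and the identical-sets degenerate case
  rev <- idi(old, new, tab, 10)
  expect_equal(got$idi + rev$idi, 0)
  same <- idi(new, new, tab, 10)
  expect_equal(same$idi, 0)
  expect_equal(same$wald_p, 1)
})

test_that("permutation test is valid, reproducible and bounded below", {
  tab <- make_cohort(entry = rep(40, 30), exit = 40 + rep(c(3, 12, 15), 10),
                     event = rep(c(TRUE, FALSE, FALSE), 10))
  set.seed(2)
  a <- runif(30, 0, 0.5); b <- runif(30, 0, 0.5)
  expect_equal(permutation_test_brier(a, a, tab, 10, n_perm = 99, seed = 1)$p, 1)
  p1 <- permutation_test_brier(a, b, tab, 10, n_perm = 199, seed = 7)
  p2 <- permutation_test_brier(a, b, tab, 10, n_perm = 199, seed = 7)
  expect_identical(p1$p, p2$p)
  expect_gt(p1$p, 0)
  expect_lte(p1$p, 1)
  expect_gte(p1$p, 1 / 200)
})

test_that("exact LOOCV equals an explicit leave-one-out loop", {
  tab <- simulate_cohort(generator_config(), 60, seed = 44)
  covs <- c("smoking", "sbp")
  got <- quiet(loocv_brier(tab, covs, 10, mode = "exact"))
  oracle_risks <- vapply(seq_len(nrow(tab)), function(i) {
    f <- quiet(weibull_ph(tab[-i, ], covs))
    predict(f, tab[i, ], 10)
  }, 0)
  expect_equal(got$risks, oracle_risks, tolerance = 1e-5)
  expect_equal(got$brier_cv, brier_score(oracle_risks, tab, 10),
               tolerance = 1e-4)
})

test_that("cross-validation penalizes overfitted small samples", {
  worse <- 0L
  for (seed in 1:7) {
    tab <- simulate_cohort(generator_config(), 50, seed = 600 + seed)
    if (sum(tab$event) < 5) next
    covs <- c("smoking", "sbp", "glucose")
    fit <- tryCatch(quiet(weibull_ph(tab, covs)), error = function(e) NULL)
    if (is.null(fit)) next
    apparent <- brier_score(predict(fit, tab, 10), tab, 10)
    cv <- tryCatch(quiet(loocv_brier(tab, covs, 10, mode = "exact")),
                   error = function(e) NULL)
    if (is.null(cv)) next
    worse <- worse + (cv$brier_cv >= apparent)
  }
  expect_gt(worse, 3L)
})

test_that("external validation scores supplied coefficients without refitting", {
  truth <- glucose_truth()
  cfg <- generator_config(preset = "external", truth_model = truth)
  ext <- simulate_cohort(cfg, 2500, seed = 55)
  chol <- nrp1a_models()$cholesterol
  v <- external_validate(truth, ext, chol, horizon = 10, n_perm = 199,
                         seed = 9)
  expect_gt(v$auc[["a"]], 0.5)
  # better than any constant prediction (the prevalence-constant is optimal)
  st <- status_at_horizon(ext, 10)
  prev <- mean(st == "event") / mean(st != "censored")
  const_brier <- brier_score(rep(prev, nrow(ext)), ext, 10)
  expect_lt(v$brier[["a"]], const_brier)
  # identical coefficient vectors give IDI exactly 0
  v2 <- external_validate(truth, ext, truth, horizon = 10, n_perm = 99,
                          seed = 1)
  expect_equal(v2$idi$idi, 0)
  # missing covariates are an error
  noglu <- ext
  noglu$glucose <- NULL
  class(noglu) <- c("cohort_table", "data.frame")
  expect_error(external_validate(truth, noglu, chol), "lacks covariate")
})

test_that("model comparison reports the full Table-style block", {
  tab <- simulate_cohort(generator_config(), 1200, seed = 66)
  cmp <- quiet(compare_models(tab, c("smoking", "sbp", "glucose"),
                              c("smoking", "sbp", "cholesterol"),
                              horizon = 10, cv_mode = "kfold", K = 5,
                              n_perm = 199, seed = 3))
  expect_s3_class(cmp, "cvd_model_comparison")
  for (f in c("brier", "brier_cv", "auc"))
    expect_named(cmp[[f]], c("a", "b"))
  expect_true(is.finite(cmp$idi$idi))
  expect_gt(cmp$perm$p, 0)
  expect_output(print(cmp), "Brier")
})
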