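test_that("linear predictor is the exact inner product over covariates", {
  m <- glucose_truth()
  prof <- data.frame(sex = "male", age = 65, smoking = TRUE, sbp = 180,
                     glucose = 6)
  expect_equal(linear_predictor(m, prof), 0.37 + 0.01 * 180 + 0.10 * 6)
  base <- data.frame(smoking = FALSE, sbp = 0, glucose = 0)
  expect_equal(linear_predictor(m, base), 0)
  # linearity in any single covariate
  p2 <- prof; p2$glucose <- 12
  expect_equal(linear_predictor(m, p2) - linear_predictor(m, prof),
               0.10 * 6)
  expect_error(linear_predictor(m, data.frame(smoking = TRUE, sbp = 140)),
               "glucose")
})

test_that("cumulative baseline hazard follows exp(alpha) t^p", {
  expect_equal(cumulative_baseline_hazard(0, 1, 3), 3)
  # frozen direct evaluation at the published male parameters
  expect_equal(cumulative_baseline_hazard(-47.7, 9.9, 65),
               1.706064e-3, tolerance = 1e-6)
  # power-law doubling property, any alpha
  for (a in c(-47.7, 0, 2)) {
    p <- 9.9
    expect_equal(cumulative_baseline_hazard(a, p, 2 * 40) /
                   cumulative_baseline_hazard(a, p, 40), 2^p)
  }
  expect_error(cumulative_baseline_hazard(0, 1, 0), "t > 0")
})

test_that("left-truncated log-likelihood matches closed forms and is additive", {
  tab1 <- make_cohort(entry = 40, exit = 50, event = FALSE)
  # alpha = 0, p = 1, no covariates: contribution -(50 - 40)
  expect_equal(suppressWarnings(weibull_ph_loglik(c(0, 0), tab1, character(0))),
               -10)
  # duplicated record doubles the contribution
  tab2 <- make_cohort(entry = c(40, 40), exit = c(50, 50),
                      event = c(FALSE, FALSE))
  expect_equal(suppressWarnings(weibull_ph_loglik(c(0, 0), tab2, character(0))),
               -20)
})

test_that("log-likelihood equals a naive per-subject summation", {
  set.seed(21)
  tab <- make_cohort(entry = runif(10, 35, 60), exit = runif(10, 61, 80),
                     event = runif(10) < 0.5,
                     sex = sample(c("male", "female"), 10, TRUE),
                     smoking = runif(10) < 0.4, sbp = runif(10, 110, 170),
                     glucose = runif(10, 4, 8))
  par <- c(-46, -57, log(9.5), log(12), 0.3, 0.012, 0.09)
  # independent oracle: literal per-subject loop over the density/survival
  alpha <- c(male = -46, female = -57); p <- c(male = 9.5, female = 12)
  beta <- c(smoking = 0.3, sbp = 0.012, glucose = 0.09)
  ll <- 0
  for (i in seq_len(nrow(tab))) {
    s <- as.character(tab$sex[i])
    lp <- beta[["smoking"]] * tab$smoking[i] + beta[["sbp"]] * tab$sbp[i] +
      beta[["glucose"]] * tab$glucose[i]
    H <- function(t) exp(alpha[[s]]) * t^p[[s]]
    cum <- (H(tab$exit_age[i]) - H(tab$age[i])) * exp(lp)
    ll <- ll - cum
    if (tab$event[i])
      ll <- ll + log(exp(alpha[[s]]) * p[[s]] * tab$exit_age[i]^(p[[s]] - 1)) + lp
  }
  expect_equal(weibull_ph_loglik(par, tab, c("smoking", "sbp", "glucose")),
               ll)
})

test_that("analytic gradient agrees with finite differences", {
  set.seed(4)
  tab <- simulate_cohort(generator_config(), 300, seed = 4)
  covs <- c("smoking", "sbp", "glucose")
  par <- c(-47, -58, log(9), log(12), 0.3, 0.01, 0.1)
  f <- function(x) weibull_ph_loglik(x, tab, covs)
  num <- vapply(seq_along(par), function(j) {
    h <- 1e-6 * max(1, abs(par[j]))
    e <- numeric(length(par)); e[j] <- h
    (f(par + e) - f(par - e)) / (2 * h)
  }, 0)
  ana <- cvdscore:::.wph_gradient(par, cvdscore:::.wph_design(tab, covs))
  expect_equal(unname(ana), num, tolerance = 1e-4)
})

test_that("two-parameter MLE matches a dense grid search", {
  set.seed(9)
  n <- 20
  entry <- runif(n, 40, 60)
  u <- runif(n)
  # one stratum, no covariates, truth alpha = -30, p = 7
  t_ev <- (entry^7 - log(u) * exp(30))^(1 / 7)
  exit <- pmin(t_ev, entry + 20)
  tab <- make_cohort(entry = entry, exit = exit, event = t_ev <= entry + 20)
  fit <- quiet(weibull_ph(tab, character(0)))
  ll <- function(a, lp) weibull_ph_loglik(c(a, lp), tab, character(0))
  # two rounds of grid refinement around the fitted point
  ctr <- fit$par
  for (width in c(2, 0.02)) {
    as <- seq(ctr[1] - width * 3, ctr[1] + width * 3, length.out = 61)
    ps <- seq(ctr[2] - width / 4, ctr[2] + width / 4, length.out = 61)
    g <- outer(as, ps, Vectorize(ll))
    best <- which(g == max(g), arr.ind = TRUE)[1, ]
    ctr <- c(as[best[1]], ps[best[2]])
  }
  expect_equal(unname(fit$par[1]), ctr[1], tolerance = 2e-3)
  expect_equal(unname(fit$par[2]), ctr[2], tolerance = 2e-3)
})

test_that("the reported optimum has a vanishing likelihood gradient", {
  tab <- simulate_cohort(generator_config(), 3000, seed = 12)
  fit <- quiet(weibull_ph(tab, c("smoking", "sbp", "glucose")))
  expect_true(fit$converged)
  expect_lt(fit$diagnostics$max_abs_gradient / (1 + abs(fit$loglik)), 1e-4)
  # covariance symmetric positive definite at the optimum
  ev <- eigen(fit$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
  expect_equal(fit$vcov, t(fit$vcov))
})

test_that("fitting is invariant to record order", {
  tab <- simulate_cohort(generator_config(), 800, seed = 31)
  fit1 <- quiet(weibull_ph(tab, c("smoking", "sbp", "glucose")))
  perm <- withr::with_seed(1, sample(nrow(tab)))
  fit2 <- quiet(weibull_ph(tab[perm, ], c("smoking", "sbp", "glucose")))
  expect_equal(coef(fit1), coef(fit2), tolerance = 1e-5)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-8)
})

test_that("single-stratum fits agree with an independent Weibull PH fitter", {
  skip_if_not_installed("flexsurv")
  tab <- simulate_cohort(generator_config(), 6000, seed = 13)
  males <- tab[tab$sex == "male", ]
  fit <- quiet(weibull_ph(males, c("smoking", "sbp", "glucose")))
  d <- as.data.frame(males)
  fs <- flexsurv::flexsurvreg(
    survival::Surv(age, exit_age, event) ~ smoking + sbp + glucose,
    data = d, dist = "weibullPH",
    inits = c(shape = unname(coef(fit)["p:male"]),
              scale = exp(unname(coef(fit)["alpha:male"])),
              smokingTRUE = 0, sbp = 0, glucose = 0))
  expect_equal(unname(coef(fit)["p:male"]),
               unname(fs$res["shape", "est"]), tolerance = 1e-3)
  expect_equal(exp(unname(coef(fit)["alpha:male"])),
               unname(fs$res["scale", "est"]), tolerance = 1e-2)
  expect_equal(unname(coef(fit)[c("smoking", "sbp", "glucose")]),
               unname(fs$res[c("smokingTRUE", "sbp", "glucose"), "est"]),
               tolerance = 1e-3)
  expect_equal(fit$loglik, fs$loglik, tolerance = 1e-6)
})

test_that("absolute risk behaves as 1 - S(a0+h)/S(a0) and is monotone", {
  m <- glucose_truth()
  prof <- data.frame(sex = "female", age = 60, smoking = TRUE, sbp = 160,
                     glucose = 7)
  r10 <- predict_absolute_risk(m, prof, 10)
  r20 <- predict_absolute_risk(m, prof, 20)
  expect_gt(r20, r10)
  expect_lt(predict_absolute_risk(m, prof, 1e-9), 1e-6)
  # algebraic identity with the unconditional survival function
  S <- function(t) exp(-cumulative_baseline_hazard(m$alpha[["female"]],
                                                   m$shape[["female"]], t) *
                         exp(linear_predictor(m, prof)))
  expect_equal(r10, 1 - S(70) / S(60))
  # monotone in age (p > 1), SBP and glucose
  older <- prof; older$age <- 65
  expect_gt(predict_absolute_risk(m, older, 10), r10)
  hi_sbp <- prof; hi_sbp$sbp <- 180
  expect_gt(predict_absolute_risk(m, hi_sbp, 10), r10)
  expect_true(all(predict_absolute_risk(m, prof, c(10)) < 1))
})

test_that("Wald machinery reproduces interval-based p-values", {
  expect_equal(wald_test(0, 1)$p, 1)
  expect_equal(wald_test(1.96, 1)$p, 0.05, tolerance = 1e-3)
  # estimate 0.10 with CI (0.00; 0.20): se = 0.10 / 1.96
  w <- wald_test(0.10, 0.10 / qnorm(0.975))
  expect_equal(w$p, 0.05, tolerance = 1e-6)
  expect_error(wald_test(1, 0), "positive")
})

test_that("confidence intervals cover the truth at nominal rate", {
  truth <- c(-47.7, -58.8, 9.9, 12.4, 0.37, 0.01, 0.10)
  nrep <- 100
  hits <- 0L; total <- 0L
  for (i in seq_len(nrep)) {
    tab <- simulate_cohort(generator_config(), 5000, seed = 5000 + i)
    fit <- quiet(weibull_ph(tab, c("smoking", "sbp", "glucose")))
    if (!fit$converged) next
    w <- fit$wald
    hits <- hits + sum(w$lower <= truth & truth <= w$upper)
    total <- total + length(truth)
  }
  coverage <- hits / total
  expect_gte(coverage, 0.93)
  expect_lte(coverage, 0.97)
})

test_that("fit objects support the standard modelling verbs", {
  tab <- simulate_cohort(generator_config(), 1500, seed = 77)
  fit <- quiet(weibull_ph(tab, c("smoking", "sbp", "glucose")))
  expect_s3_class(fit, "weibull_ph")
  expect_named(coef(fit), c("alpha:male", "alpha:female", "p:male",
                            "p:female", "smoking", "sbp", "glucose"))
  expect_equal(dim(vcov(fit)), c(7L, 7L))
  expect_equal(as.numeric(logLik(fit)), fit$loglik)
  ci <- confint(fit)
  expect_true(all(ci[, 1] < coef(fit) & coef(fit) < ci[, 2]))
  r <- residuals(fit)
  expect_true(all(r >= 0))
  expect_output(print(summary(fit)), "Weibull")
  preds <- predict(fit, horizon = 10)
  expect_length(preds, nrow(tab))
  expect_true(all(preds >= 0 & preds < 1))
  sim <- quiet(simulate(fit, seed = 1, n = 50))
  expect_s3_class(sim, "cohort_table")
  expect_equal(nrow(sim), 50L)
})
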