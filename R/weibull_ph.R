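#' @importFrom stats optim optimHess qnorm
NULL

# Internal design object: everything the likelihood needs, precomputed once.
.wph_design <- function(table, covariates) {
  stopifnot(inherits(table, "cohort_table"))
  need <- c("sex", "age", "exit_age", "event", covariates)
  keep <- complete.cases(as.data.frame(table)[, need, drop = FALSE])
  if (!all(keep)) {
    message(sprintf("weibull_ph: dropping %d record(s) with missing values",
                    sum(!keep)))
    table <- table[keep, , drop = FALSE]
  }
  if (!nrow(table)) stopf("no complete records to fit")
  strata <- intersect(c("male", "female"), unique(as.character(table$sex)))
  X <- NULL
  if (length(covariates)) {
    X <- sapply(covariates, function(k) {
      x <- table[[k]]
      if (is.logical(x)) as.numeric(x) else as.numeric(x)
    })
    X <- matrix(X, nrow = nrow(table), dimnames = list(NULL, covariates))
  }
  sidx <- match(as.character(table$sex), strata)
  d <- as.numeric(table$event)
  for (s in seq_along(strata))
    if (sum(d[sidx == s]) < 1)
      warning(sprintf("stratum '%s' has no events; its baseline is not identifiable",
                      strata[s]), call. = FALSE)
  list(table = table, strata = strata, sidx = sidx, X = X,
       d = d, logt = log(table$exit_age), logt0 = log(table$age),
       covariates = covariates,
       par_names = c(paste0("alpha:", strata), paste0("logp:", strata),
                     covariates))
}

.wph_unpack <- function(par, design) {
  ns <- length(design$strata)
  list(alpha = par[seq_len(ns)],
       logp = par[ns + seq_len(ns)],
       beta = if (length(design$covariates)) par[2 * ns + seq_along(design$covariates)] else numeric(0))
}

.wph_loglik <- function(par, design) {
  pp <- .wph_unpack(par, design)
  p <- exp(pp$logp)
  ai <- pp$alpha[design$sidx]
  pi_ <- p[design$sidx]
  lpi <- pp$logp[design$sidx]
  lp <- if (length(pp$beta)) drop(design$X %*% pp$beta) else 0
  A <- exp(ai + lp + pi_ * design$logt)
  B <- exp(ai + lp + pi_ * design$logt0)
  ll <- sum(design$d * (ai + lpi + (pi_ - 1) * design$logt + lp)) - sum(A - B)
  if (!is.finite(ll)) return(-1e10)
  ll
}

.wph_gradient <- function(par, design) {
  pp <- .wph_unpack(par, design)
  p <- exp(pp$logp)
  ai <- pp$alpha[design$sidx]
  pi_ <- p[design$sidx]
  lp <- if (length(pp$beta)) drop(design$X %*% pp$beta) else 0
  A <- exp(ai + lp + pi_ * design$logt)
  B <- exp(ai + lp + pi_ * design$logt0)
  g <- design$d - (A - B)
  ns <- length(design$strata)
  dalpha <- vapply(seq_len(ns), function(s) sum(g[design$sidx == s]), 0)
  dlogp <- vapply(seq_len(ns), function(s) {
    i <- design$sidx == s
    p[s] * sum(design$d[i] * (1 / p[s] + design$logt[i]) -
                 (A[i] * design$logt[i] - B[i] * design$logt0[i]))
  }, 0)
  dbeta <- if (length(pp$beta)) drop(crossprod(design$X, g)) else numeric(0)
  out <- c(dalpha, dlogp, dbeta)
  out[!is.finite(out)] <- 0
  out
}

#' Left-truncated Weibull PH log-likelihood
#'
#' The log-likelihood of the sex-stratified Weibull proportional-hazards model
#' on the age timescale, with delayed entry at baseline age: subjects
#' contribute `log h(exit) - [H(exit) - H(entry)]` when they die of CVD and
#' `-[H(exit) - H(entry)]` when censored, where
#' `H(t) = exp(alpha_s + beta' x) t^(p_s)`.
#'
#' @param params flat parameter vector ordered
#'   `(alpha per stratum, log p per stratum, beta per covariate)`, strata in
#'   the order `male`, `female` (restricted to strata present in `table`).
#' @param table a `cohort_table`.
#' @param covariates character vector of covariate columns.
#' @return The log-likelihood (a finite scalar; a barrier value of `-1e10`
#'   for numerically invalid parameters).
#' @export
weibull_ph_loglik <- function(params, table, covariates) {
  design <- .wph_design(table, covariates)
  if (length(params) != length(design$par_names))
    stopf("expected %d parameters (%s)", length(design$par_names),
          paste(design$par_names, collapse = ", "))
  .wph_loglik(as.numeric(params), design)
}

#' Fit a sex-stratified Weibull proportional-hazards model
#'
#' Maximum-likelihood fit of the SCORE-type parametric survival model
#' `h_s(t | x) = exp(alpha_s) p_s t^(p_s - 1) exp(beta' x)` with age as the
#' timescale and left truncation at the baseline age, so that the complete
#' follow-up contributes to estimation while the prediction horizon is chosen
#' afterwards.  Optimization is quasi-Newton (BFGS) over
#' `(alpha_s, log p_s, beta)` with analytic gradients; the covariance matrix
#' is the inverse observed information at the optimum, with a delta-method
#' transform for the shape parameters.
#'
#' @param table a [cohort_table()] with `sex`, `age`, `exit_age`, `event` and
#'   the covariate columns; records with missing values are dropped.
#' @param covariates covariate names, a subset of
#'   `c("smoking", "sbp", "glucose", "cholesterol", "diabetes")`.
#' @param start optional named start vector on the internal scale
#'   (`alpha:male`, ..., `logp:male`, ..., covariates); defaults to `p = 5`,
#'   a stratum-wise moment match for `alpha` and `beta = 0`.
#' @param control passed to [stats::optim()]; defaults to
#'   `list(maxit = 500, reltol = 1e-10)`.
#' @return An object of class `weibull_ph`: a list with the fitted
#'   [weibull_ph_model()] (`$model`), natural-scale `$coefficients` and
#'   `$vcov`, `$loglik`, `$converged`, `$n_used`, `$events_used`, and a Wald
#'   table `$wald` (estimate, SE, z, p, 95% CI).
#' @seealso [predict.weibull_ph()], [summary.weibull_ph()],
#'   [predict_absolute_risk()]
#' @examples
#' cohort <- simulate_cohort(generator_config(seed = 1), n = 2000)
#' fit <- weibull_ph(cohort, c("smoking", "sbp", "glucose"))
#' summary(fit)
#' @export
weibull_ph <- function(table, covariates = c("smoking", "sbp", "glucose"),
                       start = NULL, control = list()) {
  design <- .wph_design(table, covariates)
  ns <- length(design$strata)
  npar <- length(design$par_names)

  if (is.null(start)) {
    p0 <- 5
    start <- numeric(npar)
    for (s in seq_len(ns)) {
      i <- design$sidx == s
      expos <- sum(exp(p0 * design$logt[i]) - exp(p0 * design$logt0[i]))
      nev <- max(sum(design$d[i]), 0.5)
      start[s] <- log(nev) - log(expos)
      start[ns + s] <- log(p0)
    }
  }
  names(start) <- design$par_names
  control <- utils::modifyList(list(maxit = 500L, reltol = 1e-10), control)

  opt <- optim(start, fn = .wph_loglik, gr = .wph_gradient, design = design,
               method = "BFGS",
               control = c(control, list(fnscale = -1)))
  # restart BFGS from the current point until the objective stabilizes;
  # guards against premature stops in the strongly correlated (alpha, p)
  # directions
  for (round in 1:3) {
    opt2 <- optim(opt$par, fn = .wph_loglik, gr = .wph_gradient,
                  design = design, method = "BFGS",
                  control = c(control, list(fnscale = -1)))
    if (opt2$value <= opt$value + 1e-8) {
      if (opt2$value > opt$value) opt <- opt2
      break
    }
    opt <- opt2
  }
  # Newton polish: near the optimum the observed information is available
  # cheaply, and a few damped Newton steps drive the gradient to machine
  # noise where BFGS stalls along the correlated (alpha, p) ridge
  for (step in 1:20) {
    gr <- .wph_gradient(opt$par, design)
    if (max(abs(gr)) < 1e-6 * (1 + abs(opt$value))) break
    h <- optimHess(opt$par, fn = .wph_loglik, gr = .wph_gradient,
                   design = design)
    delta <- tryCatch(solve(-h, gr), error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) break
    lam <- 1
    improved <- FALSE
    for (half in 1:30) {
      cand <- opt$par + lam * delta
      val <- .wph_loglik(cand, design)
      if (is.finite(val) && val > opt$value) {
        opt$par <- cand
        opt$value <- val
        improved <- TRUE
        break
      }
      lam <- lam / 2
    }
    if (!improved) break
  }
  hess <- optimHess(opt$par, fn = .wph_loglik, gr = .wph_gradient,
                    design = design)
  info <- -hess
  vcov_int <- tryCatch(solve(info), error = function(e) NULL)
  grad <- .wph_gradient(opt$par, design)
  converged <- opt$convergence == 0L && !is.null(vcov_int) &&
    all(is.finite(vcov_int)) && all(diag(vcov_int) > 0) &&
    max(abs(grad)) / (1 + abs(opt$value)) < 1e-4
  if (!converged)
    warning("weibull_ph fit did not converge cleanly; inspect $diagnostics",
            call. = FALSE)
  # symmetrize against numeric asymmetry in the Hessian
  if (!is.null(vcov_int)) vcov_int <- (vcov_int + t(vcov_int)) / 2

  pp <- .wph_unpack(opt$par, design)
  p_hat <- exp(pp$logp)
  natural <- c(pp$alpha, p_hat, pp$beta)
  nat_names <- c(paste0("alpha:", design$strata), paste0("p:", design$strata),
                 design$covariates)
  names(natural) <- nat_names
  vcov_nat <- NULL
  if (!is.null(vcov_int)) {
    jac <- diag(c(rep(1, ns), p_hat, rep(1, npar - 2 * ns)), npar)
    vcov_nat <- jac %*% vcov_int %*% t(jac)
    dimnames(vcov_nat) <- list(nat_names, nat_names)
  }
  se <- if (!is.null(vcov_nat)) sqrt(pmax(diag(vcov_nat), 0)) else rep(NA_real_, npar)
  z <- natural / se
  wald <- data.frame(term = nat_names, estimate = unname(natural),
                     se = unname(se), z = unname(z),
                     p = unname(2 * pnorm(-abs(z))),
                     lower = unname(natural - qnorm(0.975) * se),
                     upper = unname(natural + qnorm(0.975) * se),
                     stringsAsFactors = FALSE)
  rownames(wald) <- NULL

  model <- weibull_ph_model(
    alpha = setNames(pp$alpha, design$strata),
    shape = setNames(p_hat, design$strata),
    beta = if (length(pp$beta)) setNames(pp$beta, design$covariates) else setNames(numeric(0), character(0)),
    label = sprintf("MLE fit (%s)", paste(design$covariates, collapse = "+")))

  structure(list(model = model,
                 coefficients = natural,
                 par = opt$par,
                 vcov = vcov_nat,
                 vcov_internal = vcov_int,
                 loglik = opt$value,
                 converged = converged,
                 n_used = nrow(design$table),
                 events_used = sum(design$d),
                 wald = wald,
                 covariates = covariates,
                 data = design$table,
                 diagnostics = list(optim_convergence = opt$convergence,
                                    optim_message = opt$message,
                                    counts = opt$counts,
                                    max_abs_gradient = max(abs(grad))),
                 call = match.call()),
            class = "weibull_ph")
}

#' @export
coef.weibull_ph <- function(object, ...) object$coefficients

#' @export
vcov.weibull_ph <- function(object, ...) object$vcov

#' @export
logLik.weibull_ph <- function(object, ...) {
  structure(object$loglik, df = length(object$par),
            nobs = object$n_used, class = "logLik")
}

#' @export
confint.weibull_ph <- function(object, parm, level = 0.95, ...) {
  w <- object$wald
  q <- qnorm(1 - (1 - level) / 2)
  ci <- cbind(w$estimate - q * w$se, w$estimate + q * w$se)
  dimnames(ci) <- list(w$term, sprintf("%.1f %%", c((1 - level) / 2,
                                                    1 - (1 - level) / 2) * 100))
  if (!missing(parm)) ci <- ci[parm, , drop = FALSE]
  ci
}

#' @export
print.weibull_ph <- function(x, ...) {
  cat("Weibull proportional-hazards fit (age timescale, left-truncated)\n")
  cat(sprintf("  n = %d, events = %d, logLik = %.2f, converged: %s\n",
              x$n_used, x$events_used, x$loglik, x$converged))
  print(x$model)
  invisible(x)
}

#' Wald summary of a Weibull PH fit
#'
#' @param object a `weibull_ph` fit.
#' @param ... unused.
#' @return The fit, invisibly; prints a table of estimates, 95% confidence
#'   intervals and two-sided Wald p-values per parameter.
#' @export
summary.weibull_ph <- function(object, ...) {
  structure(list(fit = object), class = "summary.weibull_ph")
}

#' @export
print.summary.weibull_ph <- function(x, ...) {
  fit <- x$fit
  cat("Sex-stratified Weibull proportional-hazards model\n")
  cat(sprintf("n = %d subjects, %d CVD deaths; logLik = %.2f; converged: %s\n\n",
              fit$n_used, fit$events_used, fit$loglik, fit$converged))
  w <- fit$wald
  tab <- data.frame(
    Estimate = sprintf("%.4g", w$estimate),
    `95% CI` = sprintf("(%.4g; %.4g)", w$lower, w$upper),
    `P-value` = ifelse(w$p < 0.001, "<0.001", sprintf("%.3f", w$p)),
    check.names = FALSE)
  rownames(tab) <- w$term
  print(tab)
  invisible(x)
}

#' Predict from a fitted Weibull PH model
#'
#' @param object a `weibull_ph` fit.
#' @param newdata data.frame of profiles (`sex`, `age`, covariates); the
#'   fitting data when omitted.
#' @param horizon prediction horizon in years.
#' @param type `"risk"` for the absolute risk within `horizon` years,
#'   `"lp"` for the linear predictor.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.weibull_ph <- function(object, newdata = NULL, horizon = 10,
                               type = c("risk", "lp"), ...) {
  type <- match.arg(type)
  if (is.null(newdata)) newdata <- object$data
  if (type == "lp") return(linear_predictor(object$model, newdata))
  predict_absolute_risk(object$model, newdata, horizon)
}

#' Cox-Snell residuals of a Weibull PH fit
#'
#' Under a correct model the residuals `r_i = [H0(exit) - H0(entry)] exp(lp)`
#' behave as a censored sample from the unit exponential distribution.
#'
#' @param object a `weibull_ph` fit.
#' @param ... unused.
#' @return Numeric vector with attribute `"event"`.
#' @export
residuals.weibull_ph <- function(object, ...) {
  tab <- object$data
  m <- object$model
  sex <- as.character(tab$sex)
  lp <- linear_predictor(m, tab)
  r <- (cumulative_baseline_hazard(m$alpha[sex], m$shape[sex], tab$exit_age) -
          cumulative_baseline_hazard(m$alpha[sex], m$shape[sex], tab$age)) * exp(lp)
  attr(r, "event") <- tab$event
  unname(r)
}

#' Diagnostic plot: Cox-Snell residuals against the unit exponential
#'
#' @param x a `weibull_ph` fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.weibull_ph <- function(x, ...) {
  r <- residuals(x)
  ev <- attr(r, "event")
  km <- survival::survfit(survival::Surv(r, ev) ~ 1)
  graphics::plot(km$time, -log(km$surv), type = "s",
                 xlab = "Cox-Snell residual",
                 ylab = "Cumulative hazard of residuals", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate cohorts from a fitted model
#'
#' Draws synthetic cohorts using the fitted parameters as the
#' data-generating truth (covariates from `config`, event ages from the
#' fitted Weibull law, administrative censoring per `config`).
#'
#' @param object a `weibull_ph` fit.
#' @param nsim number of cohorts.
#' @param seed integer seed.
#' @param n subjects per cohort.
#' @param config a [generator_config()]; its `truth_model` is replaced by the
#'   fitted model.
#' @param ... unused.
#' @return A `cohort_table` (`nsim = 1`) or list of them.
#' @export
simulate.weibull_ph <- function(object, nsim = 1, seed = NULL,
                                n = object$n_used,
                                config = generator_config(), ...) {
  config$truth_model <- object$model
  out <- with_seed(seed, lapply(seq_len(nsim), function(i)
    simulate_cohort(config, n, seed = NULL)))
  if (nsim == 1) out[[1]] else out
}
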