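# Small in-code fixtures shared across test files.

# A hand-sized cohort with known entries/exits/events; covariates filled in
# with plausible values unless overridden.
make_cohort <- function(entry, exit, event,
                        sex = rep("male", length(entry)),
                        smoking = rep(FALSE, length(entry)),
                        sbp = rep(130, length(entry)),
                        glucose = rep(5, length(entry)),
                        cholesterol = rep(6, length(entry)),
                        fasting_hours = rep(10, length(entry))) {
  suppressMessages(cohort_table(data.frame(
    sex = sex, age = entry, exit_age = exit, event = event,
    smoking = smoking, sbp = sbp, glucose = glucose,
    cholesterol = cholesterol, fasting_hours = fasting_hours),
    provenance = "test fixture"))
}

# Published glucose-model parameters, used widely as a known truth.
glucose_truth <- function() nrp1a_models()$glucose

# A null truth: same Weibull baselines (intercepts raised to keep the event
# rate realistic once the covariate contributions are removed), zero
# coefficients.
null_truth <- function() {
  weibull_ph_model(alpha = c(male = -45.9, female = -57.0),
                   shape = c(male = 9.9, female = 12.4),
                   beta = c(smoking = 0, sbp = 0, glucose = 0),
                   label = "null truth")
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# exact two-sided Kolmogorov-Smirnov distance between a sample and a CDF
ks_distance <- function(x, F) {
  x <- sort(x)
  n <- length(x)
  Fi <- F(x)
  max(seq_len(n) / n - Fi, Fi - (seq_len(n) - 1) / n)
}
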