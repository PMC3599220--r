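---
title: "Weibull proportional-hazards modelling of fatal CVD risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weibull proportional-hazards modelling of fatal CVD risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cvdscore)
```

## The model

`cvdscore` implements the parametric survival model behind the European
SCORE risk charts: a Weibull proportional-hazards model with **age as the
timescale**, stratified by sex, with shared covariate effects:

$$ h_s(t \mid x) = e^{\alpha_s}\, p_s\, t^{p_s - 1}\, e^{\beta^\top x},
\qquad H_{0,s}(t) = e^{\alpha_s} t^{p_s}, $$

for stratum $s \in \{\text{male}, \text{female}\}$, age $t$ in years, and
covariates $x$ drawn from current smoking (indicator), systolic blood
pressure (mmHg), and a blood marker — fasting glucose or total cholesterol
(mmol/L), optionally supplemented by a diabetes indicator. Age carries the
dominant risk gradient and therefore appears as the timescale, not as a
coefficient.

Subjects enter the risk set at their baseline age $a_0$ (left truncation /
delayed entry), so a subject observed from $a_0$ to exit age $t_i$
contributes

$$ \ell_i = d_i \log h_s(t_i \mid x_i) -
   \left[H_{0,s}(t_i) - H_{0,s}(a_0)\right] e^{\beta^\top x_i}, $$

with $d_i$ the fatal-CVD indicator. The complete follow-up is used for
fitting; the prediction horizon is chosen only afterwards. The absolute risk
of fatal CVD within $h$ years for a subject event-free at age $a_0$ is

$$ R(h \mid a_0, x) = 1 - \frac{S(a_0 + h)}{S(a_0)} =
   1 - \exp\!\left(-\left[H_0(a_0+h) - H_0(a_0)\right] e^{\beta^\top x}\right). $$

`predict_absolute_risk()` implements this identity directly; a test asserts
the algebraic equivalence with the unconditional survival function.

### Why untransformed age

Two parameterizations circulate for SCORE-type baselines: $t^p$ on raw age
and $(t-20)^p$ on shifted age. We adopt raw age because the published
magnitudes we use as reference values ($\alpha \approx -48$ with
$p \approx 10$ for men) are only consistent with untransformed age: at age
65 they give a male cumulative baseline hazard of
$e^{-47.7} \cdot 65^{9.9} \approx 1.7\times 10^{-3}$, a plausible lifetime
scale, whereas the same numbers on $(t-20)$ give values two orders of
magnitude smaller than any observed CVD mortality. Whether the original
analysis centred covariates before exponentiation cannot be confirmed from
the printed values; untransformed continuous covariates reproduce the
printed per-unit coefficient magnitudes and are adopted throughout.

### Reference coefficients and the limits of printed precision

`nrp1a_models()` ships the published parameter sets of the Swiss NRP1A
analysis (a glucose and a cholesterol variant). These are used as chart
reference models and as the data-generating truth of the synthetic-cohort
module. One caveat matters and is worth stating plainly: the printed SBP
coefficient (0.01 per mmHg) carries a single significant figure. At
SBP = 180 the linear predictor term $\beta_{sbp}\cdot 180$ is therefore only
known to within roughly $\pm 0.9$ on the log-hazard scale — nearly a factor
$e^{0.9} \approx 2.5$ on the hazard. Concretely, the worked example cell
(male, 65, smoker, SBP 180, glucose 6, 10-year horizon) computes to

```{r example-cell}
m <- nrp1a_models()$glucose
round(100 * predict_absolute_risk(
  m, data.frame(sex = "male", age = 65, smoking = TRUE,
                sbp = 180, glucose = 6), horizon = 10), 1)
```

about 8%, while an unrounded SBP coefficient of ~0.0136 — which rounds to
the printed 0.01 — would give 15%. Chart cells computed from printed
coefficients are therefore reproducible only up to this rounding envelope;
the package computes them faithfully from whatever coefficients it is
given and does not attempt to reverse-engineer unrounded values.

## Fitting

`weibull_ph()` maximizes the left-truncated log-likelihood over
$(\alpha_s, \log p_s, \beta)$ — the log transform keeps the shape positive —
using BFGS with analytic gradients, followed by damped Newton steps using
the observed information, which removes the slow tail of BFGS convergence
along the strongly correlated $(\alpha_s, p_s)$ ridge. Starting values are
$p_s = 5$, $\beta = 0$, and a stratum-wise moment match for $\alpha_s$
(events over cumulative exposure $\sum_i t_i^{p} - a_{0,i}^{p}$).
Convergence requires the optimizer's own criterion (relative tolerance
$10^{-10}$, at most 500 iterations), a maximum absolute gradient below
$10^{-4}$ relative to the log-likelihood, and a positive-definite inverse
information; the `converged` flag is honest and a failed fit warns rather
than silently returning.

The covariance matrix is the inverse observed information at the optimum;
shape parameters are reported on the natural scale with delta-method
standard errors, so the Wald table's symmetric 95% intervals match the
interval arithmetic of the published tables. Wald p-values are implemented
(`wald_test()`); whether the original tables used Wald or likelihood-ratio
tests is not determinable from the printed values, but Wald reproduces the
printed CI/p-value relationships (e.g. an estimate of 0.10 with CI
(0.00; 0.20) gives p ≈ 0.05).

Degenerate inputs: a stratum without events leaves its baseline
unidentifiable — the fit warns and flags rather than stopping, since the
coefficient part often remains usable; non-positive shapes are excluded by
the log parameterization; numerically invalid parameter points return a
finite barrier value so the optimizer can retreat.

## The synthetic-cohort generator

`generator_config()` defines the study conditions the package is exercised
under. Published facts supply the per-sex means and proportions (men/women:
age 42.4/44.1 y, smoking 50.3%/27.7%, SBP 130.2/125.4 mmHg, glucose 5.4/5.2
mmol/L, cholesterol 6.0 mmol/L both sexes) and the follow-up anchors
(median ≈ 30.8 y, 95th centile 31.2 y). Everything the source does not
state is a declared free choice, set once:

* **Dispersions**: age sd 12/13, SBP sd 16/17, glucose sd 0.9/0.8,
  cholesterol sd 1.1/1.1 (men/women) — typical of adult community cohorts.
* **Marginals**: truncated normals with physiologic floors (age 16, SBP 70,
  glucose 2.5, cholesterol 2.0 mmol/L); smoking and diabetes Bernoulli
  (diabetes prevalence 2.6%, matching the reported 160/6095). With
  `match_target_means = TRUE` the pre-truncation means are shifted so the
  *truncated* means hit the targets exactly (only the age floor at 16 is
  close enough to matter, a ~0.4-year shift).
* **Dependence**: covariates are drawn independently within sex by default
  (no correlation structure is published); a Gaussian-copula correlation
  matrix over the continuous covariates is available for sensitivity work.
* **Censoring**: administrative only by default — individual follow-up is
  the 31.2-year maximum minus a uniform stagger of width 0.8 y, which puts
  the median censoring time at ≈ 30.8 y; an optional loss-to-follow-up rate
  adds uniform dropout (the source reports ~4–7% non-linkage).
* **Sex ratio**: P(male) = 0.454, the analysed-cohort proportion
  (2768 of 6095).
* **Event times**: exact inverse-CDF draws from the truth model's
  conditional law
  $t = \left(a_0^{p} - \log(u)\, e^{-(\alpha + \beta^\top x)}\right)^{1/p}$,
  so simulated event ages follow the specified Weibull law by construction;
  a Kolmogorov–Smirnov test against the closed form guards the
  implementation.
* **Not simulated**: competing non-CVD mortality (mirroring the modelling
  choice of the reference analysis — see Limitations) and secular trends.

What passing tests on these cohorts shows is that the estimation,
prediction and comparison machinery is correct under the stated model; it
does not show that real cohort data satisfy the model (real risk factors
are correlated, hazards need not be Weibull, and censoring is rarely purely
administrative).

## Risk charts

`build_chart()` evaluates one `predict_absolute_risk()` call per cell of a
sex × smoking × age × SBP × marker grid and rounds **half-up** to integer
percent (chart cells are integers by convention; rounding is the only lossy
step, and a test bounds it at 0.5 points). Default axes — ages
{40, 50, 55, 60, 65}, SBP {120, 140, 160, 180}, marker {4,…,8} mmol/L —
are SCORE-chart conventions, not data facts, and are configurable.
`build_stratified_chart()` produces paired charts with a second marker
dichotomized at representative values (defaults 5.2 and 7.0 mmol/L,
configurable; the original choice is unpublished). Rendering supports
long-format CSV (losslessly re-readable via `read_chart()`), fixed-layout
text panels (SBP descending down rows, marker ascending along columns), and
a colour-banded figure.

## Model comparison

All metrics are computed at a fixed horizon $h$ (10 y default; 20 and 30
supported) after classifying each subject as *event* (fatal CVD within $h$
of entry), *event-free at $h$*, or *censored before $h$*.

* **IPCW Brier score**: mean weighted squared error
  $n^{-1}\sum_i w_i (y_i - r_i)^2$ with weights from the Kaplan–Meier
  estimate $G$ of the censoring distribution on the follow-up timescale:
  $1/G(T_i^-)$ for events, $1/G(h^-)$ for horizon survivors, 0 for the
  censored. The uncensored limit (exact equality with plain mean squared
  error) anchors the tests. The censoring KM comes from
  `survival::survfit`; the weighting and scoring are in-package.
* **Cross-validation**: `loocv_brier()` refits with each subject left out
  (`mode = "exact"`, warm-started at the full-data optimum) or by K-fold
  (`mode = "kfold"`, the fast path; K = 10 default). The published metrics
  are labelled cross-validated, so `compare_models()` scores
  cross-validated predictions for Brier, AUC and IDI alike. Whether the
  original leave-one-out refitted the full model per subject or merely
  re-scored is unstated; exact refitting is implemented, with k-fold as the
  approximation.
* **AUC at horizon**: IPCW-weighted probability that an event subject
  outranks an event-free subject, ties counting one half; computed by a
  sort/cumulative-weight sweep and verified against exhaustive pair
  enumeration. A naive unweighted variant is available
  (`weighted = FALSE`) for sensitivity, since the outcome definition behind
  the published AUC (binary end-of-follow-up vs horizon-censoring-aware) is
  not stated.
* **IDI**: difference in discrimination slopes (mean risk among events
  minus mean risk among event-free, censored excluded — a declared
  decision, the source is silent). The standard error uses the paired
  per-subject construction
  $\sqrt{\mathrm{var}(d_E)/n_E + \mathrm{var}(d_{\bar E})/n_{\bar E}}$ on
  the prediction differences $d = r_{new} - r_{old}$, with a two-sided Wald
  p-value.
* **Permutation test for Brier differences**: the paired scheme — each
  subject's two predicted risks are swapped independently with probability
  ½ — with statistic $|B_a - B_b|$ and
  $p = (1 + \#\{\text{null} \ge \text{obs}\})/(B + 1)$; $B = 1999$ by
  default, seed-reproducible. Because the difference statistic is a signed
  per-subject sum, each permutation draw reduces to a sign flip, making the
  null distribution cheap even at cohort scale.
* **External validation**: `external_validate()` applies *fitted
  coefficients* to a second cohort with no refitting, reporting plain
  Brier, AUC, IDI and permutation p — the published external-validation
  block's shape.

## Null-calibration design

Two property checks guard inferential validity. Permutation p-values are
checked for uniformity using 200 replicate cohorts (n = 400) whose two
prediction sets are exchangeable by construction (the true model's risks
perturbed by two independent logit-normal noises of sd 0.3). Wald p-values
are checked under a zero-coefficient truth: the null generator keeps the
published Weibull baselines but removes all covariate effects, with the
intercepts raised by the average removed linear predictor
($\alpha_m = -45.9$, $\alpha_f = -57.0$) so the event yield stays at a
realistic ~9% — otherwise the null cohorts would be too event-poor for the
asymptotic uniformity to be testable at n = 5000. Both checks use fixed
seeds and Kolmogorov–Smirnov tests at the 1% level.

## Problem sizes

The test suite exercises parameter recovery at n = 50,000 (one cohort per
model variant), CI coverage pooled over 7 parameters × 100 cohorts of
n = 5,000, null calibration with 200 replicates at n = 5,000 (Wald) and
n = 400 (permutation), simulator law checks at 100,000 draws per stratum,
and exact leave-one-out at n = 60 against a literal loop. These sizes were
chosen to keep Monte-Carlo error well inside the asserted tolerances while
the full suite stays in the minutes range.

## Known limitations

* **No competing risks.** Non-CVD mortality is neither modelled nor
  simulated; absolute risks are interpretable as risks in the hypothetical
  absence of competing death, consistent with the reference methodology but
  upward-biased as real-world probabilities, especially at high ages.
* **Printed-precision ceiling.** Chart cells from published (rounded)
  coefficients inherit the rounding envelope discussed above.
* **Independent covariates by default** in the generator; real risk-factor
  correlation (age–SBP, glucose–cholesterol) must be supplied explicitly.
* **ICD revision 9** cause codes are rejected with an explicit error; how
  inter-revision deaths were coded in the original registries is unknown,
  so no guess is made.
* The IPCW weighting assumes censoring independent of covariates
  (marginal KM); covariate-dependent censoring would need a censoring
  model, which is out of scope.
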