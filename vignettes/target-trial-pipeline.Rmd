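---
title: "Emulating a target trial from longitudinal EHR data: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Emulating a target trial from longitudinal EHR data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Routine ICU data record who received a treatment, not what would have
happened otherwise. Estimating the effect of a treatment choice — here
modelled on fluid resuscitation with albumin added to crystalloids versus
crystalloids alone, with 28-day mortality as the outcome — therefore
requires emulating the randomized trial one would have liked to run: a
**target trial** defined by its PICOT components (population, intervention,
control, outcome, time zero). Three families of analytic choices can each
silently invalidate the answer:

1. **Study design.** If follow-up starts before treatment can be assigned,
   treated patients must have survived the gap ("immortal time"), biasing
   the treated arm toward survivors.
2. **Identification.** Omitting a variable that drives both treatment and
   outcome (for ICU fluids: illness severity) leaves confounding in place no
   matter how flexible the estimator.
3. **Estimation.** Misspecified outcome or treatment models propagate into
   the effect estimate; doubly robust estimators tolerate one of the two
   being wrong, but not both.

`ehrcausal` implements the full pipeline — synthetic data with known ground
truth, PICOT cohort construction, pre-treatment feature aggregation, four
causal estimators with cross-fitted machine-learning nuisances, vibration
(multiverse) analysis, and conditional-effect estimation — so each of these
failure modes can be demonstrated and measured against the truth.

## Notation and estimands

For covariates $X$, binary treatment $A$ and binary outcome $Y$ with
potential outcomes $Y(1), Y(0)$, the package targets

$$\mathrm{RD} = E[Y(1)] - E[Y(0)], \quad
  \mathrm{RR} = \frac{E[Y(1)]}{E[Y(0)]}, \quad
  \mathrm{OR} = \frac{\mathrm{odds}(E[Y(1)])}{\mathrm{odds}(E[Y(0)])},$$

with the risk difference as the headline scale. The nuisance functions are
the propensity score $e(X) = P(A=1 \mid X)$ and the outcome regressions
$\mu_a(X) = E[Y \mid X, A=a]$ (fit separately per arm: a T-learner), plus
the marginal regression $m(X) = E[Y \mid X]$ for DML.

The estimators in `causal_ate()`:

* **naive**: $\bar Y_1 - \bar Y_0$ — the bias reference, always available.
* **IPW (Hajek)**:
  $\sum_i \frac{A_i Y_i}{\hat e_i} / \sum_i \frac{A_i}{\hat e_i} -
   \sum_i \frac{(1-A_i) Y_i}{1-\hat e_i} / \sum_i \frac{1-A_i}{1-\hat e_i}$.
  Self-normalized weights keep the estimate on $[-1, 1]$, unlike
  Horvitz–Thompson weighting.
* **G-formula (T-learner)**: $\frac1n \sum_i \hat\mu_1(X_i) - \hat\mu_0(X_i)$.
* **AIPW**: the mean of the influence-function pseudo-outcome
  $$\psi_i = \hat\mu_1(X_i) - \hat\mu_0(X_i)
    + \frac{A_i (Y_i - \hat\mu_1(X_i))}{\hat e_i}
    - \frac{(1-A_i)(Y_i - \hat\mu_0(X_i))}{1-\hat e_i}.$$
  Doubly robust: consistent if either $\hat e$ or $(\hat\mu_1, \hat\mu_0)$
  is consistent. $\psi_i$ is retained per patient and feeds the DR-learner.
* **DML**: the slope of $(Y - \hat m(X))$ on $(A - \hat e(X))$ — the
  partially linear model's constant-effect coefficient. The outcome is
  binary, so this is a risk-difference *analogue* under a constant-effect
  working model; no counterfactual arm means (hence no RR/OR) are defined.
  This mirrors how general-purpose DML implementations behave and is
  documented as such.

All nuisances are **cross-fitted** (default $K = 5$, folds stratified on the
arm): each patient's $\hat e, \hat\mu_a, \hat m$ come from models never
trained on their fold, removing own-observation overfitting bias — a
safeguard several off-the-shelf estimator implementations omit. Propensities
are clipped to $[0.01, 0.99]$ by default; clipping beyond 2% of patients
raises a positivity flag in `overlap_diagnostic()`. Confidence intervals are
percentile bootstrap over patient-level resamples with the *entire* pipeline
(nuisance refits included) re-run per resample. The default $B = 50$ keeps
machine-learning pipelines tractable but is coarse for a 95% interval; 200+
is recommended when runtime allows. Searched hyperparameters are reused
across resamples unless `strict_bootstrap = TRUE`.

Nuisance learners are ridge-penalized logistic regression (glmnet) and
probability random forests (ranger). When `search_budget > 0` (default 10
draws, scored by 3-fold cross-validated log-loss inside each training fold),
hyperparameters are chosen by random search over forest depth/trees/leaf
size and a log-uniform ridge penalty on $[10^{-4}, 10]$.

## What the synthetic generator emulates

`simulate_ehr()` produces the four raw tables of an ICU cohort (static,
time-stamped measurements, time-stamped interventions, outcomes) with a
hidden ground-truth sidecar. Its causal skeleton:

* A latent standardized severity $z$ (surfaced as a SOFA-like score,
  mean 6, SD 3.5, plus correlated lactate and weight measurements) raises
  both the odds of receiving the intervention fluid
  (`confounding_strength`, default 0.6 on the log-odds scale) and the odds
  of 28-day death (`severity_mortality_coef`, default 1.0). Emergency
  admission lowers treatment odds (the treated arm ends up ~31% emergency
  vs ~57% in controls) and mildly raises mortality.
* Potential outcomes: $p_0(X)$ is logistic in severity, septic shock, age
  and admission type, calibrated so the marginal untreated 28-day mortality
  matches `baseline_mortality_28d` (default 0.25);
  $p_1 = \mathrm{clip}(p_0 + \mathrm{RD}_{\text{true}} + \text{modifier
  terms}, 0.001, 0.999)$. The risk-difference parameterization matches the
  headline estimand. Default modifiers are zero; experiments use
  protective increments for septic shock, age ≥ 60 and male sex.
* Both potential outcomes are realized from a shared uniform draw, so under
  a null effect $Y(1) \equiv Y(0)$ patient by patient, and the realized
  outcome always equals the assigned arm's potential outcome.
* **Treatment timing.** Treatment is drawn with probability $e(X)$ but
  administered only at a random delay after the follow-up anchor (first
  crystalloid), and only if the patient's latent untreated death time
  exceeds that moment. This coupling is what makes immortal-time bias
  reproducible with a known sign.
* **Time to death.** Among patients who die within 28 days, time to death
  is lognormal (median 100 h among decedents, log-SD 1), truncated to 28
  days and calibrated per patient so $P(\text{death} \le 28\,\mathrm{d})$
  equals the assigned arm's potential-outcome probability exactly. The
  lognormal shape — few hyperacute deaths, bulk on days 2–7 — matches the
  clinical course of sepsis. A constant (exponential) hazard was considered
  and rejected: it ties the probability of death in the first hours to the
  28-day total so rigidly that a realistic mortality level cannot produce
  both a small immortal-time bias at a 24 h eligibility window and the
  pronounced window-dependence seen when eligibility is stretched to 72 h;
  the lognormal shape decouples the two, and is the more realistic model.
* Treated fraction: the treatment-model intercept is calibrated by
  root-finding so the realized treated fraction (after survival gating)
  hits `treated_fraction_target`, default 0.193 — roughly one patient in
  five, the typical share of albumin recipients in sepsis resuscitation
  cohorts.
* Measurements arrive as an admission battery at $t = 0$ plus Poisson
  repeats (default 0.15/h per variable over the first 36 h), with
  completely-at-random missingness (default 25%, matching the typical
  missingness of lactate; admission SOFA is exempt because severity scores
  are computed, not sampled). Drug exposures (vasopressors, ventilation,
  antibiotic classes) are severity-correlated indicators: proxies of $z$,
  not independent causes, so dropping them should cost little — exactly the
  behaviour the confounder-set vibration probes.

What it does **not** emulate: informative missingness or censoring,
time-varying confounding and treatment switching, billing-code selection
effects, multi-level care processes, and free-text signals. Passing tests
on this generator therefore demonstrate that the *estimators and design
machinery* behave as the theory predicts under severity confounding with
known truth — not that any given real-world analysis is unbiased.

## Cohort construction choices

* The eligibility window is half-open, $[t_0, t_0 + W)$: an administration
  exactly at the boundary belongs to the next window.
* Patients who die inside the window before receiving treatment stay in the
  control arm. This is deliberate and must not be "fixed": it is the
  mechanism by which long windows manufacture apparent benefit, which the
  vibration analysis is designed to expose. No grace-period correction is
  applied; the window length is the exposed knob.
* Control patients need at least one anchor (crystalloid) administration;
  patients without an anchor are excluded and counted in the flowchart.
* Patients alive but last seen before `min_followup_h` are excluded; an
  observed death always counts as complete follow-up (excluding early
  deaths would itself create selection bias). Patients alive at last
  contact before the horizon are treated as alive at 28 days — censoring
  is out of scope, and the generator's administrative discharges are
  completely at random.
* Flowchart counts telescope exactly; no patient is dropped silently.

## Aggregation and encoding

Measurements are collapsed patient-wise under four strategies — `first`,
`last`, `first_and_last` (two columns per variable; the default, matching
the main-analysis choice), `mean` — using only events strictly before the
cutoff (follow-up start $t_0$ by default; optionally each patient's own
treatment time, for leakage-sensitivity experiments). Ties at identical
timestamps break by input record order, which the deterministic readers
fix. Numeric missing values are median-imputed on the analysis matrix —
fit once, medians recorded, matching the common impute-once practice and
its known caveats; passing the pre-imputation matrix as
`causal_ate(raw_features = ...)` switches to the statistically stricter
convention of re-fitting the imputation inside every bootstrap resample;
categoricals are one-hot encoded with the reference level dropped to avoid
collinearity in ridge models. Each feature carries a role tag (confounder /
effect modifier / post-treatment / instrumental) and a group tag
(sociodemographic / biology / drugs) that defines the named confounder
subsets: `full`, `no_drugs`, `no_biology`, `sociodemographic_only`.
Admission severity scores enter alongside aggregated repeats, so both
"admission SOFA" and windowed summaries are available to the adjustment
set.

## Vibration analysis

`run_vibration()` sweeps the cartesian product of eligibility windows,
confounder sets, aggregation strategies, estimators and nuisance families.
Per-cell seeds derive from a hash of the cell's provenance plus the
replicate seed, so any single cell can be reproduced in isolation. Cell
failures are recorded with their messages, never aborting the grid; the
default per-cell bootstrap is reduced to $B = 30$ for tractability and
flagged in the output. When ground truth is available a per-cell bias
column is added and the forest plot draws the truth line.

## Heterogeneity (DR-learner)

`estimate_cate()` regresses the per-patient AIPW pseudo-outcomes $\psi_i$
on candidate effect modifiers — a DR-learner, whose validity piggybacks on
the average-effect pipeline. T-learner differences
$\hat\mu_1 - \hat\mu_0$ are accepted as an alternative signal. The final
model is ridge regression by default (near-unpenalized, $\lambda = 10^{-3}$,
appropriate for a handful of binary modifiers and keeping the
population-coherence identity mean($\hat\tau$) = ATE estimate exact up to
numerical tolerance); a random-forest final model is available for
non-additive heterogeneity. The standard modifier set dichotomizes age at
60 years and reports race as white vs non-white — reporting conventions,
both configurable. Quartiles use linear interpolation (R type 7) and
whiskers extend to 1.5 IQR clipped to observed values; these conventions
are recorded because quartile dialects differ across software. Modifiers
tagged post-treatment are refused outright.

A caution inherent to the DR-learner: $\psi_i$ has variance of order
$\sigma^2 / e(X)$, so subgroup contrasts of $\hat\tau$ carry sampling SEs
around $0.014$ on the risk-difference scale even at $n = 20{,}000$ with a
~19% treated fraction. Recovered modifier coefficients should be read with
that resolution in mind: a true increment of $-0.02$ (like the male term
in the recovery experiments) sits barely above the noise floor at these
sizes, while $-0.05$ (septic shock) is comfortably detectable on average
across replicates.

## Problem sizes used by the test and acceptance suites

The statistical checks run on a single CPU, so the suites use the following
analysis sizes, fixed up front as the package's standard experiment
configurations: null-effect recovery and interval coverage with forest
nuisances at $n = 2{,}000$ over 10 seeds ($B = 50$); confounding and
confounder-omission contrasts at $n = 10{,}000$; double robustness,
immortal-time window sweeps and CATE recovery at $n = 20{,}000$ (ridge
nuisances for the window sweeps and CATE, whose conclusions are
estimator-family-insensitive here); full-pipeline coverage at $n = 2{,}000$
over 100 repetitions. Checks on stochastic quantities are asserted on
across-seed means (a bias criterion) rather than per seed wherever a
per-seed assertion would fail with appreciable probability under a perfect
estimator — the per-seed sampling SEs above dictate that reading.

## Known limitations

* Only point exposures: one treatment decision per patient, no switching,
  dosing or duration.
* No censoring model; the alive-at-last-contact convention is only
  defensible because the generator's discharges are random.
* The DML estimate assumes a constant effect on the risk-difference scale;
  under heterogeneity it lands between subgroup effects (weighted by
  treatment-residual variance) rather than at the ATE.
* Percentile bootstrap at $B = 50$ has noticeably granular tails; coverage
  checks use wide tolerance bands for that reason.
* The generator's outcome surface is close to logistic-linear, which makes
  ridge nuisances nearly well-specified; contrasts between nuisance
  families on these data are therefore milder than on real EHR data, and
  relative CI widths across estimator families should not be extrapolated
  from simulation to practice.

## A minimal session

```{r example, eval = FALSE}
library(ehrcausal)

sim <- simulate_ehr(sim_config(n_patients = 5000, seed = 42))
built <- build_cohort(sim$tables, cohort_spec())
built$flowchart

fit <- ate_pipeline(sim$tables, estimator = "aipw",
                    nuisance = nuisance_spec("random_forest", search_budget = 0),
                    B = 50, seed = 1, truth = sim$truth)
summary(fit)

grid <- vibration_grid(windows_h = c(24, 48, 72),
                       confounder_sets = c("full", "sociodemographic_only"),
                       nuisances = "ridge_logistic")
vib <- run_vibration(sim$tables, cohort_spec(), grid, truth = sim$truth)
plot(vib)

cate <- estimate_cate(fit, make_modifiers(fit$cohort))
plot(cate)
```
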