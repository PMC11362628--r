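---
title: "Auditing a pulmonary-exacerbation prediction algorithm for group fairness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a pulmonary-exacerbation prediction algorithm for group fairness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pexfair)
```

## The problem

People with cystic fibrosis (CF) experience recurring acute declines in lung
function — pulmonary exacerbations (PEx). Precision-medicine algorithms
forecast an individual's PEx risk from longitudinal FEV1 percent-predicted
measurements so that care can be intensified before the event. A model that
performs well on average can still perform systematically worse for
subpopulations defined by race or ethnicity, because its predictors (genotype
mix, place-based exposures, visit frequency) are themselves correlated with
group membership.

`pexfair` implements the full audit loop for such an algorithm on synthetic
registry data:

1. **Synthetic registry generation** — cohorts with group-structured
   covariates, irregular visit times, serially correlated FEV1 trajectories,
   and IV-antibiotic episodes.
2. **FIES labeling** — the FEV1-indicated exacerbation signal, a
   rolling-baseline event definition.
3. **Lung function model** — a Gaussian stochastic-process model (fixed
   effects + random intercept/slope + integrated Brownian motion +
   measurement error), with likelihood fitting and conditional forecasting.
4. **PEx probabilities** — Monte Carlo threshold-crossing probabilities of
   the forecast FEV1 path over 3-, 6-, and 12-month horizons.
5. **Fairness evaluation** — pooled ROC and Youden-optimal cutoff, then
   group-specific AUC/sensitivity/specificity with stratified bootstrap
   confidence intervals.
6. **Predictor screening** — per-group summaries and association tests that
   explain *why* performance differs.

## The event definition (FIES)

At each visit the patient's baseline is the mean of the two highest FEV1
values recorded in the preceding 12 months while off IV antibiotics; if only
one valid value exists it is used alone. A visit whose FEV1 sits at least 10
percent-predicted points below this baseline is a PEx. Measurements taken
within 28 days at-or-after a PEx (including the PEx measurement itself) never
re-enter baseline candidate sets, so a depressed post-event value cannot
drag the baseline down. Labeling is a single chronological pass: labels
depend only on the past, a property the test suite checks by truncation and
against a from-scratch quadratic re-computation.

Two threshold readings are supported because the clinical literature mixes
them: a drop of `threshold_value` absolute percent-predicted points
(default, non-strict) and a relative fraction of baseline. The related
rapid-decline flag uses a *strict* drop of more than 10 points from the
window maximum; the differing strictness of the two rules is preserved as
printed in the source definitions.

A labeled visit inside the 28-day exclusion window still receives a PEx
label by default (`exclusion_labeling = "label"`); the alternative
(`"unlabeled"`) is available because the source definition does not say
whether such visits can count as new events.

## The lung function model

For patient $i$ at time $t$ (days since first encounter):

$$y_i(t) = x_i(t)^\top \beta + b_{0i} + b_{1i} t + W_i(t) + \varepsilon_i(t)$$

with $(b_{0i}, b_{1i}) \sim N(0, G)$, $W_i$ integrated Brownian motion with
scale $\sigma_w^2$ (covariance $\sigma_w^2\, \min^2(3\max-\min)/6$), and iid
measurement error $\varepsilon \sim N(0, \sigma_e^2)$. The IBM term makes
serial correlation nonstationary: forecast uncertainty grows like $t^{3}$ in
variance, which is what makes long-horizon prediction honest about its own
degradation.

**Estimation.** Maximum marginal likelihood (REML optional): fixed effects
are profiled out by generalized least squares, variance components are
optimized on an unconstrained scale (log SDs; Cholesky factor of $G$) with
Nelder–Mead restarted from its incumbent until the log-likelihood stops
improving — in five dimensions a single simplex run can collapse early. A
failed Cholesky triggers a documented jitter of $10^{-8}\,\mathrm{tr}(V)/n$
(escalating tenfold up to six times) with a warning.

**Forecasting.** Standard Gaussian conditioning of the joint
(history, future) vector. Forecasts target future *measurements* (the
quantity FIES sees), so $\sigma_e^2$ is included on the future diagonal.
Fixed-effect covariates are frozen at their value at the prediction origin;
no future covariate forecasting is attempted.

**PEx probability.** The probability that the forecast path drops to or
below baseline − 10 at some monthly grid point within the horizon, estimated
by Monte Carlo over the joint conditional normal (default 500 samples, grid
step 30.4375 days). All horizons are evaluated on one set of samples over
the union grid, so estimates are monotone nondecreasing in the horizon by
construction. A single-grid-point call reduces to $\Phi((c-\mu)/\sigma)$,
which the tests exploit as an analytic oracle.

## Calendar conventions

Days are the unit of time throughout: 1 month ≡ 30.4375 days, 12 months ≡
365.25 days, horizons `r paste(round(default_horizons(), 2), collapse = ", ")`
days. The FIES lookback is 365.25 days and the exclusion window 28 days.

## What the generator emulates — and what it does not

Defaults mirror the published structure of a large national CF registry
cohort qualitatively:

* race mix 92.8 / 4.4 / 2.8 % (White / Black / Other), ethnicity
  7.7 / 88.7 / 3.6 % (Hispanic / non-Hispanic / unknown);
* race-conditional F508del genotype mixes (e.g. heterozygous-and-neither
  dominated for Black patients);
* visit rates 5.25 / 4.95 / 5.30 per year by race; Gamma(shape 2) follow-up
  with mean 7.8 years, matching reported follow-up quartiles (3.7 / 7.8 /
  12.4 years) far better than an exponential;
* race-conditional place-based covariates (road densities, deprivation,
  greenspace, distance and binned drive time to the care center) as
  log-/logit-normal around group-specific medians;
* baseline age 6 + Exponential(mean 7) years, reproducing a median near 11.

The generative lung model uses intercept ≈ 105 pp, decline −0.8 pp/year of
age, small genotype/sex/Medicaid effects, intercept SD 10 pp, slope SD
≈ 1.5 pp/year, an IBM scale giving ≈ 0.6 pp forecast SD at one year, and a
residual (visit-to-visit) SD of **6 pp**. The residual SD is the one
deliberately calibrated default: at ≈ 5 visits/year it makes the FIES rule
fire at roughly 1 PEx encounter per patient-year, the rate reported for
real registry cohorts; a 3 pp residual SD yields an unrealistically quiet
cohort (≈ 0.1/year).

Not emulated: real geospatial processes (covariates are scalar draws), true
visit-time dynamics (homogeneous Poisson is an explicit assumption),
treatment effects of IV antibiotics on subsequent FEV1, and covariate
drift within patients (Medicaid, infection status are patient-constant).
Passing tests therefore demonstrate internal correctness and audit
behavior under a plausible data-generating process — not agreement with any
real registry's marginals or its reported AUC.

## The fairness audit

One encounter = one prediction record, matching per-visit evaluation; the
outcome is TRUE if at least one labeled visit in $(t, t+h]$ is a PEx, FALSE
if the window contains labeled visits and none is a PEx, and the record is
dropped (and counted) when no labeled visit confirms either way. An
`exact_date_only` variant adjudicates on the single next labeled visit.
Classification convention: score ≥ cutoff predicts PEx. Youden ties break
to the smallest maximizing threshold. Bootstrap intervals are percentile
intervals from 2000 replicates resampling positives and negatives
separately within the evaluated group; a patient-level cluster bootstrap is
deliberately *not* the default, matching the record-level stratified design
being audited, and within-patient correlation therefore makes the intervals
anti-conservative for clustered records — a known limitation.

```{r audit, eval = FALSE}
cfg <- pipeline_config(sim = sim_config(n_patients = 400), seed = 1)
audit <- run_pipeline(cfg, out_dir = "audit_out")
subset(audit$report, horizon_days == 365.25,
       select = c(group, n, auc, auc_lo, auc_hi, sens, spec, cutoff))
plot_fairness_report(audit$report, "auc")
```

## What an injected noise gap actually does

The generator can inject controlled departures from group exchangeability
(`fairness_gap()`): residual-noise inflation, covariate shift, or visit
sparsity. A structural property of FIES emerged when we studied the
noise-inflation gap at scale, and it is worth stating plainly because it
shapes what the audit can and cannot see:

*FIES self-normalizes residual noise for ranking purposes.* Doubling one
group's residual SD doubles both the spread of its rolling baselines and
the noise in the events those baselines define; the standardized distance
that drives within-group ranking is left roughly unchanged, so the noisy
group's **AUC barely moves** (symmetric 1500–2000-patient runs show
differences within sampling noise, with unstable sign). What the gap does
produce — robustly — is a **calibration failure at the shared cutoff**: the
noisy group's scores and event rates shift upward jointly, so at the pooled
Youden cutoff its sensitivity *rises* and its specificity *collapses* (by
≈ 0.2 at magnitude 2). The audit detects the injected gap through the
equalized-odds panel, not through AUC. The test suite encodes both the
specificity signature (as the robust detection check) and the
AUC/sensitivity-drop expectation (as a study-level check of the stronger
claim, which these study conditions do not bear out for this gap type).

## Problem sizes used by the checks

Chosen once as desk-scale study sizes: FIES oracle equivalence on 1000
random ≤ 50-visit trajectories; parameter recovery on 300 patients × ~20
visits (≈ 3.6-year follow-up), 20 replicates for variance-component
accuracy — the recovery study's generating point uses slope SD ≈ 2.9
pp/year and residual SD 3 pp, a locally identifiable point: with ~20
visits over ≈ 3.6 years, slope variance and the IBM scale share a
likelihood ridge (their covariance shapes, $st$ vs $\min^2(3\max-\min)/6$,
are near-collinear over short windows), and a parameter point where one
term is weak lets the MLE ride the ridge to a boundary with *higher*
likelihood than the truth; bootstrap coverage over 200 binormal
simulations with B = 500;
audit calibration and gap power on 2000-patient symmetric cohorts with
B = 400 and 100 Monte Carlo samples per forecast; the demonstration
pipeline uses 400 patients.

## Known limitations

* Percentile bootstrap CIs ignore within-patient clustering of records
  (see above); the cluster bootstrap option exists but is non-default.
* The visit process is homogeneous Poisson; real registries have
  scheduled-visit periodicity and illness-driven clustering.
* The fixed-effect set exercised in simulation is the identifiable subset
  (age, genotype, sex, Medicaid); the model API accepts any formula over
  patient and encounter columns, but wider designs are untested here.
* FEV1 clipping to [1, 150] is counted, not modeled; kernel-recovery tests
  run in unclipped regimes.
* `sigma_w2` sits near its boundary in cohorts with short follow-up; the
  optimizer's log-scale parameterization keeps it nonnegative but its
  relative error is the largest of the variance components at desk scale.
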