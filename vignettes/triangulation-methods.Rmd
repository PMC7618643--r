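---
title: "Triangulating alcohol and dementia: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triangulating alcohol and dementia: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Observational cohorts routinely show a U-shaped association between
alcohol intake and dementia: nondrinkers and heavy drinkers both have
higher incidence than light drinkers. Two reverse-causation mechanisms can
manufacture the left arm of the U without any protective effect of
drinking:

* **Sick quitters.** People in declining health stop drinking, so the
  current-nondrinker group is enriched for high-frailty individuals whose
  dementia and death hazards are elevated for reasons unrelated to
  alcohol.
* **Prodromal decline.** Drinking falls during the years preceding a
  dementia diagnosis, so intake measured close to diagnosis is lower among
  incipient cases, attenuating harmful associations and flattering
  moderate intake.

`alctri` implements the three analysis legs used to arbitrate between the
causal and reverse-causation readings — conventional survival
epidemiology, longitudinal modelling of drinking trajectories, and linear
plus nonlinear Mendelian randomization (MR) — together with a
synthetic-cohort generator in which both mechanisms and the true causal
dose–response are set by the user. Because the ground truth is known,
every estimator can be checked for calibration, power and the qualitative
triangulation signature: a U-shaped observational fit coexisting with a
monotone genetic dose–response.

## The synthetic cohort generator

`sim_config()` fixes the study conditions; `simulate_cohort()` draws a
cohort from them. The design emulates a large veteran cohort: mean age 65
(SD 8, truncated to 40–90), 90% male, over 90% current drinkers, mean
follow-up 4.3 years, roughly 5% incident dementia and 9% death over
follow-up (the baseline hazards 0.007/yr and 0.012/yr were chosen once to
reproduce those fractions).

* **Genotypes.** `m` independent biallelic SNPs (default 100), dosages
  binomial(2, p) with p uniform on the configured frequency range. No
  linkage disequilibrium — the panel stands for an already-clumped
  instrument set.
* **Exposure.** A hurdle model: latent log-intake is
  `2.0 + 0.25·z(GRS) + 0.3·U + ε`, `ε ~ N(0, 0.7²)`, with `U ~ N(0,1)` the
  latent frailty/confounder; drinkers report `DPW = exp(latent)` (drinker
  median ≈ 7 DPW, heavy tail into the >40 band). Abstention is drawn with
  probability `logistic(logit(0.08) + 1.0·U)`: at the defaults ~8–11%
  abstain and abstainers average ~0.8 SD higher frailty — the sick-quitter
  mechanism. Abstainers are labelled former (rather than never) drinkers
  with probability `logistic(U)`. The genetic score explains ~6% of latent
  variance, at the upper end of what current drinks-per-week instrument
  panels achieve; at desk-scale sample sizes this preserves the
  instrument strength that the million-participant analyses enjoy.
* **Outcomes.** Competing cause-specific exponential hazards given
  covariates: the dementia log-hazard adds the causal curve `h(DPW)`
  (null, linear `c·DPW` with `c = 0.02` by default, threshold, or
  U-shaped), `0.5·U`, and age/sex terms; the death hazard adds `0.5·U` and
  its own age/sex terms but no alcohol effect. The observed time is the
  first of dementia, death, or administrative censoring at 4.3 years.
  Under this structure cause-specific Cox models and the Aalen–Johansen
  estimator are both well specified.
* **Drinking trajectories.** Five AUDIT-C records per participant over the
  nine years before the anchor (diagnosis for cases, last follow-up for
  controls; time coded ≤ 0). The latent points-scale trajectory has a
  baseline level tied to intake, a common decline of 0.10 points/yr, and —
  for cases inside the 3-year prodrome window — an extra decline of 0.42
  points/yr. Scores are observed with noise, rounded and clamped to 0–12;
  nondrinkers are identically 0 at every visit. The prodrome window length
  is not an empirically fixed quantity; 3 years is a design choice within
  the plausible range. The extra slope was calibrated once so that the
  fitted dementia-by-time interaction of the binomial mixed model has
  magnitude ≈ 0.05 on the logit scale at the default design (n = 20,000),
  the working magnitude for this effect. Note the sign: with time coded
  negative before the anchor, a faster decline toward diagnosis makes the
  fitted interaction negative; the magnitude is the meaningful quantity.
* **Enrolment re-measurement.** Cases already inside the prodrome window
  at enrolment report proportionally lower intake than their earliest
  record, with relative decline tied to the prodromal slope. This feeds
  the exposure-timing comparison.
* **Summary statistics.** Per-SNP linear regressions of (log) DPW among
  drinkers and per-SNP logistic regressions of dementia, both adjusted for
  age and sex, emitted in the package's GWAS table dialect. The linear
  scan is computed exactly by Frisch–Waugh residualization; for the
  logistic scan a one-step efficient-score approximation (the standard
  biobank GWAS device) is available and is used inside large simulation
  loops, agreeing with per-SNP maximum likelihood to well within sampling
  error at the effect sizes generated here.

What the generator deliberately omits: linkage disequilibrium, real
ancestry structure (the "principal components" are standard-normal
placeholders), age-varying hazards beyond the included covariate terms,
informative dropout, and measurement error in covariates. Passing tests
on these cohorts therefore demonstrate internal validity of the
estimators under the stated mechanisms, not robustness to every
real-data pathology.

### A scale subtlety

The causal curve is defined per drink per week, while quantity-frequency
GWAS (and the default exposure table) are on the log-DPW scale. On the
log scale the Wald-ratio estimand is `c·E[DPW]`-like, not `c`; recovery
of `c` itself is therefore assessed with exposure statistics on the
identity scale (`generate_summary_stats(..., scale = "identity")`), and
the log-scale IVW is reported per SD of log-DPW, the convention used for
real drinks-per-week analyses.

## Observational stage

Drinks per week are derived from AUDIT-C frequency × quantity midpoints
(`audit_c_to_dpw()`; the midpoint tables are the conventional ones and
overridable, since only the product rule is standard), categorized into
the bands nondrinker, <7 (reference), 7–<14, 14–<22, 22–<40, >40, with
boundary values assigned half-open from below (40 DPW lands in >40;
AUDIT-C 4 is high-risk). `fit_cox()` maximizes the stratified Breslow
partial likelihood via `survival::coxph` — Breslow ties are adequate
because simulated times are continuous — with zero-variance covariates
rejected by name; the default covariate structure includes age, age²,
age³ and an age-by-sex interaction, reflecting the exponential rise of
dementia hazard with age. `schoenfeld_check()` tests the zero-slope
hypothesis of scaled Schoenfeld residuals against untransformed event
time; flagged nuisance covariates are candidates for stratification
(separate baseline hazards) rather than proportional modelling.
Competing risk of death is handled by cause-specific hazards plus the
Aalen–Johansen cumulative incidence (`aalen_johansen()`); a
subdistribution (Fine–Gray) fit is out of scope because in this setting
the cause-specific and subdistribution readings agree closely and the
former is the better-defined estimand under the generator. Pooling
across cohorts uses DerSimonian–Laird random effects
(`meta_analyze()`, via `metafor`). `compare_timing()` refits the
categorical model with the enrolment measurement to quantify prodromal
attenuation. Education and income enter dummy-coded (their coding was a
genuinely open choice; dummy coding avoids imposing linearity across
categories).

## Trajectory stage

`fit_trajectory_model()` treats AUDIT-C as binomial with 12 trials on the
logit scale — the denominator is a modelling choice (the instrument range
is 0–12) and is overridable — with fixed effects for time, dementia
status, baseline risk group, their interactions (including the three-way
dementia × time × risk-group term), demographic covariates, and a random
intercept per participant. The likelihood is maximized with adaptive
Gauss–Hermite quadrature; 15 nodes are the default for final inference,
which is accurate for a single random intercept. Laplace (1 node) and the
fast PIRLS-profiled approximation (`nagq = 0`) give interaction estimates
agreeing to a few percent at a fraction of the cost, and the pipeline and
the large replicate loops use those settings; single interactive fits can
afford the full quadrature. Random slopes and joint
longitudinal–survival modelling are out of scope. `predict_trajectory()`
returns population-average predictions (`12·logistic(x'β)`, random
intercept at zero) for a covariate profile, conventionally a male
participant at average covariates; predictions are bounded in [0, 12] by
construction.

## Linear MR stage

Instruments are selected at p < 5×10⁻⁸ with a documented fallback to
5×10⁻⁵ when nothing passes. `harmonize()` aligns effect alleles between
exposure and outcome tables, flipping swapped pairs and excluding
palindromic variants whose exposure allele frequency lies in
[0.42, 0.58] (the conventional ambiguity window, overridable).
`mr_ivw()` implements inverse-variance weighting with first-order ratio
standard errors (denominator uncertainty ignored — standard at the
instrument strengths generated here, and a documented limitation
otherwise); the default model applies multiplicative random-effects
scaling `max(1, sqrt(Q/df))` whenever Cochran's Q exceeds its degrees of
freedom, matching common practice for large instrument panels. MR-Egger
(`egger()`), Cochran Q with per-variant contributions and leave-one-out
(`cochran_q()`), multivariable MR (`mvmr()`), reverse MR
(`reverse_mr()`) and the binary-exposure doubling-of-prevalence scaling
(`scale_binary_exposure()`, OR per doubling = `exp(β·ln 2)`) complete
the stage. Outlier-removal and sample-overlap corrections are not
reimplemented; the leave-one-out table and Q contributions are the
in-scope diagnostics.

## Nonlinear MR stage

`compute_grs()` builds the weighted allele score (missing dosages
mean-imputed and counted). `doubly_ranked_strata()` implements
doubly-ranked stratification: sort by the instrument (ties broken by a
seeded jitter smaller than half the smallest nonzero gap, so ranks of
distinct values are preserved and runs are reproducible), cut into
pre-strata of K consecutive individuals, rank by exposure within each
pre-stratum, and let stratum j collect the j-th ranked member of each
pre-stratum; an incomplete final pre-stratum is dropped. Assignment
depends on the exposure only through within-pre-stratum ranks, so it is
exactly invariant to monotone exposure transforms — the property that
makes the method robust to instrument–exposure effect heterogeneity.
Nondrinkers enter stratification with exposure 0 (the dose–response is
evaluated down to low intake, and dropping them would break the
partition); a drinkers-only analysis is available by subsetting before
the call.

Within each stratum the localized average causal effect (LACE) is the
ratio of the instrument–outcome association (logistic regression of
dementia on the score — odds ratios are the reporting scale — with a
linear-probability option for simulation loops) to the
instrument–exposure association (linear), both adjusted for age, age²,
sex and the 10 principal-component columns, with first-order standard
error `se(num)/|den|`. Strata with |denominator z| < 2 are flagged as
weak but never dropped — precision is genuinely lower at low doses and
silent dropping would bias the curve.

`fracpoly_fit()` reconstructs the dose–response by inverse-variance
meta-regression of LACE on transformed stratum means. Each LACE
estimates the *derivative* of the log-OR curve at its stratum mean, so
candidate fractional polynomials (powers {−2, −1, −0.5, 0, 0.5, 1, 2, 3},
0 meaning log, as in the established convention; degree-2 candidates use
distinct power pairs — the repeated-power log-augmented bases add
little at five strata) model the derivative; the best-fitting powers
minimize the weighted residual sum of squares, and the chosen
derivative is integrated into a curve anchored at OR = 1 exactly at the
reference exposure (1 drink per week by default), with delta-method
pointwise bands from the fixed-effect meta-regression covariance. A
constant derivative (power 1) reduces algebraically to the IVW-pooled
LACE and a log-linear curve. With `degree = 2` the conventional
fractional-polynomial closed test decides whether the best two-term
model is significantly better (χ², 2 df on the weighted deviance drop)
than the best one-term model; otherwise the one-term curve is reported —
the same logic as reporting "the quadratic model is not preferred over
the linear". `test_nonlinearity_and_trend()` reports the quadratic-term
test of the LACE meta-regression (`p_linearity`) and the zero-slope test
of its linear version (`p_trend`). `negative_control()` regresses age
and sex — which alcohol cannot cause — on the score within each stratum;
systematic non-null associations would indicate confounded instruments
or selection bias. The enrolment DPW measurement is the default
stratification exposure (matching how the nonlinear analysis is
conventionally run), with the earliest measurement available by passing
`exposure=` explicitly.

## Numerical and tie-breaking choices

* Breslow tie handling everywhere in partial likelihoods; simulated times
  are continuous so ties are measure-zero.
* IV ties in stratification broken by seeded uniform jitter below half
  the minimum nonzero gap; exposure ties within pre-strata broken by
  first-occurrence order.
* Weighted least squares solved by QR/Cholesky on the normal equations;
  fixed-effect (known-variance) covariance matrices for meta-regression
  z-tests.
* Candidate fractional polynomials tied on weighted RSS resolve to the
  first in the documented power ordering.
* Degenerate inputs fail loudly: zero-variance covariates, monomorphic
  SNPs, all-zero or all-twelve AUDIT-C outcomes, zero instrument-exposure
  denominators, constant negative controls within a stratum.

## Problem sizes used by the checks

The test suite and the acceptance script exercise the package at the
sizes the design targets: single cohorts of 20,000–50,000 individuals
with 50–100 SNPs; 400 replicates for the size of the nonlinearity test;
200 replicates for IVW coverage and negative-control calibration; 100
replicates for trajectory-interaction recovery; 50 replicates for the
triangulation signature; and 1,000 random instances for the
stratification invariants. These sizes give the binomial bands quoted in
the tests while keeping a full run on one CPU comfortable.

## Known limitations

* First-order LACE and Wald-ratio standard errors understate uncertainty
  when instruments are weak; weak strata are flagged rather than
  corrected.
* The score-approximation GWAS scan is slightly attenuated for large
  per-SNP effects; exact per-SNP likelihood fits are the default outside
  simulation loops.
* One-sample MR on a single simulated cohort inherits mild
  winner's-curse/correlated-error bias; coverage statements in the tests
  account for it by construction (two-sample designs where the estimand
  demands it).
* The generator's abstention process is time-fixed: nobody quits or
  relapses during follow-up, so "former drinker" status is a baseline
  label only.
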