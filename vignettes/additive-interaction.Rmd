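---
title: "Additive interaction between psychosocial stress and low capital: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Additive interaction between psychosocial stress and low capital: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stressemm)
```

## The scientific question

stressemm implements the analytic pipeline of a cross-sectional
effect-measure-modification (EMM) study: does social or economic capital
buffer the association between perceived psychosocial stress and
inadequate oral health? The buffering hypothesis (Cohen & Wills) predicts
that social resources attenuate the health impact of stress, which on the
additive risk scale appears as a departure from additivity of the joint
stress x low-capital effect. The package recodes CCHS-style survey
responses into binary analysis variables, estimates adjusted prevalence
ratios (PRs), computes the relative excess risk due to interaction (RERI)
and the attributable proportion (AP) within age strata, renders
Knol–VanderWeele presentation tables, and verifies published worked
examples.

## Variables and recoding

Each survey response is dichotomized by an explicit partition of its
level set (a `dichotomy_map`): perceived life stress (5 levels; high =
"quite a bit"/"extremely stressful"), sense of belonging (4 levels; low =
somewhat/very weak), living arrangement (8 levels; living alone =
"unattached individual living alone" only), dental insurance (no = 1),
dwelling (rented = 1), and the three outcome components — bleeding gums
(often/sometimes), fair/poor self-rated oral health, persistent oral pain
(often/sometimes). Numeric household income is split at $40,000 per
annum. The published categories are "less than $39,999" and "more than
$40,000", which leaves the interval between undefined; we adopt the
single clean rule *low income iff income < $40,000*, consistent with the
spirit of the published labels. Pre-binned income is accepted as a
two-level category directly, since public-use survey files often ship it
binned.

The outcome is composite: inadequate oral health = at least one of the
three components. `build_analysis_table()` applies listwise deletion
across *all* analysis variables simultaneously, producing one analytic
sample, because all downstream analyses share a single complete-case n.
No imputation is attempted and survey weights are optional pass-through
frequency weights; whether design weights entered the original
regressions is not stated in the source material, so the default is
unweighted.

A named column in the raw data called `household_size` is accepted and
ignored: it is named among the social-capital variables in the source
description but never analyzed, so it is not part of the analysis record.

## The prevalence-ratio model

The source describes "binomial logistic regression" used to estimate
prevalence ratios. A logit-link binomial model yields odds ratios, not
PRs, so `fit_pr_model()` uses the model family that actually produces
PRs: a **log-link binomial GLM**, whose coefficients exponentiate to
prevalence ratios. Log-binomial likelihoods are well known to fail to
converge when fitted risks approach 1; the fitter therefore

1. obtains starting values from a log-link Poisson fit,
2. runs IRLS with a deviance tolerance of 1e-8 and at most 100
   iterations, and
3. on non-convergence (or fitted risks at the boundary) falls back to
   the **modified Poisson** estimator: the log-link Poisson fit with a
   robust (HC0 sandwich) variance.

The method actually used is tagged on every result. On saturated,
covariate-free data both routes reproduce the crude ratio
`crude_pr(a, b, c, d)` to numerical precision, which the test-suite uses
as an oracle on record tables reconstructed from published cell counts.
Wald intervals are computed on the log scale. Reference levels are the
first documented level of each covariate and the unexposed (0) level of
each exposure.

## Joint exposures, RERI and AP

For each capital indicator and age stratum (30–44, 45–59, 60–74),
`joint_prs()` fits **one** model of the outcome on the four-level joint
category — reference (low stress, high capital), `s10` (stress only),
`s01` (low capital only), `s11` (both) — adjusted for sex, education and
country of birth. A single four-level model, rather than three two-level
models, forces the three PRs to share one reference cell, which the
additive contrast requires for coherence:

* RERI = PR11 − PR10 − PR01 + 1 (0 = exact additivity),
* AP = RERI / PR11, reported as "N/A" when RERI < 0, following the
  published convention rather than printing a negative proportion.

The source reports no RERI uncertainty. As package extensions we provide
a **delta-method** interval (default) — gradient
(−exp g10, −exp g01, exp g11) applied to the coefficient covariance —
and a seeded percentile **bootstrap** (999 replicates by default). The
delta SE is validated against brute-force Monte-Carlo propagation in the
tests, and the two intervals are checked for substantial overlap on
synthetic data.

Two rounding modes are supported because the published tables do their
arithmetic on 2-decimal PRs: `"full"` computes RERI/AP from unrounded
estimates; `"as-published"` rounds the PRs to 2 decimals first. The
worked-example verifier always uses printed (2-decimal) values.

### The as-published verifier

`as_published_check()` recomputes RERI and AP from the printed adjusted
PRs of all 15 (indicator, stratum) blocks shipped in
`published_tables()`. A block is flagged when the recomputed RERI
differs from the printed one by more than 0.005 (half a printing unit).
Exactly one block flags: 60–74 sense of belonging, where the printed
line reads 2.36 − 1.65 − 1.40 + 1 = 0.71 although the arithmetic gives
0.31, while the printed AP 30.1% equals 0.71/2.36. The inconsistency is
reported, not resolved — there is no way to know from the publication
which figure was intended. AP agreement is tracked in a separate column
and accepts either rounding or truncation at 1 decimal, because the
published APs are not consistently rounded (e.g. 0.44/2.45 = 17.96%
printed as 17.9%); under that rule one further block (60–74 living
arrangements, printed 12.5% where 0.25/2.10 = 11.9%) carries an AP slip
without being flagged, since its RERI line is internally consistent.

## The synthetic population

Real CCHS microdata are not public, so validation rests on a generator
with closed-form truth. `sim_config()` specifies, per age stratum: the
2×2 stress × low-capital cell probabilities, categorical covariate
distributions, and a log-risk outcome model

    log P(Y = 1) = b0 + b_s·stress + b_m·lowcap + b_sm·stress·lowcap
                   + covariate terms.

Because the link is logarithmic and no covariate–exposure interaction is
modelled, covariates cancel from the PRs: the true adjusted PRs are
exp(b_s), exp(b_m), exp(b_s + b_m + b_sm), so the true RERI is available
without simulation (`truth_from_config()`). Configurations are validated
by enumerating the finite covariate space: any reachable risk above 1 is
an error, never clipped.

The composite outcome is simulated directly and the three components are
drawn afterwards, conditional on the composite, from an
independent-Bernoulli distribution truncated to "at least one present" —
simpler and sufficient, since every analysis uses the composite, and it
guarantees `compose_outcome()` recovers the composite record-by-record.
With `raw = TRUE` the generator emits raw categorical levels (a
high-stress record receives "quite a bit stressful" or "extremely
stressful"; low income is a numeric dollar amount below $40,000), so the
recode module is exercised end to end; the within-side level frequencies
are fixed plausibility constants that never affect the recoded analysis
variables. Missingness is MCAR only, matching a complete-case target
analysis that makes no missingness claims.

Defaults mirror the published study conditions: strata of 8,587 / 8,412
/ 5,730 respondents; 22.2% high stress; per-indicator low-capital
margins (29.1% low belonging, 30.2% living alone, 22.1% low income,
34.1% uninsured, 23.1% renting); per-stratum joint-PR truth echoing the
published sense-of-belonging blocks; baseline risks from the
reconstructed reference cells (0.340 / 0.308 / 0.240). Covariate–outcome
coefficients are unknowable from the publication and are scenario knobs
(small defaults near log 1.05–1.12), not claims about CCHS.

What passing simulation tests show — and do not show: they demonstrate
that the estimators recover known truth under a correctly specified
log-risk model with MCAR missingness and independent covariates. They do
not demonstrate robustness to the complex survey design, informative
missingness, or covariate–exposure interaction, none of which the
generator emulates.

## Validation design and problem sizes

The simulation studies in the test-suite use problem sizes chosen to
make Monte-Carlo error small relative to the tolerances while keeping a
full run in minutes on one CPU:

* **Parameter recovery**: truth (PR10, PR01, PR11) = (1.31, 1.26, 1.79),
  true RERI 0.22; 200 replicates of n = 40,000; the mean RERI estimate
  must fall within ±0.05 of truth and delta-method CI coverage within
  [92%, 98%].
* **Null calibration**: an additive-null scenario (b_sm chosen so that
  risk(s11) = risk(s10) + risk(s01) − risk(ref), true RERI exactly 0)
  and a multiplicative-null scenario (b_sm = 0, true RERI
  (e^{b_s}−1)(e^{b_m}−1)), each 200 replicates of n = 20,000, mean RERI
  within ±0.02 of truth. The multiplicative null is a useful reminder
  that "no interaction on the ratio scale" is *positive* interaction on
  the additive scale.
* **Headline coverage**: the published headline association (PR 1.39) is
  not reproducible without microdata, so it is covered as a property: a
  scenario with true marginal stress PR 1.39 across three strata
  (n = 20,000 total) must cover truth with its estimated 95% CI in at
  least 93% of 200 replicates.

These 200-replicate loops use the generator's analysis-format fast path
(`raw = FALSE`), which draws from the identical risk model while
skipping raw-level emission; the raw → recode → EMM path is verified
separately for exact agreement with the fast path under the same seed.

## Numerical choices and edge cases

* Convergence: deviance tolerance 1e-8, 100 iterations, Poisson starts.
* Degenerate inputs error early and loudly: constant outcome or
  exposure, empty joint cells (named), no complete cases, all-zero cell
  counts, risk-bound violations at config time.
* Output ordering is deterministic (modifier-major, then stratum) and
  all random procedures take explicit seeds; identical configs produce
  byte-identical outputs.
* Rendering: PRs to 2 decimals, RERI to 2 decimals, AP to 1 decimal
  percent; missing cells render as an em dash with a warning; a missing
  AP renders as "N/A" by design and is not a missing cell.

## Known limitations

* No survey-design variance (bootstrap replicate weights, raking) — out
  of scope; intervals assume independent observations.
* No multiplicative-scale interaction test and no synergy index S.
* The delta interval for RERI can be anti-conservative in small strata
  with rare joint cells; the bootstrap is provided for those cases.
* The generator's covariates are mutually independent; confounding
  structure is user-configurable but defaults to mild.
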