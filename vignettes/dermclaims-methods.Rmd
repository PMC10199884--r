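---
title: "Methods: matched-cohort claims analysis and short-term cost-effectiveness of AI skin-cancer triage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: matched-cohort claims analysis and short-term cost-effectiveness of AI skin-cancer triage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dermclaims)
library(data.table)
```

## The problem

When a health insurer gives its insured population free access to a
smartphone app that photographs skin lesions and returns a low/high
skin-cancer risk rating from a convolutional neural network (CNN,
optionally overridden by teledermatologists), what happens to
dermatological healthcare consumption? `dermclaims` implements the full
evaluation pipeline for this question on insurer claims data:

1. **Matching** — app users are matched 1:3 to non-user controls by
   tiered exact matching.
2. **Claims associations** — person-level odds ratios for having at
   least one claim per diagnosis category, with Fisher exact tests,
   two-proportion z-tests, and Benjamini–Hochberg (BH) adjustment.
3. **Costs** — annual dermatological cost per person and mean cost per
   claim, by category and arm.
4. **Cost-effectiveness** — a short-term incremental cost-effectiveness
   ratio (ICER) per additionally detected (pre)malignancy, extended to a
   sensitivity × specificity surface through a calibrated
   detection-cascade model.

Because real insurer claims data cannot be redistributed, the package
ships a first-class synthetic-cohort generator whose defaults emulate
the statistical structure of the reference evaluation (a Dutch insured
population offered the app in 2019: ~19,000 users matched to ~57,000
controls). Every downstream stage is developed and tested against this
generator; the published aggregate tables of the reference cohort are
additionally shipped as plain-text inputs for exact recomputation of
the headline statistics.

## Matching

Matching covariates are age in 10-year bands, sex, socio-economic
status (SES), residential area, a binary (pre)malignancy history over
the four pre-study years, and the comorbidity proxy (number of unique
drug classes, matched as an exact integer). Conventions:

* **Age bands** are anchored at 18–29 and then run in decades
  (30–39, …, 70–79, 80+). Only "10-year intervals" is specified by the
  design; the anchor is configurable via `breaks`.
* **Tiered exactness.** Tier 1 requires equality on all six covariates;
  users short of three tier-1 controls fill remaining slots from tier 2,
  which drops residential area. In the reference cohort 88.3% of users
  matched fully; the synthetic default (60 regions, smooth size decay)
  produces a qualitatively similar tier-1 share in the mid-90s, which is
  sufficient to exercise both tiers.
* **Missing SES matches missing SES** — missingness is treated as a
  category, never imputed.
* **Ties** among eligible controls are broken uniformly at random under
  a seed. Both sides are canonically sorted by person id before any
  draw, so the selection depends on the seed but not on input row order.
* **Partial matches** (1–2 controls) are retained unweighted and
  logged; users with no candidate at either tier are flagged
  `unmatched` and excluded. The reference design does not state its
  policy; retention with logging keeps the person-count analyses
  transparent.
* The **comorbidity count is capped** (default 5) inside the match key;
  exact matching on an unbounded count is infeasible in small pools and
  the distribution is overwhelmingly 0 (median 0, IQR 0–0).

Balance is reported as standardized differences on the matching
covariates. Exact matching at the full ratio forces identical covariate
distributions, so tier-1 standardized differences are exactly zero —
this is asserted, not approximated, in the tests.

## Claims statistics

All category analyses are **person-level**: a person with five nevus
claims counts once. Diagnosis-group analyses cover dermatologist
(secondary/tertiary) claims; primary-care claims enter only the
intervention-volume analysis, mirroring how GP claims are registered as
interventions rather than diagnosis groups.

* **Odds ratio**: sample cross-product ratio `(a·d)/(b·c)`, 95% CI by
  the Woolf log-normal approximation. The reference tables' point
  estimates match the cross-product ratio exactly; their CI bounds
  differ from Woolf by ≤ 0.02, suggesting an unnamed exact/conditional
  variant, so CI assertions use a ±0.02 tolerance. Zero cells fall back
  to the Haldane–Anscombe 0.5 correction with a flag.
* **Fisher's exact test** (two-sided, sum of hypergeometric
  probabilities ≤ the observed table's) via `stats::fisher.test`; the
  test suite verifies it against an independent exhaustive enumeration
  for every 2×2 table with row margins ≤ 25.
* **Two-proportion z-test**: pooled variance, no continuity correction
  by default (the design names only "two proportions z-test"); a
  corrected variant is a switch. A pooled proportion of 0 or 1 yields
  p = 1 with a degeneracy flag.
* **BH adjustment** via `stats::p.adjust(method = "BH")`, verified
  against a quadratic-time step-up reference. Families are one per
  results table (overall associations; intervention rates; each
  subgroup stratum; cost comparisons); the reference design does not
  define families, so this choice is documented rather than inferred.
* **Rates** are claims per 1000 persons (`1000·claims/persons`), the
  volume metric that reconciles exactly with the printed person
  denominators. The printed percentage-of-claims column of the
  intervention table cannot be reconciled with its stated totals
  (e.g. 1913/15,404 ≠ 12.99%) and is deliberately not reproduced.
* **Subgroups**: an assessment is high risk when either the CNN or the
  teledermatologist assigned high risk; users split by ever/never
  high-risk feedback, failed photos ignored; subgroup controls are the
  matched controls of the subgroup's users, preserving matched sets.
  The positive-history subgroup works identically.
* **Rounding** for reported estimates is two decimals, round-half-even
  (R's `round`).

## Costs

Per-person annual cost averages over *all* persons in an arm (zeros
included), per-claim means average over claims. Group comparisons use
Welch's t-test by default — the design says only "unpaired two-sided
t-tests", and with heavily zero-inflated skewed costs the
unequal-variance form is the safer default; a pooled-variance switch
exists. Only secondary/tertiary claims are costed by default, matching
the costing scope of the reference analysis (national cost-registry
prices exist only for hospital claims). Costs are stored as exact
cent-rounded values and written to CSV as two-decimal strings, so
round-trips are lossless.

## The cost-effectiveness model

The ICER is incremental cost over incremental detections, with unique
persons holding a (pre)malignancy claim as the detection proxy. As
printed, the component equations for the "full" and "benign-only"
ICERs have numerators whose terms cancel to the app cost alone; read
literally they would make the two ICERs identical and the benign costs
irrelevant, contradicting the accompanying prose ("also includes the
treatment of the additionally detected (pre)malignancies") and the two
distinct published values. We therefore interpret both numerators as
**arm differences**:

```
icer_full        = (app_cost + dNb·c_b + dNm·c_m) / dNm
icer_benign_only = (app_cost + dNb·c_b) / dNm
```

where `dNm` and `dNb` are per-user incremental (pre)malignancy and
benign/nevus claimants and `c_m`, `c_b` the euro costs per incremental
claimant.

The **surface** comes from a detection-cascade model: per user, the app
evaluates a volume of lesions of which a fraction is truly
(pre)malignant; incremental detections scale with sensitivity,
incremental benign claimants with the false-positive rate:

```
dNm(sens) = v·pi·alpha · sens        dNb(spec) = v·(1-pi)·alpha · (1-spec)
```

The products `v·pi·alpha` and `v·(1-pi)·alpha` (lesion volume ×
prevalence × adherence; only the products are identified) are
calibrated so the model reproduces the observed increments at the
app's published accuracy, sensitivity ≈ 0.87 and specificity ≈ 0.70.
By construction the surface then reproduces the observed-data ICER at
the calibration point to machine precision — asserted at 1e-9 relative
in the tests. Monotonicity (both ICERs strictly decreasing in
sensitivity and specificity whenever the app cost is positive, minimum
at perfect accuracy) follows algebraically and is verified on the full
grid. Overlap between app-triggered and background detection is set to
zero (additivity); this is the model's strongest assumption and is
configurable.

**The app subscription cost was never published.** It is a required
input; the package default of €16.26 per user-year is
reverse-engineered so the calibrated model reproduces the reference
ICER of €2567 at (0.87, 0.70), and is labelled as such wherever it
appears. It is incidentally a plausible consumer subscription price.
Consequently the perfect-accuracy ICERs this package computes (≈ €1703
full, ≈ €992 benign-only from the printed aggregates) are *not*
expected to equal the published €1119/€488 — those depend on
unpublished cost breakdowns — but they reproduce the published
direction and ordering, which is what the tests assert. A documented
derived check: with the app cost set to zero, the printed per-person
cost delta (€21.88) over the printed incremental detection proportion
gives ≈ €1535 per additional detection.

## The synthetic-cohort generator

The generator's defaults are the study conditions; they were fixed
once from the published marginals and are not tuned to test outcomes.

* **Population**: ages normal(48.4, 14) truncated at 18; 53.2% female;
  SES low/middle/high at 23.0/42.6/33.2% (renormalized) with 1.1%
  missing; history prevalence 4.7%; comorbidities negative binomial
  with P(0) ≈ 0.78 matching a 0 (0–0) median (IQR); 60 regions with
  smoothly decaying sizes. Control-pool covariates equal the user
  distributions so exact matches exist; a `covariate_shift` switch
  breaks this to exercise matching-failure paths.
* **Assessment counts** per user: zero-truncated negative binomial with
  truncated mean 64,128/18,960 ≈ 3.38 (only the total is published);
  the default size of 1 (geometric) reflects a long right tail of
  heavy users.
* **CNN outcomes** per photo: 58.5% low risk, 13.2% low risk with
  symptoms (a sub-label of low with no analytic role), 23.5% high
  risk, 4.8% failed. Teledermatologists upgrade 2.8% of CNN-low photos
  and downgrade 33.8% of CNN-high photos; failed photos carry no
  rating. Classification is high risk iff the CNN *or* the
  teledermatologist assigned high risk, so downgrades do not remove
  high-risk status.
* **Within-user correlation.** With independent photos, a per-photo
  high-risk probability of 0.2551 (CNN-high plus upgraded low) and mean
  3.38 photos would make ~50–63% of users ever-high-risk for *any*
  negative-binomial count distribution — numerically bounded well above
  the observed 37.1%. Real users re-photograph the same lesion, so
  outcomes within a user are correlated. The generator therefore draws
  a per-user high-risk propensity from a beta distribution (mean 0.235,
  precision `risk_icc`); the default precision 0.4844 was solved
  numerically, once, so the ever-high-risk share equals 37.1% while the
  per-photo marginal stays 23.5%.
* **Claims**: person-level Bernoulli per category with probabilities
  equal to the published person-count proportions by arm and, for
  users, by risk subgroup (the nevus/benign split within subgroups uses
  the overall 850:267 user split). Claimants hold 1 + Poisson(0.3)
  claims (Poisson(0) for malignant — see below). Costs are log-normal
  (sdlog 0.5), cent-rounded; a distributional choice, since only means
  are published.
* **Cost means**: malignant per-claim means are the published €613.36
  (users) and €520.05 (controls). The remaining categories have no
  published per-claim means; they were derived algebraically so that
  claim probability × claims-per-claimant × per-claim mean reproduces
  each published per-person mean, which also forces the malignant
  claims-per-claimant to 1. The resulting per-person totals land near
  the published €64.97 vs €43.09.
* **Interventions**: GP biopsy/excision and GP teledermatology claims
  are an independent Poisson stream at the published per-person rates;
  Mohs and hospital-excision labels attach to eligible secondary claims
  with probabilities derived from the published volumes.

**What the generator does not emulate**: correlation between covariates
and claim risk (so matching cannot remove confounding here — there is
none to remove), person-level overlap structure between diagnosis
categories beyond independence, within-year claim timing, and
multi-year history dynamics (history is a direct flag, not four years
of simulated claims). Passing tests therefore demonstrate the
*statistical machinery* — matching exactness, estimator correctness,
calibration identities, parameter recovery — not robustness to
confounded real-world data.

## Problem sizes and numerical choices

The analysis scripts and acceptance run simulate 400,000 insurees with
5% uptake, giving ~20,000 users and 1:3 matched controls — the same
arm sizes as the reference cohort at a pool ratio that keeps exact
matching comfortable. The parameter-recovery check generates claims
for fixed arms of 18,960 users and 56,880 controls, with configured
odds ratios {1.3, 2.9, 4.0} at the corresponding published control
prevalences, and requires the estimated OR to fall inside its own 95%
CI in ≥ 90 of 100 seeded replicates. Unit tests run on cohorts of a
few thousand persons. All randomness flows from a single integer seed
recorded in the output manifest; identical config + seed give
byte-identical output tables.

Degenerate inputs are handled explicitly rather than by crashing:
always-failing CNN configurations error after bounded regeneration
attempts; zero contingency cells flag the Haldane correction; a pooled
proportion of 0/1 flags a degenerate z-test; zero incremental
detections make the ICER infinite and flagged; empty cohorts produce
empty, well-typed tables.

## Known limitations

* The claims model is conditionally independent given arm and risk
  subgroup; it cannot generate residual confounding, so the pipeline's
  behaviour under covariate-outcome dependence is untested by design.
* The Woolf CI differs slightly from whatever exact CI the reference
  analysis used; subgroup CI comparisons inherit the ±0.02 tolerance.
* The CEA model is cross-sectional over 12 months with additive
  detection and a point grid — no QALYs, discounting, or probabilistic
  sensitivity analysis.
* Euro values that depend on the unpublished app cost and cost
  breakdown are reproduced in direction and ordering, not in value.
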