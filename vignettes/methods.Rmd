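---
title: "Methods: Mediterranean-diet adherence, psychological distress, and attributable fractions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Mediterranean-diet adherence, psychological distress, and attributable fractions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meddietpaf)
```

## The analysis this package implements

Large pregnancy cohorts ask whether adherence to the Mediterranean diet
(MD) protects against psychological distress in mid-to-late pregnancy.
The analysis chain is: food-frequency questionnaire (FFQ) responses →
daily food-group intakes → MD adherence indices dichotomised into low/high
groups → Kessler-6 (K6) distress outcome → participant exclusions →
single imputation of missing categorical covariates → modified Poisson
risk ratios (RRs) → population attributable fractions (PAFs). Each arrow
is a module here, and a seeded synthetic-cohort generator supplies data
with the statistical structure the chain assumes, because participant-level
cohort data of this kind are access-restricted.

## Exposure scoring

`daily_intake()` is the FFQ identity *frequency/day × portion (g)*.
`total_energy()` reads the energy wording of such questionnaires as
*energy density (kcal/100 g) × amount (g/day)* — the only dimensionally
consistent interpretation. Fruits and nuts form one combined component, so
the 9-component index has exactly nine entries.

Three indices are computed from the same `ComponentIntake` columns:

* **MDS** (0–9): five beneficial food groups plus the MUFA/SFA fat-quality
  ratio score 1 *at or above* the per-component median; meat and dairy
  score 1 *below* it; ethanol in the closed window 5–25 g/day scores 1.
  High adherence is ≥ 5 points.
* **rMED** (0–18): tertile-scored (0/1/2) with olive oil as the fat
  component; meat and dairy reversed; the alcohol window is scored 0/2
  dichotomously (its source definition treats alcohol as a dichotomy, and
  tertiles of a variable that is zero for almost every pregnant participant
  would be degenerate). High adherence is ≥ 11.
* **PMDS** (0–7): the pregnancy variant — no alcohol, no fat ratio, and
  dairy counted as beneficial (calcium requirements rise in pregnancy).
  High adherence is ≥ 4.

**Boundary conventions.** The median rule is explicit ("at or above");
we extend it to tertiles as lower-closed intervals `[0,t1)`, `[t1,t2)`,
`[t2,∞)`, so a value exactly at a bound falls in the upper interval. A
degenerate component with `t1 = t2` therefore puts all mass in the third
tertile, and `derive_cutoffs()` warns when that happens.

**Cutoff provenance.** Reference cutoffs from Mediterranean populations are
not published in reusable form, so the cutoff table is explicit,
first-class configuration: `default_cutoffs()` ships clearly-labelled
illustrative values of plausible magnitude for examples and tests, and
`derive_cutoffs()` recomputes within-sample medians/tertiles (quantile
type 7) for the sensitivity analysis that swaps reference for sample
cutoffs. Sex-specific cutoffs degenerate to a single set in an all-female
cohort; the table deliberately carries one row per component.

A participant missing any component required by an index gets a missing
score with a reason code and is excluded from that index's analyses —
intakes are never imputed.

## Outcome

`score_k6()` sums six 0–4 items into a 0–24 total; distress is total ≥ 13,
with reporting categories ≤4, 5–9, 10–12, ≥13. There is no prorating: any
missing item makes the outcome missing (reason-coded), mirroring the
exclusion-based handling of the studies this emulates.

## Exclusion cascade

`apply_exclusions()` applies, in order: first participation only;
abortion/stillbirth; missing or improbable exposure/outcome data; energy
intake outside a closed plausibility window; history of mental illness.
The window can be supplied (e.g. a published 216.0–3253.9 kcal/day
interval) or recomputed as mean ± 2 sample SDs via `energy_sd_bounds()`;
the bounds are treated as inclusive because published intervals report the
realised bounds, not the rule's openness. "Improbable" has no standard
definition, so it is a user-supplied list of predicates (default none).
Each step is logged (`attrition_log`), attribution is first-match, and the
cascade is idempotent.

## Covariate imputation

`impute_knn()` performs single k-nearest-neighbour imputation of
categorical covariates only (never exposure or outcome). Defaults that the
underlying studies leave unstated are fixed here for determinism: k = 5;
Hamming distance over the other covariate columns with half-weight for
pairs involving a missing value; seeded permutation for distance ties;
factor-level order for modal-vote ties; and a seeded donor-pool cap
(5,000) that keeps the search `O(n_missing × donors)` at cohort scale.
Single imputation understates downstream variance relative to multiple
imputation; that is a deliberate fidelity-to-procedure choice and a known
limitation.

## Risk ratios

`fit_modified_poisson()` implements the log-link Poisson GLM on the binary
outcome by IRLS (deviance tolerance 1e-8, ≤ 100 iterations) and pairs it
with the HC0 sandwich variance (bread = inverse Fisher information, meat =
summed score outer products). At cohort sizes in the tens of thousands the
small-sample HC1 correction is immaterial; it is available behind
`hc = "HC1"`. Dummy coding uses declared reference levels (the high
adherence group is the reference for exposures). The z-quantile is pinned
at 1.959964 for bit-stable intervals. On a saturated binary-exposure model
the estimator reduces analytically to the closed-form 2×2 risk ratio
(`crude_rr_2x2()`), which the tests verify to better than six significant
digits, and coefficients/variances are cross-checked against an
independent GLM + sandwich implementation.

`pearson_chi2()` (no continuity correction) compares distress proportions
between groups; `vif_terms()` reports `1/(1−R²)` per dummy column as the
collinearity diagnostic.

## Attributable fractions

The case-based form is
`PAF% = 100 · Pe · (RR − 1)/RR`, `Pe` = proportion of cases exposed. The
phrase "proportion of cases within each category" that accompanies this
formula in the applied literature is ambiguous; the case-based reading is
the standard one consistent with Miettinen's identity, and the Levin
population-exposure form is available via `paf_point(..., form = "levin")`
for sensitivity analysis. Negative PAFs (protective exposures) are
reported as-is.

**Interval.** Writing the estimate as `g(β, Pe) = 100·Pe·(1−e^{−β})`,
`paf_delta_ci()` propagates, per participant, the sandwich influence of
the coefficient *and* the case-sampling influence of `Pe`, then sums the
squared combined influences. The two ingredients are strongly positively
correlated — both grow when the exposed arm accrues cases — so conditioning
on the observed `Pe` (available via `pe_variance = FALSE`) gives intervals
that are systematically too narrow: in our calibration runs at n = 20,000
the coefficient-only interval covered a true PAF about 84–90% of the time,
while the full influence interval sits at the nominal rate and matches the
closed-form binomial delta on 2×2 counts and the percentile bootstrap
(`paf_bootstrap_ci()`, seeded, degenerate resamples redrawn and counted).
The analytic `β`-gradient is cross-checked against a central finite
difference (relative step 1e-6) on every call. Joint two-exposure models
produce one PAF per exposure from the single fit and reduce exactly to the
single-exposure path when only one exposure is present.

## The synthetic-cohort generator

`generate_cohort()` emulates what the analysis assumes, not any real
questionnaire:

* **Intakes** are independent lognormals per component (no published
  covariance exists to emulate). Energy is Normal(1734.95, 759.475)
  kcal/day — the mean and SD implied by a published ±2 SD plausibility
  window — so about 4.6% of participants fall outside the window, as a
  ±2 SD rule implies.
* **Calibration.** Component log-means sit `qnorm(0.580) × sdlog` above
  their median cutoffs (below, for meat), so each pregnancy-score component
  scores with probability 0.580 and the low-PMDS share —
  Poisson-binomial, computable exactly with `expected_low_pmds_share()` —
  is 0.329. Combined with the default reference-stratum risk of 0.023 and
  default exposure RR of 1.41, the overall distress prevalence is ≈ 2.6%
  and the stratum risks ≈ 3.2%/2.3%: the headline conditions of the
  cohorts this package targets. Olive oil and ethanol emulate a
  non-Mediterranean pregnant population (olive oil median 0.5 g/day; 10%
  drinkers with median 0.8 g/day, putting ≈ 0.3% of the cohort inside the
  5–25 g/day scoring window).
* **Exposure is scored, not flipped:** group labels come from actually
  scoring the simulated intakes, so scoring and regression are
  integration-tested together. A consequence worth knowing: the indices
  share components, so planting an effect for one index induces a diluted
  crude association for the overlapping index — as happens in real cohorts.
* **Outcome** is Bernoulli with
  `log risk = log(baseline) + log(RR)·1[low PMDS] + covariate terms`; a
  stratum whose risk exceeds 1 aborts with the stratum named. K6 items are
  then drawn *consistently with the outcome*: totals for non-cases follow
  the published category shares renormalised among non-cases, cases get
  `13 + Binomial(11, 0.15)`, and totals are split across the six 0–4 items
  by multivariate hypergeometric allocation over the 24 point-slots, which
  enforces the item range and the total exactly.
* **Covariates** are sampled from realistic marginal frequencies; joint
  dependence is not modelled by default. Confounded scenarios are planted
  with `covariate_intake_shift`, which moves beneficial intake log-means
  (and meat, oppositely) for chosen covariate levels, making adherence
  depend on the covariate.

What the generator does **not** emulate: item-level FFQ structure,
within-person correlation of food groups, measurement error, informative
missingness, or the two-wave questionnaire timing. Passing tests therefore
demonstrate correctness of the statistical machinery under the stated
model, not robustness to those real-data features.

## Problem sizes and verification choices

The test suite verifies: exact reproduction of published crude contrasts
from bundled aggregate counts (closed form vs regression path, ≥ 6
significant digits); exhaustive K6 scoring over all 5⁶ item vectors;
brute-force oracle equivalence of the three indices on 1,000 random intake
vectors plus boundary enumeration; 95% CI coverage of the RR and PAF
estimators over 360 synthetic replicates at n = 20,000 with planted RR ∈
{1.0, 1.2, 1.4}; delta-vs-bootstrap agreement (B = 500); and recovery of a
planted conditional RR of 1.17 under planted confounding (30 replicates,
adjusted model, 3 Monte-Carlo-SE tolerance). These sizes keep the whole
suite near a minute while leaving Monte-Carlo error well inside the
asserted bands.

## Known limitations

* Illustrative default cutoffs are synthetic; real analyses must supply
  reference cutoffs or derive within-sample ones.
* Single imputation, no variance inflation for imputation uncertainty.
* Dichotomous exposures only for PAFs (no multi-level attributable-fraction
  decomposition).
* Published adjusted results from restricted cohort data cannot be
  reproduced numerically; they are covered by planted-truth recovery
  instead. Published *crude* PAF values are not reproducible from the
  published counts under the stated formula (the formula evaluates to
  11.9% where 21.6% is printed); the package follows the formula and
  documents the discrepancy rather than matching the printed number.
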