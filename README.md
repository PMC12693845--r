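# meddietpaf

Tools for analysing the association between Mediterranean-diet (MD)
adherence during pregnancy and psychological distress, and for quantifying
how much distress is attributable to low adherence. The package covers the
whole analysis chain of a typical large pregnancy-cohort study of this
question — food-frequency-questionnaire (FFQ) arithmetic, three MD
adherence indices, Kessler-6 (K6) distress scoring, a documented
participant-exclusion cascade, k-nearest-neighbour covariate imputation,
modified Poisson risk-ratio regression, and population attributable
fractions (PAFs) — plus a seeded synthetic-cohort generator so that every
stage is testable end-to-end without restricted cohort data.

## The science in brief

**Exposure.** Daily food-group intakes (g/day) are derived from FFQ
responses as *frequency/day × portion (g)* and scored against per-component
cutoffs:

| Index | Components | Scoring | Range | High adherence |
|-------|-----------|---------|-------|----------------|
| MDS   | vegetables, fruits+nuts, legumes, fish, cereals, MUFA/SFA ratio (beneficial); meat, dairy (detrimental); ethanol 5–25 g/day | 0/1 at the median | 0–9 | ≥ 5 |
| rMED  | as MDS but olive oil replaces the fat ratio | 0/1/2 by tertile; alcohol window worth 2 | 0–18 | ≥ 11 |
| PMDS  | pregnancy variant: no alcohol or fat ratio, dairy beneficial | 0/1 at the median | 0–7 | ≥ 4 |

Boundary conventions: "at or above the median" scores beneficial-positive;
tertile intervals are lower-closed; the ethanol window is closed.

**Outcome.** K6: six items scored 0–4, total 0–24; psychological distress
is a total ≥ 13.

**Risk ratios.** Modified Poisson regression — a log-link Poisson GLM fitted
to the binary outcome by IRLS, paired with a robust (sandwich) variance
`B M B` with bread `B = (Xᵀ W X)⁻¹` and meat `M = Σᵢ (yᵢ−μᵢ)² xᵢxᵢᵀ` — so
exp(coefficients) are risk ratios with valid intervals despite the
misspecified Poisson likelihood.

**Attributable fraction.** The case-based form
`PAF% = 100 · Pe · (RR − 1)/RR`, with `Pe` the proportion of cases in the
exposed (low-adherence) group. Confidence intervals propagate both the
coefficient's sandwich influence and the case-sampling influence of `Pe`
by the delta method (a nonparametric bootstrap is available as a
cross-check).

## Worked example

Aggregate mode — the bundled published aggregate counts reproduce the crude
contrasts through both the closed form and the regression path:

```r
library(meddietpaf)
report <- run_pipeline(pipeline_config(counts = example_distress_counts(),
                                       seed = 1))
report$rr_table[c("score", "rr", "conf_low", "conf_high")]
#> 1 mds    1.10    0.991      1.21
#> 2 rmed   1.10    0.936      1.30
#> 3 pmds   1.41    1.29       1.54
```

The low-PMDS group carries a 41% higher distress risk (95% CI 1.29–1.54);
the MDS and rMED contrasts are compatible with no effect. Evaluating the
case-based PAF formula at the PMDS contrast with `Pe = 847/2071` gives
11.9%.

Participant-level mode on a synthetic cohort, with exclusion cascade,
imputation, crude/adjusted models and delta-method PAFs:

```r
report <- run_pipeline(pipeline_config(
  sim = simulation_config(20000, seed = 42),
  covariates = c("smoking_paternal", "income", "parity"),
  joint_pairs = list(c("pmds", "mds")),
  seed = 42))
report$attrition
#>   energy window: 243.4-3242.5 kcal/day
#>   first_participation_only       20000 ->   18737  (-1263)
#>   abortion_stillbirth            18737 ->   18124  (-613)
#>   missing_or_improbable_data     18124 ->   18124  (-0)
#>   energy_outside_bounds          18124 ->   17229  (-895)
#>   mental_illness_history         17229 ->   16181  (-1048)
report$rr_table[report$rr_table$score == "pmds", c("model", "rr", "conf_low", "conf_high")]
#> 1 crude     1.48     1.23      1.79
#> 2 adjusted  1.48     1.23      1.79
```

(The generator's default conditions plant a true low-PMDS risk ratio of
1.41 with no confounding, so crude and adjusted agree here; the fitted 1.48
is within simulation error of the planted value.)

Fitted objects are first-class: `tidy()`, `glance()` and `autoplot()` work
on model fits, PAF results and reports.

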