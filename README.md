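# tkacea

Patient-level cost-effectiveness analysis of total knee arthroplasty
(TKA), stratified by the four classical Eysenck temperaments.

## The problem

TKA reliably relieves pain from end-stage knee osteoarthritis, but how much
*value per dollar* it delivers varies with the patient: temperament shapes
rehabilitation adherence, symptom reporting, length of stay and outpatient
use. For health-economic screening one wants, per temperament group, the
clinical benefit in quality-adjusted life years (QALYs) and the **marginal
cost-effectiveness ratio**

```
MCER = total direct cost (2018 USD) / QALYs gained      [$ / QALY]
```

`tkacea` implements that analysis end to end for researchers in
health economics and orthopaedic outcomes:

* **EPQ scoring** — 48-item Eysenck Personality Questionnaire sheets →
  four 0–12 subscale scores → temperament quadrant (choleric, sanguine,
  melancholic, phlegmatic), plus Cronbach's α and test–retest ICC
  reliability tools.
* **WOMAC → utility** — the WOMAC osteoarthritis total (0–240,
  higher = worse) maps to a health-state utility `u = 1 − total/240`.
* **QALY engine** — remaining lifespan per patient from a sex-specific
  truncated-Normal model (means 79/75 y, SD 10 y), discounted at 3%/year
  in discrete annual periods, with a 5%-per-decade prosthesis-revision
  adjustment: `QALYs = Δu · D(T) · (1 − f·P_rev(T))`.
* **CEA** — per-patient MCER, per-temperament summaries, and a
  deterministic one-way sensitivity analysis (life expectancy ±5 years,
  prosthesis survival ±3 percentage points, one parameter at a time).
* **Cohort statistics** — chi-square, one-way ANOVA with Tukey HSD,
  uni-/multivariate logistic regression on dichotomized MCER (choleric
  reference), sample-size and reliability calculators.
* **Synthetic cohort generator** — a seeded generator calibrated to the
  published per-temperament summary tables (211 patients: 41/70/46/54), so
  the whole pipeline runs and is tested without any real patient data.

## Worked example

```r
library(tkacea)

# score one EPQ sheet and classify the temperament
key <- epq_default_key()
ans <- ifelse(key$subscale %in% c("E", "N") & key$item %% 3 != 0,
              key$keyed_answer, 1 - key$keyed_answer)
score_epq(ans, key)
#> extroversion  neuroticism psychoticism        lying
#>            8            8            0            0
classify_trait(8, 8)
#> [1] choleric

# full pipeline on the calibrated synthetic cohort
res <- run_pipeline(default_config(seed = 42))
writeLines(format_cea_report(res$base_case))
#> trait        scenario        n       QALYs gained          MCER ($/QALY)
#> choleric     base           41          3.7 (0.9)        4560.0 (1217.1)
#> sanguine     base           70          4.2 (1.0)         3726.1 (870.2)
#> melancholic  base           46          3.9 (0.9)        5358.0 (1375.6)
#> phlegmatic   base           54          3.8 (0.7)        4356.0 (1057.7)
```

Reading it: sanguine patients gain the most QALYs and pay the least per
QALY; melancholic patients pay the most per QALY (driven by their higher
hospital-stay, rehabilitation and outpatient costs). Worsening prosthesis
survival by 3 percentage points raises every group's MCER while preserving
the group ordering:

```r
writeLines(format_cea_report(
  res$sensitivity[res$sensitivity$scenario == "surv_minus3", ]))
#> trait        scenario        n       QALYs gained          MCER ($/QALY)
#> choleric     surv_minus3    41          3.2 (0.7)        5161.4 (1236.4)
#> sanguine     surv_minus3    70          3.7 (0.7)         4271.0 (878.4)
#> melancholic  surv_minus3    46          3.3 (0.7)        6235.6 (1411.2)
#> phlegmatic   surv_minus3    54          3.3 (0.6)        4964.1 (1104.0)
```

The multivariate logistic regression on above-median MCER (choleric as
reference, adjusted for age, sex and BMI) recovers the same picture —
melancholic OR ≫ 1, sanguine OR < 1:

```r
res$logistic_multivariate
#>               term odds_ratio  ci_low ci_high  p_value adjusted
#> 1    traitsanguine      0.330   0.108    1.01  5.2e-02     TRUE
#> 2 traitmelancholic     66.58   12.53   353.93  8.4e-07     TRUE
#> 3  traitphlegmatic      1.64    0.538    5.01  3.8e-01     TRUE
```

With `out_dir =`, `run_pipeline()` writes all tables as CSV plus a JSON
run manifest; identical config + seed give byte-identical outputs. A thin
command-line wrapper lives at `inst/cli/tkacea`
(`tkacea synthesize|run --out-dir DIR [--config FILE] [--seed N]`).

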