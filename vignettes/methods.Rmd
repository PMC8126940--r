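---
title: "Cost-effectiveness of knee arthroplasty by temperament: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-effectiveness of knee arthroplasty by temperament: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tkacea)
```

## The question and the quantities

Total knee arthroplasty (TKA) buys patients a large, lasting improvement in
pain and function, but not equally for everyone: temperament shapes
rehabilitation adherence, symptom reporting and resource use. `tkacea`
implements a patient-level cost-effectiveness analysis of TKA stratified by
the four classical Eysenck temperaments. Its endpoint is the marginal
cost-effectiveness ratio

$$\mathrm{MCER} = \frac{\text{total direct cost (2018 USD)}}{\text{QALYs gained}},$$

computed per patient and then summarized within temperament groups.

## EPQ scoring and the temperament quadrants

The 48-item Eysenck Personality Questionnaire has dichotomous answers and
four 12-item subscales (extroversion, neuroticism, psychoticism, lying); a
subscale score is the count of answers matching the item's keyed direction,
so scores lie in 0–12. The extroversion and neuroticism scores place a
patient in one of four quadrants: choleric (extroverted–unstable), sanguine
(extroverted–stable), melancholic (introverted–unstable), phlegmatic
(introverted–stable).

Two deliberate choices:

* **Item key.** The validated instrument's item wording and keying are
  proprietary; the package ships a structurally correct arbitrary key
  (`epq_default_key()`): 12 items per subscale, alternating keyed
  directions. Everything downstream depends only on subscale scores, so any
  real key can be dropped in as a CSV.
* **Quadrant cutoffs.** Clinical practice assigns quadrants by clinician
  judgment against norms; no numeric rule is canonical. The default is the
  scale midpoint — "extroverted" means E > 6, "unstable" N > 6, strict
  inequalities — with both cutoffs configurable and a cohort-median mode
  (`e_cut = "median"`). Changing a cutoff moves patients only across the
  corresponding boundary, never arbitrarily.

Instrument reliability is supported by `cronbach_alpha()` (with
leave-one-item-out diagnostics) and `icc_test_retest()`, the two-way
mixed-effects absolute-agreement single-measure ICC, flagged acceptable
above 0.75. Both are checked against brute-force variance/ANOVA oracles in
the test suite.

## From WOMAC to utility

WOMAC totals are scored higher-is-worse. The package defaults to the
24-item, 0–10 numeric-rating version (total range 0–240): it is the only
standard variant whose range contains the pre-operative group means around
113–117 that the analysis is calibrated to; the Likert 0–4 variant
(`total_max = 96`) is available by configuration.

Health-state utility is the linear complement

$$u = 1 - \mathrm{total}/\mathrm{total}_{\max},$$

reading the benefit as the percentage of remaining life lived at full
quality. Under this map the utility gain is exactly the WOMAC change score
divided by the range. The map is intentionally the simplest monotone choice
and is isolated in `womac_to_utility()`; a published crosswalk to EQ-5D or
similar can replace it without touching the QALY engine. No such crosswalk
is bundled because none is part of the analysis being reproduced.

## The QALY engine

For a patient of age $a$ and sex $s$, lifespan is
$L \sim \mathcal{N}(\mu_s, \sigma^2)$ truncated below at $a$, with defaults
$\mu_{\text{female}} = 79$, $\mu_{\text{male}} = 75$, $\sigma = 10$ years.
Two modes:

* **Expectation (default, `n_draws_per_patient = 0`).** Remaining years are
  the closed-form conditional mean
  $\mu + \sigma\,\phi(\alpha)/(1-\Phi(\alpha)) - a$, $\alpha = (a-\mu)/\sigma$.
  Deterministic, so pipelines are exactly reproducible and group summaries
  carry no simulation noise.
* **Simulation (`n_draws_per_patient = k`).** $k$ inverse-CDF draws from
  the conditional distribution are averaged. Inverse-CDF sampling (no
  rejection loop) makes draws a pure function of the seed. With growing
  $k$ this converges to the expectation mode.

Discounting uses discrete annual periods, benefit accruing end-of-period,
at 3% per year by default:
$D(T) = \sum_{t=1}^{\lfloor T\rfloor} (1+r)^{-t} + \mathrm{frac}(T)\,(1+r)^{-\lceil T\rceil}.$
The convention (end-of-period, fractional tail discounted one further
period) is stated here because other conventions (continuous, mid-period)
differ by up to ~1.5% at these horizons; the choice is tested against an
explicit year-by-year oracle.

Prosthesis revision is assumed to affect 5% of patients per decade;
compounding gives $P_{\mathrm{rev}}(T) = 1-(1-p)^{T/10}$. QALYs gained are

$$\Delta u \cdot D(T)\cdot\bigl(1 - f\,P_{\mathrm{rev}}(T)\bigr),$$

where $f$ is the fraction of the gain forfeited, in expectation, per unit
revision probability. The analysis being reproduced states that the QALY
loss is "the same" when revision becomes necessary, which we read as
revision-neutral: the base case uses $f = 0$. Inside the one-way
sensitivity analysis $f = 1$ for **all** scenarios including the base
column, so that prosthesis survival is a live parameter; applying $f$ only
to the perturbed scenarios would make *better* survival appear to raise
MCER relative to a revision-neutral base, inverting the direction the
sensitivity analysis is designed to show. Both knobs
(`revision.disutility_fraction`, `sensitivity.disutility_fraction`) are
configuration-exposed.

## MCER and the sensitivity analysis

MCER is computed per patient and then averaged within temperament (the
published dispersion of MCER implies a per-patient distribution; a
ratio-of-means estimator would have none). Patients with non-positive QALY
gain have no defined ratio; they are excluded from group moments and
counted in an `n_undefined` diagnostic rather than silently propagated.

`one_way_sensitivity()` perturbs exactly one parameter per scenario —
rest-of-life expectancy ±5 years, prosthesis survival ±3 percentage points
with the per-decade revision probability clamped to [0.02, 0.08] — holding
the cohort, seed and all other parameters fixed. A scenario touching two
parameters is rejected. Report tables round to one decimal, half away from
zero, matching conventional table formatting; internal arithmetic is full
precision.

## The synthetic cohort generator

`default_cohort_spec()` transcribes the published per-temperament summary
statistics: group sizes 41/70/46/54 (211 analyzed patients), ages
62.3±5.3 / 61.8±6.1 / 60.4±5.7 / 63.2±5.5 truncated to the 46–71
enrollment range, male fractions 63.4/52.9/30.4/51.9%, comorbidity
prevalences, ASA distribution, pre/post WOMAC moments, and the seven cost
components. `generate_cohort()` then draws a full patient-level cohort,
deterministically in the seed, including EPQ sheets whose E/N scores fall
in the assigned quadrant (so scoring and classification round-trip
exactly).

Choices worth knowing:

* **Dispersions.** The published cost and sensitivity tables label their
  parentheses "95% confidence interval", but values like 8432.3 (212.3)
  are impossible as CI half-widths of means at n≈41–70 given the other
  tables' SDs, and patient-level generation needs SDs. All parenthesized
  dispersions are treated as standard deviations.
* **Pre/post correlation.** Pre- and post-operative WOMAC are drawn
  jointly with correlation 0.5 (no correlation is published; 0.5
  reproduces the published change-score SDs of ~8–11 points, and the
  published rows back-solve to correlations 0.33–0.58). Post < pre and the
  instrument range are enforced by resampling; at these parameters the
  constraint binds with probability ≈ 0, so means are not biased.
* **Costs** are drawn independently across components (no covariance is
  published) and truncated at zero; the total is always recomputed as the
  component sum. Note the published component rows sum to the published
  total only for the sanguine group (15081.6); the melancholic components
  sum to ~19524, 2000 above the printed total. The generator trusts
  components, so synthetic melancholic totals sit near the component sum.
* The generator emits the 211 analyzed completers directly; the exclusion
  cascade (232 interviewed → 211) is not modelled.

## What the synthetic cohort does and does not show

Passing tests on this generator demonstrate that the pipeline's arithmetic,
seeding and orderings behave as specified for a cohort with the published
marginal moments. It does not demonstrate fidelity to the real cohort's
joint structure: comorbidities are drawn independently of costs and
outcomes, so regressions on synthetic data recover the temperament effect
(which is built into the cost and WOMAC margins) but not the published
comorbidity odds ratios, which are real-cohort artifacts.

One genuine inconsistency deserves emphasis. Under the stated
life-expectancy model, melancholic patients — the youngest group and the
one with the most women — have the *most* remaining (and discounted)
years, which outweighs their ~8% smaller WOMAC gain. The published QALY
ordering (melancholic lowest) is therefore not derivable from the stated
parameters under any monotone utility map; the published QALY means cannot
be reverse-engineered either. On synthetic cohorts the robust findings are:
sanguine has the highest QALYs and lowest MCER, and melancholic the
highest MCER, in 100% of replicate seeds; choleric vs phlegmatic is a
statistical near-tie (consistent with the published non-significant
choleric–phlegmatic contrast); melancholic QALYs often exceed phlegmatic's,
unlike the published table. The five-scenario sensitivity directions
(longer life or better survival lowers every group's MCER, and conversely)
hold in 100% of seeds.

## Numerical and design notes

* Strict inequalities at quadrant cutoffs; ties (scores equal to the
  cutoff) classify to the introverted/stable side.
* `discounted_years(T, 0) == T` exactly; `revision_prob(10, p) == p`
  exactly.
* Degenerate inputs fail loudly: ages at or beyond mean + 6 SD of lifespan
  (truncation numerically meaningless), zero total-score variance in
  reliability, zero table margins, separation in logistic fits.
* The MCER dichotomization for logistic regression defaults to the cohort
  median and is configurable (`outcome_rule`); no dichotomization rule is
  published, making this the statistics module's loudest caveat.
* The sample-size calculator implements the standard two-mean
  normal-approximation formula; with the published design inputs
  (δ = 500 $/QALY, SD = 250, α = 0.05, power 90%, 20% dropout) it yields 7
  per group, not the published 35 — the published figure is not
  reproducible from its stated inputs.
* Default seed 20180501; every stochastic entry point takes a seed or
  documented RNG-state contract.
* Problem sizes used by the test and acceptance suites: single cohorts of
  n = 211; ordering/direction rates over 100 replicate seeds; oracle
  comparisons on 5×5 matrices; parameter-recovery fits at n = 2000;
  moment checks on 10,000 truncated-normal draws. These sizes give
  Monte-Carlo error well inside the asserted tolerances.

## Limitations

No Markov state-transition structure (by design: the analysis is a
real-world patient-level one), no probabilistic sensitivity analysis or
willingness-to-pay thresholds, no mortality tables beyond the
two-parameter Normal model, no WOMAC→EQ-5D crosswalk, and no attempt to
reproduce real-cohort regression coefficients.
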