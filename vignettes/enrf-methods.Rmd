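---
title: "Nutrient-density scoring for older adults: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nutrient-density scoring for older adults: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enrf)
```

## The scoring model

Nutrient-density scores summarize how much of the nutrients a population
needs a food delivers per unit of energy. The Elderly Nutrient-Rich Food
(E-NRF) family implemented here targets dietary reference values (DRVs) for
European adults over 65. For a food expressed per 100 kcal of edible
portion, the three building blocks are

$$\mathrm{NR}_n = \sum_{i=1}^{n} \min\!\Big(100 \cdot
\frac{\text{nutrient}_i}{\mathrm{RDV}_i},\; 100\Big), \qquad
\mathrm{LIM3} = \sum_{i=1}^{3} 100 \cdot
\frac{\text{nutrient}_i}{\mathrm{MDV}_i}, \qquad
\mathrm{NRF}_{n.3} = \mathrm{NR}_n - \mathrm{LIM3},$$

where the encourage panel of $n$ nutrients varies by model and the limit
panel is fixed at saturated fat, total mono- and disaccharides ("sugar")
and sodium. All nutrients are equally weighted. The registry
(`enrf_models()`) bundles 27 variants: the bare `LIM3`, thirteen
positive-only models from `E-NR5` (protein, fiber, vitamin D, folate,
calcium) through single-micronutrient additions to `E-NR7` (+ potassium,
magnesium) and `E-NR8` (+ PUFA), and their thirteen `E-NRF*.3` full
counterparts. `E-NRF7.3` — seven nutrients to encourage, three to limit —
is the headline variant: in the development work it predicted adherence to
food-based dietary guidelines for older adults best in two independent
cohorts.

Three methodological choices matter and are fixed by design:

* **100-kcal basis.** Scores are per 100 kcal, not per 100 g or per
  serving, because nutrient-to-energy is the original definition of
  nutrient density and validates better than serving-based variants. A
  consequence worth knowing: beverages and watery foods can look extreme
  per 100 kcal, and zero-energy items (water, black coffee) have no
  defined score at all. `score_food_table()` flags them `scoreable =
  FALSE`; they contribute zero 100-kcal units to diet-level scores, so the
  individual score is unaffected.
* **Capping at 100 % DRV.** Each encouraged nutrient's percent of DRV is
  truncated at 100 so that a single heavily fortified nutrient cannot
  dominate — a food at 10× the folate DRV per 100 kcal scores exactly as
  one at 1×. The limit panel is *not* capped by default: the published
  rationale for capping concerns overvaluing positive nutrients, and a
  percent-of-maximum above 100 is meaningful information about a salty or
  sugary food. Because the original analysis does not state whether its
  LIM components were capped, `cap_lim = TRUE` provides the symmetric
  behaviour.
* **Sex handling.** DRVs are sex-specific where the underlying
  recommendations are. Individual diet scores always use the subject's own
  sex. Food-level tables need a single reference and default to the men's
  DRVs (a flag recomputes them for women); the source material does not
  state which set produced its food-group table, so this is a documented
  package choice, not a reproduction claim.

Individual scores are energy-weighted means: with $u_f$ the 100-kcal units
of food $f$ consumed per day,

$$\mathrm{NR}^{\text{subject}} = \frac{\sum_f u_f\,
\mathrm{NR}_f}{\sum_f u_f},$$

and analogously for LIM; the individual NRF is their difference. This
makes the score invariant to splitting consumption rows, to doubling all
amounts, and to the weight basis of the composition table — properties the
test suite asserts. Subjects with computed energy intakes below 500 or
above 3,500 kcal/day are excluded (`exclude_implausible()`, bounds
inclusive: exactly 500 or 3,500 is kept, matching a literal reading of the
stated exclusion rule).

Group-level reporting comes in two distinct flavours: `food_group_means()`
averages *food items* within each of the 23 groups (nutrient density of
the group's foods, unweighted by consumption), while
`group_contributions()` decomposes each subject's weighted score numerator
by group. Because NRF is signed, a group's contribution can be negative or
exceed 100 %; contributions are reported as-is rather than clipped, so they
always sum to 100 % per subject — clipping would silently break that
conservation.

## The NU-AGE adherence index

The NU-AGE index (0–160) measures adherence to European food-based dietary
guidelines for the ageing population with 16 components of 0–10 points.
`nuage_components()` encodes each component as a piecewise-linear score:
zero at or below a lower cut-off, rising linearly to 10 at the recommended
intake, and — for wholegrains, low-fat meat/poultry, sodium and sweets —
falling linearly back to 0 at a cohort-specific upper cut-off, because for
those components more is not better. Weekly guidelines are converted to
g/day (`weekly_to_daily()`, rounded to whole grams as the published
thresholds are): fish 2 × 125 g/week → 36 g/day, legumes 200 g/week →
29 g/day, and so on. The wholegrain window 163–233 g/day combines the
bread guideline (140–210 g/day) with the daily equivalent of two 80 g
portions of wholegrain pasta or rice (23 g/day).

Two components are all-or-nothing: vitamin D supplement use (10 or 0) and
alcohol, with sex-specific limits (≤ 20 g/day for men, ≤ 10 g/day for
women — at the limit still scores 10). The salt row is implemented exactly
as printed: ramp up 0 → 1,500 mg sodium, plateau 1,500–2,000 mg (the 5 g
salt guideline equals 2,000 mg sodium), ramp down to the 85th-percentile
cut-off. The epidemiological oddity that very low sodium scores low is in
the source scoring table; we do not second-guess it, but note it as a known
limitation. Eggs and nuts have no upper penalty (thresholds "> 14 g",
"> 6 g").

**Cohort-dependent cut-offs.** Four upper cut-offs are percentiles of the
cohort's own intake distribution: the maximum (100th percentile) for
wholegrains and meat/poultry, the 85th percentile for sodium and sweets.
`resolve_cutoffs()` computes them by linear interpolation between order
statistics (`stats::quantile` type 7) — percentile dialects differ, so the
choice is stated here and in the docs. The practical consequence: scoring
is invariant to cohort composition for fixed-threshold components and
depends on the cohort only through these four values; re-scoring after
adding a subject can move existing subjects' points only via those four
components (a property test asserts this). To score new subjects against a
frozen reference distribution, pass `cutoffs` explicitly.

**An ambiguity, resolved by choice.** The published footnote for the upper
ramp divides by the "standard upper limit", which cannot reach zero at the
percentile cut-off the same table specifies — the two statements are
dimensionally inconsistent. The default anchors the ramp at the cut-off:
$10\,(\text{cutoff} - \text{intake})/(\text{cutoff} - \text{plateau end})$,
which satisfies both the cut-off rule and the "(10–1)" column label. The
literal footnote formula is selectable (`upper_ramp = "footnote_c"`);
neither is presented as the verified original intent. Similarly, the
"lower range (1–10)" column is implemented as a continuous ramp (points
proportional to distance from the zero cut-off); `integer_points = TRUE`
rounds to whole points for users who read the range as ten discrete bins.

## The evaluation protocol

`evaluate_models()` reproduces the validation design: Spearman rank
correlation between each E-NRF variant and the NU-AGE total, and ordinary
least squares of

$$\text{NU-AGE index} = \beta_0 + \beta_1\,\text{E-NRF score} +
\beta_2\,\text{age} + \beta_3\,\text{sex}$$

with women coded 1. Reported are the unstandardized slope $\beta_1$, the
standardized slope $STB = \beta_1\,\mathrm{SD(score)}/\mathrm{SD(index)}$,
and two explained-variance columns whose exact published definition is not
given: we read "score R²" as the adjusted R² of the index on the score
alone and "model R²" as the adjusted R² of the full model — the reading
under which score R² ≤ model R² almost everywhere, as the published table
shows. Raw (unadjusted) variants are emitted alongside
(`r2_score_raw`, `r2_model_raw`); note that only the raw pair is
guaranteed to be ordered by nesting, which is what the test suite asserts.
Limit-only models (LIM3) are evaluated on the positive LIM scale, matching
the published presentation (positive mean, negative correlation with
adherence). `sensitivity_splits()` refits within men, women, BMI at/below
vs. above the cohort median, and energy at/below vs. above the median;
ties go to the lower stratum, a constant stratifier is dropped from the
covariates, and strata of four or fewer subjects are skipped.

## What the synthetic cohort emulates — and what it does not

Everything in the package runs without survey data via
`simulate_food_table()` and `simulate_cohort()`. The generator's job is
narrow: produce data whose *mechanics* (schemas, degenerate cases,
dependence structure) exercise the scoring pipeline, with marginals
face-valid for a Dutch elderly survey — daily energy 1,964 ± 457 kcal
truncated to the 500–3,500 kcal window, about half men, ages 70–94, BMI
around 27.4 ± 3.8. It does not attempt to reproduce any published cohort
statistic.

A single latent diet-quality factor $q_i \sim N(0,1)$ drives all
dependence, with strength `quality_effect` (default 0.5, a moderate
standardized effect chosen once): it tilts each subject's energy shares
toward vegetables, fruit, fish and legumes and away from sweets, pastry
and fats, and shifts the adherence fractions (wholegrain share of bread,
low-fat shares of dairy/cheese/meat, olive-oil share of fats), supplement
probability, alcohol and questionnaire sodium. This is a deliberate
simplification — no 16-component copula — sufficient for sign and
parameter-recovery testing.

Three design decisions deserve explanation because they were chosen to
make the generator's *null* property exact, not merely approximate. With
`quality_effect = 0` the E-NRF score and the NU-AGE index should be
independent, so that any correlation the evaluation module reports on
null data is a defect, not a generator artifact:

* Nutrient profiles are specified **per 100 kcal** and converted to
  per-100-g amounts by the food's energy density, so a food's per-100-kcal
  score carries no information about its energy density.
* Energy density is drawn once **per group** (log-normally around a
  group-typical value) and shared by the group's foods, while nutrient
  content varies per food. Gram totals per group are then determined by
  energy shares alone, so which foods a subject happens to pick moves the
  E-NRF score but not the component intakes. Real composition tables have
  substantial within-group density variation; this is the main realism the
  generator gives up, and food-level scoring does not depend on it.
* Alcohol intakes are drawn with **sex-specific medians scaled to the
  sex-specific limits** (13 g men, 6.5 g women), mimicking the large
  male–female alcohol gap in elderly surveys. A sex-neutral draw would
  let the sex-specific alcohol limits and the sex-specific DRV
  denominators manufacture a spurious correlation between the two indices
  on null data.

Component intakes for vegetables, fruits, legumes, fish and eggs are the
exact gram sums of the corresponding diet-record groups (the two
representations are consistent where they describe the same foods); the
remaining components are latent-quality-linked draws with independent
noise (`noise_sd`, default 0.5 on the logit scale). One zero-energy food
(water) is always present to exercise the degenerate path, and it counts
toward the fluid component.

What passing tests on this generator shows: the scoring algebra, index
construction, exclusion rules and evaluation statistics are correct, and
the pipeline recovers a known dependence structure with the right sign and
approximate magnitude. What it does not show: behaviour on real
composition data with sparse nutrient coverage, correlated measurement
error, or within-group density extremes — validation against real survey
data remains the user's task.

## Numerical choices and degenerate inputs

* Internal computation is in full double precision; only written reports
  round (1 decimal for scores, with a `_full.csv` companion at full
  precision).
* Missing nutrient cells are scored as 0 with a warning count — the
  conservative convention for sparse composition tables.
* Zero-energy foods: flagged, excluded from food-level tables, zero weight
  in diet scores.
* A subject whose total weighted score is exactly zero has undefined group
  contributions and is flagged rather than imputed.
* Percentile rules require a cohort of at least 2; regression requires at
  least 4 complete cases and refuses rank-deficient designs.
* Median-split ties go to the lower stratum; energy-window bounds are
  inclusive.

## Problem sizes used in the checks

The bundled checks run at sizes chosen to make Monte-Carlo error small
relative to the asserted effects while staying quick on one CPU: oracle
equivalence on 1,000 random foods; conservation and contribution checks on
a 200-subject cohort; gradient recovery on 2,000 subjects; and the null
(zero-gradient) check on 10,000 subjects, where the Spearman correlation's
sampling error is about 0.01 so the asserted |ρ| < 0.05 band is five
standard errors wide.

## Known limitations

* DRVs are population reference values; no age-stratified or personalized
  requirements, and no upper-limit (UL) handling.
* Zinc DRVs assume mixed diets with 600 mg phytate; other phytate levels
  are not implemented.
* The sugar component uses *total* mono- and disaccharides (added sugars
  are typically unavailable in composition tables).
* The mapping from foods to NU-AGE components (what counts as wholegrain,
  low-fat, olive oil) is not derivable from nutrient composition and must
  be supplied by the user; the package consumes a prepared component
  intake table.
* Supplements contribute only through the vitamin D component of the
  NU-AGE index, never to E-NRF scores.
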