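---
title: "Plant-based diet quality indices, CKD classification and replicate-weight inference"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Plant-based diet quality indices, CKD classification and replicate-weight inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Plant-based diet quality indices summarise how much of a diet comes from
plants and how healthy those plant choices are. Three companion scores are in
common use: the overall plant-based diet index (PDI) rewards all plant intake
and penalises animal intake; the healthy index (hPDI) rewards healthy plant
foods (whole grains, fruits, vegetables, nuts and seeds, legumes, unsaturated
plant oils, tea and coffee) and penalises everything else; the unhealthy index
(uPDI) rewards unhealthy plant foods (refined grains, fruit juices, saturated
plant fats, added sugars, miscellaneous plant products) and penalises
everything else. `plantdex` implements an ingredient-level variant of these
indices designed for national 24-hour-recall surveys, and the downstream
epidemiological analysis: rule-based chronic kidney disease (CKD)
classification and survey-weighted regression with replicate-weight variance.

Because the national survey microdata this design targets are
access-restricted, the package ships a synthetic cohort generator that
emulates their record structure. Everything downstream of the generator is
the real analysis machinery; the generator exists so the pipeline can be
exercised, calibrated and stress-tested end to end without restricted data.

## The scoring model

Intakes are decomposed to the ingredient level: every consumed food, beverage
or mixed dish is split by a food-composition table into mass fractions over
23 food groups (7 healthy plant, 5 unhealthy plant, 11 animal). Each food
additionally carries a *context* — core (foods from the five recommended food
groups) or discretionary (energy-dense, nutrient-poor products) — which is a
property of the parent product: the fruit inside a discretionary cake counts
as fruit consumed in the discretionary context. This yields 46 scoring units
(23 groups x 2 contexts) of grams/day, averaged over the two recall days.

Each unit's two-day mean intake is ranked into quintiles of the
survey-weighted consumption distribution of the analysis sample (zeros
included), scoring 1 (lowest quintile) to 5 (highest). Units the index
rewards enter positively; units it penalises enter reversed (6 − s). Context
modulates the weight of the signature categories:

* PDI: all 46 units weight 1; plant positive, animal reverse. Totals in
  [46, 230].
* hPDI: healthy-plant units positive with weight 2 in core and 1 in
  discretionary (a top-quintile healthy plant group scores 10 from core
  foods, 5 from discretionary); all other units reverse with weight 1.
  53 weight units; totals in [53, 265].
* uPDI: unhealthy-plant units positive with weight 2 in discretionary and 1
  in core; all other units reverse with weight 1. 51 weight units; totals in
  [51, 255].

These weights are the unique {1, 2} assignment consistent with the documented
theoretical ranges of the three indices and with the 10/5 core/discretionary
example for the hPDI, which is how the scoring matrix was reconstructed.
`score_ranges()` derives the bounds from the matrix rather than hard-coding
them, and `extreme_intake_cohort()` builds adversarial cohorts that realise
each bound through the actual cutpoint and scoring engine.

### Numerical choices in quintile assignment

The weighted quantile is the inverse weighted ECDF of "lower" type: the cut
for probability p is the smallest observed value whose cumulative weight
share reaches p. This is exactly reproducible (no interpolation rule to
disagree about), invariant to weight rescaling, and reduces to the unweighted
lower empirical quantile under equal weights. Bins are half-open upwards
(intake equal to a cut takes the lower quintile), so in the common
zero-heavy case — episodically consumed groups such as legumes or fish, where
20% or more of the weighted mass sits at zero — every zero consumer lands in
quintile 1 deterministically. Quintiles are computed per scoring unit
(group x context), once, on the post-exclusion analysis sample, using the
calibration weights; this is the only definition that yields 46 scoring
units for the PDI.

## Derived nutrient metrics

The potential renal acid load (PRAL, mEq/d) uses the established linear
formula 0.49·protein(g) + 0.037·phosphorus(mg) − 0.021·potassium(mg) −
0.026·magnesium(mg) − 0.013·calcium(mg); "phosphate" in the original
formulation is dietary phosphorus in mg/d. The protein-to-fibre ratio guards
against recalls with fibre below 0.1 g/d: those produce a flagged NA rather
than a numerically absurd ratio, and are excluded from ratio summaries.

## Outcome classification rules

* CKD: eGFR < 60 ml/min/1.73m² is stages 3–5 (moderate-severe) regardless of
  albuminuria; eGFR ≥ 60 with albuminuria is stages 1–2; otherwise no CKD.
  eGFR exactly 60 is read as "not less than 60". The albuminuria ACR cut-off
  is not part of the published rule set, so it is a configurable parameter
  defaulting to the Australian survey convention of ≥ 2.5 mg/mmol (males) and
  ≥ 3.5 mg/mmol (females).
* Blood pressure: the acquisition protocol takes a third reading when the
  first two differ by more than 10 mmHg on either scale; the analysis value
  is the second reading, or the mean of the second and third when a third
  exists. The first reading is never used. Hypertension is systolic ≥ 140 or
  diastolic ≥ 90 mmHg.
* Diabetes risk: HbA1c < 6% normal, 6–6.4% at risk, ≥ 6.5% diabetes.
* BMI is Quetelet's kg/m².

## Exclusions

Participants are removed sequentially, each counted at the first rule that
removes them: age under 18; only one 24-h recall; suspected energy
under-reporting (two-day mean energy below 800 kcal/d ≡ 3347.2 kJ/d for men,
500 kcal/d ≡ 2092.0 kJ/d for women; 1 kcal = 4.184 kJ); and missing data in
any analysis variable.

## Survey inference

The design carries one calibration weight and R replicate weight sets per
participant (default R = 60, the delete-a-group jackknife layout of the
target survey). Any estimator θ gets variance f·Σ_r (θ_r − θ)² with
f = (R−1)/R, re-computing θ under each replicate weight set — including full
model refits for regression coefficients. Point estimates use weighted least
squares (linear) or weighted maximum likelihood via IRLS (logistic; deviance
tolerance 1e-8, at most 100 iterations, replicate refits warm-started at the
full-sample solution). Confidence intervals are normal-approximation
(± 1.96 se) and p-values are two-sided normal, the standard convention for
replicate-weight estimators. Right-skewed outcomes (HDL, TAG, glucose,
HbA1c, systolic BP, waist circumference, BMI) are modelled on the natural
log scale.

The model ladder: Model 1 adjusts for age and sex; Model 2 adds education,
physical activity and smoking; Model 3 adds BMI; Model 4 adds energy and
alcohol instead; Model 5 adds both. The fully adjusted CKD logistic model
("fig2") adjusts for age, sex, energy intake, education, physical activity,
smoking, diabetes, hypertension, BMI and alcohol intake. Adiposity outcomes
(BMI, waist circumference) are never adjusted for BMI. Diet index exposures
enter as continuous per-unit scores, so logistic coefficients exponentiate
to odds ratios per score point.

Trend tests across total-score quintiles use the ordinal quintile index
1–5 as a numeric term (quintile medians are a reasonable alternative; the
ordinal index was chosen as the simpler, equally conventional option and the
median variant can be had by passing medians as the trend variable).
Categorical comparisons use Pearson's χ² on the weighted contingency table
rescaled to the sample size, divided by the Kish design effect 1 + CV²(w) as
a first-order design correction — with equal weights this is exactly the
textbook statistic. Pairwise quintile contrasts use the Bonferroni threshold
0.05/10 = 0.005.

## The synthetic cohort generator

`generate_cohort()` draws, per participant: demographics; a latent diet
"healthfulness" trait h ~ N(0,1); zero-inflated log-normal intakes for each
of the 46 units over two independent recall days, with loadings on h that
make healthy-core intakes rise and unhealthy/discretionary intakes fall as h
rises; nutrient profiles derived from the intakes through a per-gram
composition matrix plus log-normal noise (so the uPDI is negatively
correlated with fibre, magnesium and potassium, as expected of real diets);
anthropometry, 2–3 blood-pressure readings (third reading emitted exactly
when the protocol demands one), HbA1c and blood lipids within physiological
ranges; and a log-normal calibration weight with delete-a-group replicate
weights assigned round-robin.

CKD status is injected on the *true* uPDI — scored internally from the
generated intakes with the cohort's own weighted quintiles, i.e. through the
same scoring engine the analysis uses — so parameter recovery is a genuine
end-to-end test of decomposition, averaging, cutpoints, scoring,
classification and survey fitting. The probability of moderate-severe CKD
follows a logistic model with slope ln(1.037) per uPDI point plus modest,
configurable covariate effects (age, sex, diabetes, hypertension, BMI,
current smoking); the intercept is solved numerically so the marginal
moderate-severe prevalence is 103/2060, and stage 1–2 CKD (albuminuria with
preserved eGFR) gets the constant probability that brings total CKD
prevalence to 250/2060. eGFR and ACR are then drawn consistently with the
assigned stage. Defaults: n = 2060, any-CKD prevalence 250/2060 with 41.2%
moderate-severe, intake scales set so mean energy is ≈ 9.5 MJ/d — the
magnitude typical of adult national nutrition surveys — and comfortably
above the under-reporting cut-offs, so the default cohort passes exclusions
intact and the injected effect is not attenuated by sample churn.

What the generator does **not** emulate: household clustering, seasonality
or weekday effects of recalls, correlated day-to-day consumption patterns,
calibration of weights to population benchmarks, item non-response, and any
realistic nutrient-composition detail beyond the order-of-magnitude per-gram
coefficients. Passing tests therefore demonstrate that the pipeline
faithfully measures what the generator encodes — unbiased effect recovery and
honest variance under a correctly specified design — not that it would
reproduce any particular real-survey estimate.

## What the test suite computes

The suite verifies the scoring engine against a brute-force weighted-ECDF
enumeration oracle on small cohorts; the replicate variance against a naive
jackknife loop; survey fits against OLS and unweighted MLE under equal
weights; the PRAL formula against hand-computed values; and mass
conservation of decomposition under randomised inputs. At the study scale it
runs 200 default cohorts (n = 2060) through the full pipeline, checking that
mean CKD counts hit their calibration targets within Monte-Carlo error, that
the mean fitted uPDI log odds ratio recovers ln(1.037) within Monte-Carlo
error, and that the 95% CIs cover the injected effect between 92% and 98% of
the time; the trend test's type-I error is checked at nominal level over
1000 simulated null datasets (n = 300). These problem sizes were chosen to
make Monte-Carlo error small relative to the effects being checked while
keeping the default test run fast.

## Known limitations

* The two unlabelled animal food groups are placeholders; analyses that
  interpret individual animal groups should supply their own taxonomy via
  `food_groups()`.
* The stage 1–2 CKD probability is constant across participants in the
  generator; only the moderate-severe stage carries the injected diet
  effect.
* Replicate-weight p-values use the normal approximation; with few replicate
  groups a t reference with R − 1 degrees of freedom would be slightly more
  conservative.
* The categorical test's design correction is first-order (Kish design
  effect), not a full Rao–Scott second-order correction.
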