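---
title: "Methods: the RISC II score, its development machinery, and the synthetic registry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the RISC II score, its development machinery, and the synthetic registry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riscii)
```

## The model and its assumptions

RISC II predicts hospital mortality of severely injured patients from 13
clinical variables observed at or before admission. It is a purely additive
categorical score: every predictor is cut into clinically motivated
categories, each category carries a fixed contribution, and the total

$$X = \beta_0 + \sum_v \beta_{v,\,c_v(\text{patient})}$$

is mapped to a survival probability by the logistic function
$P(\text{survival}) = 1/(1+e^{-X})$. The additive, category-based form
deliberately trades detail for robustness: admission measurements are noisy,
and categories are insensitive to measurement error in a way continuous
transforms are not. No interaction terms are used.

The central design decision is the handling of missing data. Instead of
imputation or case exclusion, *missing* is a first-class category of every
predictor, and it is made the **reference** category, so its contribution is
zero by construction: an unrecorded value leaves the prognosis unchanged.
This is only defensible when patients with a missing value are
prognostically similar to the average patient, which is why
`reference_group_coverage_check()` verifies that mortality in each
reference group is compatible (Wilson interval) with overall mortality.
Age and injury codes are compulsory; a record with neither cannot be scored
meaningfully and is excluded upstream.

`risc2_model()` carries both the published rounded score points (the score
as users apply it) and the full regression coefficients. Six cells of the
printed table are mutually inconsistent — the rounded point or the
published odds ratio does not match the printed coefficient. These are
preserved verbatim and frozen in `published_model_exceptions()`; the
`audit_model_spec()` function recomputes the discrepancy list at any time.
One consequence worth knowing: because of those score-point inconsistencies
the gap between points mode and coefficients mode can reach ~0.7 in the
worst case (the sum of per-variable |point − coefficient| maxima), not the
~0.05-per-variable one would expect from rounding alone. Tests assert the
bound computed from the table itself.

A second consequence of the published category structure: a patient with
*every* variable at its reference cannot exist. The worst-injury reference
is severity 2, but then the second-worst injury (≤ 2) falls into its
"0-2" category, which carries +0.2 — a minor second injury marks the
absence of serious multiple trauma and improves the prognosis. The minimal
realistic score is therefore 3.8, not the 3.6 constant.

## Categorization conventions

Printed category labels are integer-styled ("90-110", "111-150"); they are
implemented as half-open real intervals so that every real input is
assigned:

| variable | intervals (left-closed) |
|---|---|
| systolic BP (mmHg) | [0,90), [90,111) ref, [111,151), [151,∞) |
| INR | (0,1.20), [1.20,1.40), [1.40,2.40) ref, [2.40,∞) |
| haemoglobin (g/dl) | [12,∞), [7,12) ref, [0,7) |
| base deficit (mEq/l) | (−∞,6), [6,9) ref, [9,15), [15,∞) |
| age (completed years) | 1-5, 6-10, 11-54 ref, five-year bands, 85+ |

Notes:

* Blood pressure ">150" carries 0 points but is *not* the reference: it is
  reported under its own label, and its zero effect is a property of the
  published fit, not of missingness.
* Base deficit is stored as a deficit (positive = acidotic). Base-excess
  input is accepted by the reader behind an explicit `base_excess = TRUE`
  flag and negated — a value of −2 mEq/l deficit (i.e. mild alkalosis)
  falls in the protective "<6.0" category.
* Motor function derives from the GCS motor component (6 → normal, 4-5 →
  directed = reference, 2-3 → non-directed, 1 → none).
* "Head" means the head/neck ISS body region; face is separate. The
  second-worst injury may share a region with the worst (severity levels,
  not regions, are what the model uses); with a single coded injury the
  second-worst severity is 0.
* Any AIS severity 6 caps ISS and NISS at 75, while the worst-injury
  predictor keeps its own severity-6 category.
* Records whose worst injury is below severity 2 are outside the score's
  intended population (the inclusion cascade removes them); if scored
  anyway they are treated as worst-injury reference.

The inclusion cascade applies, in a fixed first-match-wins order: transfers
in (admission status unknown), early transfers out (outcome unknown), worst
injury ≤ AIS 1 (equivalently ISS < 4), and age recorded as zero (a known
registry data-entry artefact — whether true infants under one year should
ever be scored is an open clinical question; the cascade simply removes
age 0). The count partition is order-dependent but the included set is not.

## Development methodology

`fit_missing_as_reference()` re-derives a RISC II-type model by maximum
likelihood logistic regression with *survival* as the outcome (positive
coefficients protective, matching the published sign convention), each
variable dummy-coded against its missing/reference category.
Supporting operations:

* `enforce_reference_fraction()` — coefficient stability depends on the
  size of the reference group, so during model building variables with
  fewer than 20% missing values have randomly selected observed cases
  reassigned to the reference until its share first reaches the target
  ("about 20%" is implemented as first crossing of ≥ target via seeded
  uniform sampling without replacement, for reproducibility). The target
  applies to the whole reference category (missing plus the co-reference
  observed level); this reading of the rule is an assumption. Deletion is
  strictly a model-building device: scoring always uses all available data.
* `nagelkerke_r2()` — the normalized likelihood-ratio association measure
  used to drive `forward_select()`, which starts from the basic model (age
  plus the three injury-severity items) and greedily adds the candidate
  with the largest improvement. The stopping rule is unstated in the
  original description; the default minimum improvement is 0.002,
  configurable.
* `merge_weak_categories()` — "no or only minor effect" is operationalized
  as Wald p ≥ 0.05 (configurable); such categories merge into the
  reference, and a variable reduced to its reference alone is dropped.
* Complete separation or non-convergence raises a diagnostic naming the
  suspect categories rather than returning unstable estimates; empty
  categories are merged into the reference with a warning. With rare,
  strongly protective categories (children aged 1-5) separation is expected
  at cohort sizes below roughly 10⁴ — the category may contain no deaths.

## The synthetic registry

`simulation_config()` / `generate_cohort()` emulate a registry so every
operation is testable without patient data. Generation is category-first:
the true category of each variable is drawn from configured prevalences,
then a raw value is drawn uniformly within that category's interval
(open-ended intervals use declared truncation ranges, e.g. base deficit
[15, 30)). The injury list is assembled so that the drawn worst,
second-worst, and head severities are exactly reproduced by
re-categorization. The true score $X$ uses the generating model's full
coefficients; death is Bernoulli$(1-\text{logistic}(X))$; masking is
applied *after* the outcome is drawn, at per-variable rates, so missingness
is non-informative by construction.

Default prevalences were fixed once to resemble a contemporary western
European blunt-trauma registry population — median age 47, ~72% male, ~95%
blunt mechanism, mean ISS around 20, observed mortality around 10-11% —
and per-variable missingness rates mirror documentation practice (pupil
assessments missing in over half of cases, base deficit in just under
half, sex in under 1%).

What the generator deliberately does **not** emulate: correlation between
covariates (a hypotensive, coagulopathic patient is not made more likely to
have severe anatomical injury), hospital-level clustering, informative
missingness, and AIS codebook structure (severity + region are the
interface). Two consequences matter when reading test results:

* Discrimination of the score on synthetic cohorts (AUC ≈ 0.86 at the
  defaults) is *below* what registries report (≈ 0.95), because independent
  covariates give the score less concentrated risk; this is a property of
  the simulation, not of the implementation.
* Refitting on synthetic data recovers coefficients only approximately.
  The outcome is generated from the *pre-masking* values, so the fit sees
  reference groups contaminated with masked cases whose true contributions
  are nonzero; estimates of strongly prognostic, frequently masked
  variables are attenuated. At n = 30,000 about 90% of non-reference
  coefficients fall inside their own 95% CIs — adequate for methodology
  testing, but coverage is not nominal and should not be read as a bias-free
  recovery guarantee. (Generating the outcome from post-masking values —
  the score's own missing-as-zero semantics — would make the fitted model
  correctly specified; the pre-masking convention was kept because it is
  the cleaner definition of non-informative missingness.)

## Evaluation metrics

Following standard trauma-score practice, three dimensions:

* **Discrimination** — `auc_with_ci()`: probability a random non-survivor
  outranks a random survivor (ties ½), i.e. the area under the ROC curve,
  with a DeLong confidence interval (the CI method is a package choice; it
  is deterministic and standard).
* **Precision** — `precision_report()`: mean predicted minus observed
  mortality.
* **Calibration** — `hosmer_lemeshow()`: deciles of sorted predicted risk
  (ties broken by input order, group sizes as equal as possible), statistic
  $\sum_g (O_g-E_g)^2 / (n_g \bar\pi_g(1-\bar\pi_g))$ with
  $E_g = n_g\bar\pi_g$. A group with $\bar\pi \in \{0,1\}$ has its
  denominator clamped ($\bar\pi$ moved $0.5/n_g$ from the boundary) and is
  flagged. The statistic is reported without a p-value; for *externally*
  specified probabilities its null distribution is approximately
  $\chi^2(g)$, not the $\chi^2(g-2)$ appropriate to in-sample fits — at
  the defaults the mean statistic over simulated calibrated cohorts is
  ≈ 9.5-10, so judging it against $\chi^2(8)$ rejects a well-calibrated
  model slightly too often (~12% instead of 5%).
* `risk_band_table()` produces the observed-vs-predicted table across ten
  increasing-risk bands used for calibration plots.

## Problem sizes and determinism

All randomness flows through explicit seeds (`simulation_config(seed=)`,
`enforce_reference_fraction(seed=)`, the CLI's `--seed`), with generation
deterministic given config plus seed. The test suite exercises refits at
n = 15,000-30,000, oracle comparisons on hundreds of small random cohorts,
and a 100-seed calibration-null study at n = 4,000 per seed; these sizes
were chosen so each property is measured with comfortable Monte-Carlo
margin while the whole suite stays fast.

## Known limitations

* The bundled coefficients are the published ones; no recalibrated or
  country-specific sets are provided, and legacy comparator scores (TRISS,
  the original RISC) are supported only as user-supplied probability
  columns in the evaluation functions.
* The multi-source merge of pre-hospital vs admission measurements (and the
  non-intubated-only fallback for motor function) is resolved upstream of
  the data model: each record carries one final value per field.
* The score must not be applied to patients with only minor injuries
  (worst AIS ≤ 1); virtually all survive, and the inclusion cascade removes
  them for good reason.
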