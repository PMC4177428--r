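# riscii

Risk-of-death prediction for severely injured trauma patients: an R
implementation of the Revised Injury Severity Classification, version II
(RISC II), together with the methodology used to develop such scores and the
metrics used to judge them.

## Who this is for

Trauma-registry analysts and outcomes researchers who need to

* compute anatomical severity scores (ISS, NISS, worst / second-worst / head
  injury) from AIS-coded injury lists,
* assign each admission a survival probability with the published RISC II
  score — including admissions with missing physiology or laboratory values,
* re-derive a RISC II-type model on their own registry data, and
* evaluate any mortality prognosis (this score or a competitor) for
  discrimination, precision, and calibration.

No registry data ship with the package; a synthetic trauma-registry
generator with a known mortality mechanism makes the whole pipeline testable
and reproducible.

## The model

RISC II is an additive categorical score over 13 clinical variables (15
predictor columns: the three injury-severity items — worst injury,
second-worst injury, head injury — count as one clinical variable): AIS
severity of the worst and second-worst injury, head injury, age band, sex,
pre-injury ASA class, injury mechanism, pupil reactivity and size, GCS motor
function, pre-hospital CPR, systolic blood pressure, INR, haemoglobin, and
base deficit. Each variable is partitioned into categories carrying score
points; the total score

```
X = 3.6 + Σ_v points_v(category of patient in v)
```

maps to a survival probability through the logistic function

```
P(survival) = 1 / (1 + exp(-X))
```

so `X = 0` means 50% survival, positive scores a better prognosis.

The defining design feature is *missing-as-reference*: the reference
category of every variable is the one that also absorbs missing values, and
it carries 0 points by construction, so an unknown value never changes the
prognosis and no patient is excluded for missing data. Age and the injury
codes are the compulsory minimum.

Both the published rounded score points and the full regression
coefficients are bundled (`risc2_model()`); scoring supports either
(`mode = "points"` / `"coefficients"`). Six cells of the published table are
internally inconsistent (score point vs coefficient, or OR vs coefficient);
they are stored verbatim and frozen in `published_model_exceptions()` rather
than silently corrected.

## Worked example

```r
library(riscii)

# an 82-year-old with a severe head injury, fixed dilated pupils, no motor
# response; physiology and labs not recorded
rec <- data.frame(
  id = "example", age_years = 82, sex = NA, asa = NA, mechanism = NA,
  pupil_reactivity = "fixed", pupil_size = "bilateral_dilated",
  gcs_motor = 1, cpr = NA, sbp = NA, inr = NA, hb = NA, base_deficit = NA,
  injuries = "5:head_neck;3:chest",
  transferred_in = FALSE, transferred_out_48h = FALSE, outcome = NA)

score_patient(rec)
#> RISC II score (points mode)
#>   constant                                 +3.60
#>   worst_injury         5                -1.70
#>   head_injury          5-6              -0.80
#>   age                  80-84            -2.40
#>   pupil_reactivity     fixed            -1.00
#>   pupil_size           both dilated     -0.50
#>   motor_function       none             -0.80
#>   total X = -3.600;  P(survival) = 0.0266;  P(death) = 0.9734
#>   variables with missing input: 8
```

The eight unrecorded fields contribute 0 through their reference
categories; the anatomical severity, age, and neurology drive the score to
`X = -3.6`, a predicted survival of about 2.7%.

A full pipeline on synthetic data:

```r
cohort <- generate_cohort(simulation_config(n = 5000, seed = 1))
kept   <- apply_inclusion_filters(cohort$records)$included
scored <- score_patients(kept)
evaluate_predictions(scored$p_death, kept$outcome)
#> Evaluation of 5000 predictions
#>   discrimination: AUC = 0.864 (0.847-0.881)
#>   precision:      observed 10.5% vs predicted 11.5% mortality
#>   calibration:    Hosmer-Lemeshow = 14.9 over 10 groups
```

A thin command-line wrapper over the same functions is installed at
`inst/cli/riscii.R` with subcommands `score`, `filter`, `fit`, `evaluate`,
and `simulate`.

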