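test_that("categorization maps observed values to the published categories", {
  rec <- blank_record(age_years = 63L, sex = "female", asa = 4L,
                      mechanism = "penetrating", pupil_reactivity = "brisk",
                      pupil_size = "bilateral_dilated", gcs_motor = 5L,
                      cpr = "yes", sbp = 85, inr = 1.25, hb = 6.2,
                      base_deficit = -2.0,
                      injuries = "4:chest;4:chest;3:head_neck")
  cats <- categorize_patients(rec)
  expect_identical(cats$worst_injury, "4")
  expect_identical(cats$second_worst_injury, "4")
  expect_identical(cats$head_injury, "3-4")
  expect_identical(cats$age, "60-64")
  expect_identical(cats$sex, "female")
  expect_identical(cats$asa, "4")
  expect_identical(cats$mechanism, "penetrating")
  expect_identical(cats$pupil_reactivity, "brisk")
  expect_identical(cats$pupil_size, "both dilated")
  expect_identical(cats$motor_function, "???/directed")  # GCS motor 5
  expect_identical(cats$cpr, "yes")
  expect_identical(cats$blood_pressure, "<90")
  expect_identical(cats$inr, "1.20-1.39")
  expect_identical(cats$haemoglobin, "<7.0")
  expect_identical(cats$base_deficit, "<6.0")  # base excess, still < 6
  expect_identical(cats$n_missing, 0L)
})

test_that("unknown inputs always resolve to the reference category", {
  cats <- categorize_patients(blank_record())
  m <- risc2_model()
  for (nm in c("sex", "asa", "mechanism", "pupil_reactivity", "pupil_size",
               "motor_function", "cpr", "blood_pressure", "inr",
               "haemoglobin", "base_deficit")) {
    v <- m$variables[[nm]]
    expect_identical(cats[[nm]], v$label[v$is_reference])
  }
  expect_identical(cats$n_missing, 11L)
})

test_that("numeric category boundaries follow the half-open convention", {
  rec_with <- function(col, val) { r <- blank_record(); r[[col]] <- val; r }
  cat_of <- function(col, val, var)
    categorize_patients(rec_with(col, val))[[var]]
  expect_identical(cat_of("sbp", 89.9, "blood_pressure"), "<90")
  expect_identical(cat_of("sbp", 90, "blood_pressure"), "???/90-110")
  expect_identical(cat_of("sbp", 110.5, "blood_pressure"), "???/90-110")
  expect_identical(cat_of("sbp", 111, "blood_pressure"), "111-150")
  expect_identical(cat_of("sbp", 150.9, "blood_pressure"), "111-150")
  expect_identical(cat_of("sbp", 151, "blood_pressure"), ">150")
  expect_identical(cat_of("inr", 1.20, "inr"), "1.20-1.39")
  expect_identical(cat_of("inr", 1.40, "inr"), "???/1.40-2.39")
  expect_identical(cat_of("inr", 2.40, "inr"), "2.40+")
  expect_identical(cat_of("hb", 12.0, "haemoglobin"), "12.0+")
  expect_identical(cat_of("hb", 6.99, "haemoglobin"), "<7.0")
  expect_identical(cat_of("base_deficit", 5.99, "base_deficit"), "<6.0")
  expect_identical(cat_of("base_deficit", 6, "base_deficit"), "???/6.0-8.9")
  expect_identical(cat_of("base_deficit", 9, "base_deficit"), "9.0-14.9")
  expect_identical(cat_of("base_deficit", 15, "base_deficit"), "15.0+")
  age_cat <- function(a)
    categorize_patients(blank_record(age_years = a))$age
  expect_identical(age_cat(5L), "1-5")
  expect_identical(age_cat(6L), "6-10")
  expect_identical(age_cat(54L), "11-54")
  expect_identical(age_cat(55L), "55-59")
  expect_identical(age_cat(84L), "80-84")
  expect_identical(age_cat(85L), "85+")
  expect_identical(age_cat(101L), "85+")
})

test_that("a minimal patient scores the constant plus the minor-second-injury bonus", {
  # With a single worst-grade-2 injury the second-worst injury falls in the
  # "0-2" category (+0.2): a patient with literally every variable at its
  # reference cannot exist, because worst at "2" forces second-worst below
  # its reference "3".
  s <- score_patients(blank_record())
  expect_equal(s$x, 3.6 + 0.2)
  expect_equal(s$p_survival, stats::plogis(3.8))
  expect_identical(s$n_missing, 11L)
  # the constant alone is recovered once the +0.2 contribution is removed
  one <- score_patient(blank_record())
  second <- one$contributions$points[
    one$contributions$variable == "second_worst_injury"]
  expect_equal(second, 0.2)
  expect_equal(one$x - second, 3.6)
})

test_that("the severe head-injury worked example sums to -3.6", {
  rec <- blank_record(age_years = 82L, injuries = "5:head_neck;3:chest",
                      gcs_motor = 1L, pupil_reactivity = "fixed",
                      pupil_size = "bilateral_dilated")
  s <- score_patient(rec)
  expect_equal(s$x, 3.6 - 2.4 - 1.7 + 0 - 0.8 - 0.8 - 1.0 - 0.5)
  expect_equal(s$x, -3.6)
  expect_equal(s$p_survival, 1 / (1 + exp(3.6)))
  expect_equal(round(s$p_survival, 4), 0.0266)
})

test_that("a score of zero means a 50% survival probability", {
  expect_identical(survival_probability(0), 0.5)
  expect_equal(survival_probability(2.2) + survival_probability(-2.2), 1)
  x <- seq(-14, 9, by = 0.5)
  expect_true(all(diff(survival_probability(x)) > 0))
})

test_that("masking any single observed field shifts X by exactly its contribution", {
  set.seed(501)
  maskable <- c("sex", "asa", "mechanism", "pupil_reactivity", "pupil_size",
                "gcs_motor", "cpr", "sbp", "inr", "hb", "base_deficit")
  field_to_var <- c(sex = "sex", asa = "asa", mechanism = "mechanism",
                    pupil_reactivity = "pupil_reactivity",
                    pupil_size = "pupil_size", gcs_motor = "motor_function",
                    cpr = "cpr", sbp = "blood_pressure", inr = "inr",
                    hb = "haemoglobin", base_deficit = "base_deficit")
  for (i in 1:25) {
    rec <- random_record()
    full <- score_patient(rec)
    for (f in maskable) {
      if (is.na(rec[[f]])) next
      masked <- rec
      masked[[f]] <- NA
      after <- score_patient(masked)
      contrib <- full$contributions$points[
        full$contributions$variable == field_to_var[[f]]]
      expect_equal(after$x, full$x - contrib)
      expect_identical(after$n_missing, full$n_missing + 1L)
    }
  }
})

test_that("scores stay inside the model's attainable bounds in both modes", {
  set.seed(502)
  recs <- do.call(rbind, lapply(1:100, function(i) random_record()))
  for (mode in c("points", "coefficients")) {
    b <- score_bounds(mode = mode)
    x <- score_patients(recs, mode = mode)$x
    expect_true(all(x >= b[["min"]] - 1e-12 & x <= b[["max"]] + 1e-12))
  }
  expect_equal(score_bounds()[["max"]], 3.6 + 1.4 + 0.2 + 0.2 + 0.3 + 0.2 +
                 0.2 + 0.6 + 0.3 + 0.6 + 0.4 + 0.3)
})

test_that("rounded-point and full-coefficient scores agree within the computed bound", {
  m <- risc2_model()
  per_var_gap <- vapply(m$variables, function(v)
    max(abs(v$score - v$coefficient)), numeric(1))
  bound <- sum(per_var_gap) + abs(m$constant$score - m$constant$coefficient)
  set.seed(503)
  recs <- do.call(rbind, lapply(1:100, function(i) random_record()))
  dx <- score_patients(recs, mode = "points")$x -
    score_patients(recs, mode = "coefficients")$x
  expect_true(all(abs(dx) <= bound + 1e-12))
})

test_that("vectorized scoring matches the single-record path", {
  set.seed(504)
  recs <- do.call(rbind, lapply(1:20, function(i) random_record(paste0("s", i))))
  many <- score_patients(recs)
  for (i in c(1, 7, 20)) {
    one <- score_patient(recs[i, ])
    expect_equal(many$x[i], one$x)
    expect_equal(many$p_death[i], one$p_death)
  }
})
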