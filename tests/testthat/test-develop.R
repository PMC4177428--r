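test_that("reference-fraction enforcement reaches the target by first crossing", {
  # already above target: untouched
  col <- c(rep("???", 55), rep("obs", 45))
  expect_identical(enforce_reference_fraction(col, "???"), col)
  # 5% reference in 1000 cases, target 20%: exactly 150 reassignments
  col2 <- c(rep("???", 50), rep("obs", 950))
  out <- enforce_reference_fraction(col2, "???", seed = 1)
  expect_identical(sum(out == "???"), 200L)
  expect_identical(sum(col2 != "???" & out == "???"), 150L)
  expect_equal(mean(out == "???"), 0.20)
  # all-reference column unchanged
  col3 <- rep("???", 10)
  expect_identical(enforce_reference_fraction(col3, "???"), col3)
  # deterministic given seed, different across seeds
  expect_identical(enforce_reference_fraction(col2, "???", seed = 7),
                   enforce_reference_fraction(col2, "???", seed = 7))
  expect_false(identical(enforce_reference_fraction(col2, "???", seed = 7),
                         enforce_reference_fraction(col2, "???", seed = 8)))
  expect_error(enforce_reference_fraction(col2, "???", target_fraction = 0),
               "target_fraction")
  expect_error(enforce_reference_fraction(col2, "???", target_fraction = 1.5),
               "target_fraction")
})

test_that("enforcement never lowers the reference fraction", {
  set.seed(601)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    col <- sample(c("???", "a", "b"), n, replace = TRUE,
                  prob = c(runif(1), 1, 1))
    tf <- runif(1, 0.05, 0.95)
    out <- enforce_reference_fraction(col, "???", target_fraction = tf,
                                      seed = i)
    expect_gte(mean(out == "???"), mean(col == "???"))
    expect_gte(mean(out == "???"), min(tf, 1))
    # no non-reference label was invented
    expect_true(all(out %in% unique(col)))
  }
})

test_that("Nagelkerke R2 follows its normalized likelihood-ratio formula", {
  expect_equal(nagelkerke_r2(-40, -40, 100), 0)
  expect_equal(nagelkerke_r2(0, -40, 100), 1)
  # worked case evaluated directly from the formula
  ll <- -4.2; ll0 <- -6.9; n <- 10
  direct <- (1 - exp(2 * (ll0 - ll) / n)) / (1 - exp(2 * ll0 / n))
  expect_equal(nagelkerke_r2(ll, ll0, n), direct)
  expect_error(nagelkerke_r2(-3, -2, 10), "below null")
  expect_error(nagelkerke_r2(0, 0, 10), "degenerate")
})

test_that("an all-reference cohort yields an intercept-only fit at the logit of survival", {
  recs <- do.call(rbind, lapply(1:200, function(i)
    blank_record(paste0("n", i))))
  recs$outcome <- rep(c("survived", "died"), 100)
  fit <- suppressWarnings(fit_missing_as_reference(recs))
  expect_equal(fit$intercept, 0, tolerance = 1e-8)
  expect_identical(nrow(fit$coefficients), 0L)
  expect_equal(fit$nagelkerke_r2, 0, tolerance = 1e-12)
})

test_that("a single binary predictor recovers the 2x2-table log odds ratio", {
  # CPR yes: 20 survived / 80 died; CPR no: 100 / 100
  # OR(survival, yes vs no) = (20/80) / (100/100) = 0.25
  recs <- do.call(rbind, c(
    lapply(1:20, function(i) blank_record(paste0("a", i), cpr = "yes",
                                          outcome = "survived")),
    lapply(1:80, function(i) blank_record(paste0("b", i), cpr = "yes",
                                          outcome = "died")),
    lapply(1:100, function(i) blank_record(paste0("c", i), cpr = "no",
                                           outcome = "survived")),
    lapply(1:100, function(i) blank_record(paste0("d", i), cpr = "no",
                                           outcome = "died"))))
  fit <- fit_missing_as_reference(recs, variables = "cpr")
  co <- fit$coefficients
  expect_identical(co$label, "yes")
  expect_equal(co$coefficient, log(0.25), tolerance = 1e-6)
  expect_equal(co$or, 0.25, tolerance = 1e-6)
  expect_equal(co$or_lo, exp(co$coefficient - 1.96 * co$se))
  expect_equal(co$or_hi, exp(co$coefficient + 1.96 * co$se))
})

test_that("fitting requires known outcomes and flags empty categories", {
  recs <- bind_records(blank_record("u1"), blank_record("u2"))
  expect_error(fit_missing_as_reference(recs), "outcome")
  set.seed(602)
  cfg <- simulation_config(800, seed = 77,
                           category_probs = list(cpr = c(no = 1, yes = 0)))
  co <- generate_cohort(cfg)
  expect_warning(fit_missing_as_reference(co$records, variables = "cpr"),
                 "merged into reference")
})

test_that("extra random missingness leaves non-reference estimates consistent", {
  # masking is non-informative, so inflating a covariate's missingness only
  # shrinks its observed cells; tested on CPR, whose reference group is
  # dominated by zero-contribution cases
  co <- generate_cohort(simulation_config(15000, seed = 603))
  recs <- co$records
  set.seed(6031)
  extra <- is.na(recs$cpr) | runif(nrow(recs)) < 0.40
  recs$cpr[extra] <- NA
  expect_gte(mean(is.na(recs$cpr)), 0.40)
  fit <- fit_missing_as_reference(recs)
  est <- fit$coefficients[fit$coefficients$variable == "cpr" &
                          fit$coefficients$label == "yes", ]
  expect_lt(abs(est$coefficient - (-1.752)), 3 * est$se)
})

test_that("forward selection adds the only truly predictive candidate first", {
  # generating model: injuries and age as usual, all other effects null
  # except CPR
  null_model <- risc2_model()
  for (nm in c("sex", "asa", "mechanism", "pupil_reactivity", "pupil_size",
               "motor_function", "blood_pressure", "inr", "haemoglobin",
               "base_deficit"))
    null_model$variables[[nm]]$coefficient[] <- 0
  co <- generate_cohort(simulation_config(6000, seed = 604,
                                          model = null_model))
  trace <- forward_select(co$records)
  expect_identical(trace$variable[1], "(base)")
  expect_identical(trace$variable[2], "cpr")
  expect_true(all(diff(trace$r2) > 0))
  # unreachable threshold: no additions beyond the base model
  none <- forward_select(co$records, min_delta_r2 = 1.0)
  expect_identical(nrow(none), 1L)
  # a candidate duplicating a base variable is never added
  dup <- forward_select(co$records, candidates = c("age", "cpr"))
  expect_false("age" %in% dup$variable[-1])
})

test_that("weak categories merge into the reference and degenerate variables drop", {
  spec <- risc2_model()
  fake_fit <- list(
    variables = c("cpr", "mechanism"),
    coefficients = data.frame(
      variable = c("cpr", "mechanism"),
      label = c("yes", "penetrating"),
      p = c(0.001, 0.60),
      stringsAsFactors = FALSE))
  class(fake_fit) <- "risc_fit"
  expect_warning(merged <- merge_weak_categories(fake_fit, spec),
                 "mechanism")
  expect_identical(names(merged$variables), "cpr")
  expect_identical(merged$provenance$merged, "mechanism:penetrating")
  expect_identical(merged$provenance$dropped, "mechanism")
  # all significant: spec unchanged in structure
  strong <- fake_fit
  strong$coefficients$p <- c(0.001, 0.002)
  kept <- merge_weak_categories(strong, spec)
  expect_identical(names(kept$variables), c("cpr", "mechanism"))
  expect_identical(kept$variables$cpr$label, spec$variables$cpr$label)
  # merged label folds into the reference of a multi-category variable
  multi <- list(variables = "blood_pressure",
                coefficients = data.frame(
                  variable = "blood_pressure",
                  label = c("<90", "111-150", ">150"),
                  p = c(0.001, 0.50, 0.01), stringsAsFactors = FALSE))
  class(multi) <- "risc_fit"
  out <- merge_weak_categories(multi, spec)
  v <- out$variables$blood_pressure
  expect_identical(v$label[v$is_reference], "???/90-110/111-150")
  expect_identical(nrow(v), 3L)
})

test_that("reference-group mortality coverage check uses Wilson intervals", {
  # Wilson interval against stats::prop.test without continuity correction
  for (case in list(c(5, 40), c(0, 50), c(33, 60))) {
    ours <- wilson_ci(case[1], case[2])
    ref <- stats::prop.test(case[1], case[2], correct = FALSE)$conf.int
    expect_equal(unname(ours), as.numeric(ref), tolerance = 1e-9)
  }

  # reference mortality equal to overall: passes
  recs <- do.call(rbind, lapply(1:100, function(i) blank_record(paste0("p", i))))
  recs$outcome <- rep(c("survived", "died"), 50)
  chk <- reference_group_coverage_check(recs, variables = "cpr")
  expect_true(chk$pass)
  expect_equal(chk$mortality_ref, 0.5)

  # 0/50 deaths in the reference group vs 50% overall: fails
  recs2 <- recs
  recs2$cpr <- rep(c("yes", NA), 50)           # all deaths under cpr = yes
  recs2$outcome <- rep(c("died", "survived"), 50)
  chk2 <- reference_group_coverage_check(recs2, variables = "cpr")
  expect_identical(chk2$deaths_ref, 0L)
  expect_lt(chk2$ci_hi, 0.5)
  expect_false(chk2$pass)
})
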