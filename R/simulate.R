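#' Configuration for the synthetic trauma-registry generator
#'
#' Bundles everything [generate_cohort()] needs: cohort size, seed, the true
#' per-variable category probabilities (defaults chosen to resemble a western
#' European blunt-trauma registry population: ~72% male, ~95% blunt
#' mechanism, median age around 47, mean ISS around 19), per-variable
#' missingness rates (defaults mirror registry documentation practice, e.g.
#' pupil assessments missing in over half of cases, base deficit in just
#' under half, sex in under 1%), the generating model (full coefficients of
#' the published score by default), and optional contamination rates that
#' plant records the inclusion cascade must remove (transfers, minor-injury
#' cases, age recorded as zero).
#'
#' Generation is category-first: the true category of each variable is drawn
#' from `category_probs`, then a raw value is drawn uniformly within that
#' category's interval (open-ended intervals use the declared truncation
#' ranges in `ranges`), so the true category assignment of every record is
#' known exactly.  Covariates are drawn independently apart from the enforced
#' injury-profile consistency (head and second-worst severity never exceed
#' the worst).
#'
#' @param n Cohort size.
#' @param seed Optional integer seed; generation is deterministic given the
#'   config (including the seed).
#' @param model Generating `risc_model`; its full coefficients define the
#'   mortality mechanism.
#' @param category_probs Named list of per-variable probability vectors (see
#'   defaults); each must be non-negative and sum to 1.
#' @param missingness Named vector of masking rates in `[0, 1]` for the 11
#'   maskable fields.
#' @param contamination Named list of rates: `transferred_in`,
#'   `transferred_out_48h`, `worst_ais_1`, `age_zero` (all default 0).
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n, seed = NULL, model = risc2_model(),
                              category_probs = list(), missingness = c(),
                              contamination = list()) {
  probs <- list(
    worst = c(`2` = 0.14, `3` = 0.34, `4` = 0.30, `5` = 0.18, `6` = 0.04),
    second_weights = c(`0` = 0.18, `1` = 0.10, `2` = 0.17, `3` = 0.25,
                       `4` = 0.18, `5` = 0.09, `6` = 0.03),
    head_loc = c(none = 0.55, worst = 0.30, second = 0.15),
    age = c(`1-5` = 0.02, `6-10` = 0.02, `11-54` = 0.56, `55-59` = 0.07,
            `60-64` = 0.06, `65-69` = 0.06, `70-74` = 0.06, `75-79` = 0.06,
            `80-84` = 0.05, `85+` = 0.04),
    sex = c(male = 0.716, female = 0.284),
    asa = c(`1-2` = 0.72, `3` = 0.21, `4` = 0.07),
    mechanism = c(blunt = 0.955, penetrating = 0.045),
    pupil_reactivity = c(brisk = 0.74, sluggish = 0.13, fixed = 0.13),
    pupil_size = c(normal = 0.78, anisocoria = 0.10,
                   bilateral_dilated = 0.12),
    motor = c(normal = 0.62, directed = 0.12, `non-directed` = 0.10,
              none = 0.16),
    cpr = c(no = 0.95, yes = 0.05),
    blood_pressure = c(`<90` = 0.12, `90-110` = 0.25, `111-150` = 0.45,
                       `>150` = 0.18),
    inr = c(`<1.20` = 0.55, `1.20-1.39` = 0.20, `1.40-2.39` = 0.20,
            `2.40+` = 0.05),
    haemoglobin = c(`12.0+` = 0.60, `7.0-11.9` = 0.35, `<7.0` = 0.05),
    base_deficit = c(`<6.0` = 0.70, `6.0-8.9` = 0.15, `9.0-14.9` = 0.10,
                     `15.0+` = 0.05),
    region_worst = c(chest = 0.35, extremities_pelvis = 0.30,
                     abdomen = 0.15, face = 0.10, external = 0.10))
  probs[names(category_probs)] <- category_probs

  miss <- c(sex = 0.009, asa = 0.163, mechanism = 0.061,
            pupil_reactivity = 0.535, pupil_size = 0.549,
            gcs_motor = 0.027, cpr = 0.032, sbp = 0.107, inr = 0.129,
            hb = 0.076, base_deficit = 0.460)
  miss[names(missingness)] <- missingness

  contam <- list(transferred_in = 0, transferred_out_48h = 0,
                 worst_ais_1 = 0, age_zero = 0)
  contam[names(contamination)] <- contamination

  for (nm in setdiff(names(probs), "second_weights")) {
    p <- probs[[nm]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("category probabilities for '", nm,
           "' must be non-negative and sum to 1")
  }
  if (any(probs$second_weights < 0) || sum(probs$second_weights) <= 0)
    stop("'second_weights' must be non-negative with positive sum")
  if (any(miss < 0 | miss > 1)) stop("missingness rates must be in [0, 1]")
  if (any(unlist(contam) < 0 | unlist(contam) > 1))
    stop("contamination rates must be in [0, 1]")
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0, n == floor(n))

  structure(list(n = as.integer(n), seed = seed, model = model,
                 category_probs = probs, missingness = miss,
                 contamination = contam,
                 ranges = list(sbp = c(40, 200), inr = c(0.8, 5),
                               hb = c(3, 17), base_deficit = c(-10, 30),
                               age_top = 99)),
            class = "sim_config")
}

draw <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE, prob = probs)]
}

runif_band <- function(cat, bounds) {
  lo <- bounds[[1]][cat]; hi <- bounds[[2]][cat]
  stats::runif(length(cat), lo, hi)
}

#' Generate a synthetic trauma cohort
#'
#' Draws a cohort from a [simulation_config()]: true categories per variable,
#' raw values within them, an injury list consistent with the drawn
#' worst/second-worst/head severities, the true score `X` under the
#' generating model's full coefficients, a death drawn as
#' `Bernoulli(1 - logistic(X))`, and finally non-informative missingness
#' (fields are masked after the outcome is generated, so masking carries no
#' outcome information).  Contaminated records for filter testing are
#' modified last; their rows are marked in the truth table.
#'
#' @param config A `sim_config`.
#' @return List with `records` (patient table, post-masking) and `truth`
#'   (data frame of the true category labels, `x`, `p_death`, and logical
#'   `contaminated`).  `truth$p_death` is exact: scoring the pre-masking
#'   records in coefficient mode with the generating model reproduces it.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  n <- config$n
  pr <- config$category_probs
  rg <- config$ranges
  if (n == 0L) {
    empty <- read_patient_table(
      data.frame(age_years = integer(0), injuries = character(0)))
    return(list(records = empty,
                truth = data.frame(x = numeric(0), p_death = numeric(0))))
  }

  # --- anatomical severity ---------------------------------------------
  worst <- as.integer(draw(n, pr$worst))
  second <- vapply(worst, function(w) {
    wts <- pr$second_weights[as.integer(names(pr$second_weights)) <= w]
    as.integer(draw(1L, wts))
  }, integer(1))
  head_loc <- draw(n, pr$head_loc)
  region_w <- ifelse(head_loc == "worst", "head_neck",
                     draw(n, pr$region_worst))
  region_s <- ifelse(head_loc == "second", "head_neck",
                     draw(n, pr$region_worst))
  injuries <- ifelse(second > 0L,
                     paste0(worst, ":", region_w, ";", second, ":", region_s),
                     paste0(worst, ":", region_w))

  # --- age: band first, uniform completed years within ------------------
  age_band <- draw(n, pr$age)
  age_lo <- c(`1-5` = 1, `6-10` = 6, `11-54` = 11, `55-59` = 55,
              `60-64` = 60, `65-69` = 65, `70-74` = 70, `75-79` = 75,
              `80-84` = 80, `85+` = 85)
  age_hi <- c(`1-5` = 5, `6-10` = 10, `11-54` = 54, `55-59` = 59,
              `60-64` = 64, `65-69` = 69, `70-74` = 74, `75-79` = 79,
              `80-84` = 84, `85+` = rg$age_top)
  age <- age_lo[age_band] +
    floor(stats::runif(n) * (age_hi[age_band] - age_lo[age_band] + 1))

  # --- categorical covariates ------------------------------------------
  sex <- draw(n, pr$sex)
  asa_cat <- draw(n, pr$asa)
  asa <- ifelse(asa_cat == "1-2", 1L + (stats::runif(n) < 0.5),
                ifelse(asa_cat == "3", 3L, 4L))
  mechanism <- draw(n, pr$mechanism)
  preact <- draw(n, pr$pupil_reactivity)
  psize <- draw(n, pr$pupil_size)
  motor_cat <- draw(n, pr$motor)
  gcs_motor <- ifelse(motor_cat == "normal", 6L,
               ifelse(motor_cat == "directed", 4L + (stats::runif(n) < 0.5),
               ifelse(motor_cat == "non-directed",
                      2L + (stats::runif(n) < 0.5), 1L)))
  cpr <- draw(n, pr$cpr)

  # --- numeric covariates, uniform within the drawn category ------------
  bp_cat <- draw(n, pr$blood_pressure)
  sbp <- runif_band(bp_cat, list(
    c(`<90` = rg$sbp[1], `90-110` = 90, `111-150` = 111, `>150` = 151),
    c(`<90` = 90, `90-110` = 111, `111-150` = 151, `>150` = rg$sbp[2])))
  inr_cat <- draw(n, pr$inr)
  inr <- runif_band(inr_cat, list(
    c(`<1.20` = rg$inr[1], `1.20-1.39` = 1.20, `1.40-2.39` = 1.40,
      `2.40+` = 2.40),
    c(`<1.20` = 1.20, `1.20-1.39` = 1.40, `1.40-2.39` = 2.40,
      `2.40+` = rg$inr[2])))
  hb_cat <- draw(n, pr$haemoglobin)
  hb <- runif_band(hb_cat, list(
    c(`12.0+` = 12, `7.0-11.9` = 7, `<7.0` = rg$hb[1]),
    c(`12.0+` = rg$hb[2], `7.0-11.9` = 12, `<7.0` = 7)))
  bd_cat <- draw(n, pr$base_deficit)
  bd <- runif_band(bd_cat, list(
    c(`<6.0` = rg$base_deficit[1], `6.0-8.9` = 6, `9.0-14.9` = 9,
      `15.0+` = 15),
    c(`<6.0` = 6, `6.0-8.9` = 9, `9.0-14.9` = 15,
      `15.0+` = rg$base_deficit[2])))

  records <- data.frame(
    id = sprintf("sim%06d", seq_len(n)),
    age_years = as.integer(age),
    sex = sex, asa = as.integer(asa), mechanism = mechanism,
    pupil_reactivity = preact, pupil_size = psize,
    gcs_motor = as.integer(gcs_motor), cpr = cpr,
    sbp = sbp, inr = inr, hb = hb, base_deficit = bd,
    injuries = injuries,
    transferred_in = FALSE, transferred_out_48h = FALSE,
    outcome = NA_character_, stringsAsFactors = FALSE)

  # --- truth, outcome ---------------------------------------------------
  truth_cats <- categorize_patients(records)
  scored <- score_patients(records, config$model, mode = "coefficients",
                           categories = truth_cats)
  p_death <- scored$p_death
  died <- stats::runif(n) < p_death
  records$outcome <- ifelse(died, "died", "survived")

  # --- non-informative masking (after outcome generation) ---------------
  m <- config$missingness
  mask <- function(col) {
    hit <- stats::runif(n) < m[[col]]
    records[[col]][hit] <<- NA
  }
  for (col in names(m)) mask(col)

  # --- contamination for filter testing ---------------------------------
  cn <- config$contamination
  contaminated <- logical(n)
  if (cn$transferred_in > 0) {
    hit <- stats::runif(n) < cn$transferred_in
    records$transferred_in[hit] <- TRUE; contaminated <- contaminated | hit
  }
  if (cn$transferred_out_48h > 0) {
    hit <- stats::runif(n) < cn$transferred_out_48h
    records$transferred_out_48h[hit] <- TRUE
    contaminated <- contaminated | hit
  }
  if (cn$worst_ais_1 > 0) {
    hit <- stats::runif(n) < cn$worst_ais_1
    records$injuries[hit] <- "1:extremities_pelvis"
    contaminated <- contaminated | hit
  }
  if (cn$age_zero > 0) {
    hit <- stats::runif(n) < cn$age_zero
    records$age_years[hit] <- 0L; contaminated <- contaminated | hit
  }

  truth <- truth_cats
  truth$x <- scored$x
  truth$p_death <- p_death
  truth$contaminated <- contaminated
  list(records = records, truth = truth)
}
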