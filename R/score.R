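#' Map patient records to RISC II categories
#'
#' Assigns every record exactly one category label per model variable.
#' Unknown values (`NA`) always map to the variable's reference category
#' (the `???/...` label), which carries zero points, so missing data never
#' change the prognosis.  Numeric variables use half-open intervals that
#' preserve the printed integer-styled category labels while covering all
#' real values:
#'
#' * systolic blood pressure: `[0,90)`, `[90,111)`, `[111,151)`, `[151,Inf)`
#'   (the `>150` category is distinct from the reference but also carries 0
#'   points);
#' * INR: `(0,1.20)`, `[1.20,1.40)`, `[1.40,2.40)`, `[2.40,Inf)`;
#' * haemoglobin: `[12,Inf)`, `[7,12)`, `[0,7)` (g/dl);
#' * base deficit: `(-Inf,6)`, `[6,9)`, `[9,15)`, `[15,Inf)` (mEq/l,
#'   positive = acidotic; base-excess input is negated by the reader);
#' * age: completed years, bands `1-5`, `6-10`, `11-54` (reference),
#'   five-year bands to `80-84`, then `85+`.
#'
#' Motor function derives from the GCS motor component: 6 = normal,
#' 4-5 = directed (reference), 2-3 = non-directed, 1 = none.
#'
#' @param records Patient table (see [patient_table]).
#' @param profile Injury profile data frame from [injury_profiles()];
#'   computed from `records$injuries` when `NULL`.
#' @return Data frame of category labels, one column per model variable, one
#'   row per record, plus integer column `n_missing` (number of variables
#'   that fell back to the reference because the input was unknown).
#' @export
categorize_patients <- function(records, profile = NULL) {
  n <- nrow(records)
  if (is.null(profile)) profile <- injury_profiles(records)
  stopifnot(nrow(profile) == n)

  band <- function(x, breaks, labels, right_open = TRUE) {
    # half-open [b_i, b_{i+1}) intervals over finite values
    idx <- findInterval(x, breaks, rightmost.closed = FALSE)
    idx[idx < 1L] <- 1L
    idx[idx > length(labels)] <- length(labels)
    labels[idx]
  }
  lvl <- function(x, map, ref) {
    out <- unname(map[as.character(x)])
    out[is.na(out)] <- ref
    out
  }

  worst <- pmin(pmax(profile$worst_ais, 2L), 6L)
  second <- band(profile$second_worst_ais, c(0, 3, 4, 5),
                 c("0-2", "3", "4", "5-6"))
  head_inj <- band(profile$head_ais, c(0, 3, 5), c("0-2", "3-4", "5-6"))
  age <- band(records$age_years, c(1, 6, 11, 55, 60, 65, 70, 75, 80, 85),
              c("1-5", "6-10", "11-54", "55-59", "60-64", "65-69",
                "70-74", "75-79", "80-84", "85+"))

  sex <- lvl(records$sex, c(male = "???/male", female = "female"), "???/male")
  asa <- lvl(records$asa, c(`1` = "1-2", `2` = "1-2", `3` = "???/3",
                            `4` = "4"), "???/3")
  mech <- lvl(records$mechanism,
              c(blunt = "???/blunt", penetrating = "penetrating"),
              "???/blunt")
  preact <- lvl(records$pupil_reactivity,
                c(brisk = "brisk", sluggish = "???/sluggish",
                  fixed = "fixed"), "???/sluggish")
  psize <- lvl(records$pupil_size,
               c(normal = "normal", anisocoria = "???/anisocoria",
                 bilateral_dilated = "both dilated"), "???/anisocoria")
  motor <- lvl(records$gcs_motor,
               c(`6` = "normal", `5` = "???/directed", `4` = "???/directed",
                 `3` = "non-directed", `2` = "non-directed", `1` = "none"),
               "???/directed")
  cpr <- lvl(records$cpr, c(no = "???/no", yes = "yes"), "???/no")

  num_band <- function(x, breaks, labels, ref) {
    out <- rep(ref, n)
    ok <- !is.na(x)
    out[ok] <- band(x[ok], breaks, labels)
    out
  }
  bp <- num_band(records$sbp, c(0, 90, 111, 151),
                 c("<90", "???/90-110", "111-150", ">150"), "???/90-110")
  inr <- num_band(records$inr, c(0, 1.20, 1.40, 2.40),
                  c("<1.20", "1.20-1.39", "???/1.40-2.39", "2.40+"),
                  "???/1.40-2.39")
  hb <- num_band(records$hb, c(0, 7, 12),
                 c("<7.0", "???/7.0-11.9", "12.0+"), "???/7.0-11.9")
  bd <- num_band(records$base_deficit, c(-Inf, 6, 9, 15),
                 c("<6.0", "???/6.0-8.9", "9.0-14.9", "15.0+"),
                 "???/6.0-8.9")

  maskable <- cbind(is.na(records$sex), is.na(records$asa),
                    is.na(records$mechanism), is.na(records$pupil_reactivity),
                    is.na(records$pupil_size), is.na(records$gcs_motor),
                    is.na(records$cpr), is.na(records$sbp),
                    is.na(records$inr), is.na(records$hb),
                    is.na(records$base_deficit))

  data.frame(
    worst_injury = as.character(worst),
    second_worst_injury = second,
    head_injury = head_inj,
    age = age,
    sex = sex, asa = asa, mechanism = mech,
    pupil_reactivity = preact, pupil_size = psize,
    motor_function = motor, cpr = cpr,
    blood_pressure = bp, inr = inr, haemoglobin = hb, base_deficit = bd,
    n_missing = as.integer(rowSums(maskable)),
    stringsAsFactors = FALSE)
}

category_values <- function(spec, mode) {
  col <- if (mode == "points") "score" else "coefficient"
  lapply(spec$variables, function(v) {
    vals <- v[[col]]
    names(vals) <- v$label
    vals
  })
}

#' Score a cohort with a RISC II-type model
#'
#' Computes, for every record, the total score `X` (constant plus one
#' contribution per variable, with unknown inputs contributing 0 through the
#' reference category), and transforms it to survival and death
#' probabilities via `P(survival) = 1/(1 + exp(-X))`.
#'
#' @param records Patient table (see [patient_table]).
#' @param spec A `risc_model`; default the published model.
#' @param mode `"points"` (default) sums the published rounded score points;
#'   `"coefficients"` sums the full regression coefficients.
#' @param categories Optional pre-computed output of [categorize_patients()];
#'   supply to score the same categorization repeatedly.
#' @return Data frame with one row per record: the per-variable category
#'   labels, `n_missing`, `x`, `p_survival`, `p_death`.
#' @examples
#' rec <- data.frame(id = "a", age_years = 30, sex = NA, asa = NA,
#'                   mechanism = NA, pupil_reactivity = NA, pupil_size = NA,
#'                   gcs_motor = NA, cpr = NA, sbp = NA, inr = NA, hb = NA,
#'                   base_deficit = NA, injuries = "2:chest",
#'                   transferred_in = FALSE, transferred_out_48h = FALSE,
#'                   outcome = NA)
#' score_patients(rec)$x  # 3.6: every variable at its reference
#' @export
score_patients <- function(records, spec = risc2_model(),
                           mode = c("points", "coefficients"),
                           categories = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(spec, "risc_model"))
  if (is.null(categories)) categories <- categorize_patients(records)
  vals <- category_values(spec, mode)
  contrib <- vapply(names(spec$variables), function(nm) {
    v <- vals[[nm]][categories[[nm]]]
    if (anyNA(v))
      stop("category label(s) outside the model for variable '", nm, "': ",
           paste(unique(categories[[nm]][is.na(v)]), collapse = ", "))
    unname(v)
  }, numeric(nrow(categories)))
  if (nrow(categories) == 1L) contrib <- matrix(contrib, nrow = 1L)
  const <- if (mode == "points") spec$constant$score else spec$constant$coefficient
  x <- const + rowSums(contrib)
  out <- categories
  out$x <- x
  out$p_survival <- survival_probability(x)
  out$p_death <- 1 - out$p_survival
  out
}

#' Score a single patient, with per-variable contributions
#'
#' As [score_patients()] but for one record, returning an object whose print
#' method shows the contribution of every variable.
#'
#' @inheritParams score_patients
#' @param record One-row patient table.
#' @return A `risc_score` object: list with `contributions` (data frame of
#'   `variable`, `category`, `points`), `constant`, `x`, `p_survival`,
#'   `p_death`, `n_missing`, `mode`.
#' @export
score_patient <- function(record, spec = risc2_model(),
                          mode = c("points", "coefficients")) {
  mode <- match.arg(mode)
  stopifnot(nrow(record) == 1L)
  cats <- categorize_patients(record)
  vals <- category_values(spec, mode)
  contributions <- data.frame(
    variable = names(spec$variables),
    category = vapply(names(spec$variables), function(nm) cats[[nm]],
                      character(1)),
    points = vapply(names(spec$variables), function(nm)
      unname(vals[[nm]][cats[[nm]]]), numeric(1)),
    stringsAsFactors = FALSE)
  const <- if (mode == "points") spec$constant$score else spec$constant$coefficient
  x <- const + sum(contributions$points)
  structure(list(contributions = contributions, constant = const, x = x,
                 p_survival = survival_probability(x),
                 p_death = 1 - survival_probability(x),
                 n_missing = cats$n_missing, mode = mode),
            class = "risc_score")
}

#' @export
print.risc_score <- function(x, ...) {
  cat("RISC II score (", x$mode, " mode)\n", sep = "")
  shown <- x$contributions[x$contributions$points != 0, ]
  cat(sprintf("  constant%32s%+6.2f\n", "", x$constant))
  if (nrow(shown))
    cat(sprintf("  %-20s %-15s %+6.2f\n", shown$variable, shown$category,
                shown$points), sep = "")
  cat(sprintf("  total X = %.3f;  P(survival) = %.4f;  P(death) = %.4f\n",
              x$x, x$p_survival, x$p_death))
  cat("  variables with missing input:", x$n_missing, "\n")
  invisible(x)
}

#' Logistic survival transform
#'
#' `P(survival) = 1 / (1 + exp(-X))`; `X = 0` gives 0.5, positive scores a
#' better and negative scores a worse prognosis.
#'
#' @param x Score value(s) (the logit of survival).
#' @return Probability in `[0, 1]`.
#' @export
survival_probability <- function(x) stats::plogis(x)

#' Attainable score range of a model
#'
#' Minimum and maximum total score `X`, computed from the model's own
#' category values (constant plus per-variable minima/maxima).
#'
#' @inheritParams score_patients
#' @return Named numeric vector `c(min, max)`.
#' @export
score_bounds <- function(spec = risc2_model(),
                         mode = c("points", "coefficients")) {
  mode <- match.arg(mode)
  vals <- category_values(spec, mode)
  const <- if (mode == "points") spec$constant$score else spec$constant$coefficient
  c(min = const + sum(vapply(vals, min, numeric(1))),
    max = const + sum(vapply(vals, max, numeric(1))))
}
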