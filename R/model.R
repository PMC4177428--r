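#' @title RISC II model specifications
#' @description
#' A RISC II-type model is a categorical additive score: each of the 15
#' predictor columns (13 clinical variables, with the three injury-severity
#' items counted separately here) is partitioned into categories, each
#' category carrying a rounded score point (one decimal) and a full logistic
#' regression coefficient.  Exactly one category per variable is the
#' reference; its score and coefficient are 0 by construction, and an unknown
#' value always resolves to it, so missing data never alter the prognosis.
#' The linear predictor X (constant plus the per-variable contributions) maps
#' to a survival probability through the logistic function
#' `P(survival) = 1 / (1 + exp(-X))`.
#' @name risc_model
NULL

new_variable <- function(name, labels, scores, coefs, reference) {
  stopifnot(length(labels) == length(scores),
            length(labels) == length(coefs),
            reference %in% labels)
  ref <- labels == reference
  stopifnot(sum(ref) == 1L, scores[ref] == 0, coefs[ref] == 0)
  data.frame(variable = name, label = labels, score = scores,
             coefficient = coefs, is_reference = ref,
             stringsAsFactors = FALSE)
}

#' The published RISC II model
#'
#' Returns the full published model table: 15 predictor variables, their
#' category labels (labels containing `???/` mark the category that also
#' absorbs missing values), rounded score points, full coefficients, and the
#' constant (+3.6 points, coefficient 3.590).  The printed table contains a
#' handful of cells where score point and coefficient (or OR and coefficient)
#' are mutually inconsistent; they are stored exactly as printed and listed by
#' [published_model_exceptions()].
#'
#' @return A `risc_model` object: list with elements `variables` (named list
#'   of per-variable category data frames), `constant` (list with `score`,
#'   `coefficient`) and `version`.
#' @examples
#' m <- risc2_model()
#' m$constant$score  # +3.6
#' @export
risc2_model <- function() {
  v <- list(
    worst_injury = new_variable(
      "worst_injury", c("2", "3", "4", "5", "6"),
      c(0, -0.5, -1.3, -1.7, -2.9),
      c(0, -0.517, -1.259, -1.742, -2.941), "2"),
    second_worst_injury = new_variable(
      "second_worst_injury", c("0-2", "3", "4", "5-6"),
      c(0.2, 0, -0.6, -1.4),
      c(0.254, 0, -0.617, -1.429), "3"),
    head_injury = new_variable(
      "head_injury", c("0-2", "3-4", "5-6"),
      c(0, -0.2, -0.8),
      c(0, -0.199, -0.755), "0-2"),
    age = new_variable(
      "age", c("1-5", "6-10", "11-54", "55-59", "60-64", "65-69",
               "70-74", "75-79", "80-84", "85+"),
      c(1.4, 0.6, 0, -0.5, -0.8, -0.9, -1.2, -1.9, -2.4, -2.7),
      c(1.411, 0.581, 0, -0.544, -0.784, -0.921, -1.250, -1.888,
        -2.244, -2.665), "11-54"),
    sex = new_variable(
      "sex", c("???/male", "female"), c(0, 0.2), c(0, 0.231), "???/male"),
    asa = new_variable(
      "asa", c("1-2", "???/3", "4"), c(0.3, 0, -1.3),
      c(0.335, 0, -1.334), "???/3"),
    mechanism = new_variable(
      "mechanism", c("???/blunt", "penetrating"), c(0, -0.6),
      c(0, -0.623), "???/blunt"),
    pupil_reactivity = new_variable(
      "pupil_reactivity", c("brisk", "???/sluggish", "fixed"),
      c(0.2, 0, -1.0), c(0.271, 0, -1.011), "???/sluggish"),
    pupil_size = new_variable(
      "pupil_size", c("normal", "???/anisocoria", "both dilated"),
      c(0.2, 0, -0.5), c(0.178, 0, -0.490), "???/anisocoria"),
    motor_function = new_variable(
      "motor_function", c("normal", "???/directed", "non-directed", "none"),
      c(0.6, 0, -0.4, -0.8), c(0.609, 0, -0.378, -0.819), "???/directed"),
    cpr = new_variable(
      "cpr", c("???/no", "yes"), c(0, -1.8), c(0, -1.752), "???/no"),
    blood_pressure = new_variable(
      "blood_pressure", c("<90", "???/90-110", "111-150", ">150"),
      c(-0.7, 0, 0.3, 0), c(-0.665, 0, 0.310, 0), "???/90-110"),
    inr = new_variable(
      "inr", c("<1.20", "1.20-1.39", "???/1.40-2.39", "2.40+"),
      c(0.6, 0.2, 0, -0.4), c(0.637, 0.184, 0, -0.383), "???/1.40-2.39"),
    haemoglobin = new_variable(
      "haemoglobin", c("12.0+", "???/7.0-11.9", "<7.0"),
      c(0.4, 0, -0.5), c(0.372, 0, -0.551), "???/7.0-11.9"),
    base_deficit = new_variable(
      "base_deficit", c("<6.0", "???/6.0-8.9", "9.0-14.9", "15.0+"),
      c(0.3, 0, -0.4, -1.5), c(0.267, 0, -0.404, -1.544), "???/6.0-8.9"))
  structure(list(variables = v,
                 constant = list(score = 3.6, coefficient = 3.590),
                 version = "risc2-published-1"),
            class = "risc_model")
}

#' Known inconsistencies in the published model table
#'
#' Cells of the published score table where the printed score point does not
#' equal `round(coefficient, 1)`, or the printed odds ratio does not equal
#' `round(exp(coefficient), 2)`.  These printed values are kept verbatim in
#' [risc2_model()]; this frozen table is what [audit_model_spec()] results are
#' compared against.  (The age 80-84 pair is consistent with a coefficient of
#' -2.444 misprinted as -2.244.)
#'
#' @return Data frame with columns `variable`, `label`, `field` (`"score"` or
#'   `"or"`), `printed`, `implied`.
#' @export
published_model_exceptions <- function() {
  data.frame(
    variable = c("second_worst_injury", "age", "age",
                 "pupil_reactivity", "pupil_size", "haemoglobin"),
    label    = c("0-2", "80-84", "80-84", "brisk", "normal", "<7.0"),
    field    = c("score", "score", "or", "score", "or", "score"),
    printed  = c(0.2, -2.4, 0.09, 0.2, 1.20, -0.5),
    implied  = c(0.3, -2.2, 0.11, 0.3, 1.19, -0.6),
    stringsAsFactors = FALSE)
}

#' Published odds ratios, as printed
#'
#' The OR column of the published model table (reference categories print
#' OR = 1).  Used by the audit; kept separate from [risc2_model()] because
#' the OR is derived, not part of the score.
#' @return Data frame with columns `variable`, `label`, `or`.
#' @keywords internal
published_or_table <- function() {
  m <- risc2_model()
  tab <- model_table(m)
  tab$or <- round(exp(tab$coefficient), 2)
  # printed ORs that differ from exp(coefficient):
  tab$or[tab$variable == "age" & tab$label == "80-84"] <- 0.09
  tab$or[tab$variable == "pupil_size" & tab$label == "normal"] <- 1.20
  tab[, c("variable", "label", "or")]
}

#' Flatten a model to one row per category
#'
#' @param spec A `risc_model`.
#' @return Data frame with columns `variable`, `label`, `score`,
#'   `coefficient`, `is_reference`.
#' @export
model_table <- function(spec) {
  stopifnot(inherits(spec, "risc_model"))
  out <- do.call(rbind, spec$variables)
  rownames(out) <- NULL
  out
}

#' Audit score point / coefficient / OR consistency
#'
#' Checks, for every category of a model, that the rounded score point equals
#' `round(coefficient, 1)` and (when an OR table is supplied) that the OR
#' equals `round(exp(coefficient), 2)`.  Returns the discrepancies; for the
#' bundled published model these are exactly [published_model_exceptions()].
#'
#' @param spec A `risc_model`.
#' @param or_table Optional data frame of printed ORs (columns `variable`,
#'   `label`, `or`); defaults to the published OR column when auditing the
#'   published model.
#' @return Data frame in the format of [published_model_exceptions()] (zero
#'   rows if fully consistent).
#' @export
audit_model_spec <- function(spec = risc2_model(),
                             or_table = published_or_table()) {
  tab <- model_table(spec)
  rows <- list()
  for (i in seq_len(nrow(tab))) {
    implied_score <- round(tab$coefficient[i], 1)
    if (!isTRUE(all.equal(tab$score[i], implied_score)))
      rows[[length(rows) + 1L]] <- data.frame(
        variable = tab$variable[i], label = tab$label[i], field = "score",
        printed = tab$score[i], implied = implied_score,
        stringsAsFactors = FALSE)
  }
  if (!is.null(or_table)) {
    for (i in seq_len(nrow(tab))) {
      j <- which(or_table$variable == tab$variable[i] &
                 or_table$label == tab$label[i])
      if (!length(j)) next
      implied_or <- round(exp(tab$coefficient[i]), 2)
      if (!isTRUE(all.equal(or_table$or[j[1]], implied_or)))
        rows[[length(rows) + 1L]] <- data.frame(
          variable = tab$variable[i], label = tab$label[i], field = "or",
          printed = or_table$or[j[1]], implied = implied_or,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(published_model_exceptions()[0, ])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Odds ratio of a coefficient
#'
#' `exp(coefficient)`, rounded to two decimals as in published score tables.
#'
#' @param coefficient Finite numeric coefficient(s).
#' @param digits Decimals for rounding; `NULL` for no rounding.
#' @return Numeric odds ratio(s).
#' @examples
#' odds_ratio(-0.517)  # 0.60
#' @export
odds_ratio <- function(coefficient, digits = 2) {
  stopifnot(all(is.finite(coefficient)))
  or <- exp(coefficient)
  if (!is.null(digits)) or <- round(or, digits)
  or
}

#' @export
print.risc_model <- function(x, ...) {
  cat("RISC II-type categorical score (", x$version, ")\n", sep = "")
  cat(length(x$variables), "variables; constant:",
      sprintf("%+.1f points (coefficient %.3f)\n",
              x$constant$score, x$constant$coefficient))
  tab <- model_table(x)
  tab$label <- ifelse(tab$is_reference, paste0(tab$label, "*"), tab$label)
  print(tab[, c("variable", "label", "score", "coefficient")],
        row.names = FALSE)
  cat("* reference category (absorbs missing values)\n")
  invisible(x)
}

#' Write a model specification to JSON
#'
#' The JSON layout round-trips exactly through [read_model_spec()].
#'
#' @param spec A `risc_model`.
#' @param path Output path.
#' @export
write_model_spec <- function(spec, path) {
  stopifnot(inherits(spec, "risc_model"))
  payload <- list(
    format = "risc-model/1",
    version = spec$version,
    constant = spec$constant,
    variables = lapply(spec$variables, function(v)
      list(categories = v$label, score = v$score,
           coefficient = v$coefficient,
           reference = v$label[v$is_reference])))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a model specification from JSON
#'
#' @param path Path to a JSON file written by [write_model_spec()].
#' @return A `risc_model`.
#' @export
read_model_spec <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(p$format) || p$format != "risc-model/1")
    stop("not a risc-model/1 JSON file: ", path)
  vars <- lapply(names(p$variables), function(nm) {
    v <- p$variables[[nm]]
    new_variable(nm, as.character(v$categories), as.numeric(v$score),
                 as.numeric(v$coefficient), as.character(v$reference))
  })
  names(vars) <- names(p$variables)
  structure(list(variables = vars,
                 constant = list(score = as.numeric(p$constant$score),
                                 coefficient = as.numeric(p$constant$coefficient)),
                 version = as.character(p$version)),
            class = "risc_model")
}

#' A short version hash of a model specification
#'
#' Deterministic content hash (djb2 over the serialized category table) used
#' by the command-line interface's `--version` output.
#' @param spec A `risc_model`.
#' @return Character scalar.
#' @export
model_spec_hash <- function(spec) {
  tab <- model_table(spec)
  s <- paste(c(t(as.matrix(format(tab, digits = 12)))),
             spec$version, spec$constant$coefficient, collapse = "|")
  h <- 5381
  for (b in utf8ToInt(s)) h <- (h * 33 + b) %% 2^31
  sprintf("%s@%08x", spec$version, h)
}
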