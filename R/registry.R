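#' @title Trauma-registry patient tables
#' @description
#' Patient records are plain data frames, one row per admission, using the
#' column dictionary below.  Unknown values are `NA` throughout (the CSV
#' missing token is the empty field; see `na_tokens`).
#'
#' | column               | type / levels                                        |
#' |----------------------|------------------------------------------------------|
#' | `id`                 | character, opaque                                    |
#' | `age_years`          | integer >= 0 (compulsory)                            |
#' | `sex`                | `male`, `female`                                     |
#' | `asa`                | pre-injury ASA physical status, 1-4                  |
#' | `mechanism`          | `blunt`, `penetrating`                               |
#' | `pupil_reactivity`   | `brisk`, `sluggish`, `fixed`                         |
#' | `pupil_size`         | `normal`, `anisocoria`, `bilateral_dilated`          |
#' | `gcs_motor`          | GCS motor component, 1-6                             |
#' | `cpr`                | pre-hospital CPR, `yes`/`no`                         |
#' | `sbp`                | systolic blood pressure, mmHg                        |
#' | `inr`                | international normalized ratio                       |
#' | `hb`                 | haemoglobin, g/dl                                    |
#' | `base_deficit`       | mEq/l, positive = acidotic                           |
#' | `injuries`           | `";"`-separated `severity:region` tokens (compulsory)|
#' | `transferred_in`     | logical                                              |
#' | `transferred_out_48h`| logical                                              |
#' | `outcome`            | `survived`, `died`                                   |
#' @name patient_table
NULL

PATIENT_COLUMNS <- c("id", "age_years", "sex", "asa", "mechanism",
                     "pupil_reactivity", "pupil_size", "gcs_motor", "cpr",
                     "sbp", "inr", "hb", "base_deficit", "injuries",
                     "transferred_in", "transferred_out_48h", "outcome")

MANDATORY_COLUMNS <- c("age_years", "injuries")

LEVELS <- list(
  sex = c("male", "female"),
  mechanism = c("blunt", "penetrating"),
  pupil_reactivity = c("brisk", "sluggish", "fixed"),
  pupil_size = c("normal", "anisocoria", "bilateral_dilated"),
  cpr = c("yes", "no"),
  outcome = c("survived", "died"))

#' Read a trauma-registry patient table
#'
#' Reads a CSV/TSV file (or an in-memory data frame) into the canonical
#' patient-table layout documented in [patient_table].  Optional fields that
#' are blank, listed in `na_tokens`, or unparseable become `NA` (unknown);
#' the compulsory fields `age_years` and `injuries` must parse for every row.
#'
#' @param source Path to a delimited text file, or a data frame.
#' @param sep Field separator; `","` (default) or `"\t"`.
#' @param na_tokens Strings treated as the missing value; the empty field is
#'   always missing.
#' @param ais_map Optional AIS code mapping passed to [parse_injuries()].
#' @param base_excess If `TRUE`, the `base_deficit` column holds base excess
#'   and is negated on input (deficit = -excess).
#' @return A data frame of patient records.
#' @export
read_patient_table <- function(source, sep = ",", na_tokens = c("", "NA"),
                               ais_map = NULL, base_excess = FALSE) {
  df <- if (is.data.frame(source)) {
    as.data.frame(source, stringsAsFactors = FALSE)
  } else {
    utils::read.table(source, header = TRUE, sep = sep, quote = "\"",
                      colClasses = "character", check.names = TRUE,
                      stringsAsFactors = FALSE, na.strings = NULL,
                      comment.char = "")
  }
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(df))
  if (length(missing_cols))
    stop("patient table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  n <- nrow(df)
  get_chr <- function(col) {
    if (!col %in% names(df)) return(rep(NA_character_, n))
    v <- trimws(as.character(df[[col]]))
    v[v %in% na_tokens | !nzchar(v)] <- NA_character_
    v
  }
  num_opt <- function(col) suppressWarnings(as.numeric(get_chr(col)))
  int_opt <- function(col) suppressWarnings(as.integer(get_chr(col)))
  lvl_opt <- function(col) {
    v <- get_chr(col)
    v[!is.na(v) & !(v %in% LEVELS[[col]])] <- NA_character_
    v
  }
  flag <- function(col) {
    v <- tolower(get_chr(col))
    out <- v %in% c("true", "t", "1", "yes")
    out[is.na(v)] <- FALSE
    out
  }

  age <- suppressWarnings(as.integer(trimws(as.character(df$age_years))))
  if (n && any(is.na(age) | age < 0))
    stop("compulsory field 'age_years' unparseable or negative in row(s): ",
         paste(utils::head(which(is.na(age) | age < 0), 5), collapse = ", "))
  inj <- get_chr("injuries")
  inj[is.na(inj)] <- ""
  for (i in seq_len(n)) parse_injuries(inj[i], ais_map = ais_map)  # raises

  bd <- num_opt("base_deficit")
  if (base_excess) bd <- -bd

  id <- get_chr("id")
  if (all(is.na(id))) id <- as.character(seq_len(n))

  out <- data.frame(
    id = id,
    age_years = age,
    sex = lvl_opt("sex"),
    asa = int_opt("asa"),
    mechanism = lvl_opt("mechanism"),
    pupil_reactivity = lvl_opt("pupil_reactivity"),
    pupil_size = lvl_opt("pupil_size"),
    gcs_motor = int_opt("gcs_motor"),
    cpr = lvl_opt("cpr"),
    sbp = num_opt("sbp"),
    inr = num_opt("inr"),
    hb = num_opt("hb"),
    base_deficit = bd,
    injuries = inj,
    transferred_in = flag("transferred_in"),
    transferred_out_48h = flag("transferred_out_48h"),
    outcome = lvl_opt("outcome"),
    stringsAsFactors = FALSE)
  out$asa[!is.na(out$asa) & !(out$asa %in% 1:4)] <- NA_integer_
  out$gcs_motor[!is.na(out$gcs_motor) & !(out$gcs_motor %in% 1:6)] <- NA_integer_
  out$sbp[!is.na(out$sbp) & out$sbp < 0] <- NA_real_
  out$inr[!is.na(out$inr) & out$inr <= 0] <- NA_real_
  out$hb[!is.na(out$hb) & out$hb < 0] <- NA_real_
  out
}

#' Write a patient table to CSV
#'
#' @param records Patient table data frame.
#' @param path Output file path.
#' @param sep Field separator.
#' @export
write_patient_table <- function(records, path, sep = ",") {
  utils::write.table(records, path, sep = sep, row.names = FALSE,
                     quote = FALSE, na = "")
  invisible(path)
}

EXCLUSION_REASONS <- c("transferred_in", "transferred_out_48h",
                       "worst_ais_le_1", "age_zero")

#' Cohort inclusion filtering
#'
#' Applies the registry inclusion cascade in a fixed order; each record is
#' counted under the first rule it matches, or as included:
#'
#' 1. transferred in from another hospital (initial status unknown);
#' 2. transferred out to another hospital within 48 h (outcome unknown);
#' 3. worst injury of AIS grade 1 or less, i.e. ISS < 4 (records with no
#'    coded injuries have worst severity 0 and fall here);
#' 4. age recorded as zero (registry data-entry artefact).
#'
#' Included records therefore have a worst AIS severity of at least 2 and an
#' age of at least 1 year.  The counts per reason plus the included count
#' always partition the input.
#'
#' @param records Patient table data frame.
#' @return A list with `included` (the filtered data frame) and `log`, an
#'   `exclusion_log` object of counts per reason.
#' @export
apply_inclusion_filters <- function(records) {
  n <- nrow(records)
  worst <- if (n) injury_profiles(records)$worst_ais else integer(0)
  reason <- rep(NA_character_, n)
  reason[is.na(reason) & records$transferred_in] <- "transferred_in"
  reason[is.na(reason) & records$transferred_out_48h] <- "transferred_out_48h"
  reason[is.na(reason) & worst <= 1L] <- "worst_ais_le_1"
  reason[is.na(reason) & records$age_years == 0L] <- "age_zero"
  counts <- vapply(EXCLUSION_REASONS,
                   function(r) sum(reason == r, na.rm = TRUE), integer(1))
  log <- structure(
    list(counts = c(as.list(counts), list(included = sum(is.na(reason)))),
         total = n),
    class = "exclusion_log")
  list(included = records[is.na(reason), , drop = FALSE], log = log)
}

#' @export
print.exclusion_log <- function(x, ...) {
  cat("Cohort inclusion cascade (", x$total, " records)\n", sep = "")
  for (r in EXCLUSION_REASONS)
    cat(sprintf("  excluded, %-20s %d\n", paste0(r, ":"), x$counts[[r]]))
  cat(sprintf("  included:                     %d\n", x$counts$included))
  invisible(x)
}

#' Serialize an exclusion log to JSON
#'
#' @param log An `exclusion_log` from [apply_inclusion_filters()].
#' @param path Output path.
#' @export
write_exclusion_log <- function(log, path) {
  jsonlite::write_json(c(log$counts, list(total = log$total)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
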