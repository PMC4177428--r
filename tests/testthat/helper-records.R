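# Builders and independent oracles shared across test files.

# single-row patient record with every optional field unknown, overridable
blank_record <- function(id = "r1", age_years = 30L, injuries = "2:chest",
                         ...) {
  rec <- data.frame(
    id = id, age_years = age_years,
    sex = NA_character_, asa = NA_integer_, mechanism = NA_character_,
    pupil_reactivity = NA_character_, pupil_size = NA_character_,
    gcs_motor = NA_integer_, cpr = NA_character_,
    sbp = NA_real_, inr = NA_real_, hb = NA_real_,
    base_deficit = NA_real_, injuries = injuries,
    transferred_in = FALSE, transferred_out_48h = FALSE,
    outcome = NA_character_, stringsAsFactors = FALSE)
  dots <- list(...)
  for (nm in names(dots)) rec[[nm]] <- dots[[nm]]
  rec
}

bind_records <- function(...) do.call(rbind, list(...))

random_injury_tokens <- function(max_injuries = 6) {
  k <- sample(0:max_injuries, 1)
  if (k == 0) return("")
  paste(paste0(sample(1:6, k, replace = TRUE), ":",
               sample(ISS_REGIONS, k, replace = TRUE)),
        collapse = ";")
}

# random record with a mix of observed and unknown fields
random_record <- function(id = "r") {
  maybe <- function(x) if (runif(1) < 0.3) NA else x
  blank_record(
    id = id,
    age_years = sample(1:95, 1),
    injuries = random_injury_tokens(),
    sex = maybe(sample(c("male", "female"), 1)),
    asa = maybe(sample(1:4, 1)),
    mechanism = maybe(sample(c("blunt", "penetrating"), 1)),
    pupil_reactivity = maybe(sample(c("brisk", "sluggish", "fixed"), 1)),
    pupil_size = maybe(sample(c("normal", "anisocoria",
                                "bilateral_dilated"), 1)),
    gcs_motor = maybe(sample(1:6, 1)),
    cpr = maybe(sample(c("yes", "no"), 1)),
    sbp = maybe(runif(1, 40, 200)),
    inr = maybe(runif(1, 0.8, 5)),
    hb = maybe(runif(1, 3, 17)),
    base_deficit = maybe(runif(1, -10, 30)))
}

# ISS oracle: maximise sum of squared region-maxima over all subsets of
# at most three distinct regions (brute force; AIS 6 caps at 75)
iss_oracle <- function(injuries) {
  injuries <- parse_injuries(injuries)
  if (!nrow(injuries)) return(0L)
  if (any(injuries$severity == 6)) return(75L)
  rmax <- tapply(injuries$severity, injuries$region, max)
  regions <- names(rmax)
  best <- 0
  for (k in seq_len(min(3, length(regions)))) {
    combos <- utils::combn(regions, k, simplify = FALSE)
    for (cc in combos) best <- max(best, sum(rmax[cc]^2))
  }
  as.integer(best)
}

# NISS oracle: maximise sum of squares over all subsets of at most three
# individual injuries
niss_oracle <- function(injuries) {
  injuries <- parse_injuries(injuries)
  sev <- injuries$severity
  if (!length(sev)) return(0L)
  if (any(sev == 6)) return(75L)
  best <- 0
  for (k in seq_len(min(3, length(sev)))) {
    combos <- utils::combn(seq_along(sev), k, simplify = FALSE)
    for (cc in combos) best <- max(best, sum(sev[cc]^2))
  }
  as.integer(best)
}

# AUC oracle: exhaustive concordant-pair counting, ties count one half
auc_oracle <- function(p_death, died) {
  pos <- p_death[died]
  neg <- p_death[!died]
  total <- 0
  for (a in pos) for (b in neg)
    total <- total + (a > b) + 0.5 * (a == b)
  total / (length(pos) * length(neg))
}

sort_exceptions <- function(df) {
  df <- df[order(df$variable, df$label, df$field), ]
  rownames(df) <- NULL
  df
}
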