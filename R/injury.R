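#' ISS body regions
#'
#' The six body regions of the Injury Severity Score. `head_neck` is the
#' region used both for the ISS and for the head-injury predictor of RISC II;
#' face is a separate region.
#'
#' @export
ISS_REGIONS <- c("head_neck", "face", "chest", "abdomen",
                 "extremities_pelvis", "external")

#' Parse an injury token string
#'
#' Injuries travel through tabular I/O as a single `";"`-separated string of
#' `severity:region` tokens, e.g. `"5:head_neck;3:chest"`.  An empty string
#' (or `NA`) means no coded injuries.
#'
#' @param tokens A single character string of `";"`-separated tokens.
#' @param ais_map Optional data frame with columns `code`, `severity`,
#'   `region` used to resolve tokens that are bare AIS codes rather than
#'   `severity:region` pairs.
#' @return A data frame with integer column `severity` (1-6) and character
#'   column `region` (one of [ISS_REGIONS]), one row per injury.
#' @examples
#' parse_injuries("5:head_neck;3:chest")
#' @export
parse_injuries <- function(tokens, ais_map = NULL) {
  empty <- data.frame(severity = integer(0), region = character(0))
  if (length(tokens) != 1L) stop("'tokens' must be a single string")
  if (is.na(tokens) || !nzchar(trimws(tokens))) return(empty)
  parts <- trimws(strsplit(tokens, ";", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (!length(parts)) return(empty)
  sev <- integer(length(parts))
  reg <- character(length(parts))
  for (i in seq_along(parts)) {
    p <- parts[i]
    if (grepl(":", p, fixed = TRUE)) {
      bits <- strsplit(p, ":", fixed = TRUE)[[1]]
      sev[i] <- suppressWarnings(as.integer(bits[1]))
      reg[i] <- bits[2]
    } else if (!is.null(ais_map)) {
      hit <- match(p, as.character(ais_map$code))
      if (is.na(hit)) stop("unrecognised AIS code in injury list: '", p, "'")
      sev[i] <- as.integer(ais_map$severity[hit])
      reg[i] <- as.character(ais_map$region[hit])
    } else {
      stop("cannot parse injury token '", p,
           "' (expected 'severity:region'; supply 'ais_map' for bare codes)")
    }
  }
  validate_injuries(data.frame(severity = sev, region = reg,
                               stringsAsFactors = FALSE))
}

validate_injuries <- function(injuries) {
  if (is.character(injuries) && length(injuries) == 1L)
    injuries <- parse_injuries(injuries)
  stopifnot(is.data.frame(injuries),
            all(c("severity", "region") %in% names(injuries)))
  sev <- injuries$severity
  if (any(is.na(sev)) || any(sev < 1L | sev > 6L) || any(sev != floor(sev)))
    stop("AIS severity must be an integer in 1..6")
  bad <- setdiff(unique(injuries$region), ISS_REGIONS)
  if (length(bad))
    stop("unknown ISS body region(s): ", paste(bad, collapse = ", "))
  injuries
}

#' Injury Severity Score (ISS)
#'
#' Sum of squares of the highest AIS severity in each of the (up to) three
#' worst-affected of the six ISS body regions.  By convention any AIS grade 6
#' injury sets the score to its maximum of 75.  An empty injury list scores 0.
#'
#' @param injuries A data frame as returned by [parse_injuries()], or a
#'   token string accepted by it.
#' @return Integer ISS in 0-75.
#' @examples
#' compute_iss("3:head_neck;3:chest;3:abdomen")  # 27
#' compute_iss("5:chest")                        # 25
#' @export
compute_iss <- function(injuries) {
  injuries <- validate_injuries(injuries)
  if (!nrow(injuries)) return(0L)
  if (any(injuries$severity == 6L)) return(75L)
  region_max <- tapply(injuries$severity, injuries$region, max)
  top <- sort(as.integer(region_max), decreasing = TRUE)
  top <- top[seq_len(min(3L, length(top)))]
  as.integer(sum(top^2))
}

#' New Injury Severity Score (NISS)
#'
#' Sum of squares of the three highest AIS severities regardless of body
#' region; otherwise as [compute_iss()] (AIS 6 caps the score at 75).
#'
#' @inheritParams compute_iss
#' @return Integer NISS in 0-75.
#' @examples
#' compute_niss("4:chest;3:chest;3:chest;2:face")  # 34
#' @export
compute_niss <- function(injuries) {
  injuries <- validate_injuries(injuries)
  if (!nrow(injuries)) return(0L)
  if (any(injuries$severity == 6L)) return(75L)
  top <- sort(injuries$severity, decreasing = TRUE)
  top <- top[seq_len(min(3L, length(top)))]
  as.integer(sum(top^2))
}

#' Injury severity profile of one patient
#'
#' Derives the anatomical severity summaries RISC II scores from: the worst
#' and second-worst AIS severities over all injuries (any regions, including
#' two injuries in the same region), the worst head/neck severity, and
#' ISS/NISS.  With fewer than two coded injuries the second-worst severity is
#' zero; with none, all fields are zero.
#'
#' @inheritParams compute_iss
#' @return A one-row data frame with integer columns `worst_ais`,
#'   `second_worst_ais`, `head_ais`, `iss`, `niss`.
#' @examples
#' derive_injury_profile("5:head_neck;3:chest")
#' @export
derive_injury_profile <- function(injuries) {
  injuries <- validate_injuries(injuries)
  sev <- sort(injuries$severity, decreasing = TRUE)
  head_sev <- injuries$severity[injuries$region == "head_neck"]
  data.frame(
    worst_ais = if (length(sev)) sev[1] else 0L,
    second_worst_ais = if (length(sev) > 1L) sev[2] else 0L,
    head_ais = if (length(head_sev)) max(head_sev) else 0L,
    iss = compute_iss(injuries),
    niss = compute_niss(injuries))
}

#' Injury profiles for a whole cohort
#'
#' Applies [derive_injury_profile()] to the `injuries` token column of a
#' patient table.
#'
#' @param x A patient table (data frame with an `injuries` column) or a
#'   character vector of injury token strings.
#' @param ais_map Passed to [parse_injuries()].
#' @return A data frame with one profile row per patient.
#' @export
injury_profiles <- function(x, ais_map = NULL) {
  tokens <- if (is.data.frame(x)) x$injuries else x
  if (is.null(tokens)) stop("no 'injuries' column found")
  n <- length(tokens)
  tokens <- as.character(tokens)
  tokens[is.na(tokens)] <- ""
  out <- data.frame(worst_ais = integer(n), second_worst_ais = integer(n),
                    head_ais = integer(n), iss = integer(n),
                    niss = integer(n))
  parts <- strsplit(tokens, ";", fixed = TRUE)
  parts <- lapply(parts, function(p) { p <- trimws(p); p[nzchar(p)] })
  counts <- lengths(parts)
  flat <- unlist(parts, use.names = FALSE)
  if (!length(flat)) return(out)
  rid <- rep.int(seq_len(n), counts)

  has_colon <- grepl(":", flat, fixed = TRUE)
  sev <- rep(NA_integer_, length(flat))
  reg <- rep(NA_character_, length(flat))
  sev[has_colon] <- suppressWarnings(
    as.integer(sub(":.*$", "", flat[has_colon])))
  reg[has_colon] <- sub("^[^:]*:", "", flat[has_colon])
  if (any(!has_colon)) {
    if (is.null(ais_map))
      stop("cannot parse injury token '", flat[!has_colon][1],
           "' (expected 'severity:region'; supply 'ais_map' for bare codes)")
    hit <- match(flat[!has_colon], as.character(ais_map$code))
    if (anyNA(hit))
      stop("unrecognised AIS code in injury list: '",
           flat[!has_colon][is.na(hit)][1], "'")
    sev[!has_colon] <- as.integer(ais_map$severity[hit])
    reg[!has_colon] <- as.character(ais_map$region[hit])
  }
  if (anyNA(sev) || any(sev < 1L | sev > 6L))
    stop("AIS severity must be an integer in 1..6")
  bad <- setdiff(unique(reg), ISS_REGIONS)
  if (length(bad))
    stop("unknown ISS body region(s): ", paste(bad, collapse = ", "))

  # worst / second-worst / NISS from severities sorted within record
  ord <- order(rid, -sev)
  rid_o <- rid[ord]; sev_o <- sev[ord]
  gs <- rle(rid_o)$lengths
  first <- which(!duplicated(rid_o))
  out$worst_ais[rid_o[first]] <- sev_o[first]
  second_at <- first[gs >= 2L] + 1L
  out$second_worst_ais[rid_o[second_at]] <- sev_o[second_at]
  pos <- sequence(gs)
  top3 <- pos <= 3L
  niss <- rowsum(sev_o[top3]^2, rid_o[top3])
  out$niss[as.integer(rownames(niss))] <- as.integer(niss)

  # head/neck maximum
  hsel <- reg == "head_neck"
  if (any(hsel)) {
    agg <- tapply(sev[hsel], rid[hsel], max)
    out$head_ais[as.integer(names(agg))] <- as.integer(agg)
  }

  # ISS: per-record top-3 region maxima
  ord2 <- order(rid, reg, -sev)
  keydup <- duplicated(paste(rid[ord2], reg[ord2], sep = "\r"))
  rm_rid <- rid[ord2][!keydup]; rm_sev <- sev[ord2][!keydup]
  ord3 <- order(rm_rid, -rm_sev)
  rr <- rm_rid[ord3]; rs <- rm_sev[ord3]
  pos2 <- sequence(rle(rr)$lengths)
  topr <- pos2 <= 3L
  iss <- rowsum(rs[topr]^2, rr[topr])
  out$iss[as.integer(rownames(iss))] <- as.integer(iss)

  # any AIS 6 caps both scores at 75
  cap <- unique(rid[sev == 6L])
  out$iss[cap] <- 75L
  out$niss[cap] <- 75L
  out
}
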