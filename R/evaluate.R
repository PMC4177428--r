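normalize_outcomes <- function(outcomes) {
  died <- if (is.logical(outcomes)) outcomes
  else if (is.numeric(outcomes)) outcomes != 0
  else as.character(outcomes) == "died"
  if (anyNA(died)) stop("outcomes must be known ('survived'/'died')")
  died
}

#' ROC area under the curve with DeLong confidence interval
#'
#' Discrimination: the probability that a randomly chosen non-survivor has a
#' higher predicted death probability than a randomly chosen survivor (ties
#' count one half); 0.5 is chance, 1.0 perfect separation.  The confidence
#' interval uses the DeLong method.
#'
#' @param p_death Predicted death probabilities (any monotone risk score
#'   works: the AUC is rank-based).
#' @param outcomes `"survived"`/`"died"`, or logical/0-1 death indicator.
#' @param conf Confidence level; default 0.95.
#' @return Named numeric vector `c(auc, lo, hi)`.
#' @export
auc_with_ci <- function(p_death, outcomes, conf = 0.95) {
  died <- normalize_outcomes(outcomes)
  if (!any(died) || all(died))
    stop("AUC undefined: need at least one death and one survivor")
  roc <- pROC::roc(response = died, predictor = p_death,
                   levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- as.numeric(pROC::ci.auc(roc, conf.level = conf, method = "delong"))
  c(auc = as.numeric(pROC::auc(roc)), lo = ci[1], hi = ci[3])
}

#' Hosmer-Lemeshow calibration statistic over deciles of risk
#'
#' Splits the cohort into `n_groups` near-equal groups by sorted predicted
#' death probability (ties broken by original record order) and compares
#' observed with expected deaths:
#' `HL = sum_g (O_g - E_g)^2 / (n_g * pbar_g * (1 - pbar_g))`, with
#' `E_g = n_g * pbar_g` and `pbar_g` the group's mean predicted probability.
#' Low values indicate good calibration.  A group whose mean probability is
#' exactly 0 or 1 has its denominator clamped (`pbar` moved to `0.5/n_g`
#' from the boundary) and is flagged in the returned table.
#'
#' @inheritParams auc_with_ci
#' @param n_groups Number of risk groups; default 10 (deciles).
#' @return List with `statistic` and `table` (data frame: `band`, `n`,
#'   `observed`, `expected`, `mean_p`, `flagged`).
#' @export
hosmer_lemeshow <- function(p_death, outcomes, n_groups = 10) {
  died <- normalize_outcomes(outcomes)
  n <- length(p_death)
  stopifnot(length(died) == n, n >= n_groups, n_groups >= 2)
  ord <- order(p_death)                      # stable: ties keep input order
  cuts <- floor(n * (0:n_groups) / n_groups)
  band_of <- rep(seq_len(n_groups), diff(cuts))
  band <- integer(n)
  band[ord] <- band_of
  rows <- lapply(seq_len(n_groups), function(g) {
    in_g <- band == g
    n_g <- sum(in_g)
    pbar <- mean(p_death[in_g])
    flagged <- pbar <= 0 || pbar >= 1
    pb <- min(max(pbar, 0.5 / n_g), 1 - 0.5 / n_g)
    O <- sum(died[in_g])
    E <- n_g * pbar
    data.frame(band = g, n = n_g, observed = O, expected = E,
               mean_p = pbar, term = (O - E)^2 / (n_g * pb * (1 - pb)),
               flagged = flagged)
  })
  tab <- do.call(rbind, rows)
  list(statistic = sum(tab$term),
       table = tab[, c("band", "n", "observed", "expected", "mean_p",
                       "flagged")])
}

#' Precision: observed versus mean predicted mortality
#'
#' @inheritParams auc_with_ci
#' @return List with `observed` (death fraction), `predicted` (mean
#'   predicted death probability) and `difference` (predicted - observed).
#' @export
precision_report <- function(p_death, outcomes) {
  died <- normalize_outcomes(outcomes)
  stopifnot(length(p_death) == length(died), length(died) > 0)
  observed <- mean(died)
  predicted <- mean(p_death)
  list(observed = observed, predicted = predicted,
       difference = predicted - observed)
}

#' Observed and predicted mortality in increasing risk bands
#'
#' The calibration-plot table: the cohort is split into `n_bands` near-equal
#' groups of increasing predicted risk; each band reports its observed death
#' rate and mean predicted death probability.
#'
#' @inheritParams hosmer_lemeshow
#' @param n_bands Number of risk bands; default 10.
#' @return Data frame: `band`, `n`, `observed_rate`, `predicted_rate`.
#' @export
risk_band_table <- function(p_death, outcomes, n_bands = 10) {
  hl <- hosmer_lemeshow(p_death, outcomes, n_groups = n_bands)
  tab <- hl$table
  data.frame(band = tab$band, n = tab$n,
             observed_rate = tab$observed / tab$n,
             predicted_rate = tab$mean_p)
}

#' Full evaluation report for a vector of predictions
#'
#' Discrimination (AUC with DeLong CI), precision (observed vs mean predicted
#' mortality) and calibration (Hosmer-Lemeshow over deciles of risk) in one
#' object.
#'
#' @inheritParams hosmer_lemeshow
#' @param conf Confidence level for the AUC interval.
#' @param nagelkerke Optional Nagelkerke R-squared to carry along.
#' @return An `evaluation_report` object (list with `auc`, `auc_ci`,
#'   `observed_mortality`, `predicted_mortality`, `hl_statistic`, `hl_table`,
#'   `risk_bands`, `nagelkerke_r2`, `n`).
#' @export
evaluate_predictions <- function(p_death, outcomes, n_groups = 10,
                                 conf = 0.95, nagelkerke = NULL) {
  auc <- auc_with_ci(p_death, outcomes, conf)
  hl <- hosmer_lemeshow(p_death, outcomes, n_groups)
  prec <- precision_report(p_death, outcomes)
  structure(list(
    auc = auc[["auc"]], auc_ci = c(auc[["lo"]], auc[["hi"]]),
    observed_mortality = prec$observed,
    predicted_mortality = prec$predicted,
    hl_statistic = hl$statistic, hl_table = hl$table,
    risk_bands = risk_band_table(p_death, outcomes, n_groups),
    nagelkerke_r2 = nagelkerke, n = length(p_death)),
    class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("Evaluation of", x$n, "predictions\n")
  cat(sprintf("  discrimination: AUC = %.3f (%.3f-%.3f)\n",
              x$auc, x$auc_ci[1], x$auc_ci[2]))
  cat(sprintf("  precision:      observed %.1f%% vs predicted %.1f%% mortality\n",
              100 * x$observed_mortality, 100 * x$predicted_mortality))
  cat(sprintf("  calibration:    Hosmer-Lemeshow = %.1f over %d groups\n",
              x$hl_statistic, nrow(x$hl_table)))
  if (!is.null(x$nagelkerke_r2))
    cat(sprintf("  Nagelkerke R2:  %.3f\n", x$nagelkerke_r2))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `evaluation_report`.
#' @param path Output path.
#' @export
write_evaluation_report <- function(report, path) {
  payload <- unclass(report)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows")
  invisible(path)
}
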