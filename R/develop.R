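#' Enforce a minimum reference-category fraction
#'
#' During score development the stability of coefficients depends on the size
#' of each variable's reference (missing) category, so variables with few
#' missing values have a randomly selected set of observed cases reassigned
#' to the reference category until it first reaches at least the target
#' fraction (about 20% of cases).  Columns already at or above the target are
#' returned unchanged; reassignment draws uniformly without replacement and
#' is deterministic given `seed`.  This deletion applies to model building
#' only — scoring always uses all available data.
#'
#' @param column Character or factor vector of category assignments.
#' @param reference The reference category label.
#' @param target_fraction Minimum reference share, in `(0, 1]`; default 0.20.
#' @param seed Optional integer seed (local to this call).
#' @return The column with reassignments applied (same type as input).
#' @export
enforce_reference_fraction <- function(column, reference,
                                       target_fraction = 0.20, seed = NULL) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      is.na(target_fraction) || target_fraction <= 0 || target_fraction > 1)
    stop("'target_fraction' must be a number in (0, 1]")
  was_factor <- is.factor(column)
  col <- as.character(column)
  n <- length(col)
  if (!n) return(column)
  n_ref <- sum(col == reference)
  need <- ceiling(target_fraction * n) - n_ref
  if (need <= 0) return(column)
  idx <- which(col != reference)
  pick <- local_seed(seed, sample(idx, size = need))
  col[pick] <- reference
  if (was_factor) factor(col, levels = levels(column)) else col
}

# evaluate expr under a temporary RNG state when seed is given
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

categories_to_factors <- function(categories, spec, variables) {
  out <- lapply(variables, function(nm) {
    v <- spec$variables[[nm]]
    factor(categories[[nm]], levels = c(v$label[v$is_reference],
                                        v$label[!v$is_reference]))
  })
  names(out) <- variables
  as.data.frame(out, check.names = FALSE)
}

#' Fit a missing-as-reference logistic model
#'
#' Maximum-likelihood binary logistic regression with survival (not death) as
#' the dependent variable, dummy-coding every predictor against its reference
#' category — the category that also absorbs missing values, whose
#' coefficient is therefore zero by construction.  Positive coefficients are
#' protective, matching the published table's sign convention.
#'
#' @param records Patient table with known `outcome`.
#' @param spec A `risc_model` supplying the category structure (labels and
#'   reference) of each variable; fitted coefficients replace its values in
#'   the returned object's `spec` when requested via [fit_to_spec()].
#' @param variables Character vector of model variables to include; default
#'   all variables of `spec`.
#' @param enforce_reference If `TRUE`, applies [enforce_reference_fraction()]
#'   to every variable before fitting.
#' @param target_fraction Target for the enforcement step.
#' @param seed Seed for the enforcement step.
#' @param categories Optional pre-computed [categorize_patients()] output.
#' @return A `risc_fit` object: data frame `coefficients` (one row per
#'   non-reference category: `variable`, `label`, `coefficient`, `se`, `p`,
#'   `or`, `or_lo`, `or_hi`, `n`), plus `loglik`, `loglik_null`, `n`,
#'   `nagelkerke_r2`, `reference_fractions`, `merged_empty`, `variables`.
#' @export
fit_missing_as_reference <- function(records, spec = risc2_model(),
                                     variables = names(spec$variables),
                                     enforce_reference = FALSE,
                                     target_fraction = 0.20, seed = NULL,
                                     categories = NULL) {
  if (anyNA(records$outcome))
    stop("all records must have a known outcome for model fitting")
  if (is.null(categories)) categories <- categorize_patients(records)
  design <- categories_to_factors(categories, spec, variables)
  if (enforce_reference) {
    for (j in seq_along(design)) {
      s <- if (is.null(seed)) NULL else seed + j
      design[[j]] <- enforce_reference_fraction(
        design[[j]], reference = levels(design[[j]])[1],
        target_fraction = target_fraction, seed = s)
    }
  }
  y <- as.integer(records$outcome == "survived")

  merged_empty <- character(0)
  for (j in seq_along(design)) {
    tab <- table(design[[j]])
    empty <- names(tab)[tab == 0L & names(tab) != levels(design[[j]])[1]]
    if (length(empty)) {
      merged_empty <- c(merged_empty,
                        paste0(names(design)[j], ":", empty))
      design[[j]] <- droplevels(design[[j]])
    }
  }
  if (length(merged_empty))
    warning("empty categor(ies) merged into reference: ",
            paste(merged_empty, collapse = ", "))
  keep <- vapply(design, function(f) nlevels(f) > 1L, logical(1))
  design <- design[keep]

  dat <- cbind(data.frame(.y = y), design)
  fit <- if (ncol(design))
    stats::glm(.y ~ ., data = dat, family = stats::binomial())
  else  # every variable collapsed to its reference: intercept-only model
    stats::glm(.y ~ 1, data = dat, family = stats::binomial())
  co <- summary(fit)$coefficients
  big <- rownames(co)[abs(co[, "Estimate"]) > 10 | co[, "Std. Error"] > 50]
  if (!fit$converged || length(big))
    stop("logistic fit did not converge cleanly",
         if (length(big)) paste0(" (suspect separation in: ",
                                 paste(big, collapse = ", "), ")"))

  rows <- list()
  for (nm in names(design)) {
    lv <- levels(design[[nm]])
    for (lab in lv[-1]) {
      i <- intersect(c(paste0(nm, lab), paste0("`", nm, "`", lab)),
                     rownames(co))[1]
      if (is.na(i))
        stop("term for ", nm, ":", lab, " not found in fit")
      est <- co[i, "Estimate"]; se <- co[i, "Std. Error"]
      rows[[length(rows) + 1L]] <- data.frame(
        variable = nm, label = lab, coefficient = est, se = se,
        p = co[i, "Pr(>|z|)"], or = exp(est),
        or_lo = exp(est - 1.96 * se), or_hi = exp(est + 1.96 * se),
        n = sum(design[[nm]] == lab), stringsAsFactors = FALSE)
    }
  }
  coefs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variable = character(0), label = character(0),
               coefficient = numeric(0), se = numeric(0), p = numeric(0),
               or = numeric(0), or_lo = numeric(0), or_hi = numeric(0),
               n = integer(0), stringsAsFactors = FALSE)
  rownames(coefs) <- NULL

  ll <- as.numeric(stats::logLik(fit))
  fit0 <- stats::glm(.y ~ 1, data = dat, family = stats::binomial())
  ll0 <- as.numeric(stats::logLik(fit0))
  structure(list(
    coefficients = coefs,
    intercept = unname(co["(Intercept)", "Estimate"]),
    loglik = ll, loglik_null = ll0, n = length(y),
    nagelkerke_r2 = nagelkerke_r2(ll, ll0, length(y)),
    reference_fractions = vapply(design, function(f)
      mean(f == levels(f)[1]), numeric(1)),
    merged_empty = merged_empty,
    variables = names(design)),
    class = "risc_fit")
}

#' @export
print.risc_fit <- function(x, ...) {
  cat("Missing-as-reference logistic fit: n =", x$n,
      sprintf("; Nagelkerke R2 = %.3f\n", x$nagelkerke_r2))
  cat(sprintf("constant = %.3f; log-likelihood = %.1f (null %.1f)\n",
              x$intercept, x$loglik, x$loglik_null))
  tab <- x$coefficients
  tab$coefficient <- round(tab$coefficient, 3)
  tab$se <- round(tab$se, 3)
  tab$p <- signif(tab$p, 2)
  tab$or <- round(tab$or, 2)
  tab$or_lo <- round(tab$or_lo, 2)
  tab$or_hi <- round(tab$or_hi, 2)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Turn a fit into a score specification
#'
#' Builds a `risc_model` from fitted coefficients: reference categories keep
#' value 0, score points are the coefficients rounded to one decimal, and the
#' fitted intercept becomes the constant.
#'
#' @param fit A `risc_fit`.
#' @param spec The `risc_model` that supplied the category structure.
#' @return A `risc_model`.
#' @export
fit_to_spec <- function(fit, spec) {
  vars <- lapply(fit$variables, function(nm) {
    v <- spec$variables[[nm]]
    coefs <- numeric(nrow(v))
    for (i in seq_len(nrow(v))) {
      j <- which(fit$coefficients$variable == nm &
                 fit$coefficients$label == v$label[i])
      coefs[i] <- if (length(j)) fit$coefficients$coefficient[j] else 0
    }
    new_variable(nm, v$label, round(coefs, 1), coefs,
                 v$label[v$is_reference])
  })
  names(vars) <- fit$variables
  structure(list(variables = vars,
                 constant = list(score = round(fit$intercept, 1),
                                 coefficient = fit$intercept),
                 version = "refit-1"),
            class = "risc_model")
}

#' Nagelkerke's pseudo R-squared
#'
#' Strength of association of a binary model with the observed outcome:
#' `R2 = (1 - exp(2 (ll0 - ll) / n)) / (1 - exp(2 ll0 / n))`, where `ll` and
#' `ll0` are model and null (intercept-only) log-likelihoods.
#'
#' @param loglik_model Model log-likelihood (>= `loglik_null`).
#' @param loglik_null Null-model log-likelihood (< 0; a degenerate null with
#'   all outcomes identical is rejected).
#' @param n Number of observations.
#' @return Number in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(loglik_model, loglik_null, n) {
  stopifnot(n >= 1)
  if (loglik_model < loglik_null - 1e-8)
    stop("model log-likelihood below null log-likelihood")
  if (loglik_null >= -1e-12)
    stop("degenerate null model (all outcomes identical): R2 undefined")
  cox_snell <- 1 - exp(2 * (loglik_null - loglik_model) / n)
  max_r2 <- 1 - exp(2 * loglik_null / n)
  cox_snell / max_r2
}

#' Greedy forward selection by Nagelkerke R-squared
#'
#' Starts from a basic model (by default age and the three injury-severity
#' variables) and repeatedly adds the candidate variable that most improves
#' Nagelkerke's R-squared, stopping when the best improvement falls below
#' `min_delta_r2`.
#'
#' @inheritParams fit_missing_as_reference
#' @param base_variables Variables of the starting model.
#' @param candidates Candidate variables to consider adding.
#' @param min_delta_r2 Minimum R-squared improvement to keep adding;
#'   default 0.002.
#' @return A data frame trace with columns `step`, `variable`, `r2`
#'   (`step` 0 is the base model); R-squared is non-decreasing down the rows.
#' @export
forward_select <- function(records, spec = risc2_model(),
                           base_variables = c("age", "worst_injury",
                                              "second_worst_injury",
                                              "head_injury"),
                           candidates = setdiff(names(spec$variables),
                                                base_variables),
                           min_delta_r2 = 0.002, categories = NULL, ...) {
  if (is.null(categories)) categories <- categorize_patients(records)
  fit_r2 <- function(vars)
    fit_missing_as_reference(records, spec, variables = vars,
                             categories = categories, ...)$nagelkerke_r2
  current <- unique(base_variables)
  pool <- setdiff(candidates, current)
  r2 <- fit_r2(current)
  trace <- data.frame(step = 0L, variable = "(base)", r2 = r2,
                      stringsAsFactors = FALSE)
  step <- 0L
  while (length(pool)) {
    gains <- vapply(pool, function(v) fit_r2(c(current, v)), numeric(1))
    best <- which.max(gains)
    if (gains[best] - r2 < min_delta_r2) break
    step <- step + 1L
    current <- c(current, pool[best])
    r2 <- gains[best]
    trace <- rbind(trace, data.frame(step = step, variable = pool[best],
                                     r2 = r2, stringsAsFactors = FALSE))
    pool <- pool[-best]
  }
  trace
}

#' Merge weak categories into the reference
#'
#' Categories whose Wald p-value meets or exceeds `p_threshold` ("no or only
#' minor effects") are merged into their variable's reference category; the
#' caller should refit afterwards.  A variable left with only its reference
#' category is dropped with a warning.  Merges are recorded in the returned
#' spec's `provenance`.
#'
#' @param fit A `risc_fit`.
#' @param spec The `risc_model` the fit was based on.
#' @param p_threshold Wald p-value threshold; default 0.05.
#' @return A modified `risc_model`.
#' @export
merge_weak_categories <- function(fit, spec, p_threshold = 0.05) {
  merged <- character(0)
  dropped <- character(0)
  vars <- list()
  for (nm in fit$variables) {
    v <- spec$variables[[nm]]
    weak <- fit$coefficients$label[fit$coefficients$variable == nm &
                                   fit$coefficients$p >= p_threshold]
    keep <- !(v$label %in% weak)
    if (length(weak))
      merged <- c(merged, paste0(nm, ":", weak))
    if (sum(keep) <= 1L) {  # only the reference would remain
      dropped <- c(dropped, nm)
      next
    }
    ref_lab <- v$label[v$is_reference]
    new_labels <- v$label[keep]
    ref_new <- if (length(weak))
      paste(c(ref_lab, weak), collapse = "/") else ref_lab
    new_labels[new_labels == ref_lab] <- ref_new
    vars[[nm]] <- new_variable(
      nm, new_labels,
      ifelse(new_labels == ref_new, 0, v$score[keep]),
      ifelse(new_labels == ref_new, 0, v$coefficient[keep]),
      ref_new)
  }
  if (length(dropped))
    warning("variable(s) dropped (all categories merged into reference): ",
            paste(dropped, collapse = ", "))
  out <- structure(list(variables = vars, constant = spec$constant,
                        version = paste0(spec$version, "+merged")),
                   class = "risc_model")
  out$provenance <- list(merged = merged, dropped = dropped,
                         p_threshold = p_threshold)
  out
}

#' Wilson score confidence interval for a proportion
#'
#' @param x Number of events.
#' @param n Number of trials (> 0).
#' @param conf Confidence level; default 0.95.
#' @return Numeric vector `c(lo, hi)`.
#' @export
wilson_ci <- function(x, n, conf = 0.95) {
  stopifnot(n > 0, x >= 0, x <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  centre <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(lo = max(0, centre - half), hi = min(1, centre + half))
}

#' Check that reference-group mortality covers the overall rate
#'
#' The missing-as-reference design is only defensible when mortality in each
#' variable's reference (missing) group is compatible with the cohort's
#' overall mortality; this check computes, per variable, the reference-group
#' mortality with its Wilson confidence interval and flags variables whose
#' interval does not cover the overall rate.
#'
#' @param records Patient table with known outcomes.
#' @param spec A `risc_model`.
#' @param variables Variables to check; default all in `spec`.
#' @param conf Confidence level; default 0.95.
#' @param categories Optional pre-computed [categorize_patients()] output.
#' @return Data frame: `variable`, `n_ref`, `deaths_ref`, `mortality_ref`,
#'   `ci_lo`, `ci_hi`, `overall_mortality`, `pass` (logical; `NA` with a
#'   flag when the reference group is empty).
#' @export
reference_group_coverage_check <- function(records, spec = risc2_model(),
                                           variables = names(spec$variables),
                                           conf = 0.95, categories = NULL) {
  if (anyNA(records$outcome)) stop("outcomes must be known")
  if (is.null(categories)) categories <- categorize_patients(records)
  died <- records$outcome == "died"
  overall <- mean(died)
  rows <- lapply(variables, function(nm) {
    v <- spec$variables[[nm]]
    ref <- categories[[nm]] == v$label[v$is_reference]
    n_ref <- sum(ref)
    if (!n_ref)
      return(data.frame(variable = nm, n_ref = 0L, deaths_ref = 0L,
                        mortality_ref = NA_real_, ci_lo = NA_real_,
                        ci_hi = NA_real_, overall_mortality = overall,
                        pass = NA, stringsAsFactors = FALSE))
    d <- sum(died[ref])
    ci <- wilson_ci(d, n_ref, conf)
    data.frame(variable = nm, n_ref = n_ref, deaths_ref = d,
               mortality_ref = d / n_ref, ci_lo = ci[["lo"]],
               ci_hi = ci[["hi"]], overall_mortality = overall,
               pass = ci[["lo"]] <= overall & overall <= ci[["hi"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
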