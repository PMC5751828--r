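#' Crude odds ratio from a 2x2 table
#'
#' `OR = (a * d) / (b * c)` for a table with cells a = exposed with event,
#' b = exposed without event, c = reference with event, d = reference
#' without event, with a Woolf (log-scale Wald) confidence interval
#' `exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` and a Wald p-value.
#' The Haldane-Anscombe correction adds 0.5 to every cell before the
#' arithmetic and is required when a cell is zero.
#'
#' @param t numeric vector `c(a, b, c, d)` (optionally named) or 2x2 matrix
#'   `rbind(c(a, b), c(c, d))`.
#' @param correction `"none"` or `"haldane"`.
#' @param conf_level confidence level for the Woolf interval.
#' @return List of class `odds_ratio_result`: `or`, `ci_low`, `ci_high`,
#'   `p_value`, `method = "crude"`, `correction_applied`.
#' @export
crude_or <- function(t, correction = c("none", "haldane"),
                     conf_level = 0.95) {
  correction <- match.arg(correction)
  cells <- as.numeric(t)
  if (length(cells) != 4 || any(cells < 0) || any(cells != round(cells)))
    stop_np("need four nonnegative integer cells (a, b, c, d)")
  if (correction == "none" && any(cells == 0))
    stop_np("zero cell in 2x2 table; use correction = 'haldane'")
  if (correction == "haldane") cells <- cells + 0.5
  a <- cells[1]; b <- cells[2]; cc <- cells[3]; d <- cells[4]
  or <- (a * d) / (b * cc)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  z <- qnorm(1 - (1 - conf_level) / 2)
  p <- 2 * pnorm(-abs(log(or) / se))
  structure(list(or = or, ci_low = exp(log(or) - z * se),
                 ci_high = exp(log(or) + z * se), p_value = p,
                 method = "crude",
                 correction_applied = correction == "haldane"),
            class = "odds_ratio_result")
}

#' @export
print.odds_ratio_result <- function(x, ...) {
  cat(sprintf("OR %.2f (95%% CI %.2f-%.2f), p = %.3g [%s%s]\n",
              x$or, x$ci_low, x$ci_high, x$p_value, x$method,
              if (isTRUE(x$correction_applied)) ", Haldane" else ""))
  invisible(x)
}

#' Per-profile 2x2 outcome tables
#'
#' Builds, from per-subject profile membership and a binary outcome, the
#' exposed-versus-reference 2x2 table for every non-reference profile plus
#' one-versus-all-others tables for requested profiles. Subjects with a
#' missing outcome are excluded (complete case) and counted.
#'
#' @param profiles character/factor of profile names, one per subject.
#' @param outcome logical (or 0/1) event indicator; `NA` allowed.
#' @param reference reference profile name (default `"Moraxella-dominant"`).
#' @param versus_all profiles to also tabulate against all other subjects.
#' @return List with `reference`, `tables` (named list of `c(a, b, c, d)`
#'   versus the reference), `versus_all` tables, and `n_missing`.
#' @export
profile_outcome_tables <- function(profiles, outcome,
                                   reference = "Moraxella-dominant",
                                   versus_all = character()) {
  profiles <- as.character(profiles)
  stopifnot(length(profiles) == length(outcome))
  if (!reference %in% profiles)
    stop_np("reference profile '%s' has no subjects", reference)
  if (reference %in% versus_all)
    stop_np("reference profile cannot also be an exposure profile")
  keep <- !is.na(outcome)
  n_missing <- sum(!keep)
  if (!any(keep)) stop_np("outcome missing for every subject")
  profiles <- profiles[keep]
  ev <- as.logical(outcome[keep])
  others <- setdiff(unique(profiles), reference)
  ref_mask <- profiles == reference
  tables <- lapply(others, function(pr) {
    c(a = sum(profiles == pr & ev), b = sum(profiles == pr & !ev),
      c = sum(ref_mask & ev), d = sum(ref_mask & !ev))
  })
  names(tables) <- others
  va <- lapply(versus_all, function(pr) {
    if (!pr %in% profiles) stop_np("profile '%s' has no subjects", pr)
    c(a = sum(profiles == pr & ev), b = sum(profiles == pr & !ev),
      c = sum(profiles != pr & ev), d = sum(profiles != pr & !ev))
  })
  names(va) <- versus_all
  empty <- vapply(tables, function(tt) sum(tt[1:2]) == 0, logical(1))
  if (any(empty)) {
    warn_np("profiles with no subjects after missingness filter excluded: %s",
            paste(names(tables)[empty], collapse = ", "))
    tables <- tables[!empty]
  }
  list(reference = reference, tables = tables, versus_all = va,
       n_missing = n_missing)
}

# the 11 patient-level adjustment covariates (reference-coded factors for
# the categorical ones); the coding is fixed by the generator's metadata
# dictionary
severity_covariates <- function() {
  c("age_months", "male", "race_ethnicity", "gest_age_weeks",
    "prev_breathing", "daycare", "other_children", "hx_antibiotics",
    "hx_corticosteroids", "abx_prehosp", "virus_pcr")
}

# assemble the complete-case model frame for the severity models
severity_frame <- function(cohort, profiles, outcome, los_threshold,
                           adjusted, exposure_profile, reference) {
  md <- cohort$metadata
  y <- switch(outcome,
              icu = as.numeric(md$icu_use),
              los = as.numeric(md$los_days >= los_threshold),
              stop_np("outcome must be 'icu' or 'los'"))
  df <- data.frame(.y = y, .profile = as.character(profiles),
                   site_id = md$site_id, stringsAsFactors = FALSE)
  covs <- if (isTRUE(adjusted)) severity_covariates() else character()
  miss_cov <- setdiff(covs, names(md))
  if (length(miss_cov))
    stop_np("metadata lacks covariates: %s", paste(miss_cov, collapse = ", "))
  for (v in covs) df[[v]] <- md[[v]]
  if (is.null(exposure_profile)) {
    lev <- c(reference, sort(setdiff(unique(df$.profile), reference)))
    if (!reference %in% df$.profile)
      stop_np("reference profile '%s' has no subjects", reference)
    df$.exposure <- factor(df$.profile, levels = lev)
  } else {
    if (identical(exposure_profile, reference))
      stop_np("exposure profile must differ from the reference")
    df$.exposure <- as.numeric(df$.profile == exposure_profile)
  }
  cc <- complete.cases(df)
  attr(df, "n_dropped") <- sum(!cc)
  df[cc, , drop = FALSE]
}

or_rows <- function(est, se, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  data.frame(or = exp(est), ci_low = exp(est - z * se),
             ci_high = exp(est + z * se),
             p_value = 2 * pnorm(-abs(est / se)))
}

#' Fixed-effects logistic model of profile versus severity
#'
#' Maximum-likelihood logistic regression of a severity outcome on profile
#' membership, optionally adjusted for the 11 patient-level covariates
#' (age in months, sex, race/ethnicity, gestational age, previous breathing
#' problems, daycare attendance, other children at home, history of
#' antibiotic use, history of corticosteroid use, antibiotics during the
#' pre-hospitalization visit, and respiratory viruses by PCR). Exposure is
#' either the full profile factor (reference-coded) or one profile versus
#' all other subjects. Complete-case with a reported drop count; quasi- or
#' complete separation is flagged with a warning.
#'
#' @param cohort a [paired_cohort()] whose metadata carries the covariates.
#' @param profiles per-subject profile names (e.g. from
#'   [cluster_site_profiles()]).
#' @param outcome `"icu"` (intensive care use) or `"los"` (length of stay
#'   dichotomized at `los_threshold` days).
#' @param los_threshold LOS dichotomization in days (primary 5; 3 mirrors
#'   the antecedent nasopharyngeal analysis).
#' @param adjusted include the 11 covariates?
#' @param exposure_profile `NULL` for all profiles versus the reference, or
#'   a profile name for one-versus-all-others.
#' @param reference reference profile for the factor coding.
#' @return List of class `severity_fit`: `estimates` (data.frame of
#'   exposure-term ORs with Wald CIs and p-values), `model`, `converged`,
#'   `separation`, `n`, `n_dropped`, `method = "logistic"`.
#' @export
fit_profile_logistic <- function(cohort, profiles, outcome = c("icu", "los"),
                                 los_threshold = 5, adjusted = TRUE,
                                 exposure_profile = NULL,
                                 reference = "Moraxella-dominant") {
  outcome <- match.arg(outcome)
  df <- severity_frame(cohort, profiles, outcome, los_threshold, adjusted,
                       exposure_profile, reference)
  rhs <- c(".exposure", if (isTRUE(adjusted)) severity_covariates())
  form <- stats::reformulate(rhs, response = ".y")
  fit <- glm(form, family = binomial(), data = df)
  cf <- coef(summary(fit))
  idx <- grep("^\\.exposure", rownames(cf))
  est <- or_rows(cf[idx, "Estimate"], cf[idx, "Std. Error"])
  rownames(est) <- sub("^\\.exposure", "", rownames(cf)[idx])
  mu <- fitted(fit)
  separation <- (any(mu < 1e-8) || any(mu > 1 - 1e-8)) &&
    any(abs(coef(fit)) > 10, na.rm = TRUE)
  if (separation)
    warn_np("possible separation: term '%s' has |coef| > 10",
            names(which.max(abs(coef(fit)))))
  structure(list(estimates = est, model = fit, converged = fit$converged,
                 separation = separation, n = nrow(df),
                 n_dropped = attr(df, "n_dropped"), method = "logistic"),
            class = "severity_fit")
}

#' Mixed-effects logistic model with a collection-site random intercept
#'
#' As [fit_profile_logistic()] but fitted with `lme4::glmer` adding a
#' Gaussian random intercept for collection site (Laplace approximation;
#' the approximation used is recorded in the result). Requires at least two
#' sites — with a single site the model is unidentifiable and the error
#' directs to the fixed-effects fit.
#'
#' @inheritParams fit_profile_logistic
#' @param nAGQ number of adaptive Gauss-Hermite quadrature points (1 =
#'   Laplace).
#' @return List of class `severity_fit` with the additional element
#'   `site_sd` (estimated random-intercept SD) and `method` recording the
#'   approximation.
#' @export
fit_profile_glmm <- function(cohort, profiles, outcome = c("icu", "los"),
                             los_threshold = 5, adjusted = TRUE,
                             exposure_profile = NULL,
                             reference = "Moraxella-dominant", nAGQ = 1) {
  outcome <- match.arg(outcome)
  df <- severity_frame(cohort, profiles, outcome, los_threshold, adjusted,
                       exposure_profile, reference)
  if (length(unique(df$site_id)) < 2)
    stop_np("only one collection site: use fit_profile_logistic()")
  rhs <- c(".exposure", if (isTRUE(adjusted)) severity_covariates(),
           "(1 | site_id)")
  form <- stats::as.formula(paste(".y ~", paste(rhs, collapse = " + ")))
  fit <- lme4::glmer(form, family = binomial(), data = df, nAGQ = nAGQ)
  cf <- coef(summary(fit))
  idx <- grep("^\\.exposure", rownames(cf))
  est <- or_rows(cf[idx, "Estimate"], cf[idx, "Std. Error"])
  rownames(est) <- sub("^\\.exposure", "", rownames(cf)[idx])
  vc <- lme4::VarCorr(fit)
  site_sd <- attr(vc$site_id, "stddev")[[1]]
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(estimates = est, model = fit, converged = conv,
                 separation = FALSE, n = nrow(df),
                 n_dropped = attr(df, "n_dropped"), site_sd = site_sd,
                 method = if (nAGQ == 1) "glmm_laplace" else
                   sprintf("glmm_agq%d", nAGQ)),
            class = "severity_fit")
}

#' @export
print.severity_fit <- function(x, ...) {
  cat(sprintf("<severity_fit> %s, n = %d (%d dropped)%s\n", x$method, x$n,
              x$n_dropped,
              if (!is.null(x$site_sd))
                sprintf(", site SD = %.3f", x$site_sd) else ""))
  print(round(x$estimates, 3))
  invisible(x)
}
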