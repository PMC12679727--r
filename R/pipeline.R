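#' Impute missing covariate values
#'
#' Applies the missing-data rule used throughout the analysis: missing values
#' of categorical variables become an explicit \code{"missing"} indicator
#' level (which then enters downstream design matrices as its own dummy),
#' and missing values of continuous variables are replaced by the cohort
#' median of the observed values. Deterministic.
#'
#' A variable with 5\% or more missingness triggers a warning (the emulated
#' cohorts all stay below 5\%) but is still imputed; a fully missing variable
#' is an error.
#'
#' @param table data frame.
#' @param variables columns to impute; defaults to all columns except
#'   identifiers, outcomes and the structurally missing diabetes duration.
#' @return the imputed table.
#' @export
impute_missing <- function(table, variables = NULL) {
  if (is.null(variables))
    variables <- setdiff(names(table),
                         c("id", "t2d", "followup_years", "died", "cause",
                           "diab_dur"))
  for (v in variables) {
    x <- table[[v]]
    nmiss <- sum(is.na(x))
    if (nmiss == 0L) next
    if (nmiss == length(x)) stop("variable '", v, "' is fully missing")
    if (nmiss / length(x) >= 0.05)
      warning("variable '", v, "' has >= 5% missingness; imputing anyway")
    if (is.numeric(x)) {
      x[is.na(x)] <- stats::median(x, na.rm = TRUE)
    } else {
      x <- as.character(x)
      x[is.na(x)] <- "missing"
      x <- factor(x)
    }
    table[[v]] <- x
  }
  table
}

#' Percentage reporting for count/denominator pairs
#'
#' Formats proportions the way cohort reports print them: percentages to one
#' decimal place.
#'
#' @param count numeric vector of counts.
#' @param denominator numeric vector of denominators (> 0).
#' @return numeric vector of percentages rounded to 1 decimal.
#' @export
proportion_pct <- function(count, denominator) {
  if (any(denominator <= 0)) stop("denominators must be positive")
  if (any(count < 0 | count > denominator))
    stop("counts must lie in [0, denominator]")
  round(100 * count / denominator, 1)
}

#' Analysis configuration
#'
#' Bundles the knobs of the end-to-end analysis: threshold dialect,
#' adjustment covariates, exposure definition, reference group, sensitivity
#' exclusions, bootstrap settings and the master seed.
#'
#' @param cohort_dialect \code{"CCDRFS"}, \code{"NHANES"} or \code{"UKB"}.
#' @param dialect a \code{\link{threshold_dialect}}; defaults to the preset
#'   for \code{cohort_dialect}.
#' @param covariates adjustment covariate columns; defaults follow the
#'   cohort: age, sex, education, economic status, CVD and cancer history,
#'   plus residence (CCDRFS) or race (others).
#' @param exposure \code{"risk_count"} (control categories vs controls) or
#'   \code{"lifestyle_by_metabolic"} (lifestyle count within metabolic
#'   strata).
#' @param use_weighted_score use the mortality-weighted score with
#'   count-matched cut points instead of the unweighted count.
#' @param exclude_first2y drop participants who died within the first 2
#'   years of follow-up (reverse-causation sensitivity).
#' @param bootstrap_runs Monte-Carlo runs for life-expectancy CIs (>= 2).
#' @param seed master seed; all pipeline randomness derives from it.
#' @return list of class \code{analysis_config}.
#' @export
analysis_config <- function(cohort_dialect = c("CCDRFS", "NHANES", "UKB"),
                            dialect = NULL, covariates = NULL,
                            exposure = c("risk_count",
                                         "lifestyle_by_metabolic"),
                            use_weighted_score = FALSE,
                            exclude_first2y = FALSE,
                            bootstrap_runs = 1000, seed = 1L) {
  cohort_dialect <- match.arg(cohort_dialect)
  exposure <- match.arg(exposure)
  if (bootstrap_runs < 2) stop("bootstrap_runs must be >= 2")
  if (is.null(dialect)) dialect <- threshold_dialect(cohort_dialect)
  if (is.null(covariates))
    covariates <- c("age", "sex", "education", "econ", "hist_cvd",
                    "hist_cancer",
                    if (cohort_dialect == "CCDRFS") "residence" else "race")
  structure(list(cohort_dialect = cohort_dialect, dialect = dialect,
                 covariates = covariates, exposure = exposure,
                 use_weighted_score = use_weighted_score,
                 exclude_first2y = exclude_first2y,
                 bootstrap_runs = as.integer(bootstrap_runs),
                 seed = as.integer(seed)),
            class = "analysis_config")
}

# exposure category per participant: controls are the reference, T2D
# participants carry their risk-factor control category
.risk_count_exposure <- function(cohort, config) {
  prof <- evaluate_targets(cohort[cohort$t2d, , drop = FALSE],
                           config$dialect)
  cat_t2d <- prof$category
  if (config$use_weighted_score) {
    flags <- prof[paste0("within_", .factor_names)]
    t2d_rows <- cohort[cohort$t2d, , drop = FALSE]
    fit_dat <- cbind(t2d_rows, !flags)
    names(fit_dat)[(ncol(fit_dat) - 5):ncol(fit_dat)] <-
      paste0("out_", .factor_names)
    bfit <- fit_cox(fit_dat, terms = c(paste0("out_", .factor_names),
                                       intersect(config$covariates,
                                                 names(fit_dat))))
    betas <- stats::setNames(bfit$table$beta[seq_len(6)], .factor_names)
    ws <- weighted_score(prof, betas)
    cat_t2d <- weighted_categorize(ws, prof$score)
  }
  exposure <- rep("control", nrow(cohort))
  exposure[cohort$t2d] <- as.character(cat_t2d)
  list(exposure = factor(exposure,
                         levels = c("control", "optimal", "suboptimal",
                                    "poor")),
       profile = prof)
}

# one HR/e50 report row set for a fitted exposure model
.category_rows <- function(data, exposure, fit_all, fit_cvd, config,
                           schedule_male, schedule_female) {
  levs <- levels(exposure)
  ref <- levs[1]
  rows <- lapply(levs, function(lv) {
    sel <- exposure == lv
    term <- paste0("exposure", lv)
    get <- function(fit, col) {
      if (lv == ref) return(if (col == "hr") 1 else NA_real_)
      i <- match(term, fit$table$term)
      if (is.na(i)) return(NA_real_)
      fit$table[[col]][i]
    }
    died <- as.logical(data$died)
    is_cvd <- died & !is.na(data$cause) & data$cause == "CVD"
    beta <- if (lv == ref) 0 else get(fit_all, "beta")
    se <- if (lv == ref) 0 else get(fit_all, "se")
    flagged <- sum(died[sel]) == 0
    ci_m <- ci_f <- list(e50 = NA_real_, lower = NA_real_, upper = NA_real_)
    if (!flagged && !is.na(beta)) {
      ci_m <- monte_carlo_ci(beta, se, schedule_male,
                             runs = config$bootstrap_runs,
                             seed = config$seed + 101L)
      ci_f <- monte_carlo_ci(beta, se, schedule_female,
                             runs = config$bootstrap_runs,
                             seed = config$seed + 102L)
    }
    data.frame(category = lv,
               n = sum(sel),
               person_years = sum(data$followup_years[sel]),
               deaths_cvd = sum(is_cvd[sel]),
               hr_cvd = get(fit_cvd, "hr"),
               hr_cvd_lcl = get(fit_cvd, "lcl"),
               hr_cvd_ucl = get(fit_cvd, "ucl"),
               deaths_all = sum(died[sel]),
               hr_all = get(fit_all, "hr"),
               hr_all_lcl = get(fit_all, "lcl"),
               hr_all_ucl = get(fit_all, "ucl"),
               e50_male = ci_m$e50, e50_male_lcl = ci_m$lower,
               e50_male_ucl = ci_m$upper,
               e50_female = ci_f$e50, e50_female_lcl = ci_f$lower,
               e50_female_ucl = ci_f$upper,
               flagged = flagged)
  })
  do.call(rbind, rows)
}

.prepare_cohort <- function(cohort, config) {
  if (config$exclude_first2y)
    cohort <- cohort[!(cohort$died & cohort$followup_years <= 2), ,
                     drop = FALSE]
  impute_missing(cohort)
}

# cause-specific all-cause / CVD fits with zero-event categories excluded
# from the model but flagged in the report
.fit_exposure_models <- function(data, exposure, covars) {
  died <- as.logical(data$died)
  ev_by <- tapply(died, exposure, sum)
  usable <- names(ev_by)[!is.na(ev_by) & ev_by > 0]
  keep <- exposure %in% usable
  d <- data[keep, , drop = FALSE]
  d$exposure <- droplevels(exposure[keep])
  fit_all <- fit_cox(d, terms = c("exposure", covars))
  d$died_cvd <- as.logical(d$died) & !is.na(d$cause) & d$cause == "CVD"
  fit_cvd <- fit_cox(d, event = "died_cvd", terms = c("exposure", covars))
  list(all = fit_all, cvd = fit_cvd)
}

#' Mortality and life expectancy by risk-factor control category
#'
#' End-to-end report in the shape of the headline comparison: per exposure
#' category (matched controls as reference; then optimal / suboptimal / poor
#' risk-factor control among T2D) the person-years, CVD and all-cause deaths,
#' adjusted hazard ratios with 95\% CIs, and life expectancy at age 50 by sex
#' with Monte-Carlo CIs obtained by scaling the sex-specific reference
#' schedule by the category's all-cause hazard ratio.
#'
#' @param cohort participant table (cases and controls) — typically the
#'   retained rows of a matched cohort.
#' @param config an \code{\link{analysis_config}}.
#' @param schedule_male,schedule_female reference (control-group) mortality
#'   schedules by sex, as data frames with \code{x}, \code{n}, \code{rate}.
#' @return data frame, one row per exposure category; zero-event categories
#'   are flagged, not dropped.
#' @export
run_table2 <- function(cohort, config, schedule_male, schedule_female) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- .prepare_cohort(cohort, config)
  exp_def <- .risk_count_exposure(cohort, config)
  exposure <- exp_def$exposure
  covars <- intersect(config$covariates, names(cohort))
  fits <- .fit_exposure_models(cohort, exposure, covars)
  .category_rows(cohort, exposure, fits$all, fits$cvd, config,
                 schedule_male, schedule_female)
}

#' Lifestyle factors within metabolic-control strata
#'
#' Among participants with T2D, cross-classifies metabolic control (all
#' three metabolic targets achieved vs not) with the number of low-risk
#' lifestyle factors (0-1 vs 2-3) and reports, within each metabolic
#' stratum, hazard ratios for the healthier-lifestyle group against the 0-1
#' reference plus life expectancy at 50 by sex (reference schedule taken to
#' describe the stratum's 0-1 lifestyle group).
#'
#' @inheritParams run_table2
#' @return data frame, one row per stratum x lifestyle group.
#' @export
run_table3 <- function(cohort, config, schedule_male, schedule_female) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- .prepare_cohort(cohort, config)
  t2d <- cohort[cohort$t2d, , drop = FALSE]
  prof <- evaluate_targets(t2d, config$dialect)
  t2d$lifestyle_group <- factor(ifelse(prof$lifestyle_low_risk_count >= 2,
                                       "2-3", "0-1"), levels = c("0-1", "2-3"))
  t2d$metabolic <- ifelse(prof$metabolic_all_optimal, "optimal", "suboptimal")
  covars <- intersect(config$covariates, names(t2d))
  out <- lapply(c("optimal", "suboptimal"), function(ms) {
    d <- t2d[t2d$metabolic == ms, , drop = FALSE]
    if (!nrow(d) || any(table(d$lifestyle_group) == 0)) {
      return(data.frame(metabolic = ms, category = levels(t2d$lifestyle_group),
                        n = as.integer(table(d$lifestyle_group)),
                        person_years = NA, deaths_cvd = NA, hr_cvd = NA,
                        hr_cvd_lcl = NA, hr_cvd_ucl = NA, deaths_all = NA,
                        hr_all = NA, hr_all_lcl = NA, hr_all_ucl = NA,
                        e50_male = NA, e50_male_lcl = NA, e50_male_ucl = NA,
                        e50_female = NA, e50_female_lcl = NA,
                        e50_female_ucl = NA, flagged = TRUE))
    }
    fits <- .fit_exposure_models(d, d$lifestyle_group, covars)
    rows <- .category_rows(d, d$lifestyle_group, fits$all, fits$cvd, config,
                           schedule_male, schedule_female)
    cbind(metabolic = ms, rows)
  })
  do.call(rbind, out)
}

#' Hazard ratios and life-years implied by individual factors
#'
#' For each of the six risk factors among participants with T2D: the
#' adjusted hazard ratio for being within (vs outside) that factor's target,
#' and the life expectancy gain at age 50 implied by applying that hazard
#' ratio to the reference schedule (averaged over the sex-specific
#' schedules).
#'
#' @inheritParams run_table2
#' @return data frame with \code{factor}, \code{hr}, \code{lcl}, \code{ucl},
#'   \code{gain_years_male}, \code{gain_years_female}.
#' @export
run_individual_factors <- function(cohort, config, schedule_male,
                                   schedule_female) {
  stopifnot(inherits(config, "analysis_config"))
  cohort <- .prepare_cohort(cohort, config)
  t2d <- cohort[cohort$t2d, , drop = FALSE]
  prof <- evaluate_targets(t2d, config$dialect)
  covars <- intersect(config$covariates, names(t2d))
  rows <- lapply(.factor_names, function(f) {
    t2d$within <- prof[[paste0("within_", f)]]
    fit <- fit_cox(t2d, terms = c("within", covars))
    i <- match("withinTRUE", fit$table$term)
    hr <- fit$table$hr[i]
    base_m <- life_expectancy_at_50(schedule_male, 1)
    base_f <- life_expectancy_at_50(schedule_female, 1)
    data.frame(factor = f, hr = hr, lcl = fit$table$lcl[i],
               ucl = fit$table$ucl[i],
               gain_years_male = life_expectancy_at_50(schedule_male, hr) -
                 base_m,
               gain_years_female = life_expectancy_at_50(schedule_female, hr) -
                 base_f)
  })
  do.call(rbind, rows)
}
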