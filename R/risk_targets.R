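#' Guideline threshold dialects
#'
#' Construct the set of guideline target thresholds used to judge whether each
#' of the six risk factors (never smoking, physical activity, diet, HbA1c,
#' systolic blood pressure, lipids) is within its recommended range. Three
#' presets named for the source cohorts are shipped; they share the clinical
#' thresholds and differ only in the diet rule:
#' \itemize{
#'   \item \code{"CCDRFS"}: fruit + vegetables >= 400 g/d AND red meat <= 100 g/d;
#'   \item \code{"NHANES"}: diet-quality (HEI) value in the top third of the
#'     cohort's distribution;
#'   \item \code{"UKB"}: at least 5 of a configurable list of food-item
#'     recommendations met (supplied as a count column).
#' }
#'
#' Boundary semantics follow the guidelines as printed: maxima are strict
#' (HbA1c < 7.0\%, SBP < 140 mmHg or < 130 mmHg with prior CVD, TG < 1.7
#' mmol/L) and minima are inclusive (activity >= 150 min/week, HDL-C >= 1.29
#' mmol/L for women / >= 1.03 mmol/L for men, fruit + vegetables >= 400 g/d).
#'
#' @param cohort one of \code{"CCDRFS"}, \code{"NHANES"}, \code{"UKB"};
#'   selects the diet rule preset.
#' @param ... named overrides for individual thresholds, e.g.
#'   \code{hba1c_max = 6.5}, or \code{lipid_rule = "ldl"} together with
#'   \code{ldl_max} for the LDL-based sensitivity dialect, or
#'   \code{hba1c_limit_col} naming a column of per-participant individualized
#'   HbA1c limits.
#' @return an object of class \code{threshold_dialect}: a named list of
#'   thresholds plus the active diet rule.
#' @export
threshold_dialect <- function(cohort = c("CCDRFS", "NHANES", "UKB"), ...) {
  cohort <- match.arg(cohort)
  d <- list(
    cohort          = cohort,
    hba1c_max       = 7.0,
    sbp_max         = 140,
    sbp_max_cvd     = 130,
    tg_max          = 1.7,
    hdl_min_female  = 1.29,
    hdl_min_male    = 1.03,
    activity_min    = 150,
    fruitveg_min    = 400,
    redmeat_max     = 100,
    ukb_items_min   = 5,
    lipid_rule      = "tg_hdl",   # or "ldl" (sensitivity dialect)
    ldl_max         = 2.6,
    hba1c_limit_col = NULL,       # per-participant individualized limits
    diet_rule       = switch(cohort,
                             CCDRFS = "ccdrfs",
                             NHANES = "nhanes",
                             UKB    = "ukb")
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(d))
  if (length(unknown))
    stop("unknown threshold_dialect field(s): ", paste(unknown, collapse = ", "))
  d[names(ov)] <- ov
  num <- c("hba1c_max", "sbp_max", "sbp_max_cvd", "tg_max", "hdl_min_female",
           "hdl_min_male", "activity_min", "fruitveg_min", "redmeat_max",
           "ukb_items_min", "ldl_max")
  for (f in num)
    if (!is.numeric(d[[f]]) || length(d[[f]]) != 1L || d[[f]] <= 0)
      stop("threshold_dialect field '", f, "' must be a positive scalar")
  if (!d$diet_rule %in% c("ccdrfs", "nhanes", "ukb"))
    stop("diet_rule must be one of 'ccdrfs', 'nhanes', 'ukb'")
  structure(d, class = "threshold_dialect")
}

#' @export
print.threshold_dialect <- function(x, ...) {
  cat("Guideline threshold dialect (", x$cohort, ")\n", sep = "")
  cat("  HbA1c < ", x$hba1c_max, " %\n", sep = "")
  cat("  SBP < ", x$sbp_max, " mmHg (< ", x$sbp_max_cvd, " with CVD)\n", sep = "")
  if (x$lipid_rule == "tg_hdl")
    cat("  TG < ", x$tg_max, " & HDL-C >= ", x$hdl_min_female, " (F) / ",
        x$hdl_min_male, " (M) mmol/L\n", sep = "")
  else
    cat("  LDL-C < ", x$ldl_max, " mmol/L\n", sep = "")
  cat("  activity >= ", x$activity_min, " min/week; diet rule: ",
      x$diet_rule, "\n", sep = "")
  invisible(x)
}

#' Healthy-diet flag for the top-third diet-quality rule
#'
#' Returns TRUE for participants whose diet-quality value lies in the top
#' third of the cohort distribution, i.e. at or above the empirical 2/3
#' quantile (type-7 linear interpolation of order statistics, computed once
#' over the pooled cohort).
#'
#' @param values numeric vector of diet-quality (e.g. HEI) values; NA allowed.
#' @return logical vector; NA where the input is NA.
#' @export
diet_rule_nhanes <- function(values) {
  obs <- values[!is.na(values)]
  if (length(obs) == 0L) stop("all diet-quality values are missing")
  if (length(obs) < 3L) stop("need at least 3 non-missing diet-quality values")
  cut <- stats::quantile(obs, 2 / 3, type = 7, names = FALSE)
  values >= cut
}

#' Map a risk-factor count to a control category
#'
#' Categories follow the guideline-control stratification: optimal for 0-1
#' factors outside target, suboptimal for 2-4, poor for 5-6.
#'
#' @param S integer vector of counts of factors outside target (0-6).
#' @return factor with levels \code{optimal}, \code{suboptimal}, \code{poor}.
#' @export
categorize_score <- function(S) {
  if (any(is.na(S)) || any(S != round(S)) || any(S < 0 | S > 6))
    stop("S must be integers in 0..6")
  cut(S, breaks = c(-0.5, 1.5, 4.5, 6.5),
      labels = c("optimal", "suboptimal", "poor"))
}

.lifestyle_factors <- c("smoking", "activity", "diet")
.metabolic_factors <- c("hba1c", "bp", "lipids")
.factor_names <- c(.lifestyle_factors, .metabolic_factors)

#' Evaluate guideline targets for each participant
#'
#' Judges the six risk factors against a threshold dialect and builds the
#' unweighted risk score: one point per factor outside its target, summed
#' (S, 0-6), with control categories optimal (0-1), suboptimal (2-4) and poor
#' (5-6). Also returns the lifestyle low-risk count (0-3 of never smoking,
#' active, healthy diet) and the all-three-metabolic-targets flag used for
#' lifestyle-by-metabolic-control cross-classification.
#'
#' The lipid target is joint: TG below its maximum AND sex-specific HDL-C at
#' or above its minimum (or LDL-C below \code{ldl_max} under the LDL
#' sensitivity dialect). The SBP threshold drops to the lower bound for
#' participants with a history of CVD. Exposure measurements must be complete:
#' resolve missing values with \code{\link{impute_missing}} first.
#'
#' @param data cohort data frame; see \code{\link{generate_cohort}} for the
#'   column dictionary. Diet columns required depend on the dialect:
#'   \code{fruitveg_g_d}/\code{redmeat_g_d} (CCDRFS), \code{hei_score}
#'   (NHANES), \code{diet_items_met} (UKB).
#' @param dialect a \code{\link{threshold_dialect}}.
#' @return data frame with the six \code{within_*} logical flags,
#'   \code{score} (S), \code{category}, \code{lifestyle_low_risk_count} and
#'   \code{metabolic_all_optimal}, one row per input row.
#' @export
evaluate_targets <- function(data, dialect = threshold_dialect("CCDRFS")) {
  stopifnot(inherits(dialect, "threshold_dialect"))
  need <- c("smoking_ever", "activity_min_wk", "hba1c_pct", "sbp_mmhg",
            "hist_cvd", "sex")
  need <- c(need, switch(dialect$diet_rule,
                         ccdrfs = c("fruitveg_g_d", "redmeat_g_d"),
                         nhanes = "hei_score",
                         ukb    = "diet_items_met"))
  need <- c(need, if (dialect$lipid_rule == "ldl") "ldl_mmol_l"
                  else c("tg_mmol_l", "hdl_mmol_l"))
  miss_col <- setdiff(need, names(data))
  if (length(miss_col))
    stop("missing column(s): ", paste(miss_col, collapse = ", "))

  # smoking may arrive as logical or as a missing-indicator factor
  smk <- data$smoking_ever
  if (is.logical(smk)) {
    within_smoking <- !smk
  } else {
    within_smoking <- as.character(smk) == "FALSE"
  }
  within_activity <- data$activity_min_wk >= dialect$activity_min

  within_diet <- switch(dialect$diet_rule,
    ccdrfs = data$fruitveg_g_d >= dialect$fruitveg_min &
             data$redmeat_g_d <= dialect$redmeat_max,
    nhanes = diet_rule_nhanes(data$hei_score),
    ukb    = data$diet_items_met >= dialect$ukb_items_min)

  if (!is.null(dialect$hba1c_limit_col)) {
    lim <- data[[dialect$hba1c_limit_col]]
    if (is.null(lim)) stop("individualized HbA1c limit column '",
                           dialect$hba1c_limit_col, "' not found")
    within_hba1c <- data$hba1c_pct < lim
  } else {
    within_hba1c <- data$hba1c_pct < dialect$hba1c_max
  }

  cvd_hist <- if (is.logical(data$hist_cvd)) data$hist_cvd
              else as.character(data$hist_cvd) == "TRUE"
  sbp_lim <- ifelse(cvd_hist, dialect$sbp_max_cvd, dialect$sbp_max)
  within_bp <- data$sbp_mmhg < sbp_lim

  if (dialect$lipid_rule == "ldl") {
    within_lipids <- data$ldl_mmol_l < dialect$ldl_max
  } else {
    hdl_min <- ifelse(data$sex == "female", dialect$hdl_min_female,
                      dialect$hdl_min_male)
    within_lipids <- data$tg_mmol_l < dialect$tg_max &
                     data$hdl_mmol_l >= hdl_min
  }

  flags <- data.frame(within_smoking, within_activity, within_diet,
                      within_hba1c, within_bp, within_lipids)
  if (anyNA(flags))
    stop("unresolved missing exposure values; run impute_missing() first")

  S <- as.integer(rowSums(!flags))
  out <- flags
  out$score <- S
  out$category <- categorize_score(S)
  out$lifestyle_low_risk_count <-
    as.integer(within_smoking) + as.integer(within_activity) +
    as.integer(within_diet)
  out$metabolic_all_optimal <- within_hba1c & within_bp & within_lipids
  out
}

#' Mortality-weighted risk score
#'
#' Weighted analogue of the unweighted count: each factor outside target
#' contributes its mortality log-hazard (beta coefficient from a Cox model on
#' the same cohort) instead of one point.
#'
#' @param flags data frame or matrix with the six \code{within_*} logical
#'   columns (as returned by \code{\link{evaluate_targets}}), or a logical
#'   matrix of OUTSIDE-target indicators with columns named by factor.
#' @param betas named numeric vector of per-factor log-hazard ratios; names
#'   must be \code{smoking, activity, diet, hba1c, bp, lipids}.
#' @return numeric vector of weighted scores (0 when all factors are within
#'   target).
#' @export
weighted_score <- function(flags, betas) {
  if (!all(.factor_names %in% names(betas)))
    stop("betas must be named for all six factors: ",
         paste(.factor_names, collapse = ", "))
  if (anyNA(betas[.factor_names])) stop("missing beta coefficient")
  wi <- paste0("within_", .factor_names)
  if (all(wi %in% colnames(flags))) {
    outside <- !as.matrix(as.data.frame(flags)[wi])
    colnames(outside) <- .factor_names
  } else if (all(.factor_names %in% colnames(flags))) {
    outside <- as.matrix(as.data.frame(flags)[.factor_names])
  } else {
    stop("flags must carry within_* or per-factor outside-target columns")
  }
  drop(outside %*% betas[.factor_names])
}

#' Categorize weighted scores with count-matched cut points
#'
#' Category cut points for the weighted score are the weighted-score quantiles
#' at the cumulative proportions of participants with S <= 1 and S <= 4, so
#' the weighted categories have (close to) the same sizes as the unweighted
#' ones. Quantiles use type-7 linear interpolation; ties at a cut point go to
#' the lower-risk category.
#'
#' @param wscore numeric vector of weighted scores.
#' @param S integer vector of unweighted scores (same length).
#' @return factor with levels \code{optimal}, \code{suboptimal}, \code{poor}.
#' @export
weighted_categorize <- function(wscore, S) {
  if (length(wscore) != length(S)) stop("wscore and S lengths differ")
  if (any(S < 0 | S > 6)) stop("S must be in 0..6")
  p1 <- mean(S <= 1)
  p4 <- mean(S <= 4)
  c1 <- stats::quantile(wscore, p1, type = 7, names = FALSE)
  c2 <- stats::quantile(wscore, p4, type = 7, names = FALSE)
  factor(ifelse(wscore <= c1, "optimal",
         ifelse(wscore <= c2, "suboptimal", "poor")),
         levels = c("optimal", "suboptimal", "poor"))
}
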