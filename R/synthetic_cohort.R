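#' Simulation configuration for synthetic cohorts
#'
#' Bundles and validates every knob of the synthetic-cohort generator. The
#' defaults emulate the structure of a Chinese surveillance-style T2D cohort:
#' per-factor outside-target prevalences follow the published baseline table
#' of that cohort, mortality follows a Gompertz baseline hazard in attained
#' age under a proportional-hazards linear predictor over the six
#' outside-target indicators, and the CVD share of deaths rises with the
#' number of uncontrolled factors.
#'
#' @param n_t2d,n_nont2d positive integers; cohort arm sizes.
#' @param seed integer RNG seed.
#' @param cohort_dialect \code{"CCDRFS"}, \code{"NHANES"} or \code{"UKB"};
#'   decides which diet components are generated (and which covariates exist).
#' @param factor_prevalences named probabilities (in [0,1]) of being OUTSIDE
#'   target for \code{smoking, activity, diet, hba1c, bp, lipids}.
#' @param factor_log_hazards named per-factor true log hazard ratios for
#'   all-cause death.
#' @param category_log_hazards optional named vector \code{c(optimal = ...,
#'   suboptimal = ..., poor = ...)}; when supplied, the linear predictor of a
#'   T2D participant is the log hazard ratio of their control category
#'   (non-T2D participants stay at 0) instead of the factor-wise sum —
#'   the design used when true category-level hazard ratios are wanted.
#' @param cvd_death_fraction_fn function mapping the count of outside-target
#'   factors (0-6) to the probability that a death is a CVD death.
#' @param gompertz_a baseline hazard per person-year at age 50 (> 0).
#' @param gompertz_b log-hazard slope per year of age (>= 0).
#' @param t2d_excess_log_hazard extra log hazard for T2D status itself.
#' @param horizon_years administrative censoring horizon (> 0).
#' @param dropout_rate exponential dropout rate per year (>= 0).
#' @param factor_correlation latent pairwise correlation of the six factors
#'   (Gaussian copula, equicorrelated), in [0, 1).
#' @param covariate_model list of covariate distribution settings; see
#'   defaults in the function signature.
#' @return validated list of class \code{sim_config}.
#' @export
sim_config <- function(n_t2d = 10000, n_nont2d = 20000, seed = 1L,
                       cohort_dialect = c("CCDRFS", "NHANES", "UKB"),
                       factor_prevalences = c(smoking = 0.349,
                                              activity = 0.193,
                                              diet = 0.727,
                                              hba1c = 0.357,
                                              bp = 0.468,
                                              lipids = 0.607),
                       factor_log_hazards = c(smoking = log(1.35),
                                              activity = log(1.40),
                                              diet = log(1.15),
                                              hba1c = log(1.30),
                                              bp = log(1.05),
                                              lipids = log(1.05)),
                       category_log_hazards = NULL,
                       cvd_death_fraction_fn = function(S)
                         pmin(1, pmax(0, 0.30 + 0.05 * S)),
                       gompertz_a = 0.0038, gompertz_b = 0.092,
                       t2d_excess_log_hazard = log(1.15),
                       horizon_years = 9.4, dropout_rate = 0.002,
                       factor_correlation = 0.2,
                       covariate_model = list(
                         age_range = c(40, 70), male_prob = 0.461,
                         urban_prob = 0.506, white_prob = 0.70,
                         educ_probs = c(low = 0.60, medium = 0.33, high = 0.07),
                         econ_mean = 0, econ_sd = 1,
                         hist_cvd_prob = 0.052, hist_cancer_prob = 0.027,
                         diab_dur_mean = 6)) {
  cohort_dialect <- match.arg(cohort_dialect)
  chk_count <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1L || x < 1 || x != round(x))
      stop("sim_config field '", nm, "' must be a positive integer")
  }
  chk_count(n_t2d, "n_t2d"); chk_count(n_nont2d, "n_nont2d")
  chk_prob <- function(x, nm) {
    if (!is.numeric(x) || anyNA(x) || any(x < 0 | x > 1))
      stop("sim_config field '", nm, "' must be probabilities in [0,1]")
  }
  if (!all(.factor_names %in% names(factor_prevalences)))
    stop("sim_config field 'factor_prevalences' must name all six factors")
  chk_prob(factor_prevalences, "factor_prevalences")
  if (!all(.factor_names %in% names(factor_log_hazards)))
    stop("sim_config field 'factor_log_hazards' must name all six factors")
  if (!is.null(category_log_hazards) &&
      !all(c("optimal", "suboptimal", "poor") %in%
           names(category_log_hazards)))
    stop("sim_config field 'category_log_hazards' must name the three ",
         "categories optimal, suboptimal, poor")
  if (!is.function(cvd_death_fraction_fn))
    stop("sim_config field 'cvd_death_fraction_fn' must be a function")
  chk_prob(cvd_death_fraction_fn(0:6), "cvd_death_fraction_fn (values)")
  if (gompertz_a <= 0) stop("sim_config field 'gompertz_a' must be > 0")
  if (gompertz_b < 0) stop("sim_config field 'gompertz_b' must be >= 0")
  if (horizon_years <= 0) stop("sim_config field 'horizon_years' must be > 0")
  if (dropout_rate < 0) stop("sim_config field 'dropout_rate' must be >= 0")
  if (factor_correlation < 0 || factor_correlation >= 1)
    stop("sim_config field 'factor_correlation' must be in [0,1)")
  structure(list(
    n_t2d = as.integer(n_t2d), n_nont2d = as.integer(n_nont2d),
    seed = as.integer(seed), cohort_dialect = cohort_dialect,
    factor_prevalences = factor_prevalences[.factor_names],
    factor_log_hazards = factor_log_hazards[.factor_names],
    category_log_hazards = category_log_hazards,
    cvd_death_fraction_fn = cvd_death_fraction_fn,
    gompertz_a = gompertz_a, gompertz_b = gompertz_b,
    t2d_excess_log_hazard = t2d_excess_log_hazard,
    horizon_years = horizon_years, dropout_rate = dropout_rate,
    factor_correlation = factor_correlation,
    covariate_model = covariate_model), class = "sim_config")
}

# Gompertz event time from baseline age, by analytic inversion of the
# integrated hazard  H(t) = (a/b) e^{b(age0-50)} (e^{bt}-1) e^{lp}.
.gompertz_time <- function(E, age0, a, b, lp) {
  rate0 <- a * exp(b * (age0 - 50) + lp)
  if (b == 0) E / rate0 else log1p(b * E / rate0) / b
}

#' Generate a synthetic participant cohort with known ground truth
#'
#' Draws \code{n_t2d + n_nont2d} participants with demographics, the six
#' risk-factor measurements (constructed so that each measurement lands on
#' the intended side of its guideline threshold), event times from a Gompertz
#' proportional-hazards model in attained age, independent censoring
#' (administrative horizon plus exponential dropout), and a cause of death
#' (CVD / non-CVD) drawn from \code{cvd_death_fraction_fn} given the count of
#' outside-target factors. The returned truth ledger records the exact linear
#' predictor and generating parameters for parameter-recovery tests.
#'
#' @param config a \code{\link{sim_config}}.
#' @return list with \code{cohort} (one data frame row per participant; see
#'   the package vignette for the column dictionary) and \code{truth}
#'   (per-participant true linear predictor plus the generating parameters).
#' @export
generate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_t2d + config$n_nont2d
  cm <- config$covariate_model
  t2d <- rep(c(TRUE, FALSE), c(config$n_t2d, config$n_nont2d))

  age <- stats::runif(n, cm$age_range[1], cm$age_range[2])
  sex <- ifelse(stats::runif(n) < cm$male_prob, "male", "female")
  education <- sample(names(cm$educ_probs), n, TRUE, prob = cm$educ_probs)
  econ <- stats::rnorm(n, cm$econ_mean, cm$econ_sd)
  hist_cvd <- stats::runif(n) < cm$hist_cvd_prob
  hist_cancer <- stats::runif(n) < cm$hist_cancer_prob
  diab_dur <- ifelse(t2d, stats::rgamma(n, shape = 2,
                                        scale = cm$diab_dur_mean / 2), NA)

  # six outside-target indicators via an equicorrelated Gaussian copula
  rho <- config$factor_correlation
  z_shared <- stats::rnorm(n)
  lat <- sqrt(rho) * z_shared +
    sqrt(1 - rho) * matrix(stats::rnorm(n * 6), n, 6)
  prev <- config$factor_prevalences
  outside <- sweep(stats::pnorm(lat), 2, prev, `<`)
  colnames(outside) <- .factor_names

  d <- threshold_dialect(config$cohort_dialect)
  runi <- function(lo, hi) stats::runif(n, lo, hi)
  smoking_ever <- outside[, "smoking"]
  activity_min_wk <- ifelse(outside[, "activity"], runi(0, 149),
                            runi(d$activity_min, 600))
  hba1c_pct <- ifelse(outside[, "hba1c"], runi(d$hba1c_max, 11),
                      runi(5.3, d$hba1c_max - 0.05))
  sbp_lim <- ifelse(hist_cvd, d$sbp_max_cvd, d$sbp_max)
  sbp_mmhg <- ifelse(outside[, "bp"], stats::runif(n, sbp_lim, 200),
                     stats::runif(n, 95, sbp_lim - 1))
  # lipid violation mode: high TG, low HDL, or both
  hdl_min <- ifelse(sex == "female", d$hdl_min_female, d$hdl_min_male)
  viol <- sample(1:3, n, TRUE)
  tg_mmol_l <- ifelse(outside[, "lipids"] & viol != 2, runi(d$tg_max, 5),
                      runi(0.5, d$tg_max - 0.01))
  hdl_mmol_l <- ifelse(outside[, "lipids"] & viol != 1,
                       stats::runif(n, 0.4, hdl_min - 0.01),
                       stats::runif(n, hdl_min, hdl_min + 1.2))

  cohort <- data.frame(id = seq_len(n), t2d, age, sex,
                       education = factor(education,
                                          levels = c("low", "medium", "high")),
                       econ, hist_cvd, hist_cancer, diab_dur,
                       smoking_ever, activity_min_wk,
                       hba1c_pct, sbp_mmhg, tg_mmol_l, hdl_mmol_l,
                       stringsAsFactors = FALSE)
  if (config$cohort_dialect == "CCDRFS") {
    cohort$residence <- ifelse(stats::runif(n) < cm$urban_prob,
                               "urban", "rural")
    cohort$fruitveg_g_d <- ifelse(outside[, "diet"], runi(50, d$fruitveg_min - 1),
                                  runi(d$fruitveg_min, 900))
    cohort$redmeat_g_d <- ifelse(outside[, "diet"], runi(0, 300),
                                 runi(0, d$redmeat_max))
  } else if (config$cohort_dialect == "NHANES") {
    cohort$race <- ifelse(stats::runif(n) < cm$white_prob, "white", "nonwhite")
    cohort$survey_cycle <- sample(1:10, n, TRUE)
    cohort$hei_score <- ifelse(outside[, "diet"], runi(20, 60), runi(60, 95))
  } else {
    cohort$race <- ifelse(stats::runif(n) < cm$white_prob, "white", "nonwhite")
    cohort$diet_items_met <- ifelse(outside[, "diet"],
                                    sample(0:4, n, TRUE),
                                    sample(5:9, n, TRUE))
  }

  # proportional-hazards event times and censoring
  S <- rowSums(outside)
  if (!is.null(config$category_log_hazards)) {
    catg <- as.character(categorize_score(as.integer(S)))
    lp <- ifelse(t2d, unname(config$category_log_hazards[catg]), 0) +
      config$t2d_excess_log_hazard * t2d
  } else {
    lp <- drop(outside %*% config$factor_log_hazards) +
      config$t2d_excess_log_hazard * t2d
  }
  tt <- .gompertz_time(stats::rexp(n), age, config$gompertz_a,
                       config$gompertz_b, lp)
  cens <- if (config$dropout_rate > 0)
    pmin(config$horizon_years, stats::rexp(n, config$dropout_rate))
  else rep(config$horizon_years, n)
  cohort$followup_years <- pmin(tt, cens)
  cohort$died <- tt <= cens
  p_cvd <- config$cvd_death_fraction_fn(S)
  cohort$cause <- ifelse(cohort$died,
                         ifelse(stats::runif(n) < p_cvd, "CVD", "nonCVD"),
                         NA_character_)

  truth <- list(
    per_participant = data.frame(id = cohort$id, lp = lp,
                                 n_outside = as.integer(S)),
    factor_log_hazards = config$factor_log_hazards,
    t2d_excess_log_hazard = config$t2d_excess_log_hazard,
    gompertz_a = config$gompertz_a, gompertz_b = config$gompertz_b)
  list(cohort = cohort, truth = truth)
}

#' Mask values completely at random
#'
#' Introduces missing-completely-at-random holes into selected columns, to
#' exercise the median / missing-indicator imputation rule. Per-variable
#' missingness in the emulated cohorts is below 5\%, so rates at or above
#' that bound are refused.
#'
#' @param table data frame.
#' @param rate per-variable masking probability, in [0, 0.05).
#' @param seed integer seed (masking is reproducible).
#' @param variables columns to mask; defaults to every column except
#'   identifiers and outcome columns.
#' @return the table with NAs injected.
#' @export
inject_missingness <- function(table, rate, seed = 1L, variables = NULL) {
  if (rate < 0 || rate >= 0.05)
    stop("rate must be in [0, 0.05): per-variable missingness in the ",
         "emulated cohorts is below 5%")
  if (is.null(variables))
    variables <- setdiff(names(table),
                         c("id", "t2d", "followup_years", "died", "cause"))
  if (rate == 0) return(table)
  set.seed(seed)
  for (v in variables) {
    mask <- stats::runif(nrow(table)) < rate
    table[[v]][mask] <- NA
  }
  table
}

#' Contiguous age bands for abridged life tables
#'
#' @param from first band start (default 50).
#' @param width band width in years (default 5).
#' @param open_from start of the open-ended terminal band (default 100).
#' @return data frame with columns \code{x} (band start) and \code{n}
#'   (band width; \code{Inf} for the terminal band).
#' @export
age_bands <- function(from = 50, width = 5, open_from = 100) {
  if (open_from <= from) stop("open_from must exceed from")
  x <- seq(from, open_from - width, by = width)
  data.frame(x = c(x, open_from), n = c(rep(width, length(x)), Inf))
}

.check_bands <- function(bands) {
  if (!all(c("x", "n") %in% names(bands))) stop("bands need columns x and n")
  k <- nrow(bands)
  if (k < 1L) stop("empty band table")
  if (!is.infinite(bands$n[k])) stop("terminal band must be open-ended (n = Inf)")
  if (k > 1L) {
    if (any(is.infinite(bands$n[-k])) || any(bands$n[-k] <= 0))
      stop("non-terminal band widths must be finite and positive")
    if (any(abs(bands$x[-1] - (bands$x[-k] + bands$n[-k])) > 1e-9))
      stop("bands must be contiguous and non-overlapping")
  }
  invisible(bands)
}

#' Gompertz reference mortality schedule over age bands
#'
#' Builds an age-specific mortality schedule by evaluating a Gompertz hazard
#' (level \code{gompertz_a} at age 50, log-slope \code{gompertz_b} per year)
#' at each band's midpoint. The open terminal band uses its start plus half
#' the preceding band's width as midpoint.
#'
#' @param gompertz_a hazard per person-year at age 50 (> 0).
#' @param gompertz_b log-hazard slope per year (>= 0).
#' @param bands band table from \code{\link{age_bands}}.
#' @return data frame with \code{x}, \code{n} and \code{rate} (deaths per
#'   person-year).
#' @export
reference_mortality_schedule <- function(gompertz_a, gompertz_b,
                                         bands = age_bands()) {
  if (gompertz_a <= 0) stop("gompertz_a must be > 0")
  if (gompertz_b < 0) stop("gompertz_b must be >= 0")
  .check_bands(bands)
  k <- nrow(bands)
  half <- bands$n / 2
  if (k > 1L) half[k] <- bands$n[k - 1L] / 2 else half[k] <- 2.5
  mid <- bands$x + half
  data.frame(x = bands$x, n = bands$n,
             rate = gompertz_a * exp(gompertz_b * (mid - 50)))
}

#' Write a cohort table as delimited text
#'
#' Comma-delimited with a header row, one participant per row, missing values
#' encoded as empty fields.
#'
#' @param cohort cohort data frame.
#' @param path output file path.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "")
}

#' Read a cohort table written by \code{\link{write_cohort}}
#'
#' @param path input file path.
#' @return data frame.
#' @export
read_cohort <- function(path) {
  x <- utils::read.csv(path, na.strings = "", stringsAsFactors = FALSE)
  if ("education" %in% names(x))
    x$education <- factor(x$education, levels = c("low", "medium", "high"))
  x
}
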