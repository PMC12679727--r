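#' Person-time from baseline to death or censoring
#'
#' @param entry entry time (baseline; usually 0).
#' @param exit exit time (death or censoring, whichever came first).
#' @return follow-up in years; errors when exit precedes entry.
#' @export
person_time <- function(entry, exit) {
  if (any(exit < entry)) stop("exit time precedes entry time")
  exit - entry
}

#' Fit a Cox proportional-hazards model
#'
#' Maximizes the partial likelihood with Efron tie handling (continuous
#' follow-up rarely ties; Efron is the accurate default) and returns a tidy
#' coefficient table with hazard ratios and Wald 95\% confidence intervals
#' exp(beta +/- 1.96 se). Factor exposures contribute beta = 0 for the
#' reference level.
#'
#' @param data data frame with one row per participant.
#' @param time,event column names for follow-up time (> 0) and the event
#'   indicator (logical or 0/1).
#' @param terms character vector of covariate column names; the first is
#'   conventionally the exposure.
#' @return object of class \code{cox_fit}: list with \code{table} (term,
#'   beta, se, hr, lcl, ucl, p), \code{loglik} (log partial likelihood at the
#'   optimum), \code{ties = "efron"}, \code{n}, \code{n_events} and the
#'   underlying \code{survival::coxph} fit in \code{fit}.
#' @export
fit_cox <- function(data, time = "followup_years", event = "died", terms) {
  if (!all(c(time, event, terms) %in% names(data)))
    stop("missing column(s): ",
         paste(setdiff(c(time, event, terms), names(data)), collapse = ", "))
  ev <- as.logical(data[[event]])
  if (sum(ev) < 2) stop("need at least 2 events to fit a Cox model")
  if (any(data[[time]] <= 0)) stop("person-time must be positive")
  # a factor level with subjects but no events drives its beta to -Inf
  for (tm in terms) {
    v <- data[[tm]]
    if (is.factor(v) || is.character(v) || is.logical(v)) {
      tab_n <- table(v)
      tab_e <- tapply(ev, v, sum)
      zero <- names(tab_n)[tab_n > 0 & (is.na(tab_e) | tab_e == 0)]
      if (length(zero))
        stop("no events in category '", zero[1], "' of term '", tm,
             "': partial likelihood is monotone")
    }
  }
  mm <- stats::model.matrix(
    stats::reformulate(terms), data = data)
  if (qr(mm)$rank < ncol(mm)) stop("design matrix is rank deficient")

  fml <- stats::as.formula(paste0("survival::Surv(", time, ", ", event,
                                  ") ~ ", paste(terms, collapse = " + ")))
  fit <- survival::coxph(fml, data = data, ties = "efron",
                         control = survival::coxph.control(iter.max = 100))
  if (!is.null(fit$info) && isTRUE(fit$info$convergence > 0))
    stop("Cox model did not converge")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  z <- beta / se
  tab <- data.frame(term = names(beta), beta = unname(beta), se = unname(se),
                    hr = exp(unname(beta)),
                    lcl = exp(unname(beta) - 1.96 * unname(se)),
                    ucl = exp(unname(beta) + 1.96 * unname(se)),
                    p = 2 * stats::pnorm(-abs(unname(z))),
                    row.names = NULL)
  structure(list(table = tab, loglik = fit$loglik[2], ties = "efron",
                 n = fit$n, n_events = fit$nevent, fit = fit),
            class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties): n = ", x$n,
      ", events = ", x$n_events, "\n", sep = "")
  tab <- x$table
  tab[-1] <- lapply(tab[-1], function(v) signif(v, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write a Cox coefficient table as delimited text
#'
#' Columns: term, beta, se, hr, lcl, ucl, p.
#'
#' @param fit a \code{cox_fit}.
#' @param path output path.
#' @export
write_cox_fit <- function(fit, path) {
  utils::write.csv(fit$table, path, row.names = FALSE)
}

#' Schoenfeld-residual test of proportional hazards
#'
#' Score test of a zero slope of the scaled Schoenfeld residuals against time
#' (identity time transform), per model term plus a global test.
#'
#' @param fit a \code{cox_fit}.
#' @return data frame with \code{term}, \code{chisq}, \code{df}, \code{p};
#'   the last row is the global test.
#' @export
schoenfeld_ph_test <- function(fit) {
  stopifnot(inherits(fit, "cox_fit"))
  if (fit$n_events < 3) stop("need at least 3 events for the PH test")
  z <- survival::cox.zph(fit$fit, transform = "identity")
  data.frame(term = rownames(z$table), chisq = z$table[, "chisq"],
             df = z$table[, "df"], p = z$table[, "p"], row.names = NULL)
}

#' Stratified Cox fits with an interaction test
#'
#' Fits the exposure model separately within each stratum and tests
#' effect-measure modification with a Wald chi-square on the
#' exposure-by-stratum product terms of the pooled model.
#'
#' @param data data frame.
#' @param exposure exposure column name (factor or logical).
#' @param stratum stratification column name.
#' @param covariates additional adjustment columns.
#' @param time,event as in \code{\link{fit_cox}}.
#' @return list with \code{by_stratum} (named list of \code{cox_fit}),
#'   \code{p_interaction} and \code{wald} (statistic and df).
#' @export
stratified_and_interaction <- function(data, exposure, stratum,
                                       covariates = character(),
                                       time = "followup_years",
                                       event = "died") {
  s <- data[[stratum]]
  if (is.null(s)) stop("stratum column not found")
  s <- factor(s)
  if (any(table(s) == 0) || nlevels(s) < 2)
    stop("need at least 2 non-empty strata")
  ev <- as.logical(data[[event]])
  ev_by <- tapply(ev, s, sum)
  if (any(is.na(ev_by) | ev_by < 2))
    stop("every stratum needs at least 2 events; stratum '",
         names(ev_by)[which(is.na(ev_by) | ev_by < 2)[1]], "' has fewer")
  by_stratum <- lapply(levels(s), function(lev)
    fit_cox(data[s == lev, , drop = FALSE], time, event,
            c(exposure, covariates)))
  names(by_stratum) <- levels(s)

  fml <- stats::as.formula(paste0(
    "survival::Surv(", time, ", ", event, ") ~ ", exposure, " * ", stratum,
    if (length(covariates)) paste(" +", paste(covariates, collapse = " + "))
    else ""))
  pooled <- survival::coxph(fml, data = data, ties = "efron")
  cn <- names(stats::coef(pooled))
  ix <- grep(":", cn, fixed = TRUE)
  if (!length(ix)) stop("no interaction terms identified in the pooled model")
  b <- stats::coef(pooled)[ix]
  V <- stats::vcov(pooled)[ix, ix, drop = FALSE]
  W <- drop(t(b) %*% solve(V, b))
  df <- length(b)
  list(by_stratum = by_stratum,
       p_interaction = stats::pchisq(W, df, lower.tail = FALSE),
       wald = c(statistic = W, df = df))
}

#' Population-attributable fraction from an adjusted hazard ratio
#'
#' PAF = P_d (HR_adj - 1) / HR_adj, where P_d is the proportion of deaths
#' exposed to the risk factor and HR_adj the adjusted hazard ratio. The
#' confidence interval substitutes the HR confidence bounds into the same
#' formula.
#'
#' @param p_d proportion of deaths exposed, in [0, 1].
#' @param hr_adj adjusted hazard ratio (> 0).
#' @param hr_lcl,hr_ucl optional HR confidence bounds.
#' @return list with \code{paf} and (when bounds are given) \code{lower},
#'   \code{upper}.
#' @export
paf <- function(p_d, hr_adj, hr_lcl = NULL, hr_ucl = NULL) {
  if (any(p_d < 0 | p_d > 1)) stop("p_d must lie in [0, 1]")
  if (any(hr_adj <= 0)) stop("hr_adj must be positive")
  val <- p_d * (hr_adj - 1) / hr_adj
  out <- list(paf = val)
  if (!is.null(hr_lcl)) {
    if (any(hr_lcl <= 0)) stop("hr_lcl must be positive")
    out$lower <- p_d * (hr_lcl - 1) / hr_lcl
  }
  if (!is.null(hr_ucl)) {
    if (any(hr_ucl <= 0)) stop("hr_ucl must be positive")
    out$upper <- p_d * (hr_ucl - 1) / hr_ucl
  }
  out
}
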