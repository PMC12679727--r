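# Small in-code fixtures shared across test files.

# a fully in-target participant row (CCDRFS dialect measurements)
in_target_row <- function(...) {
  row <- data.frame(
    id = 1L, t2d = TRUE, age = 55, sex = "male",
    education = factor("medium", levels = c("low", "medium", "high")),
    econ = 0, hist_cvd = FALSE, hist_cancer = FALSE, diab_dur = 4,
    smoking_ever = FALSE, activity_min_wk = 200,
    fruitveg_g_d = 500, redmeat_g_d = 50,
    hba1c_pct = 6.9, sbp_mmhg = 139, tg_mmol_l = 1.6, hdl_mmol_l = 1.10,
    followup_years = 5, died = FALSE, cause = NA_character_,
    stringsAsFactors = FALSE)
  mods <- list(...)
  row[names(mods)] <- mods
  row
}

# two-group exponential survival data with known rate ratio
exp_two_group <- function(n_per_arm, rate0, rate1, seed, horizon = Inf) {
  set.seed(seed)
  x <- rep(c(0, 1), each = n_per_arm)
  tt <- stats::rexp(2 * n_per_arm, rate = ifelse(x == 1, rate1, rate0))
  data.frame(exposed = x == 1,
             followup_years = pmin(tt, horizon),
             died = tt <= horizon)
}

# Efron-free partial log-likelihood for untied data (independent oracle)
partial_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# brute-force greedy nearest-neighbour matching oracle: cases in descending
# score order, each takes its `ratio` nearest unused controls
greedy_match_oracle <- function(scores, t2d, ratio, caliper = NULL) {
  cases <- which(t2d)[order(scores[which(t2d)], decreasing = TRUE)]
  free <- which(!t2d)
  out <- list()
  g <- 0L
  for (cs in cases) {
    picked <- integer(0)
    for (r in seq_len(ratio)) {
      if (!length(free)) break
      d <- abs(scores[free] - scores[cs])
      j <- which.min(d)
      if (!is.null(caliper) && d[j] > caliper) break
      picked <- c(picked, free[j])
      free <- free[-j]
    }
    if (length(picked)) {
      g <- g + 1L
      out[[g]] <- data.frame(id = c(cs, picked), group = g,
                             role = c("case", rep("control", length(picked))))
    }
  }
  do.call(rbind, out)
}

# exact remaining life expectancy at 50 under a Gompertz hazard
# a at age 50, slope b (numerical quadrature; independent of life tables)
gompertz_e50 <- function(a, b) {
  S <- function(t) exp(-(a / b) * (exp(b * t) - 1))
  stats::integrate(S, 0, Inf, rel.tol = 1e-10)$value
}
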