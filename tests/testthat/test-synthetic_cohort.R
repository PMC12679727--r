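test_that("generation is deterministic and sized correctly", {
  cfg <- sim_config(n_t2d = 400, n_nont2d = 800, seed = 21)
  g1 <- generate_cohort(cfg)
  g2 <- generate_cohort(cfg)
  expect_identical(g1$cohort, g2$cohort)
  expect_identical(g1$truth$per_participant, g2$truth$per_participant)
  expect_equal(nrow(g1$cohort), 1200)
  expect_equal(sum(g1$cohort$t2d), 400)
  # record-level invariants
  expect_true(all(g1$cohort$followup_years > 0))
  expect_identical(is.na(g1$cohort$cause), !g1$cohort$died)
  expect_true(all(is.na(g1$cohort$diab_dur[!g1$cohort$t2d])))
})

test_that("configuration errors name the offending field", {
  expect_error(sim_config(n_t2d = 0), "n_t2d")
  expect_error(sim_config(factor_prevalences = c(smoking = 1.2, activity = 0,
                                                 diet = 0, hba1c = 0, bp = 0,
                                                 lipids = 0)),
               "factor_prevalences")
  expect_error(sim_config(horizon_years = 0), "horizon_years")
  expect_error(sim_config(gompertz_a = -1), "gompertz_a")
})

test_that("risk-factor marginals converge to the configured prevalences", {
  prev <- c(smoking = 0.35, activity = 0.19, diet = 0.73, hba1c = 0.36,
            bp = 0.47, lipids = 0.61)
  g <- generate_cohort(sim_config(n_t2d = 20000, n_nont2d = 1, seed = 5,
                                  factor_prevalences = prev))
  prof <- evaluate_targets(g$cohort, threshold_dialect("CCDRFS"))
  emp <- colMeans(!prof[paste0("within_", names(prev))])
  # binomial error at n = 20,000 is ~0.01; allow 3 sd
  expect_true(all(abs(emp - prev) < 0.012))
})

test_that("constant-hazard event times have the exponential mean", {
  lam <- 0.05
  cfg <- sim_config(n_t2d = 10000, n_nont2d = 1, seed = 13,
                    factor_log_hazards = stats::setNames(rep(0, 6),
                      c("smoking", "activity", "diet", "hba1c", "bp",
                        "lipids")),
                    t2d_excess_log_hazard = 0,
                    gompertz_a = lam, gompertz_b = 0,
                    horizon_years = 1e6, dropout_rate = 0)
  g <- generate_cohort(cfg)
  expect_true(all(g$cohort$died))
  expect_lt(abs(mean(g$cohort$followup_years) - 1 / lam),
            3 / lam / sqrt(10000))
})

test_that("null-hazard configuration gives exchangeable score groups", {
  # with all log-hazards zero, survival should not depend on the score:
  # log-rank p-values behave like a uniform draw over replicates
  ps <- vapply(1:30, function(i) {
    g <- generate_cohort(sim_config(n_t2d = 1500, n_nont2d = 1, seed = 100 + i,
                                    factor_log_hazards = stats::setNames(
                                      rep(0, 6),
                                      c("smoking", "activity", "diet", "hba1c",
                                        "bp", "lipids")),
                                    t2d_excess_log_hazard = 0))
    prof <- evaluate_targets(g$cohort, threshold_dialect("CCDRFS"))
    grp <- prof$score <= 2
    sd <- survival::survdiff(survival::Surv(followup_years, died) ~ grp,
                             data = g$cohort)
    stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
  }, numeric(1))
  expect_lte(mean(ps < 0.05), 0.2)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
})

test_that("single-factor effects are recovered by a downstream Cox fit", {
  cfg <- sim_config(n_t2d = 20000, n_nont2d = 1, seed = 3,
                    factor_prevalences = c(smoking = 0.4, activity = 0,
                                           diet = 0, hba1c = 0, bp = 0,
                                           lipids = 0),
                    factor_log_hazards = c(smoking = log(1.5), activity = 0,
                                           diet = 0, hba1c = 0, bp = 0,
                                           lipids = 0),
                    t2d_excess_log_hazard = 0, factor_correlation = 0,
                    horizon_years = 15)
  g <- generate_cohort(cfg)
  fit <- fit_cox(g$cohort, terms = c("smoking_ever", "age", "sex"))
  b <- fit$table$beta[fit$table$term == "smoking_everTRUE"]
  expect_lt(abs(b - log(1.5)), 0.1)
  # age enters the true hazard with slope gompertz_b
  b_age <- fit$table$beta[fit$table$term == "age"]
  expect_lt(abs(b_age - cfg$gompertz_b), 0.03)
})

test_that("missingness injection is MCAR at the requested rate", {
  g <- generate_cohort(sim_config(n_t2d = 5000, n_nont2d = 5000, seed = 2))
  t0 <- g$cohort
  expect_identical(inject_missingness(t0, 0), t0)
  t1 <- inject_missingness(t0, 0.03, seed = 77)
  t2 <- inject_missingness(t0, 0.03, seed = 77)
  expect_identical(t1, t2)
  frac <- mean(is.na(t1$hba1c_pct))
  expect_gte(frac, 0.025)   # binomial CI at n = 10,000
  expect_lte(frac, 0.035)
  expect_error(inject_missingness(t0, 0.05), "5%")
})

test_that("reference schedules evaluate the Gompertz hazard at midpoints", {
  b <- age_bands(50, 5, 100)
  s0 <- reference_mortality_schedule(0.01, 0, b)
  expect_true(all(s0$rate == 0.01))
  # a = 0.01, b = 0.1: band 70-75 has midpoint 72.5, offset 22.5 from 50;
  # the closed form for an offset of 25 y is 0.01 e^2.5
  s1 <- reference_mortality_schedule(0.01, 0.1, age_bands(50, 10, 100))
  expect_equal(s1$rate[s1$x == 70], 0.01 * exp(0.1 * 25))
  expect_true(all(diff(s1$rate) > 0))
  bad <- data.frame(x = c(50, 52), n = c(5, Inf))
  expect_error(reference_mortality_schedule(0.01, 0.1, bad), "contiguous")
})

test_that("cohort tables round-trip through delimited text", {
  g <- generate_cohort(sim_config(n_t2d = 50, n_nont2d = 50, seed = 8))
  path <- tempfile(fileext = ".csv")
  write_cohort(g$cohort, path)
  back <- read_cohort(path)
  expect_equal(back$hba1c_pct, g$cohort$hba1c_pct, tolerance = 1e-12)
  expect_identical(back$cause, g$cohort$cause)
  expect_identical(back$education, g$cohort$education)
  unlink(path)
})
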