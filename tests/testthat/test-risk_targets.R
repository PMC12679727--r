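test_that("all-in-target participant scores 0 and is optimal", {
  prof <- evaluate_targets(in_target_row(), threshold_dialect("CCDRFS"))
  expect_true(all(unlist(prof[paste0("within_", c("smoking", "activity",
                                                  "diet", "hba1c", "bp",
                                                  "lipids"))])))
  expect_identical(prof$score, 0L)
  expect_equal(as.character(prof$category), "optimal")
  expect_identical(prof$lifestyle_low_risk_count, 3L)
  expect_true(prof$metabolic_all_optimal)
})

test_that("boundary semantics match the guidelines as printed", {
  d <- threshold_dialect("CCDRFS")
  # SBP threshold drops to 130 with prior CVD
  expect_false(evaluate_targets(in_target_row(sbp_mmhg = 135,
                                              hist_cvd = TRUE), d)$within_bp)
  expect_true(evaluate_targets(in_target_row(sbp_mmhg = 135,
                                             hist_cvd = FALSE), d)$within_bp)
  # HDL minimum is inclusive, sex-specific
  expect_true(evaluate_targets(in_target_row(hdl_mmol_l = 1.03,
                                             tg_mmol_l = 1.0), d)$within_lipids)
  expect_false(evaluate_targets(in_target_row(hdl_mmol_l = 1.03, sex = "female",
                                              tg_mmol_l = 1.0), d)$within_lipids)
  # maxima strict: exactly at the cut is outside
  expect_false(evaluate_targets(in_target_row(hba1c_pct = 7.0), d)$within_hba1c)
  expect_false(evaluate_targets(in_target_row(sbp_mmhg = 140), d)$within_bp)
  expect_false(evaluate_targets(in_target_row(tg_mmol_l = 1.7), d)$within_lipids)
  # minima inclusive
  expect_true(evaluate_targets(in_target_row(activity_min_wk = 150),
                               d)$within_activity)
  expect_true(evaluate_targets(in_target_row(fruitveg_g_d = 400,
                                             redmeat_g_d = 100), d)$within_diet)
  # the lipid target is joint
  expect_false(evaluate_targets(in_target_row(tg_mmol_l = 2.0,
                                              hdl_mmol_l = 1.5), d)$within_lipids)
})

test_that("score categories follow the 0-1 / 2-4 / 5-6 stratification", {
  expect_equal(as.character(categorize_score(0:6)),
               c("optimal", "optimal", "suboptimal", "suboptimal",
                 "suboptimal", "poor", "poor"))
  expect_error(categorize_score(7), "0\\.\\.6")
  expect_error(categorize_score(-1), "0\\.\\.6")
})

test_that("worsening any single measurement never decreases the score", {
  d <- threshold_dialect("CCDRFS")
  base <- in_target_row()
  worse <- list(smoking_ever = TRUE, activity_min_wk = 10, fruitveg_g_d = 100,
                hba1c_pct = 8.5, sbp_mmhg = 165,
                tg_mmol_l = 3.0)
  s0 <- evaluate_targets(base, d)$score
  for (nm in names(worse)) {
    args <- stats::setNames(worse[nm], nm)
    s1 <- do.call(in_target_row, args)
    expect_gte(evaluate_targets(s1, d)$score, s0)
  }
  # flags + S always account for all six factors
  g <- generate_cohort(sim_config(n_t2d = 300, n_nont2d = 1, seed = 42))
  prof <- evaluate_targets(g$cohort, d)
  expect_true(all(rowSums(prof[1:6]) + prof$score == 6))
  expect_true(all(prof$lifestyle_low_risk_count +
                    rowSums(!prof[c("within_smoking", "within_activity",
                                    "within_diet")]) == 3))
})

test_that("missing exposures are refused with a pointer to imputation", {
  expect_error(evaluate_targets(in_target_row(hba1c_pct = NA),
                                threshold_dialect("CCDRFS")),
               "impute_missing")
})

test_that("top-third diet rule matches a brute-force sort", {
  expect_equal(diet_rule_nhanes(1:9), c(rep(FALSE, 6), rep(TRUE, 3)))
  expect_true(all(diet_rule_nhanes(rep(5, 10))))   # degenerate: all at the cut
  # for 1..10 the type-7 2/3 quantile interpolates to (10-1)*2/3 + 1 = 7
  # exactly (hand computation), so members are 7..10
  expect_equal(which(diet_rule_nhanes(1:10)), 7:10)
  expect_error(diet_rule_nhanes(c(NA_real_, NA_real_)), "missing")
})

test_that("UKB dialect counts food-item recommendations", {
  d <- threshold_dialect("UKB")
  row <- in_target_row()
  row$diet_items_met <- 5
  expect_true(evaluate_targets(row, d)$within_diet)
  row$diet_items_met <- 4
  expect_false(evaluate_targets(row, d)$within_diet)
})

test_that("weighted score sums betas over outside-target factors", {
  betas <- c(smoking = 0.2, activity = 0.5, diet = 0.1,
             hba1c = 0.3, bp = 0.05, lipids = 0.02)
  flags <- data.frame(within_smoking = FALSE, within_activity = FALSE,
                      within_diet = FALSE, within_hba1c = TRUE,
                      within_bp = TRUE, within_lipids = TRUE)
  expect_equal(weighted_score(flags, betas), 0.2 + 0.5 + 0.1)  # hand sum
  all_in <- as.data.frame(lapply(flags, function(x) TRUE))
  expect_equal(weighted_score(all_in, betas), 0)
  expect_error(weighted_score(flags, betas[-1]), "six factors")
})

test_that("equal positive betas reproduce the unweighted categories", {
  g <- generate_cohort(sim_config(n_t2d = 2000, n_nont2d = 1, seed = 9))
  prof <- evaluate_targets(g$cohort, threshold_dialect("CCDRFS"))
  betas <- stats::setNames(rep(0.3, 6),
                           c("smoking", "activity", "diet", "hba1c", "bp",
                             "lipids"))
  ws <- weighted_score(prof, betas)
  expect_equal(ws, 0.3 * prof$score)
  expect_equal(as.character(weighted_categorize(ws, prof$score)),
               as.character(prof$category))
})

test_that("individualized HbA1c limits and the LDL dialect are honoured", {
  d <- threshold_dialect("CCDRFS", hba1c_limit_col = "hba1c_limit")
  row <- in_target_row(hba1c_pct = 7.5)
  row$hba1c_limit <- 8.0
  expect_true(evaluate_targets(row, d)$within_hba1c)
  row$hba1c_limit <- 7.0
  expect_false(evaluate_targets(row, d)$within_hba1c)
  d2 <- threshold_dialect("CCDRFS", lipid_rule = "ldl")
  row2 <- in_target_row(tg_mmol_l = 9)   # TG ignored under the LDL rule
  row2$ldl_mmol_l <- 2.5
  expect_true(evaluate_targets(row2, d2)$within_lipids)
  row2$ldl_mmol_l <- 2.6
  expect_false(evaluate_targets(row2, d2)$within_lipids)
})
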