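test_that("person-time is the interval from baseline to exit", {
  expect_equal(person_time(0, 4.5), 4.5)
  expect_equal(person_time(0, 13.3), 13.3)
  expect_error(person_time(2, 1), "precedes")
})

test_that("two-group exponential data recover the rate ratio", {
  d <- exp_two_group(5000, rate0 = 0.1, rate1 = 0.2, seed = 6)
  fit <- fit_cox(d, terms = "exposed")
  expect_lt(abs(fit$table$hr[1] - 2.0), 0.1)
  expect_true(fit$table$lcl[1] < fit$table$hr[1] &&
                fit$table$hr[1] < fit$table$ucl[1])
})

test_that("the fit maximizes the partial likelihood (grid oracle)", {
  d <- data.frame(
    followup_years = c(2.3, 1.1, 4.8, 3.2, 0.7, 5.5, 2.9, 4.1, 1.8, 3.7),
    died = c(TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, TRUE, FALSE, TRUE),
    x = c(0, 1, 0, 1, 0, 1, 0, 1, 0, 1))
  fit <- fit_cox(d, terms = "x")
  # independent oracle: maximize the untied partial likelihood numerically
  opt <- optimize(function(b) partial_loglik(b, d$followup_years, d$died, d$x),
                  c(-5, 5), maximum = TRUE)
  expect_lt(abs(fit$table$beta[1] - opt$maximum), 1e-3)
  expect_equal(fit$loglik,
               partial_loglik(fit$table$beta[1], d$followup_years, d$died,
                              d$x), tolerance = 1e-8)
})

test_that("null exposures are covered by the CI at the nominal rate", {
  covered <- 0
  for (i in 1:40) {
    set.seed(300 + i)
    d <- data.frame(followup_years = rexp(300), died = runif(300) < 0.6,
                    x = runif(300) < 0.5)
    fit <- fit_cox(d, terms = "x")
    if (fit$table$lcl[1] <= 1 && 1 <= fit$table$ucl[1]) covered <- covered + 1
  }
  expect_gte(covered, 33)  # ~95% nominal, binomial slack at 40 replicates
})

test_that("fit is invariant to row order and covariate rescaling", {
  d <- exp_two_group(400, 0.1, 0.18, seed = 9)
  d$age <- rnorm(800, 60, 8)
  f1 <- fit_cox(d, terms = c("exposed", "age"))
  perm <- sample(nrow(d))
  f2 <- fit_cox(d[perm, ], terms = c("exposed", "age"))
  expect_equal(f1$table$beta, f2$table$beta, tolerance = 1e-8)
  d$age10 <- d$age / 10
  f3 <- fit_cox(d, terms = c("exposed", "age10"))
  expect_equal(f3$table$beta[f3$table$term == "age10"],
               10 * f1$table$beta[f1$table$term == "age"], tolerance = 1e-6)
  expect_equal(f3$table$hr[1], f1$table$hr[1], tolerance = 1e-6)
})

test_that("degenerate designs are refused with informative errors", {
  d <- exp_two_group(50, 0.1, 0.2, seed = 2)
  expect_error(fit_cox(d[1:3, ][c(TRUE, FALSE, FALSE), ], terms = "exposed"),
               "2 events")
  d$g <- factor(rep(c("a", "b"), each = 50))
  d$died[d$g == "b"] <- FALSE
  expect_error(fit_cox(d, terms = "g"), "no events in category 'b'")
  d2 <- exp_two_group(50, 0.1, 0.2, seed = 3)
  d2$dup <- as.numeric(d2$exposed)
  expect_error(fit_cox(d2, terms = c("exposed", "dup")), "rank")
})

test_that("the Schoenfeld test keeps its size and detects sign flips", {
  # null: proportional hazards -> p roughly uniform
  ps <- vapply(1:25, function(i) {
    d <- exp_two_group(200, 0.1, 0.2, seed = 500 + i)
    schoenfeld_ph_test(fit_cox(d, terms = "exposed"))$p[1]
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.001)
  # alternative: effect flips sign at t0 = 5 -> strong rejection
  rej <- 0
  for (i in 1:10) {
    set.seed(700 + i)
    n <- 1000
    x <- rep(c(0, 1), each = n)
    lam0 <- 0.1
    t0 <- 5
    # group 1 hazard 3*lam0 before t0, lam0/3 after (piecewise inversion)
    u <- rexp(2 * n)
    t1 <- ifelse(u < 3 * lam0 * t0, u / (3 * lam0),
                 t0 + (u - 3 * lam0 * t0) / (lam0 / 3))
    tt <- ifelse(x == 1, t1, u / lam0)
    d <- data.frame(followup_years = pmin(tt, 30), died = tt <= 30,
                    x = x == 1)
    p <- schoenfeld_ph_test(fit_cox(d, terms = "x"))$p[1]
    if (p < 0.05) rej <- rej + 1
  }
  expect_gte(rej, 8)
  # too few events
  tiny <- data.frame(followup_years = c(1, 2, 3, 4),
                     died = c(TRUE, TRUE, FALSE, FALSE),
                     x = c(0, 1, 1, 0))
  expect_error(schoenfeld_ph_test(fit_cox(tiny, terms = "x")), "3 events")
})

test_that("interaction tests find differing stratum effects", {
  set.seed(88)
  n <- 4000
  mkstr <- function(hr, lab) {
    d <- exp_two_group(n / 2, 0.1, 0.1 * hr, seed = sample.int(1e6, 1))
    d$stratum <- lab
    d
  }
  d <- rbind(mkstr(3.2, "A"), mkstr(2.0, "B"))
  res <- stratified_and_interaction(d, "exposed", "stratum")
  expect_lt(res$p_interaction, 0.05)
  expect_gt(res$by_stratum$A$table$hr[1], res$by_stratum$B$table$hr[1])
  # identical strata: p_interaction is not systematically small
  d0 <- rbind(mkstr(2.0, "A"), mkstr(2.0, "B"))
  res0 <- stratified_and_interaction(d0, "exposed", "stratum")
  expect_gt(res0$p_interaction, 0.001)
  # a stratum without events is refused
  d$died[d$stratum == "B"] <- FALSE
  expect_error(stratified_and_interaction(d, "exposed", "stratum"),
               "at least 2 events")
})

test_that("PAF follows the standard adjusted formula", {
  expect_equal(paf(0.5, 2)$paf, 0.25)
  expect_equal(paf(0.3, 1)$paf, 0)
  expect_equal(paf(0.7, 1)$paf, 0)
  # monotone in both arguments; bounded by P_d
  hrs <- c(1, 1.5, 2, 4, 20, 1000)
  v <- vapply(hrs, function(h) paf(1, h)$paf, numeric(1))
  expect_true(all(diff(v) > 0))
  expect_true(all(v < 1))
  pds <- seq(0, 1, 0.1)
  v2 <- vapply(pds, function(p) paf(p, 2)$paf, numeric(1))
  expect_true(all(diff(v2) > 0))
  expect_true(all(v2 <= pds))
  # CI by HR-bound substitution
  r <- paf(0.5, 2, hr_lcl = 1.5, hr_ucl = 3)
  expect_equal(r$lower, 0.5 * 0.5 / 1.5)
  expect_equal(r$upper, 0.5 * 2 / 3)
  expect_error(paf(0.5, -1), "positive")
  expect_error(paf(1.2, 2), "\\[0, 1\\]")
})
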