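#!/usr/bin/env Rscript
# Score every T2D participant against the six guideline targets, then match
# each T2D case to two non-diabetic controls by propensity score.
# Run after 01_simulate.R.

library(t2dlife)

cohort <- read_cohort("results/cohort.csv")
seed <- 2026L

cohort <- impute_missing(cohort)
dialect <- threshold_dialect("CCDRFS")
prof <- evaluate_targets(cohort[cohort$t2d, ], dialect)
write.csv(cbind(id = cohort$id[cohort$t2d], prof), "results/scores.csv",
          row.names = FALSE)
message("risk-factor control among T2D:")
print(table(prof$category))
message("achieving >= 5 targets (score <= 1): ",
        proportion_pct(sum(prof$score <= 1), nrow(prof)), "%")

ps <- estimate_propensity(cohort, matching_covariates("CCDRFS"))
matched <- nearest_neighbor_match(ps, cohort$t2d, ratio = 2, seed = seed)
write_matched_cohort(matched, "results/matched.csv")
print(matched)

bal <- balance_table(cohort, matched, c("age"))
write.csv(bal, "results/balance.csv", row.names = FALSE)
message("age SMD before/after matching: ",
        round(bal$smd_before, 4), " / ", round(bal$smd_after, 4))
message("written: results/scores.csv, results/matched.csv, results/balance.csv")
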