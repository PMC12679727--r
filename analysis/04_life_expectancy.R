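#!/usr/bin/env Rscript
# Life expectancy at age 50 by control category with parametric-bootstrap
# CIs, and the years-of-life-lost comparison against matched controls.
# Run after 03_mortality_models.R.

library(t2dlife)

tab2 <- read.csv("results/table2.csv")

yll <- data.frame(
  category = tab2$category,
  yll_male = years_of_life_lost(tab2$e50_male[tab2$category == "control"],
                                tab2$e50_male),
  yll_female = years_of_life_lost(tab2$e50_female[tab2$category == "control"],
                                  tab2$e50_female))
write.csv(yll, "results/years_of_life_lost.csv", row.names = FALSE)

message("life expectancy at 50 and years lost vs matched controls:")
print(cbind(tab2[, c("category", "e50_male", "e50_female")],
            yll[, c("yll_male", "yll_female")]))
best <- tab2$category == "optimal"
worst <- tab2$category == "poor"
message("best- vs worst-controlled T2D gain: ",
        round(tab2$e50_male[best] - tab2$e50_male[worst], 1), " y (male), ",
        round(tab2$e50_female[best] - tab2$e50_female[worst], 1),
        " y (female)")
message("written: results/years_of_life_lost.csv")
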