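#!/usr/bin/env Rscript
# Robustness-style runs: expectancies over restricted age windows (full
# 40-74, older 50-74, early 40-50) by gender x parity, plus the approximate
# decomposition check — expectancy over 40-74 should be close to the 40-50
# window estimate plus the 50-74 continuation.

library(worklife)
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(n_persons = 20000, seed = 101)
pan <- generate_panel(cfg)
spec <- model_spec(knots = cfg$truth$knots)

windows <- list(full_40_74 = c(40, 75), older_50_74 = c(50, 75),
                early_40_50 = c(40, 50))
tabs <- lapply(names(windows), function(w) {
  res <- pipeline_expectancies(pan, spec = spec, groups = c("gender", "parity"),
                               min_age = windows[[w]][1], max_age = windows[[w]][2])
  cbind(window = w, as.data.frame(res))
})
out <- do.call(rbind, tabs)
write.csv(out, "results/age_window_expectancies.csv", row.names = FALSE)

full <- tabs[[1]]; older <- tabs[[2]]; early <- tabs[[3]]
gap <- full$employment - (early$employment + older$employment)
cat("employment 40-74 vs (40-50) + (50-74), by cell (years):\n")
print(data.frame(gender = full$gender, parity = full$parity,
                 full = round(full$employment, 2),
                 sum_of_windows = round(early$employment + older$employment, 2),
                 difference = round(gap, 2)))
cat(sprintf("\nmax |difference|: %.2f years (approximate identity: the window\n", max(abs(gap))))
cat("fits re-estimate age effects and the 50-74 run re-anchors its radix at age 50)\n")
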