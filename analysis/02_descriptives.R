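#!/usr/bin/env Rscript
# Descriptive summary of the annual synthetic panel: per-gender percentages
# of person-waves by parity, education, marital status and the extra
# covariate — the standard sample-composition table for a panel study.

library(worklife)
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(n_persons = 20000, seed = 101)
pan <- generate_panel(cfg)
s <- summarize_panel(pan)
write.csv(as.data.frame(s), "results/descriptives_annual.csv", row.names = FALSE)

cat("person-waves by gender:\n")
print(as.data.frame(s[s$block == "N", ]))
cat("\nparity distribution (% of person-waves):\n")
print(as.data.frame(s[s$block == "parity", ]), digits = 3)
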