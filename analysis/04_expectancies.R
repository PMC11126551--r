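#!/usr/bin/env Rscript
# State expectancies at age 40 (employment, joblessness, retirement, total
# residual LE to 74) by gender x parity and by gender x parity x education,
# estimated from the annual synthetic panel, side by side with the
# generator's ground truth for the same covariate profiles.

library(worklife)
dir.create("results", showWarnings = FALSE)

cfg <- generator_config(n_persons = 20000, seed = 101)
pan <- generate_panel(cfg)
spec <- model_spec(knots = cfg$truth$knots)
rec <- build_transition_records(pan, 1)
qty <- c("employment", "joblessness", "retirement", "total")

for (grp in list(c("gender", "parity"), c("gender", "parity", "education"))) {
  res <- pipeline_expectancies(pan, spec = spec, groups = grp)
  tru <- t(sapply(seq_len(nrow(res)), function(i) {
    cell <- res[i, ]
    prof <- population_profile(rec[rec$gender == cell$gender, ],
                               parity = cell$parity,
                               education = if ("education" %in% grp) cell$education)
    unlist(truth_expectancies(cfg, profile = prof, gender = cell$gender)[qty])
  }))
  colnames(tru) <- paste0("truth_", qty)
  out <- cbind(as.data.frame(res), round(tru, 3))
  f <- file.path("results",
                 paste0("expectancy_", paste(grp, collapse = "_"), ".csv"))
  write.csv(out, f, row.names = FALSE)
  cat("\n==", paste(grp, collapse = " x "), "==\n")
  print(cbind(out[grp], round(out[c("employment", "truth_employment", "total")], 2)))
}
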