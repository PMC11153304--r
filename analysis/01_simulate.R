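#!/usr/bin/env Rscript
# Step 1 — simulate the synthetic cohort and its monitor wear records.
#
# Draws the default three-stratum cohort (NGM 1341 / IGM 363 / T2D 684,
# n = 2388) with known generating parameters, plus eight days of day-level
# activPAL-style records per participant, and writes everything under
# results/. Later steps consume only these files.

suppressPackageStartupMessages(library(timeuse24))

seed <- 20240101L
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(synthetic_config(seed = seed))
d <- cohort$participants
cat(sprintf("Simulated %d participants (%s)\n", nrow(d),
            paste(names(table(d$stratum)), table(d$stratum),
                  collapse = ", ", sep = " = ")))

records <- generate_day_records(cohort)
cat(sprintf("Simulated %d day records and %d stepping epochs\n",
            nrow(records$days), nrow(records$epochs)))

write.csv(d, "results/participants.csv", row.names = FALSE)
write.csv(records$days, "results/days.csv", row.names = FALSE)
write.csv(records$epochs, "results/epochs.csv", row.names = FALSE)
truth <- cohort$truth
truth$beta <- apply(truth$beta, 1, as.list)
truth$centres <- apply(truth$centres, 1, as.list)
yaml::write_yaml(list(seed = seed, beta = truth$beta,
                      gamma = as.list(truth$gamma),
                      noise_sd = truth$noise_sd,
                      centres = truth$centres),
                 "results/truth.yaml")
cat("Wrote participants.csv, days.csv, epochs.csv, truth.yaml\n")
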