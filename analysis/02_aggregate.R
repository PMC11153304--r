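#!/usr/bin/env Rscript
# Step 2 — apply the wear-day validity rules and average to one daily
# composition per participant.
#
# Day 1 is dropped (clinic day), a final day with <= 14 h of recorded
# information is dropped, remaining days need >= 14 h of waking time, and
# stepping is split into LPA/MVPA at 100 steps/min. The monitor-derived
# compositions are joined back to covariates and markers to form the
# analysis table.

suppressPackageStartupMessages(library(timeuse24))

days <- read.csv("results/days.csv")
epochs <- read.csv("results/epochs.csv")
participants <- read.csv("results/participants.csv")

days <- attach_stepping(days, epochs)
agg <- aggregate_participants(days)

cat(sprintf("Valid participants: %d of %d (%d excluded)\n",
            nrow(agg$compositions), length(unique(days$participant_id)),
            nrow(agg$exclusions)))
if (nrow(agg$exclusions) > 0) {
  for (r in seq_len(nrow(agg$exclusions))) {
    cat(sprintf("  excluded %s: %s\n", agg$exclusions$participant_id[r],
                agg$exclusions$reason[r]))
  }
}
cat(sprintf("Mean valid wear days: %.1f\n",
            mean(agg$compositions$n_valid_days)))

keep <- setdiff(names(participants), BEHAVIOUR_PARTS)
analysis <- merge(agg$compositions, participants[, keep],
                  by = "participant_id", sort = TRUE)
gm <- geometric_mean_composition(as.matrix(analysis[, BEHAVIOUR_PARTS]))
cat("Compositional mean of the analysed sample (h:mm):\n")
for (p in BEHAVIOUR_PARTS) cat(sprintf("  %-9s %s\n", p, format_hmm(gm[p])))

write.csv(analysis, "results/analysis_table.csv", row.names = FALSE)
write.csv(agg$exclusions, "results/exclusions.csv", row.names = FALSE)
cat("Wrote analysis_table.csv, exclusions.csv\n")
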