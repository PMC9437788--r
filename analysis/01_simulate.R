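#!/usr/bin/env Rscript
# Simulate the two preset engagement cohorts and write them as CSV pairs
# (events.csv: participant_id, day_index for each logged-in day;
# participants.csv: ids, true group, covariates, outcome).
#
# The iCanQuit-like preset plants three trajectory archetypes (brief,
# 4-week, persistent users) mixed 57.06/28.34/14.59% with outcome
# probabilities 0.23/0.30/0.56; the QuitGuide-like preset plants two
# (week-1 means 1.4 and 2.8 days) mixed 65.32/34.68% with outcome
# probabilities 0.21/0.23.

library(engtraj)

seed <- 20260927L
out_root <- "results/cohorts"

for (arm in c("icanquit", "quitguide")) {
  cfg <- preset_config(arm, seed = seed)
  cohort <- generate_cohort(cfg)
  dir <- file.path(out_root, arm)
  write_cohort(cohort, dir)
  write_cohort_config(cfg, file.path(dir, "config.yaml"))
  cat(sprintf("%s: n = %d, planted groups:\n", arm, cfg$n))
  print(table(cohort$participants$true_group))
  cat(sprintf("  planted abstinence by group:\n"))
  print(round(tapply(cohort$participants$abstinent,
                     cohort$participants$true_group, mean), 3))
  cat("  written to", dir, "\n\n")
}
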