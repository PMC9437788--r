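#!/usr/bin/env Rscript
# Cluster the simulated cohorts' log-in trajectories: rebuild the daily
# binary matrix from the event CSV, presmooth (7-day trailing mean),
# summarize by FPCA at a 90% variance threshold, select the number of
# groups by prediction strength (>= 0.6) with minimum-size (>= 5%) and
# separation (>= 1 within-group SD) rules, cluster with CLARA, and name
# groups by weeks of sustained engagement. Writes assignments, group
# summaries and the FPC bundle under results/<arm>/.

library(engtraj)

seed <- 20260927L

for (arm in c("icanquit", "quitguide")) {
  dir <- file.path("results/cohorts", arm)
  if (!dir.exists(dir)) stop("run analysis/01_simulate.R first")
  dat <- read_cohort_csv(dir)
  events <- utils::read.csv(file.path(dir, "events.csv"))
  daily <- binarize_events(events, dat$participants$participant_id)

  pl <- run_cluster_pipeline(daily, pipeline_config(seed = seed))
  out <- file.path("results", arm)
  write_pipeline(pl, out)

  cat(sprintf("\n== %s arm ==\n", arm))
  print(pl)
  cat("k-selection diagnostics:\n")
  print(pl$clusters$diagnostics, digits = 3)
  truth <- dat$participants$true_group[
    match(pl$ids, dat$participants$participant_id)
  ]
  cat("assigned vs planted groups:\n")
  print(table(pl$assignments$group_name, truth))
  cat("outputs written to", out, "\n")
}
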