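#!/usr/bin/env Rscript
# Relate trajectory groups to the 12-month abstinence outcome and to
# baseline covariates: logistic regression of abstinence on group
# membership (least-persistent group as reference) with univariate
# screening and AIC-stepwise covariate selection, and a multinomial (3+
# groups) or logistic (2 groups) model of group membership on baseline
# covariates. Writes table-style CSV reports under results/<arm>/models/.

library(engtraj)

seed <- 20260927L

for (arm in c("icanquit", "quitguide")) {
  dir <- file.path("results/cohorts", arm)
  if (!dir.exists(dir)) stop("run analysis/01_simulate.R first")
  dat <- read_cohort_csv(dir)
  daily <- dat$logins[rowSums(dat$logins) > 0, , drop = FALSE]
  pl <- run_cluster_pipeline(daily, pipeline_config(seed = seed))

  models <- run_association(pl, dat$participants)
  out <- file.path("results", arm, "models")
  write_association(models, out)

  cat(sprintf("\n== %s arm: outcome model ==\n", arm))
  print(models$outcome_model)
  cat(sprintf("dropped %d missing outcomes; screened covariates: %s\n",
              attr(models$outcome_model, "n_dropped"),
              paste(attr(models$outcome_model, "screened"), collapse = ", ")))
  cat(sprintf("\n== %s arm: membership model ==\n", arm))
  print(models$membership_model)
  cat("reports written to", out, "\n")
}
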