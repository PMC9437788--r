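# engtraj

Engagement-trajectory clustering and outcome modelling for digital health
interventions.

Smartphone-delivered behavioural interventions log when each participant
opens the app. The day-level engagement record is a binary series — did
participant *i* log in at least once on day *d*, for *d* = 0…181 from
randomization — and participants follow markedly different temporal
patterns: most disengage within a week, some taper over about a month, a
few keep returning for six months. engtraj identifies such data-driven
trajectory groups and estimates how group membership relates to a distal
binary outcome (e.g. 30-day point-prevalence smoking abstinence at 12
months) and to baseline characteristics.

## Method

1. **Presmoothing.** Each binary series is smoothed with a 7-day trailing
   moving average (window includes the current day and shrinks at the
   series start), yielding dense functional data
   *X<sub>i</sub>(t)* ∈ [0, 1].
2. **FPCA by smoothed covariance.** The sample covariance surface
   *G(s,t)* is smoothed with a product-Gaussian local-linear smoother
   (bandwidth 7 days), symmetrized and PSD-projected; the quadrature
   eigenproblem gives eigenfunctions φ<sub>k</sub> and scores
   ξ<sub>ik</sub> = Σ<sub>t</sub> w<sub>t</sub>(X<sub>i</sub>(t) −
   μ(t))φ<sub>k</sub>(t). The smallest K explaining ≥ 90% of variance is
   retained.
3. **Clustering.** FPC scores are clustered with k-medoids
   (PAM/CLARA, Euclidean distance). The number of groups k ∈ 2…6 is the
   largest candidate with prediction strength ≥ 0.6 over random
   half-splits, all group sizes ≥ 5% of the sample, and group mean
   trajectories separated by at least one pooled within-group SD. Groups
   are named by persistence — the last week their mean weekly log-ins
   stay ≥ 1 day — e.g. "1-week users", "26-week users".
4. **Association models.** Logistic regression of the outcome on group
   membership with the least-persistent group as reference, covariates
   chosen by univariate screening (Wald p < .05) then AIC-stepwise
   selection with the group terms forced; multinomial (k ≥ 3) or
   logistic (k = 2) regression of group membership on baseline
   covariates. Odds ratios with 95% Wald CIs throughout.

A synthetic-cohort generator plants trajectory archetypes (weekly
log-in means, mixture weights, group-specific outcome probabilities)
so the entire pipeline is testable without trial data; two presets
reproduce the published engagement-group structure of a large two-app
smoking-cessation trial.

## Worked example

```r
library(engtraj)

cohort   <- generate_cohort(preset_config("icanquit", seed = 1))
pipeline <- run_cluster_pipeline(cohort$logins, pipeline_config(seed = 1))
print(pipeline)
#> Engagement trajectory pipeline (1068 participants, 1 excluded)
#> FPCA of 1068 trajectories on 182 grid points
#> Retained 2 component(s) at 90% variance threshold; explained: 81.6%, 11.1%
#> Trajectory clustering: k = 3 (prediction strength 0.885)
#>          group size  share week1_mean
#>   1-week users  608 56.93%       1.88
#>   4-week users  296 27.72%       4.74
#>  26-week users  164 15.36%       5.35

models <- run_association(pipeline, cohort$participants)
model_report(models$outcome_model)
#>                            term    or ci_low ci_high        p  aic
#> 1                   (Intercept) 0.342  0.285   0.411 9.85e-31 1307
#> 2  trajectory_group4-week users 1.754  1.302   2.362 2.18e-04 1307
#> 3 trajectory_group26-week users 4.567  3.177   6.564 2.36e-16 1307
```

The pipeline recovers the three planted groups at very nearly their
planted shares (57.06/28.34/14.59%), names them by persistence, and the
outcome model reports the abstinence odds of the 4-week and 26-week
groups relative to the 1-week reference group — here 1.75 and 4.57, to
be read against the value of about 4.26 implied by the planted rates
0.56 vs 0.23 for the most- vs least-persistent contrast.

## Analysis workflow

The `analysis/` scripts run the study end to end, writing tables under
`results/`:

```sh
Rscript analysis/01_simulate.R   # two preset cohorts -> event/participant CSVs
Rscript analysis/02_cluster.R    # binarize -> presmooth -> FPCA -> CLARA -> naming
Rscript analysis/03_associate.R  # outcome + membership model reports
Rscript analysis/04_figures.R    # mean weekly log-ins per group (ggplot2)
```

## Package layout

- `R/` — generator (`synth_cohort`), preprocessing (`binarize_events`,
  `presmooth`, `weekly_login_summary`), FPCA (`fit_fpca` and its
  pieces), clustering (`pam_fit`, `clara_fit`, `prediction_strength`,
  `select_k`, `name_groups`), models (`fit_logistic`,
  `fit_multinomial`, `univariate_screen`, `stepwise_aic`,
  `group_outcome_model`, `baseline_predictor_model`) and pipeline
  orchestration (`run_cluster_pipeline`, `run_association`).
- `vignettes/engagement-trajectories.Rmd` — the methods vignette:
  model, assumptions, defaults, design decisions and limitations.
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force and closed-form oracles.
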