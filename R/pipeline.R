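#' Pipeline configuration
#'
#' Collects the tunable parameters of the trajectory pipeline with their
#' defaults: 7-day presmoothing, FPCA at a 90% variance threshold with
#' bandwidth 7 days, k searched over 2..6 with prediction-strength
#' threshold 0.6 and minimum group share 5%.
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param window Presmoothing window (days).
#' @param fpca_threshold Variance-explained threshold.
#' @param fpca_bandwidth Covariance smoother bandwidth (days).
#' @param k_range Candidate group numbers.
#' @param ps_threshold Minimum prediction strength.
#' @param min_group_frac Minimum group share of the sample.
#' @param sep_threshold Minimum separation of group mean trajectories, in
#'   pooled within-group SD units (`NULL` disables); default 1.
#' @param n_splits Prediction-strength half-splits.
#' @param n_subsamples,subsample_size CLARA subsampling settings (`NULL`
#'   size = classical `min(n, 40 + 2k)`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed, window = 7L, fpca_threshold = 0.90,
                            fpca_bandwidth = 7, k_range = 2:6,
                            ps_threshold = 0.6, min_group_frac = 0.05,
                            sep_threshold = 1, n_splits = 10,
                            n_subsamples = 5, subsample_size = NULL) {
  stopifnot(
    window >= 1, fpca_threshold > 0, fpca_threshold <= 1,
    fpca_bandwidth > 0, ps_threshold >= 0, ps_threshold <= 1,
    min_group_frac >= 0, min_group_frac < 1
  )
  structure(
    list(
      seed = as.integer(seed), window = as.integer(window),
      fpca_threshold = fpca_threshold, fpca_bandwidth = fpca_bandwidth,
      k_range = as.integer(k_range), ps_threshold = ps_threshold,
      min_group_frac = min_group_frac, sep_threshold = sep_threshold,
      n_splits = n_splits,
      n_subsamples = n_subsamples, subsample_size = subsample_size
    ),
    class = "pipeline_config"
  )
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path File path.
#' @return For `read_pipeline_config`, a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  y$k_range <- if (!is.null(y$k_range)) as.integer(y$k_range) else 2:6
  do.call(pipeline_config, y)
}

#' @rdname read_pipeline_config
#' @param config A `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the trajectory-clustering pipeline
#'
#' Runs presmoothing, FPCA and trajectory clustering on a daily engagement
#' matrix: the binary series are presmoothed with a trailing moving
#' average, summarized by FPC scores retaining the configured share of
#' variance, and clustered with CLARA, choosing the number of groups by
#' prediction strength with a minimum-group-size rule. Groups are named and
#' ordered by engagement persistence (group 1 = least persistent).
#'
#' @param daily n x 182 binary matrix (e.g. a cohort's `logins` or
#'   [binarize_events()] output). Rows with zero log-ins are excluded and
#'   counted.
#' @param config A [pipeline_config()].
#' @param k Optional fixed number of groups (skips selection).
#' @return An object of class `traj_pipeline`: `fpca` (the `fpc_model`),
#'   `clusters` (a `traj_clusters`), `assignments` (data.frame of
#'   participant_id, group_index, group_name), `smoothed`, the retained row
#'   ids, `n_excluded`, and the `config`.
#' @export
run_cluster_pipeline <- function(daily, config, k = NULL) {
  stopifnot(is.matrix(daily), inherits(config, "pipeline_config"))
  active <- rowSums(daily) > 0
  n_excluded <- sum(!active)
  if (n_excluded) {
    message(n_excluded, " participant(s) with zero log-ins excluded before clustering")
  }
  daily <- daily[active, , drop = FALSE]
  smoothed <- presmooth(daily, config$window)
  fpc <- fit_fpca(smoothed, threshold = config$fpca_threshold,
                  bandwidth = config$fpca_bandwidth)
  clusters <- cluster_trajectories(
    fpc$scores, daily,
    k = k, k_range = config$k_range, ps_threshold = config$ps_threshold,
    min_group_frac = config$min_group_frac,
    sep_threshold = config$sep_threshold, n_splits = config$n_splits,
    seed = config$seed, curves = smoothed,
    n_subsamples = config$n_subsamples,
    subsample_size = config$subsample_size
  )
  ids <- rownames(daily)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(daily)))
  assignments <- data.frame(
    participant_id = ids,
    group_index = clusters$labels,
    group_name = clusters$group_names[clusters$labels],
    stringsAsFactors = FALSE
  )
  structure(
    list(
      fpca = fpc, clusters = clusters, assignments = assignments,
      smoothed = smoothed, ids = ids, n_excluded = n_excluded,
      config = config
    ),
    class = "traj_pipeline"
  )
}

#' @export
print.traj_pipeline <- function(x, ...) {
  cat("Engagement trajectory pipeline (", length(x$ids), " participants, ",
      x$n_excluded, " excluded)\n", sep = "")
  print(x$fpca)
  print(x$clusters)
  invisible(x)
}

#' Fit the outcome and membership models for a pipeline run
#'
#' Aligns the participant table with the pipeline's retained rows and fits
#' the trajectory-group outcome model ([group_outcome_model()]) and the
#' baseline membership model ([baseline_predictor_model()]).
#'
#' @param pipeline A `traj_pipeline`.
#' @param participants Participant table containing `participant_id`,
#'   `abstinent` and baseline covariates.
#' @param covariates Optional character vector of candidate covariate names.
#' @param ... Passed to [group_outcome_model()].
#' @return List with `outcome_model` and `membership_model`.
#' @export
run_association <- function(pipeline, participants, covariates = NULL, ...) {
  stopifnot(inherits(pipeline, "traj_pipeline"))
  idx <- match(pipeline$ids, participants$participant_id)
  if (anyNA(idx)) {
    stop("participant table is missing ",
         sum(is.na(idx)), " clustered participant(s)")
  }
  pt <- participants[idx, , drop = FALSE]
  list(
    outcome_model = group_outcome_model(pipeline$clusters, pt,
                                        covariates = covariates, ...),
    membership_model = baseline_predictor_model(pipeline$clusters, pt,
                                                covariates = covariates)
  )
}

#' Write pipeline outputs as CSV reports
#'
#' Writes the group assignment table, a group summary (size, share,
#' persistence and 26 weekly mean log-ins, reproducing the content of a
#' mean-weekly-log-ins trajectory figure in tabular form), and the FPCA
#' bundle.
#'
#' @param pipeline A `traj_pipeline`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_pipeline <- function(pipeline, dir) {
  stopifnot(inherits(pipeline, "traj_pipeline"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(pipeline$assignments,
                   file.path(dir, "assignments.csv"), row.names = FALSE)
  cl <- pipeline$clusters
  summary <- data.frame(
    group = cl$group_names,
    size = cl$group_sizes,
    share = cl$group_sizes / sum(cl$group_sizes),
    persistence_weeks = cl$persistence,
    cl$group_weekly_means
  )
  utils::write.csv(summary, file.path(dir, "group_summary.csv"),
                   row.names = FALSE)
  write_fpca(pipeline$fpca, file.path(dir, "fpca"))
  # audit trail: effective configuration, counts and a content hash
  cfg <- unclass(pipeline$config)
  cfg$subsample_size <- cfg$subsample_size %||% "classical (40 + 2k)"
  yaml::write_yaml(
    list(
      config = cfg,
      config_digest = sum(utf8ToInt(paste(deparse(cfg), collapse = ""))),
      n_clustered = length(pipeline$ids),
      n_excluded = pipeline$n_excluded
    ),
    file.path(dir, "run_info.yaml")
  )
  invisible(dir)
}

#' Write model reports as CSV
#'
#' @param models List from [run_association()].
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_association <- function(models, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(model_report(models$outcome_model),
                   file.path(dir, "outcome_model.csv"), row.names = FALSE)
  utils::write.csv(model_report(models$membership_model),
                   file.path(dir, "membership_model.csv"), row.names = FALSE)
  invisible(dir)
}
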