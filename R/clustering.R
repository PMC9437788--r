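#' Partitioning Around Medoids (PAM)
#'
#' k-medoids clustering with Euclidean dissimilarity: greedy BUILD
#' initialization followed by SWAP steps, each applying the single
#' (medoid, non-medoid) exchange that most decreases total dissimilarity,
#' until no exchange strictly decreases it. Points are labeled by nearest
#' medoid; distance ties go to the lowest medoid index. The algorithm is
#' deterministic.
#'
#' @param points Numeric matrix (rows = points) or vector (1-D points).
#' @param k Number of medoids, `1 <= k <= nrow(points)`.
#' @return List with `medoid_indices` (sorted row indices), `labels`
#'   (1..k, aligned with sorted medoids), `total_dissimilarity`, and `k`.
#' @export
pam_fit <- function(points, k) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (k < 1) stop("'k' must be >= 1")
  if (k > n) stop("'k' (", k, ") exceeds the number of points (", n, ")")
  D <- as.matrix(stats::dist(points))
  med <- pam_core(D, k)
  pam_solution(D, med, k)
}

# BUILD + SWAP on a precomputed distance matrix; returns sorted medoids.
pam_core <- function(D, k) {
  n <- nrow(D)
  med <- unname(which.min(colSums(D)))
  while (length(med) < k) {
    dmin <- row_mins(D[, med, drop = FALSE])
    gain <- colSums(pmax(dmin - D, 0))
    gain[med] <- -Inf
    med <- c(med, unname(which.max(gain)))
  }
  repeat {
    cost <- sum(row_mins(D[, med, drop = FALSE]))
    best <- cost
    best_swap <- NULL
    for (m in med) {
      others <- setdiff(med, m)
      dother <- if (length(others)) row_mins(D[, others, drop = FALSE]) else
        rep(Inf, n)
      for (h in setdiff(seq_len(n), med)) {
        new_cost <- sum(pmin(dother, D[, h]))
        if (new_cost < best - 1e-12) {
          best <- new_cost
          best_swap <- c(m, h)
        }
      }
    }
    if (is.null(best_swap)) break
    med <- c(setdiff(med, best_swap[1]), best_swap[2])
  }
  sort(med)
}

# Assemble labels/objective for a medoid set; ties to lowest medoid index.
pam_solution <- function(D, med, k) {
  dm <- D[, med, drop = FALSE]
  labels <- apply(dm, 1, which.min) # which.min returns first (lowest) index
  list(
    medoid_indices = med,
    labels = as.integer(labels),
    total_dissimilarity = sum(dm[cbind(seq_len(nrow(D)), labels)]),
    k = k
  )
}

#' CLARA: k-medoids for large data by subsampling
#'
#' Runs [pam_fit()] on random subsamples, assigns all points to the
#' subsample medoids, and keeps the solution with the smallest full-data
#' total dissimilarity. Following the classical scheme, the best medoids
#' found so far are forced into each subsequent subsample. With
#' `subsample_size >= n` this reduces exactly to PAM on all points (one
#' pass).
#'
#' @inheritParams pam_fit
#' @param n_subsamples Number of subsamples; default 5.
#' @param subsample_size Points per subsample; default `min(n, 40 + 2 * k)`.
#' @param seed Integer seed for subsample draws (`NULL` uses the current RNG
#'   state).
#' @return As [pam_fit()], with labels/objective computed on all points.
#' @export
clara_fit <- function(points, k, n_subsamples = 5, subsample_size = NULL,
                      seed = NULL) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (k < 1) stop("'k' must be >= 1")
  if (k > n) stop("'k' (", k, ") exceeds the number of points (", n, ")")
  if (is.null(subsample_size)) subsample_size <- min(n, 40 + 2 * k)
  if (subsample_size < k) stop("'subsample_size' must be >= k")
  if (subsample_size >= n) {
    return(pam_fit(points, k))
  }
  with_seed(seed, {
    best <- NULL
    for (s in seq_len(n_subsamples)) {
      forced <- if (is.null(best)) integer(0) else best$medoid_indices
      pool <- setdiff(seq_len(n), forced)
      idx <- sort(c(forced, sample(pool, subsample_size - length(forced))))
      sub <- pam_core(as.matrix(stats::dist(points[idx, , drop = FALSE])), k)
      med <- idx[sub]
      # full-data assignment to these medoids
      dm <- vapply(med, function(m) {
        sqrt(rowSums(sweep(points, 2, points[m, ])^2))
      }, numeric(n))
      obj <- sum(row_mins(dm))
      if (is.null(best) || obj < best$total_dissimilarity - 1e-12) {
        labels <- apply(dm, 1, which.min)
        best <- list(
          medoid_indices = med,
          labels = as.integer(labels),
          total_dissimilarity = obj,
          k = k
        )
      }
    }
    best
  })
}

#' Prediction strength of a k-cluster solution
#'
#' For each random half-split, both halves are clustered with
#' [clara_fit()]; test points are additionally classified to their nearest
#' training-half medoid. For every test cluster with at least two members,
#' the proportion of its member pairs that the training classification
#' co-assigns is computed; the split's prediction strength is the minimum
#' of these proportions, and the returned value is the mean over splits.
#' `k = 1` has prediction strength 1 by definition.
#'
#' @param points Numeric matrix of points (e.g. FPC scores).
#' @param k Number of clusters.
#' @param n_splits Number of random half-splits; default 10.
#' @param seed Integer seed for the splits and subsampling.
#' @param ... Passed to [clara_fit()] (`n_subsamples`, `subsample_size`).
#' @return Prediction strength in \[0, 1\].
#' @export
prediction_strength <- function(points, k, n_splits = 10, seed = NULL, ...) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  if (n < 4) stop("need at least 4 points for a half-split")
  if (k < 1) stop("'k' must be >= 1")
  if (k == 1) return(1)
  with_seed(seed, {
    ps <- vapply(seq_len(n_splits), function(s) {
      perm <- sample.int(n)
      train <- perm[seq_len(n %/% 2)]
      test <- perm[(n %/% 2 + 1):n]
      fit_tr <- clara_fit(points[train, , drop = FALSE], k, ...)
      fit_te <- clara_fit(points[test, , drop = FALSE], k, ...)
      tr_med <- points[train[fit_tr$medoid_indices], , drop = FALSE]
      dtm <- vapply(seq_len(k), function(j) {
        sqrt(rowSums(sweep(points[test, , drop = FALSE], 2, tr_med[j, ])^2))
      }, numeric(length(test)))
      train_class <- apply(dtm, 1, which.min)
      props <- vapply(seq_len(k), function(j) {
        members <- which(fit_te$labels == j)
        m <- length(members)
        if (m < 2) return(NA_real_)
        tab <- table(train_class[members])
        sum(choose(tab, 2)) / choose(m, 2)
      }, numeric(1))
      min(props, na.rm = TRUE)
    }, numeric(1))
    mean(ps)
  })
}

#' Choose the number of trajectory groups
#'
#' Evaluates each candidate `k` by prediction strength, a minimum group
#' size rule, and separation of the group mean trajectories. A `k`
#' qualifies if (a) its prediction strength meets `ps_threshold`, (b) every
#' cluster of the full-data solution contains at least `min_group_frac` of
#' the sample, and (c) when `curves` are supplied and `sep_threshold` is
#' not `NULL`, the separation diagnostic -- the minimum over group pairs of
#' the root-mean-square distance between group mean curves, divided by the
#' pooled within-group SD -- is at least `sep_threshold`. The largest
#' qualifying `k` is chosen (the richest structure that is stable, sizable
#' and separated); if none qualifies, the `k` with maximal prediction
#' strength is returned with a warning.
#'
#' The separation rule makes a judgment call explicit: at the lenient
#' prediction-strength threshold of 0.6, discrete log-in data can support
#' reproducible but meaningless sub-splits of one engagement continuum, so
#' a qualifying solution must also keep its group mean trajectories at
#' least one within-group standard deviation apart. Set
#' `sep_threshold = NULL` to rank on prediction strength and group size
#' alone.
#'
#' @param points Score matrix to cluster.
#' @param k_range Candidate numbers of groups; default `2:6`.
#' @param ps_threshold Minimum prediction strength; default 0.6.
#' @param min_group_frac Minimum group share of the sample; default 0.05.
#' @param n_splits Prediction-strength half-splits; default 10.
#' @param seed Integer seed.
#' @param curves Optional smoothed-trajectory matrix aligned with `points`,
#'   used for the separation diagnostic.
#' @param sep_threshold Minimum separation (in pooled within-group SD
#'   units) for a qualifying solution; default 1. `NULL` disables the rule
#'   (separation is then reported only).
#' @param ... Passed to [clara_fit()].
#' @return List with `k` (chosen), `diagnostics` (data.frame: k, ps,
#'   min_share, separation), and `fits` (the full-data `clara_fit` solution
#'   per candidate k, named by k).
#' @export
select_k <- function(points, k_range = 2:6, ps_threshold = 0.6,
                     min_group_frac = 0.05, n_splits = 10, seed = NULL,
                     curves = NULL, sep_threshold = 1, ...) {
  if (!length(k_range)) stop("'k_range' must be non-empty")
  if (!is.matrix(points)) points <- matrix(points, ncol = 1)
  n <- nrow(points)
  k_range <- sort(unique(as.integer(k_range)))
  fits <- list()
  diag <- data.frame(k = k_range, ps = NA_real_, min_share = NA_real_,
                     separation = NA_real_)
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    fit <- clara_fit(points, k, seed = stage_seed(seed %||% 0, 1000 + k), ...)
    fits[[as.character(k)]] <- fit
    diag$ps[i] <- prediction_strength(points, k, n_splits = n_splits,
                                      seed = stage_seed(seed %||% 0, 2000 + k),
                                      ...)
    diag$min_share[i] <- min(tabulate(fit$labels, k)) / n
    if (!is.null(curves)) {
      diag$separation[i] <- trajectory_separation(curves, fit$labels)
    }
  }
  ok <- diag$ps >= ps_threshold & diag$min_share >= min_group_frac
  if (!is.null(sep_threshold) && !is.null(curves)) {
    ok <- ok & diag$separation >= sep_threshold
  }
  if (any(ok)) {
    k <- max(k_range[ok])
  } else {
    k <- k_range[which.max(diag$ps)]
    warning("no candidate k met the prediction-strength, group-size and ",
            "separation rules; falling back to k = ", k,
            " (maximal prediction strength)")
  }
  list(k = k, diagnostics = diag, fits = fits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Min over group pairs of ||mean curve difference||_2 / pooled within SD.
trajectory_separation <- function(curves, labels) {
  gs <- sort(unique(labels))
  if (length(gs) < 2) return(NA_real_)
  means <- rowsum(curves, labels) / as.vector(table(labels)[as.character(gs)])
  within <- sqrt(mean((curves - means[match(labels, gs), , drop = FALSE])^2))
  if (within == 0) return(Inf)
  pairs <- utils::combn(seq_along(gs), 2)
  dists <- apply(pairs, 2, function(p) {
    sqrt(mean((means[p[1], ] - means[p[2], ])^2))
  })
  min(dists) / within
}

#' Name trajectory groups by engagement persistence
#'
#' A group's persistence is the last week (1-based) in which its mean
#' weekly log-in days is at least 1.0 (0 if never). Groups are ordered by
#' ascending persistence -- ties broken by ascending total mean log-ins,
#' then by original label -- and named `"<persistence>-week users"`.
#'
#' @param labels Cluster labels (1..k) aligned with `daily` rows.
#' @param daily n x 182 daily binary matrix.
#' @return List with `order` (original group indices sorted least to most
#'   persistent), `rank` (per original group, 1 = least persistent),
#'   `names` (per original group), `persistence` (per original group), and
#'   `weekly_means` (k x 26, rows in original label order).
#' @export
name_groups <- function(labels, daily) {
  wk <- weekly_login_summary(daily, labels)
  k <- nrow(wk)
  persistence <- apply(wk, 1, function(v) {
    at_least_one <- which(v >= 1.0)
    if (length(at_least_one)) max(at_least_one) else 0L
  })
  total <- rowSums(wk)
  ord <- order(persistence, total, seq_len(k))
  rank <- match(seq_len(k), ord)
  list(
    order = ord,
    rank = rank,
    names = paste0(persistence, "-week users"),
    persistence = as.integer(persistence),
    weekly_means = wk
  )
}

#' Cluster smoothed trajectories end to end
#'
#' Combines [select_k()] (or a fixed `k`), the full-data [clara_fit()]
#' solution, and persistence-based naming into one trajectory-group
#' solution. Output groups are relabeled in order of engagement
#' persistence, so group 1 is always the least persistent (the natural
#' reference group for outcome models).
#'
#' @param scores FPC score matrix (n x K).
#' @param daily Daily binary matrix aligned with `scores` rows.
#' @param k Fixed number of groups, or `NULL` (default) to choose via
#'   [select_k()].
#' @param k_range,ps_threshold,min_group_frac,n_splits,sep_threshold See
#'   [select_k()].
#' @param seed Integer seed.
#' @param curves Optional smoothed matrix for the separation diagnostic;
#'   defaults to `presmooth(daily)` when `k` is selected automatically.
#' @param ... Passed to [clara_fit()].
#' @return An object of class `traj_clusters`: `k`, `labels` (1 = least
#'   persistent), `medoid_indices`, `total_dissimilarity`,
#'   `prediction_strength`, `group_sizes`, `group_names`, `persistence`,
#'   `group_weekly_means` (k x 26 in persistence order), and `diagnostics`.
#' @export
cluster_trajectories <- function(scores, daily, k = NULL, k_range = 2:6,
                                 ps_threshold = 0.6, min_group_frac = 0.05,
                                 n_splits = 10, seed = NULL, curves = NULL,
                                 sep_threshold = 1, ...) {
  if (!is.matrix(scores)) scores <- matrix(scores, ncol = 1)
  stopifnot(nrow(scores) == nrow(daily))
  diagnostics <- NULL
  if (is.null(k)) {
    if (is.null(curves)) curves <- presmooth(daily)
    sel <- select_k(scores, k_range, ps_threshold, min_group_frac, n_splits,
                    seed = seed, curves = curves,
                    sep_threshold = sep_threshold, ...)
    k <- sel$k
    fit <- sel$fits[[as.character(k)]]
    diagnostics <- sel$diagnostics
    ps <- diagnostics$ps[diagnostics$k == k]
  } else {
    fit <- clara_fit(scores, k, seed = stage_seed(seed %||% 0, 1000 + k), ...)
    ps <- if (nrow(scores) >= 4) {
      prediction_strength(scores, k, n_splits = n_splits,
                          seed = stage_seed(seed %||% 0, 2000 + k), ...)
    } else {
      NA_real_
    }
  }
  nm <- name_groups(fit$labels, daily)
  labels <- nm$rank[fit$labels] # 1 = least persistent
  structure(
    list(
      k = k,
      labels = labels,
      medoid_indices = fit$medoid_indices[nm$order],
      total_dissimilarity = fit$total_dissimilarity,
      prediction_strength = ps,
      group_sizes = tabulate(labels, k),
      group_names = nm$names[nm$order],
      persistence = nm$persistence[nm$order],
      group_weekly_means = nm$weekly_means[nm$order, , drop = FALSE],
      diagnostics = diagnostics
    ),
    class = "traj_clusters"
  )
}

#' @export
print.traj_clusters <- function(x, ...) {
  cat("Trajectory clustering: k =", x$k,
      sprintf("(prediction strength %.3f)\n", x$prediction_strength))
  df <- data.frame(
    group = x$group_names,
    size = x$group_sizes,
    share = sprintf("%.2f%%", 100 * x$group_sizes / sum(x$group_sizes)),
    week1_mean = sprintf("%.2f", x$group_weekly_means[, 1])
  )
  print(df, row.names = FALSE)
  invisible(x)
}
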