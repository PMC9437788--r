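#' Logistic regression with odds-ratio reporting
#'
#' Maximum-likelihood logistic fit (iteratively reweighted least squares via
#' `stats::glm`, relative convergence tolerance 1e-10, at most 100
#' iterations) with Wald standard errors, odds ratios and 95% Wald CIs
#' (`exp(beta +/- 1.96 * SE)`). Errors explicitly on a rank-deficient
#' design (naming the aliased terms) and on complete or quasi-complete
#' separation (non-converged likelihood with coefficient magnitude > 15, or
#' fitted probabilities pinned at 0/1).
#'
#' @param outcome Binary vector (0/1); must contain at least one event and
#'   one non-event.
#' @param design Data frame of named predictors (may have zero columns for
#'   an intercept-only model). Factors are expanded to reference-coded
#'   dummies with the most frequent level as reference.
#' @return An object of class `traj_model` (see [model_report()]).
#' @export
fit_logistic <- function(outcome, design) {
  outcome <- as.numeric(outcome)
  stopifnot(all(outcome %in% c(0, 1)))
  if (sum(outcome) == 0 || sum(outcome) == length(outcome)) {
    stop("outcome must contain at least one event and one non-event")
  }
  design <- prepare_design(design, length(outcome))
  dat <- cbind(.y = outcome, design)
  f <- if (ncol(design)) {
    stats::reformulate(sprintf("`%s`", names(design)), response = ".y")
  } else {
    .y ~ 1
  }
  mm <- stats::model.matrix(f, dat)
  check_full_rank(mm)
  fit <- suppressWarnings(stats::glm(
    f, data = dat, family = stats::binomial(),
    control = stats::glm.control(epsilon = 1e-10, maxit = 100)
  ))
  check_separation(fit)
  build_traj_model(fit, family = "logistic",
                   reference = attr(design, "references"))
}

prepare_design <- function(design, n) {
  if (is.null(design)) design <- data.frame(row.names = seq_len(n))
  if (!is.data.frame(design)) design <- as.data.frame(design)
  if (nrow(design) && nrow(design) != n) {
    stop("design rows (", nrow(design), ") do not match outcome length (", n, ")")
  }
  refs <- character(0)
  for (nm in names(design)) {
    v <- design[[nm]]
    if (is.character(v) || is.factor(v)) {
      v <- as.factor(v)
      ref <- names(which.max(table(v))) # most frequent level as reference
      design[[nm]] <- stats::relevel(v, ref = ref)
      refs[nm] <- ref
    }
  }
  attr(design, "references") <- refs
  design
}

check_full_rank <- function(mm) {
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    bad <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    stop("design is rank deficient; collinear term(s): ",
         paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

check_separation <- function(fit) {
  co <- stats::coef(fit)
  pinned <- any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if ((!fit$converged && max(abs(co)) > 15) ||
      (pinned && max(abs(co)) > 15)) {
    stop("complete or quasi-complete separation detected (diverging coefficients)")
  }
  invisible(TRUE)
}

build_traj_model <- function(fit, family, reference = character(0)) {
  s <- summary(fit)$coefficients
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    term = rownames(s),
    estimate = s[, 1],
    se = s[, 2],
    or = exp(s[, 1]),
    ci_low = exp(s[, 1] - z * s[, 2]),
    ci_high = exp(s[, 1] + z * s[, 2]),
    p = 2 * stats::pnorm(-abs(s[, 1] / s[, 2])),
    row.names = NULL
  )
  ll <- as.numeric(stats::logLik(fit))
  structure(
    list(
      family = family,
      coefficients = tab,
      log_likelihood = ll,
      aic = 2 * attr(stats::logLik(fit), "df") - 2 * ll,
      n_used = stats::nobs(fit),
      reference_levels = reference,
      fit = fit
    ),
    class = "traj_model"
  )
}

#' Baseline-category multinomial logistic regression
#'
#' Maximum-likelihood multinomial logit fit (`nnet::multinom`) with the
#' first factor level of `groups` as the baseline category, reporting
#' per-category odds ratios with Wald 95% CIs. With two categories the
#' coefficients coincide with [fit_logistic()] on the indicator.
#'
#' @param groups Factor (or coercible) of G >= 2 categories; the reference
#'   category must be set as the first level before calling (e.g. the
#'   least-engaged group).
#' @param design Data frame of named predictors.
#' @return A `traj_model`; coefficient terms are prefixed
#'   `"<category>: <term>"`.
#' @export
fit_multinomial <- function(groups, design) {
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) < 2) stop("need at least 2 categories")
  design <- prepare_design(design, length(groups))
  dat <- cbind(.g = groups, design)
  f <- if (ncol(design)) {
    stats::reformulate(sprintf("`%s`", names(design)), response = ".g")
  } else {
    .g ~ 1
  }
  mm <- stats::model.matrix(f, dat)
  check_full_rank(mm)
  cap <- utils::capture.output(
    fit <- nnet::multinom(f, data = dat, trace = FALSE, maxit = 500,
                          reltol = 1e-12, Hess = TRUE)
  )
  co <- stats::coef(fit)
  if (is.null(dim(co))) co <- matrix(co, nrow = 1,
                                     dimnames = list(levels(groups)[2],
                                                     names(co)))
  v <- stats::vcov(fit)
  se <- matrix(sqrt(diag(v)), nrow = nrow(co), byrow = TRUE,
               dimnames = dimnames(co))
  if (max(abs(co)) > 15) {
    stop("complete or quasi-complete separation detected (diverging coefficients)")
  }
  z <- stats::qnorm(0.975)
  tab <- data.frame(
    term = paste0(rep(rownames(co), ncol(co)), ": ",
                  rep(colnames(co), each = nrow(co))),
    estimate = as.vector(co),
    se = as.vector(se),
    row.names = NULL
  )
  tab$or <- exp(tab$estimate)
  tab$ci_low <- exp(tab$estimate - z * tab$se)
  tab$ci_high <- exp(tab$estimate + z * tab$se)
  tab$p <- 2 * stats::pnorm(-abs(tab$estimate / tab$se))
  ll <- -fit$value
  npar <- length(co)
  structure(
    list(
      family = "multinomial",
      coefficients = tab,
      log_likelihood = ll,
      aic = 2 * npar - 2 * ll,
      n_used = nrow(dat),
      reference_levels = c(.response = levels(groups)[1],
                           attr(design, "references")),
      fit = fit
    ),
    class = "traj_model"
  )
}

#' @export
print.traj_model <- function(x, digits = 3, ...) {
  cat(sprintf("%s model (n = %d, logLik = %.3f, AIC = %.3f)\n",
              x$family, x$n_used, x$log_likelihood, x$aic))
  if (length(x$reference_levels)) {
    cat("reference:", paste(names(x$reference_levels), "=",
                            x$reference_levels, collapse = ", "), "\n")
  }
  tab <- x$coefficients
  tab[-1] <- lapply(tab[-1], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Tabular model report
#'
#' @param model A `traj_model`.
#' @return Data frame with term, OR, 95% CI bounds, p-value and the model
#'   AIC, in the style of a trial results table.
#' @export
model_report <- function(model) {
  stopifnot(inherits(model, "traj_model"))
  data.frame(
    term = model$coefficients$term,
    or = model$coefficients$or,
    ci_low = model$coefficients$ci_low,
    ci_high = model$coefficients$ci_high,
    p = model$coefficients$p,
    aic = model$aic
  )
}

#' Univariate covariate screen
#'
#' Fits one single-predictor model per covariate against the response and
#' keeps those with any Wald p-value below `alpha`. Covariates that
#' separate the response perfectly are retained and flagged (their
#' association is maximal, not absent).
#'
#' @param response Binary outcome vector or group factor.
#' @param covariates Data frame of candidate covariates.
#' @param alpha Two-sided significance level; default 0.05.
#' @param family `"logistic"` (binary response) or `"multinomial"`.
#' @return Character vector of retained covariate names, with attribute
#'   `flagged` naming any separating covariates.
#' @export
univariate_screen <- function(response, covariates, alpha = 0.05,
                              family = c("logistic", "multinomial")) {
  family <- match.arg(family)
  if (!length(covariates) || !ncol(as.data.frame(covariates))) {
    out <- character(0)
    attr(out, "flagged") <- character(0)
    return(out)
  }
  covariates <- as.data.frame(covariates)
  keep <- character(0)
  flagged <- character(0)
  for (nm in names(covariates)) {
    p <- tryCatch({
      m <- if (family == "logistic") {
        fit_logistic(response, covariates[nm])
      } else {
        fit_multinomial(response, covariates[nm])
      }
      slope <- m$coefficients[!grepl("\\(Intercept\\)", m$coefficients$term), ]
      min(slope$p)
    }, error = function(e) {
      if (grepl("separation", conditionMessage(e))) {
        flagged <<- c(flagged, nm)
        0 # perfectly predictive: retain
      } else {
        stop(e)
      }
    })
    if (p < alpha) keep <- c(keep, nm)
  }
  attr(keep, "flagged") <- flagged
  keep
}

#' Stepwise covariate selection by AIC with forced terms
#'
#' Starts from the model containing only the forced terms and, at each
#' step, evaluates every single-term addition from `candidates` and every
#' removal of a currently included non-forced term; the move with the
#' lowest AIC is applied, and selection stops when no move strictly lowers
#' the AIC. Ties are broken deterministically: additions before removals,
#' then alphabetical term name. Forced terms are never removed.
#'
#' @param response Binary outcome (logistic) or group factor (multinomial).
#' @param forced Data frame of terms always kept in the model (e.g. the
#'   trajectory-group factor); may be `NULL`.
#' @param candidates Data frame of candidate covariates.
#' @param family `"logistic"` or `"multinomial"`.
#' @return The final fitted `traj_model`, with attribute `selected` naming
#'   the retained candidate covariates.
#' @export
stepwise_aic <- function(response, forced, candidates,
                         family = c("logistic", "multinomial")) {
  family <- match.arg(family)
  n <- length(response)
  forced <- if (is.null(forced)) {
    data.frame(row.names = seq_len(n))[, 0, drop = FALSE]
  } else {
    as.data.frame(forced)
  }
  candidates <- if (is.null(candidates)) {
    data.frame(row.names = seq_len(n))[, 0, drop = FALSE]
  } else {
    as.data.frame(candidates)
  }
  fit_with <- function(sel) {
    design <- cbind(forced, candidates[, sel, drop = FALSE])
    if (family == "logistic") fit_logistic(response, design)
    else fit_multinomial(response, design)
  }
  current <- character(0)
  best_fit <- fit_with(current)
  repeat {
    pool <- sort(setdiff(names(candidates), current))
    moves <- c(
      lapply(pool, function(nm) list(sel = c(current, nm))),
      lapply(sort(current), function(nm) list(sel = setdiff(current, nm)))
    )
    if (!length(moves)) break
    aics <- vapply(moves, function(mv) {
      # separating candidates are unusable, not fatal; anything else propagates
      tryCatch(fit_with(mv$sel)$aic, error = function(e) {
        if (grepl("separation", conditionMessage(e))) Inf else stop(e)
      })
    }, numeric(1))
    if (min(aics) >= best_fit$aic - 1e-9) break
    current <- moves[[which.min(aics)]]$sel
    best_fit <- fit_with(current)
  }
  attr(best_fit, "selected") <- sort(current)
  best_fit
}

#' Trajectory-group effects on the binary outcome
#'
#' Complete-case logistic regression of the outcome on trajectory-group
#' dummies (reference = least-persistent group), with covariates chosen by
#' a univariate screen followed by AIC-stepwise selection; the group terms
#' are forced into the model throughout, so group odds ratios are always
#' reported.
#'
#' @param clusters A `traj_clusters` solution (or an integer label vector
#'   with 1 = least-persistent group).
#' @param participants Data frame aligned with the clustered rows,
#'   containing `abstinent` (0/1, `NA` when missing) and optionally
#'   `missing_outcome`; all other columns except identifiers and
#'   `true_group` are treated as candidate covariates unless `covariates`
#'   is given.
#' @param covariates Optional character vector naming the candidate
#'   covariate columns.
#' @param missing_as_smoker If `TRUE`, missing outcomes are coded 0
#'   (smoking) instead of dropped; default `FALSE` (complete case).
#' @param alpha Univariate screen level; default 0.05.
#' @return The final `traj_model`, with attributes `selected` (covariates
#'   kept by stepwise), `n_dropped` (missing outcomes removed) and
#'   `group_levels`.
#' @export
group_outcome_model <- function(clusters, participants, covariates = NULL,
                                missing_as_smoker = FALSE, alpha = 0.05) {
  labels <- if (inherits(clusters, "traj_clusters")) clusters$labels else clusters
  group_names <- if (inherits(clusters, "traj_clusters")) {
    clusters$group_names
  } else {
    paste0("group", sort(unique(labels)))
  }
  stopifnot(length(labels) == nrow(participants))
  if (!"abstinent" %in% names(participants)) {
    stop("'participants' must contain an 'abstinent' outcome column")
  }
  y <- participants$abstinent
  if (missing_as_smoker) {
    y[is.na(y)] <- 0
    keep <- rep(TRUE, length(y))
  } else {
    keep <- !is.na(y)
  }
  n_dropped <- sum(!keep)
  y <- y[keep]
  grp <- factor(group_names[labels[keep]], levels = group_names)
  covs <- candidate_covariates(participants[keep, , drop = FALSE], covariates)
  if (anyNA(covs)) stop("candidate covariates contain missing values")
  if (any(tabulate(labels[keep], length(group_names)) == 0)) {
    stop("a trajectory group has no retained outcomes")
  }
  cand <- univariate_screen(y, covs, alpha = alpha, family = "logistic")
  fit <- stepwise_aic(y, data.frame(trajectory_group = grp),
                      covs[, cand, drop = FALSE], family = "logistic")
  attr(fit, "n_dropped") <- n_dropped
  attr(fit, "group_levels") <- group_names
  attr(fit, "screened") <- as.character(cand)
  fit
}

candidate_covariates <- function(participants, covariates) {
  if (is.null(covariates)) {
    drop <- c("participant_id", "id", "true_group", "abstinent",
              "missing_outcome")
    covariates <- setdiff(names(participants), drop)
  }
  participants[, covariates, drop = FALSE]
}

#' Baseline predictors of trajectory-group membership
#'
#' Models group membership from baseline covariates: a univariate screen at
#' `alpha`, then AIC-stepwise selection, fitting a baseline-category
#' multinomial model when there are three or more groups and an ordinary
#' logistic model when there are two. The least-persistent group is the
#' reference.
#'
#' @inheritParams group_outcome_model
#' @return The final `traj_model` with attribute `selected`.
#' @export
baseline_predictor_model <- function(clusters, participants,
                                     covariates = NULL, alpha = 0.05) {
  labels <- if (inherits(clusters, "traj_clusters")) clusters$labels else clusters
  group_names <- if (inherits(clusters, "traj_clusters")) {
    clusters$group_names
  } else {
    paste0("group", sort(unique(labels)))
  }
  stopifnot(length(labels) == nrow(participants))
  grp <- factor(group_names[labels], levels = group_names)
  covs <- candidate_covariates(participants, covariates)
  if (anyNA(covs)) stop("candidate covariates contain missing values")
  if (nlevels(grp) >= 3) {
    cand <- univariate_screen(grp, covs, alpha = alpha, family = "multinomial")
    fit <- stepwise_aic(grp, NULL, covs[, cand, drop = FALSE],
                        family = "multinomial")
  } else {
    y <- as.integer(grp == levels(grp)[2])
    cand <- univariate_screen(y, covs, alpha = alpha, family = "logistic")
    fit <- stepwise_aic(y, NULL, covs[, cand, drop = FALSE],
                        family = "logistic")
  }
  attr(fit, "group_levels") <- group_names
  attr(fit, "screened") <- as.character(cand)
  fit
}
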