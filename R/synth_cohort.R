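#' Trajectory archetype
#'
#' An archetype describes one planted engagement pattern: the expected number
#' of log-in days per week over 26 weeks, the share of the cohort following
#' the pattern, and the group's marginal probability of the distal binary
#' outcome (30-day point-prevalence abstinence at 12 months).
#'
#' @param name Label for the archetype (e.g. `"1-week"`).
#' @param weekly_mean_logins Numeric vector of length 26; expected log-in
#'   days per week, each in \[0, 7\].
#' @param mixture_weight Share of the cohort in this group, in \[0, 1\].
#' @param abstinence_prob Marginal outcome probability, in \[0, 1\].
#' @param covariate_effects Named numeric vector of log-odds shifts on the
#'   outcome per unit of the named covariate. Default empty, so group
#'   outcome rates are exactly the planted marginals.
#' @return An object of class `archetype`.
#' @export
archetype <- function(name, weekly_mean_logins, mixture_weight,
                      abstinence_prob, covariate_effects = numeric(0)) {
  stopifnot(is.character(name), length(name) == 1)
  weekly_mean_logins <- as.numeric(weekly_mean_logins)
  if (length(weekly_mean_logins) != 26) {
    stop("'weekly_mean_logins' must have length 26 (one value per week)")
  }
  if (any(weekly_mean_logins < 0 | weekly_mean_logins > 7)) {
    stop("weekly mean log-in days must lie in [0, 7]")
  }
  stopifnot(
    mixture_weight >= 0, mixture_weight <= 1,
    abstinence_prob >= 0, abstinence_prob <= 1
  )
  if (length(covariate_effects) && is.null(names(covariate_effects))) {
    stop("'covariate_effects' must be a named numeric vector")
  }
  structure(
    list(
      name = name,
      weekly_mean_logins = weekly_mean_logins,
      mixture_weight = mixture_weight,
      abstinence_prob = abstinence_prob,
      covariate_effects = covariate_effects
    ),
    class = "archetype"
  )
}

# Unprinted tail weeks: geometric decay (ratio 0.5) from the last specified
# weekly mean, capped at 0.9 so the tail stays strictly below one log-in day
# per week, and floored at 0.1.
decay_tail <- function(last, len, ratio = 0.5, cap = 0.9, floor = 0.1) {
  out <- numeric(len)
  v <- last
  for (i in seq_len(len)) {
    v <- min(cap, v * ratio)
    out[i] <- max(floor, v)
  }
  out
}

#' Preset archetype libraries
#'
#' Returns the planted archetypes for the two study-arm presets. The
#' `"icanquit"` preset has three groups -- brief users who log in about
#' 2 days in week 1 and almost never after, 4-week users starting at
#' 4.6 days/week and tapering through week 4, and persistent users who stay
#' above 5 days/week for 5 weeks then taper to about 2 days/week held
#' through week 26 -- mixed 57.06/28.34/14.59% with outcome probabilities
#' 0.23/0.30/0.56. The `"quitguide"` preset has two groups (week-1 means
#' 1.4 and 2.8 days) mixed 65.32/34.68% with outcome probabilities
#' 0.21/0.23.
#'
#' @param arm_label `"icanquit"` or `"quitguide"` (an `"-like"` suffix and
#'   any letter case are accepted).
#' @return A list of [archetype] objects whose mixture weights sum to 1.
#' @export
archetype_library <- function(arm_label) {
  stopifnot(is.character(arm_label), length(arm_label) == 1)
  arm <- sub("-like$", "", tolower(arm_label))
  if (arm == "icanquit") {
    w <- c(0.5706, 0.2834, 0.1459) # printed shares sum to 0.9999; normalize
    w <- w / sum(w)
    list(
      archetype("1-week", c(2.0, decay_tail(2.0, 25)), w[1], 0.23),
      archetype("4-week", c(4.6, 3.1, 2.0, 1.2, decay_tail(1.2, 22)), w[2], 0.30),
      archetype(
        "26-week",
        c(
          seq(5.4, 5.0, length.out = 5),          # weeks 1-5
          seq(4.7, 3.1, length.out = 5),          # weeks 6-10
          seq(3.1, 2.0, length.out = 8)[-1],      # weeks 11-17, taper to 2
          rep(2.0, 9)                             # weeks 18-26
        ),
        w[3], 0.56
      )
    )
  } else if (arm == "quitguide") {
    list(
      archetype("1-week", c(1.4, decay_tail(1.4, 25)), 0.6532, 0.21),
      archetype("3-week", c(2.8, 1.7, 1.1, decay_tail(1.1, 23)), 0.3468, 0.23)
    )
  } else {
    stop("unknown arm label '", arm_label,
         "'; expected \"icanquit\" or \"quitguide\"")
  }
}

#' Default baseline covariate distributions
#'
#' Binary prevalences and continuous mean/SD pairs loosely matching a large
#' adult smoking-cessation trial population: 70% female, 36% racial/ethnic
#' minority, 40% high-school-or-less education, 75% smoking more than half
#' a pack per day, age 37.8 (SD 10.8) years.
#'
#' @return A list with elements `binary` (named prevalences) and
#'   `continuous` (named list of `c(mean, sd)`).
#' @export
default_covariate_spec <- function() {
  list(
    binary = c(
      female = 0.7028,
      minority = 0.3572,
      hs_or_less = 0.4046,
      heavy_smoker = 0.7454
    ),
    continuous = list(age = c(mean = 37.8, sd = 10.8))
  )
}

#' Cohort simulation configuration
#'
#' @param n Number of participants (>= 0).
#' @param seed Integer seed; the cohort is fully reproducible from it.
#' @param arm_label Free-text label stored with the cohort.
#' @param archetypes List of [archetype] objects; mixture weights must sum
#'   to 1 (tolerance 1e-9).
#' @param covariate_spec Baseline covariate distributions, as from
#'   [default_covariate_spec()].
#' @param missing_rate Probability an outcome is missing completely at
#'   random. Default 0; 0.12 mirrors an 88% retention rate.
#' @param day_persistence First-order within-participant day-to-day
#'   correlation of log-in indicators, in \[0, 1). Default 0 (independent
#'   Bernoulli days).
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n, seed, arm_label = "custom", archetypes,
                          covariate_spec = default_covariate_spec(),
                          missing_rate = 0, day_persistence = 0) {
  stopifnot(
    is.numeric(n), length(n) == 1, n >= 0, n == floor(n),
    is.numeric(seed), length(seed) == 1,
    missing_rate >= 0, missing_rate <= 1,
    day_persistence >= 0, day_persistence < 1
  )
  if (!length(archetypes)) stop("'archetypes' must be a non-empty list")
  if (!all(vapply(archetypes, inherits, logical(1), "archetype"))) {
    stop("'archetypes' must be a list of archetype objects")
  }
  w <- vapply(archetypes, `[[`, numeric(1), "mixture_weight")
  if (abs(sum(w) - 1) > 1e-9) {
    stop("mixture weights must sum to 1 (got ", format(sum(w), digits = 12), ")")
  }
  structure(
    list(
      n = as.integer(n), seed = as.integer(seed), arm_label = arm_label,
      archetypes = archetypes, covariate_spec = covariate_spec,
      missing_rate = missing_rate, day_persistence = day_persistence
    ),
    class = "cohort_config"
  )
}

#' Preset cohort configurations
#'
#' Convenience wrapper combining [archetype_library()] with the arm sample
#' sizes used throughout the package examples (1069 for `"icanquit"`, 1064
#' for `"quitguide"`).
#'
#' @param arm_label Passed to [archetype_library()].
#' @param seed Integer seed.
#' @param n Cohort size; defaults to the preset arm size.
#' @param ... Further arguments passed to [cohort_config()].
#' @return A `cohort_config`.
#' @export
preset_config <- function(arm_label, seed, n = NULL, ...) {
  arch <- archetype_library(arm_label)
  if (is.null(n)) {
    n <- if (length(arch) == 3) 1069L else 1064L
  }
  cohort_config(n = n, seed = seed, arm_label = arm_label,
                archetypes = arch, ...)
}

#' Sample one participant's 182-day log-in indicator series
#'
#' Day `d` (0-based) belongs to week `floor(d / 7)`; its log-in indicator is
#' Bernoulli with success probability `weekly_mean_logins[week] / 7`, so the
#' expected week sum equals the archetype's weekly mean. With
#' `day_persistence > 0`, consecutive days follow a two-state Markov chain
#' with the same marginal probabilities and lag-1 correlation
#' `day_persistence`.
#'
#' @param arch An [archetype].
#' @param day_persistence Lag-1 correlation in \[0, 1); default 0.
#' @return Integer vector of 182 zeros/ones.
#' @export
sample_daily_logins <- function(arch, day_persistence = 0) {
  stopifnot(inherits(arch, "archetype"))
  p <- rep(arch$weekly_mean_logins / 7, each = 7)
  if (day_persistence == 0) {
    return(stats::rbinom(182L, 1L, p))
  }
  rho <- day_persistence
  x <- integer(182L)
  x[1] <- stats::rbinom(1L, 1L, p[1])
  for (d in 2:182) {
    pd <- if (x[d - 1] == 1) p[d] + rho * (1 - p[d]) else p[d] * (1 - rho)
    x[d] <- stats::rbinom(1L, 1L, min(1, max(0, pd)))
  }
  x
}

#' Generate a synthetic engagement cohort
#'
#' Draws each participant's trajectory group from the configured mixture,
#' simulates 182 daily log-in indicators from the group archetype, draws
#' baseline covariates from `covariate_spec`, and draws the binary outcome
#' with `logit(p) = logit(abstinence_prob) + sum(covariate_effects * x)`.
#' Identical configurations (including seed) give identical cohorts.
#'
#' @param config A [cohort_config].
#' @return An object of class `cohort`: a list with `participants` (a
#'   data.frame of id, true_group, covariates, abstinent, missing_outcome),
#'   `logins` (an n x 182 binary matrix, row names = participant ids), and
#'   the `config`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  n <- config$n
  arch <- config$archetypes
  ids <- sprintf("P%04d", seq_len(n))
  with_seed(config$seed, {
    w <- vapply(arch, `[[`, numeric(1), "mixture_weight")
    grp <- if (n > 0) {
      sample(seq_along(arch), n, replace = TRUE, prob = w)
    } else {
      integer(0)
    }
    logins <- matrix(0L, n, 182L, dimnames = list(ids, paste0("d", 0:181)))
    for (i in seq_len(n)) {
      logins[i, ] <- sample_daily_logins(arch[[grp[i]]], config$day_persistence)
    }
    covs <- draw_covariates(n, config$covariate_spec)
    eta <- vapply(seq_len(n), function(i) {
      a <- arch[[grp[i]]]
      e <- stats::qlogis(a$abstinence_prob)
      for (nm in names(a$covariate_effects)) {
        if (!nm %in% names(covs)) {
          stop("covariate effect on '", nm, "' has no matching covariate")
        }
        e <- e + a$covariate_effects[[nm]] * covs[[nm]][i]
      }
      e
    }, numeric(1))
    abstinent <- if (n > 0) stats::rbinom(n, 1L, stats::plogis(eta)) else integer(0)
    missing_outcome <- if (config$missing_rate > 0 && n > 0) {
      stats::rbinom(n, 1L, config$missing_rate) == 1L
    } else {
      rep(FALSE, n)
    }
    abstinent[missing_outcome] <- NA_integer_
    participants <- data.frame(
      participant_id = ids,
      true_group = vapply(arch, `[[`, character(1), "name")[grp],
      covs,
      abstinent = abstinent,
      missing_outcome = missing_outcome,
      stringsAsFactors = FALSE
    )
    structure(
      list(participants = participants, logins = logins, config = config),
      class = "cohort"
    )
  })
}

draw_covariates <- function(n, spec) {
  out <- list()
  for (nm in names(spec$binary)) {
    out[[nm]] <- stats::rbinom(n, 1L, spec$binary[[nm]])
  }
  for (nm in names(spec$continuous)) {
    par <- spec$continuous[[nm]]
    out[[nm]] <- stats::rnorm(n, par[["mean"]], par[["sd"]])
  }
  if (!length(out)) return(data.frame(row.names = seq_len(n))[, 0, drop = FALSE])
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' @export
print.cohort <- function(x, ...) {
  cat("Synthetic engagement cohort:", nrow(x$participants), "participants,",
      length(x$config$archetypes), "planted groups (arm:",
      x$config$arm_label, ")\n")
  print(table(x$participants$true_group))
  invisible(x)
}

#' Write a cohort to CSV files
#'
#' Writes `events.csv` -- one row `(participant_id, day_index)` per day with
#' at least one log-in, 0-based from randomization -- and
#' `participants.csv` with the participant table.
#'
#' @param cohort A `cohort`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(cohort$logins == 1L, arr.ind = TRUE)
  events <- data.frame(
    participant_id = rownames(cohort$logins)[idx[, 1]],
    day_index = idx[, 2] - 1L
  )
  events <- events[order(events$participant_id, events$day_index), ]
  ev_path <- file.path(dir, "events.csv")
  pt_path <- file.path(dir, "participants.csv")
  utils::write.csv(events, ev_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(cohort$participants, pt_path, row.names = FALSE, quote = FALSE)
  invisible(c(events = ev_path, participants = pt_path))
}

#' Read or write a cohort configuration as YAML
#'
#' The file stores `n`, `seed`, `arm_label` and either an arm preset (via
#' `preset: true`) or explicit archetypes (name, weekly_mean_logins, weight,
#' abstinence_prob).
#'
#' @param path File path.
#' @return For `read_cohort_config`, a `cohort_config`.
#' @export
read_cohort_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (isTRUE(y$preset)) {
    return(preset_config(y$arm_label, seed = y$seed, n = y$n))
  }
  arch <- lapply(y$archetypes, function(a) {
    archetype(a$name, as.numeric(a$weekly_mean_logins), a$weight,
              a$abstinence_prob)
  })
  cohort_config(n = y$n, seed = y$seed,
                arm_label = if (is.null(y$arm_label)) "custom" else y$arm_label,
                archetypes = arch)
}

#' @rdname read_cohort_config
#' @param config A `cohort_config` to serialize.
#' @export
write_cohort_config <- function(config, path) {
  stopifnot(inherits(config, "cohort_config"))
  y <- list(
    n = config$n, seed = config$seed, arm_label = config$arm_label,
    archetypes = lapply(config$archetypes, function(a) {
      list(name = a$name, weekly_mean_logins = a$weekly_mean_logins,
           weight = a$mixture_weight, abstinence_prob = a$abstinence_prob)
    })
  )
  yaml::write_yaml(y, path)
  invisible(path)
}
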