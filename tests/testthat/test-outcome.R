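test_that("logistic fits match the 2x2 closed form and Bernoulli MLE", {
  # 56/100 vs 23/100 events: OR = (56*77)/(44*23)
  y <- c(rep(1, 23), rep(0, 77), rep(1, 56), rep(0, 44))
  g <- rep(c(0, 1), each = 100)
  fit <- fit_logistic(y, data.frame(groupB = g))
  or_closed <- (56 * 77) / (44 * 23)
  row <- fit$coefficients[fit$coefficients$term == "groupB", ]
  expect_equal(row$or, or_closed, tolerance = 1e-6)
  expect_equal(row$or, exp(row$estimate), tolerance = 1e-12)
  expect_true(row$ci_low < row$or && row$or < row$ci_high)

  # equal rates: OR exactly 1
  y2 <- rep(c(1, 0, 1, 0), each = 50)
  fit2 <- fit_logistic(y2, data.frame(groupB = rep(c(0, 1), each = 100)))
  expect_equal(fit2$coefficients$or[2], 1, tolerance = 1e-10)

  # intercept-only closed form: 25 events in 100
  y3 <- c(rep(1, 25), rep(0, 75))
  fit3 <- fit_logistic(y3, data.frame(row.names = 1:100))
  expect_equal(fit3$coefficients$estimate[1], log(25 / 75), tolerance = 1e-9)
  expect_equal(fit3$log_likelihood, 25 * log(0.25) + 75 * log(0.75),
               tolerance = 1e-9)
  expect_equal(fit3$aic, 2 * 1 - 2 * fit3$log_likelihood, tolerance = 1e-9)

  expect_error(fit_logistic(rep(1, 10), data.frame(x = rnorm(10))),
               "at least one event")
})

test_that("logistic fits match 2x2 closed forms on random contingency tables", {
  set.seed(30)
  for (rep in 1:5) {
    a <- sample(5:40, 1); b <- sample(5:40, 1)
    c_ <- sample(5:40, 1); d <- sample(5:40, 1)
    y <- c(rep(1, a), rep(0, b), rep(1, c_), rep(0, d))
    x <- c(rep(0, a + b), rep(1, c_ + d))
    fit <- fit_logistic(y, data.frame(x = x))
    expect_equal(fit$coefficients$or[2], (c_ * b) / (d * a), tolerance = 1e-6)
  }
})

test_that("separation and rank deficiency raise explicit errors", {
  set.seed(31)
  y <- rbinom(60, 1, 0.5)
  expect_error(fit_logistic(y, data.frame(x = y)), "separation")
  x <- rnorm(60)
  expect_error(fit_logistic(y, data.frame(x = x, x2 = 2 * x)),
               "rank deficient.*x2")
})

test_that("multinomial fits reduce to logistic at G=2 and recover planted effects", {
  set.seed(32)
  x <- rnorm(400)
  y <- rbinom(400, 1, plogis(-0.5 + 0.8 * x))
  lg <- fit_logistic(y, data.frame(x = x))
  mn <- fit_multinomial(factor(y), data.frame(x = x))
  expect_equal(mn$coefficients$estimate, lg$coefficients$estimate,
               tolerance = 1e-6)
  expect_equal(mn$log_likelihood, lg$log_likelihood, tolerance = 1e-6)

  # planted ln(2) shift on category C membership, null on B
  set.seed(33)
  n <- 50000
  xb <- rbinom(n, 1, 0.5)
  eta <- cbind(0, 0.2 + 0 * xb, -0.4 + log(2) * xb)
  pr <- exp(eta) / rowSums(exp(eta))
  cum <- t(apply(pr, 1, cumsum))
  u <- runif(n)
  g <- factor(c("A", "B", "C")[1L + (u > cum[, 1]) + (u > cum[, 2])],
              levels = c("A", "B", "C"))
  fit <- fit_multinomial(g, data.frame(xb = xb))
  or_c <- fit$coefficients$or[fit$coefficients$term == "C: xb"]
  or_b <- fit$coefficients$or[fit$coefficients$term == "B: xb"]
  expect_gt(or_c, 1.8)
  expect_lt(or_c, 2.2)
  expect_gt(or_b, 0.9)
  expect_lt(or_b, 1.1)
})

test_that("univariate screening calibrates to the nominal level on noise", {
  set.seed(34)
  n <- 5000
  y <- rbinom(n, 1, 0.3)
  noise <- as.data.frame(matrix(rnorm(n * 40), n,
                                dimnames = list(NULL, paste0("z", 1:40))))
  kept <- univariate_screen(y, noise, alpha = 0.05)
  # expected 2 retained; allow 3 binomial SE above
  expect_lte(length(kept), ceiling(40 * 0.05 + 3 * sqrt(40 * 0.05 * 0.95)))

  # perfectly predictive covariate is retained and flagged
  kept2 <- univariate_screen(y, data.frame(copy = y, z = rnorm(n)))
  expect_true("copy" %in% kept2)
  expect_equal(attr(kept2, "flagged"), "copy")

  empty <- univariate_screen(y, data.frame(row.names = seq_len(n)))
  expect_length(empty, 0)
})

test_that("stepwise AIC keeps true effects, drops noise, never beats the forced model", {
  set.seed(35)
  n <- 5000
  grp <- factor(sample(c("lo", "hi"), n, replace = TRUE), levels = c("lo", "hi"))
  x_true <- rbinom(n, 1, 0.5)
  noise <- as.data.frame(matrix(rnorm(n * 5), n,
                                dimnames = list(NULL, paste0("z", 1:5))))
  y <- rbinom(n, 1, plogis(-1 + 0.5 * (grp == "hi") + log(2) * x_true))
  cand <- cbind(data.frame(x_true = x_true), noise)
  forced <- data.frame(grp = grp)
  fit <- stepwise_aic(y, forced, cand, family = "logistic")
  expect_true("x_true" %in% attr(fit, "selected"))
  forced_only <- fit_logistic(y, forced)
  expect_lte(fit$aic, forced_only$aic)
  # forced terms survive selection
  expect_true(any(grepl("grp", fit$coefficients$term)))

  # all-noise candidates: selection usually stops at the forced model
  set.seed(36)
  y0 <- rbinom(n, 1, 0.3)
  fit0 <- stepwise_aic(y0, forced, noise, family = "logistic")
  expect_lte(length(attr(fit0, "selected")), 2)

  expect_error(
    stepwise_aic(y, forced, data.frame(x_true = x_true, x_dup = x_true),
                 family = "logistic"),
    "rank deficient"
  )
})

test_that("group outcome model uses the least-engaged group as reference", {
  co <- generate_cohort(preset_config("icanquit", seed = 2))
  truth <- match(co$participants$true_group, c("1-week", "4-week", "26-week"))
  fit <- group_outcome_model(truth, co$participants)
  # reference: smallest-persistence group absent from the terms
  terms <- fit$coefficients$term
  expect_false(any(grepl("group1", terms)))
  or3 <- fit$coefficients$or[grepl("group3", terms)]
  ci <- fit$coefficients[grepl("group3", terms), c("ci_low", "ci_high")]
  # unadjusted closed form from planted rates 0.56 vs 0.23
  or_closed <- (0.56 * 0.77) / (0.44 * 0.23)
  expect_gt(or_closed, ci$ci_low)
  expect_lt(or_closed, ci$ci_high)

  # planted equal rates: group ORs compatible with 1
  arches <- lapply(archetype_library("icanquit"), function(a) {
    archetype(a$name, a$weekly_mean_logins, a$mixture_weight, 0.30)
  })
  co0 <- generate_cohort(cohort_config(1069, 3, archetypes = arches))
  truth0 <- match(co0$participants$true_group, c("1-week", "4-week", "26-week"))
  fit0 <- group_outcome_model(truth0, co0$participants)
  rows <- grepl("group[23]", fit0$coefficients$term)
  expect_true(all(fit0$coefficients$ci_low[rows] < 1 &
                    fit0$coefficients$ci_high[rows] > 1))
})

test_that("missing outcomes are dropped (or coded as smokers on request)", {
  co <- generate_cohort(preset_config("icanquit", seed = 4, n = 1500,
                                      missing_rate = 0.12))
  truth <- match(co$participants$true_group, c("1-week", "4-week", "26-week"))
  fit_cc <- group_outcome_model(truth, co$participants)
  n_miss <- sum(co$participants$missing_outcome)
  expect_equal(attr(fit_cc, "n_dropped"), n_miss)
  expect_equal(fit_cc$n_used, 1500 - n_miss)
  fit_ms <- group_outcome_model(truth, co$participants,
                                missing_as_smoker = TRUE)
  expect_equal(fit_ms$n_used, 1500)
})

test_that("membership models dispatch by group count and recover planted effects", {
  # two groups route to logistic
  co2 <- generate_cohort(preset_config("quitguide", seed = 5, n = 800))
  truth2 <- match(co2$participants$true_group, c("1-week", "3-week"))
  fit2 <- baseline_predictor_model(truth2, co2$participants)
  expect_equal(fit2$family, "logistic")

  # planted ln(1.5) shift of group-3 membership odds per covariate unit
  set.seed(37)
  n <- 10000
  x <- rbinom(n, 1, 0.5)
  eta <- cbind(0, -0.7, -1.0 + log(1.5) * x)
  pr <- exp(eta) / rowSums(exp(eta))
  cum <- t(apply(pr, 1, cumsum))
  u <- runif(n)
  g <- 1L + (u > cum[, 1]) + (u > cum[, 2])
  pt <- data.frame(participant_id = seq_len(n), x = x,
                   abstinent = rbinom(n, 1, 0.3),
                   missing_outcome = FALSE)
  fit3 <- baseline_predictor_model(g, pt, covariates = "x")
  expect_equal(fit3$family, "multinomial")
  or <- fit3$coefficients$or[fit3$coefficients$term == "group3: x"]
  expect_gt(or, 1.35)
  expect_lt(or, 1.65)
})

test_that("model reports expose OR, CI, p and AIC columns", {
  set.seed(38)
  y <- rbinom(200, 1, 0.4)
  fit <- fit_logistic(y, data.frame(x = rnorm(200)))
  rep <- model_report(fit)
  expect_named(rep, c("term", "or", "ci_low", "ci_high", "p", "aic"))
  expect_true(all(rep$ci_low <= rep$or & rep$or <= rep$ci_high))
})
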