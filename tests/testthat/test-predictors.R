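# Local risk models: death counting, logistic regression, classification
# trees, and severity-score customization.

test_that("death counting is the mortality rate among the top-N neighbors", {
  ranking <- simpredict:::make_ranking("idx", c("a", "b", "c", "d"),
                                       c(0.9, 0.8, 0.7, 0.6))
  outc <- c(a = 1L, b = 0L, c = 1L, d = 0L)
  expect_equal(death_count_risk(ranking, outc, 3)$risk, 2 / 3)
  expect_equal(death_count_risk(ranking, c(a = 0L, b = 0L, c = 0L, d = 0L),
                                4)$risk, 0)
  expect_error(death_count_risk(ranking, outc, 5), "exceeds")

  # oracle: direct slice + mean on a random 500-patient ranking
  with_seed_test(3, {
    ids <- sprintf("n%03d", 1:500)
    vals <- runif(500)
    y <- setNames(rbinom(500, 1, 0.3), ids)
    rk <- simpredict:::make_ranking("idx", ids, vals)
    top100 <- ids[order(-vals, ids)][1:100]
    expect_equal(death_count_risk(rk, y, 100)$risk, mean(y[top100]))
  })
})

test_that("local logistic regression recovers known generating coefficients", {
  cohort <- two_feature_cohort(5000, seed = 21)
  fit <- fit_local_logistic(cohort)
  expect_true(fit$converged)
  co <- fit$coefficients
  expect_lt(abs(co[["(Intercept)"]] - (-1)), 0.15)
  expect_lt(abs(co[["x1"]] - 1), 0.15)
  expect_lt(abs(co[["x2"]] - (-0.5)), 0.15)

  # independent route: glm agrees with the unpenalized IRLS fit
  strict <- fit_local_logistic(cohort, ridge = 0)
  ref <- glm(died30 ~ x1 + x2, data = cohort$data, family = binomial())
  expect_equal(unname(strict$coefficients), unname(coef(ref)),
               tolerance = 1e-6)
  # the default tiny ridge moves coefficients imperceptibly
  expect_equal(unname(fit$coefficients), unname(coef(ref)), tolerance = 1e-4)
})

test_that("logistic prediction is the inverse-logit of the linear score", {
  cohort <- two_feature_cohort(200, seed = 4)
  fit <- fit_local_logistic(cohort)
  fit$coefficients[] <- c(-1, 1, -0.5)
  newpt <- cohort_subset(cohort, 1)
  newpt$data$x1 <- 0.6
  newpt$data$x2 <- 0.8
  expect_equal(predict(fit, newpt), plogis(-1 + 0.6 - 0.4))

  fit$coefficients[] <- 0
  expect_equal(unname(predict(fit, cohort)), rep(0.5, 200))
})

test_that("single-class neighborhoods are rejected; absent levels warn and map to reference", {
  cohort <- random_cohort(300, seed = 8)
  dead <- cohort_subset(cohort, outcomes(cohort) == 1)
  expect_error(fit_local_logistic(dead), "single outcome class")
  expect_error(fit_local_tree(dead), "single outcome class")

  # neighborhood without CSRU patients, but CSRU exists globally
  sub <- cohort_subset(cohort, cohort$data$service != "CSRU")
  full_levels <- list(service = c("CCU", "CSRU", "MICU", "SICU"),
                      vasopressor = c("no", "yes"))
  expect_warning(fit <- fit_local_logistic(sub, full_levels = full_levels),
                 "CSRU.*absent")
  expect_error(
    suppressWarnings(fit_local_logistic(sub, full_levels = full_levels,
                                        strict = TRUE)),
    "absent")
  # a declared-but-absent CSRU patient is scored exactly like a reference
  # (CCU) patient: its dummy column existed but earned coefficient 0
  pt <- cohort_subset(cohort, 1)
  pt$data$service <- "CSRU"
  ref <- cohort_subset(cohort, 1)
  ref$data$service <- "CCU"
  expect_equal(predict(fit, pt), predict(fit, ref))
  # a label never declared anywhere maps to the reference with a warning
  novel <- cohort_subset(cohort, 1)
  novel$data$service <- "step-down"
  expect_warning(risk_novel <- predict(fit, novel),
                 "outside the training levels")
  expect_equal(risk_novel, predict(fit, ref))
})

test_that("trees separate a perfectly separable outcome and smooth leaf risks", {
  with_seed_test(31, {
    n <- 2000
    x <- rnorm(n)
    cohort <- new_cohort(
      data.frame(patient_id = sprintf("t%05d", 1:n), x1 = x, x2 = rnorm(n),
                 died30 = as.integer(x > 0)),
      cohort_schema(c(x1 = "continuous", x2 = "continuous"),
                    outcome_column = "died30", id_column = "patient_id")
    )
    fit <- fit_local_tree(cohort)
    expect_equal(auroc(predict(fit, cohort), outcomes(cohort)), 1)
  })

  # a pure leaf of 10 deaths reports the Laplace-smoothed risk 11/12
  leafy <- new_cohort(
    data.frame(patient_id = sprintf("l%02d", 1:40),
               x1 = rep(c(0, 1), c(30, 10)), x2 = 0,
               died30 = rep(c(0L, 1L), c(30, 10))),
    cohort_schema(c(x1 = "continuous", x2 = "continuous"),
                  outcome_column = "died30", id_column = "patient_id")
  )
  fit <- fit_local_tree(leafy, min_leaf = 10)
  pt <- cohort_subset(leafy, 40)
  expect_equal(predict(fit, pt), 11 / 12)
  raw <- fit_local_tree(leafy, min_leaf = 10, laplace = FALSE)
  expect_equal(predict(raw, pt), 1)
})

test_that("the first tree split lands on the known risk-change threshold", {
  with_seed_test(17, {
    n <- 4000
    x <- runif(n)
    y <- rbinom(n, 1, ifelse(x > 0.5, 0.8, 0.1))
    cohort <- new_cohort(
      data.frame(patient_id = sprintf("s%05d", 1:n), x1 = x, x2 = runif(n),
                 died30 = y),
      cohort_schema(c(x1 = "continuous", x2 = "continuous"),
                    outcome_column = "died30", id_column = "patient_id")
    )
    fit <- fit_local_tree(cohort)
    split_row <- fit$rpart$splits[1, ]
    expect_lt(abs(split_row[["index"]] - 0.5), 0.05)

    # oracle: exhaustive scan of split points for the best Gini reduction
    gini_split <- function(threshold) {
      left <- y[x <= threshold]; right <- y[x > threshold]
      imp <- function(v) {
        if (!length(v)) return(0)
        p <- mean(v); length(v) * 2 * p * (1 - p)
      }
      imp(left) + imp(right)
    }
    cand <- sort(unique(x))
    mids <- (cand[-1] + cand[-length(cand)]) / 2
    best <- mids[which.min(vapply(mids, gini_split, numeric(1)))]
    expect_lt(abs(split_row[["index"]] - best), 0.05)
  })
})

test_that("severity-score customization recovers its generating model and preserves ranking", {
  with_seed_test(12, {
    # score range spans logit -3..+3 around (alpha, beta) = (-3, 0.2), so
    # both parameters are well identified at this n
    s <- runif(10000, 0, 30)
    y <- rbinom(10000, 1, plogis(-3 + 0.2 * s))
    model <- customize_soi(s, y)
    expect_lt(abs(model$alpha - (-3)), 0.1)
    expect_lt(abs(model$beta - 0.2), 0.1)

    # rank invariance: a positive-slope logit refit never changes AUROC
    expect_gt(model$beta, 0)
    expect_identical(auroc(predict(model, s), y), auroc(s, y))

    # a perfect ranker stays perfect after customization
    y2 <- rbinom(200, 1, 0.3)
    perfect <- suppressWarnings(customize_soi(y2 * 10 + 0.0, y2))
    expect_equal(auroc(predict(perfect, y2 * 10), y2), 1)

    expect_error(customize_soi(rep(5, 100), rbinom(100, 1, 0.5)), "constant")
    expect_error(customize_soi(s[1:100], rep(1L, 100)), "both outcome classes")
  })
})
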