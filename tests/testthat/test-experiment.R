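# The per-fold personalized-prediction loop, the N sweep, peak detection,
# and benchmark comparisons.

test_that("predict_fold reproduces a brute-force PSM-sort-and-count oracle", {
  train <- random_cohort(200, seed = 61)
  test <- random_cohort(20, seed = 62)
  # avoid id collisions between the two draws
  test$data$patient_id <- sub("^r", "t", test$data$patient_id)
  preds <- predict_fold(train, test, "death_count", n = 10)
  expect_equal(nrow(preds), 20)
  expect_true(all(preds$risk >= 0 & preds$risk <= 1))

  scaler <- fit_scaler(train)
  tr <- cohort_vectors(train, scaler)
  te <- cohort_vectors(test, scaler, levels = tr$levels)
  y <- outcomes(train)
  for (i in c(1, 9, 20)) {
    vals <- vapply(seq_len(200), function(j) {
      oracle_psm(te$X[i, ],
                 as.character(test$data[i, c("service", "vasopressor")]),
                 tr$X[j, ],
                 as.character(train$data[j, c("service", "vasopressor")]))
    }, numeric(1))
    top <- order(-vals, tr$ids)[1:10]
    expect_equal(preds$risk[i], mean(y[top]))
  }
})

test_that("a test patient identical to a training patient ranks first with PSM 1", {
  train <- random_cohort(50, seed = 63)
  twin <- cohort_subset(train, 17)
  twin$data$patient_id <- "twin"
  scaler <- fit_scaler(train)
  tr <- cohort_vectors(train, scaler)
  index <- simpredict:::vector_at(
    cohort_vectors(twin, scaler, levels = tr$levels), 1)
  index$id <- "twin"
  ranking <- rank_neighbors(index, tr)
  expect_equal(ranking$entries$candidate_id[1], patient_ids(train)[17])
  expect_equal(ranking$entries$psm[1], 1, tolerance = 1e-12)
})

test_that("the sweep has the promised shape and is deterministic", {
  cohort <- random_cohort(300, seed = 64)
  config <- sweep_config("death_count", n_grid = c(10, 20), k_folds = 3,
                         seed = 5)
  res <- run_sweep(cohort, config)
  expect_s3_class(res, "sweep_result")
  expect_equal(nrow(res$table), 2 * 2)   # 2 metrics x 2 values of N
  expect_equal(sort(unique(res$table$metric)), c("AUPRC", "AUROC"))
  expect_named(res$table, c("metric", "n_similar", "mean", "ci_low",
                            "ci_high", "fold_1", "fold_2", "fold_3"))
  expect_true(all(res$table$ci_low <= res$table$mean &
                    res$table$mean <= res$table$ci_high))

  res2 <- run_sweep(cohort, config)
  expect_identical(res, res2)

  expect_error(run_sweep(cohort, sweep_config("death_count", c(10, 250),
                                              k_folds = 3, seed = 5)),
               "exceeds the smallest training fold")
})

test_that("top-N neighborhoods nest: smaller N is a prefix of larger N", {
  train <- random_cohort(80, seed = 65)
  test <- random_cohort(5, seed = 66)
  test$data$patient_id <- sub("^r", "t", test$data$patient_id)
  scaler <- fit_scaler(train)
  tr <- cohort_vectors(train, scaler)
  te <- cohort_vectors(test, scaler, levels = tr$levels)
  sims <- simpredict:::psm_cross(te, tr)
  for (i in 1:5) {
    ord <- order(-sims[i, ], tr$ids, method = "radix")
    expect_identical(ord[1:10], ord[1:30][1:10])
  }
})

test_that("at N = full training size, personalized logistic equals the global fit", {
  cohort <- two_feature_cohort(400, seed = 67)
  folds <- stratified_folds(outcomes(cohort), 2, seed = 1)
  train <- cohort_subset(cohort, folds$fold != 1)
  test <- cohort_subset(cohort, folds$fold == 1)
  n_full <- n_patients(train)
  per_index <- predict_fold(train, test, "logistic", n = n_full,
                            fast_path = FALSE)
  global_model <- fit_local_logistic(train)
  global_risk <- predict(global_model, test)
  expect_lt(max(abs(per_index$risk - global_risk)), 1e-8)
  # and the single-fit fast path agrees too
  fast <- predict_fold(train, test, "logistic", n = n_full, fast_path = TRUE)
  expect_equal(fast$risk, per_index$risk, tolerance = 1e-10)
})

test_that("single-class neighborhoods fall back to death counting, visibly", {
  # outcome constant among each index patient's nearest neighbors is easy
  # to force with a tiny N and a rare outcome
  cohort <- random_cohort(120, seed = 68)
  folds <- stratified_folds(outcomes(cohort), 2, seed = 2)
  train <- cohort_subset(cohort, folds$fold != 1)
  test <- cohort_subset(cohort, folds$fold == 1)
  preds <- suppressWarnings(
    predict_fold(train, test, "logistic", n = 5)
  )
  expect_true(any(preds$fallback))
  expect_true(all(preds$risk >= 0 & preds$risk <= 1))
  expect_error(predict_fold(train, test, "logistic", n = 5,
                            fit_fallback = FALSE),
               "model fit failed")
})

test_that("find_peak returns the maximal mean, ties to the smaller N", {
  fake_result <- function(means, grid) {
    k <- 3
    tab <- do.call(rbind, lapply(seq_along(grid), function(g) {
      fv <- means[g] + c(-0.01, 0, 0.01)
      data.frame(metric = "AUROC", n_similar = grid[g], mean = means[g],
                 ci_low = means[g] - 0.02, ci_high = means[g] + 0.02,
                 fold_1 = fv[1], fold_2 = fv[2], fold_3 = fv[3])
    }))
    structure(list(config = sweep_config("death_count", grid, k_folds = 3,
                                         seed = 1),
                   folds = NULL, table = tab),
              class = "sweep_result")
  }
  res <- fake_result(c(0.78, 0.797, 0.78), c(50, 100, 150))
  pk <- find_peak(res, "AUROC")
  expect_equal(pk$n_star, 100)
  expect_equal(pk$summary$mean, 0.797)

  expect_equal(find_peak(fake_result(0.8, 50), "AUROC")$n_star, 50)
  expect_equal(find_peak(fake_result(c(0.7, 0.8, 0.8), c(10, 20, 30)),
                         "AUROC")$n_star, 20)
})

test_that("comparisons: a peak at max-N yields p = 1; fold counts must match", {
  cohort <- random_cohort(200, seed = 69, score = TRUE)
  config <- sweep_config("death_count", n_grid = c(10, 20), k_folds = 3,
                         seed = 6)
  res <- run_sweep(cohort, config)
  comp <- compare_conditions(res)
  expect_true(all(c("comparison", "metric", "p_value") %in% names(comp)))
  # a sweep whose peak ties the max-N row (identical folds) must give p = 1
  flat <- res
  flat$table[flat$table$metric == "AUROC",
             c("mean", "fold_1", "fold_2", "fold_3")] <-
    rep(c(0.8, 0.78, 0.80, 0.82), each = 2)
  flat_comp <- compare_conditions(flat)
  expect_equal(
    flat_comp$p_value[flat_comp$comparison == "peak_vs_max_n" &
                        flat_comp$metric == "AUROC"], 1)

  bench <- run_benchmarks(cohort, res$folds)
  comp2 <- compare_conditions(res, bench)
  expect_true("peak_vs_sofa" %in% comp2$comparison)

  bad_bench <- bench
  bad_bench$sofa$AUROC$fold_values <- rep(0.5, 7)
  expect_error(compare_conditions(res, bad_bench), "folds")
})

test_that("benchmarks share the sweep's partitions and a null score sits near 0.5", {
  cohort <- random_cohort(400, seed = 70, score = TRUE)
  cohort$data$sofa <- with_seed_test(71, runif(400))   # outcome-independent
  folds <- stratified_folds(outcomes(cohort), 5, seed = 3)
  bench <- run_benchmarks(cohort, folds)
  expect_named(bench, "sofa")
  s <- bench$sofa$AUROC
  expect_equal(length(s$fold_values), 5)
  expect_true(s$ci_low <= 0.5 && 0.5 <= s$ci_high + 0.1)
  expect_lt(abs(s$mean - 0.5), 0.15)
  expect_error(run_benchmarks(random_cohort(50, seed = 1), folds),
               "no score columns")
})
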