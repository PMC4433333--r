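# Orchestration of the personalized-prediction experiment: the
# per-index-patient loop inside one cross-validation fold, the sweep over
# neighborhood size N, peak identification, and benchmark comparisons.
#
# The dominant cost is the pairwise PSM computation, so each index
# patient's neighbor ordering is computed once per fold and reused across
# the entire N grid; for death counting the whole grid then reduces to a
# cumulative sum over the ordered outcomes.

#' Configuration of a neighborhood-size sweep
#'
#' @param model_kind `"death_count"`, `"logistic"`, or `"tree"`.
#' @param n_grid Strictly increasing vector of neighborhood sizes N. The
#'   conventional grids are 10-500 by 10 for death counting, 5000 upward
#'   by 1000 for logistic regression, and 2000 upward by 1000 for trees.
#' @param k_folds Number of stratified cross-validation folds (default 10).
#' @param seed Seed driving the fold assignment (and any other
#'   randomness).
#' @param normalization_mode `"per_fold"` (default): the min-max scaler is
#'   fitted on each training fold and applied, with clipping, to its test
#'   fold - no leakage. `"global"`: fitted once on the full cohort.
#' @param minimum_n Smallest admissible N for the model; defaults to 10
#'   (death counting), 5000 (logistic), 2000 (tree). These floors exist
#'   because a logistic fit needs every categorical level represented and
#'   a tree needs outcome variability; they are configuration, not
#'   constants, and shrink for smaller datasets.
#' @param fit_fallback On a model-fit failure for an individual index
#'   patient (e.g. a single-class neighborhood), fall back to death
#'   counting on the same neighborhood (default) instead of erroring.
#' @return An object of class `sweep_config`.
#' @export
sweep_config <- function(model_kind = c("death_count", "logistic", "tree"),
                         n_grid, k_folds = 10L, seed = 1L,
                         normalization_mode = c("per_fold", "global"),
                         minimum_n = NULL, fit_fallback = TRUE) {
  model_kind <- match.arg(model_kind)
  normalization_mode <- match.arg(normalization_mode)
  n_grid <- as.integer(n_grid)
  if (length(n_grid) < 1L || any(diff(n_grid) <= 0L)) {
    abort("n_grid must be non-empty and strictly increasing")
  }
  minimum_n <- as.integer(minimum_n %||% default_minimum_n(model_kind))
  if (n_grid[1] < minimum_n) {
    abort("smallest N (%d) is below minimum_n (%d) for model '%s'",
          n_grid[1], minimum_n, model_kind)
  }
  structure(
    list(model_kind = model_kind, n_grid = n_grid,
         k_folds = as.integer(k_folds), seed = as.integer(seed),
         normalization_mode = normalization_mode, minimum_n = minimum_n,
         fit_fallback = fit_fallback),
    class = "sweep_config"
  )
}

#' Personalized predictions for one train/test split
#'
#' For every test ("index") patient: rank all training patients by PSM,
#' keep the `n` most similar, train the model on them alone, and predict
#' the index patient's risk. The scaler is fitted on `train` unless a
#' pre-fitted `scaler` is supplied.
#'
#' @param train,test `cohort` objects sharing a schema.
#' @param model_kind `"death_count"`, `"logistic"`, or `"tree"`.
#' @param n Neighborhood size (at most `n_patients(train)`).
#' @param scaler Optional pre-fitted `feature_scaler` (e.g. a global one).
#' @param fit_fallback Fall back to death counting when a per-index model
#'   fit fails; the fallback is recorded in the output, never silent.
#' @param fast_path With `n == n_patients(train)` every index patient's
#'   neighborhood is the whole training fold, so logistic/tree models are
#'   fitted once and shared (default `TRUE`).
#' @param ridge,min_leaf,max_depth Passed to the local model fitters.
#' @return A data frame with one row per test patient: `patient_id`,
#'   `risk`, `model_kind`, `n_similar_used`, `fallback`.
#' @export
predict_fold <- function(train, test, model_kind, n, scaler = NULL,
                         fit_fallback = TRUE, fast_path = TRUE,
                         ridge = 1e-6, min_leaf = 20L, max_depth = 8L) {
  stopifnot(inherits(train, "cohort"), inherits(test, "cohort"))
  n <- as.integer(n)
  if (n > n_patients(train)) {
    abort("n = %d exceeds the training size %d", n, n_patients(train))
  }
  scaler <- scaler %||% suppressWarnings(fit_scaler(train))
  tr_vec <- cohort_vectors(train, scaler)
  te_vec <- cohort_vectors(test, scaler, levels = tr_vec$levels)
  sims <- psm_cross(te_vec, tr_vec)
  y_train <- outcomes(train)

  out <- data.frame(patient_id = te_vec$ids, risk = NA_real_,
                    model_kind = model_kind, n_similar_used = n,
                    fallback = FALSE, stringsAsFactors = FALSE)

  if (model_kind == "death_count") {
    out$risk <- vapply(seq_len(nrow(sims)), function(i) {
      ord <- order(-sims[i, ], tr_vec$ids, method = "radix")
      mean(y_train[ord[seq_len(n)]])
    }, numeric(1))
    return(out)
  }

  full_levels <- lapply(
    train$data[categorical_features(train$schema)],
    function(v) sort(unique(v))
  )
  fit_one <- function(subset) {
    if (model_kind == "logistic") {
      suppressWarnings(
        fit_local_logistic(subset, ridge = ridge, full_levels = full_levels)
      )
    } else {
      fit_local_tree(subset, min_leaf = min_leaf, max_depth = max_depth)
    }
  }

  if (fast_path && n == n_patients(train)) {
    model <- fit_one(train)
    out$risk <- suppressWarnings(stats::predict(model, test))
    return(out)
  }

  orderings <- neighbor_orderings(sims, tr_vec$ids)
  for (i in seq_len(nrow(sims))) {
    nb <- cohort_subset(train, orderings[[i]][seq_len(n)])
    index_pt <- cohort_subset(test, i)
    res <- tryCatch(
      suppressWarnings(stats::predict(fit_one(nb), index_pt)),
      error = function(e) e
    )
    if (inherits(res, "error")) {
      if (!fit_fallback) {
        abort("model fit failed for index patient '%s': %s", te_vec$ids[i],
              conditionMessage(res))
      }
      out$risk[i] <- mean(outcomes(nb))
      out$fallback[i] <- TRUE
    } else {
      out$risk[i] <- res
    }
  }
  if (any(out$fallback)) {
    warn("death-counting fallback used for %d of %d index patients",
         sum(out$fallback), nrow(out))
  }
  out
}

# per-index-patient neighbor ordering: descending PSM, ties by ascending id
neighbor_orderings <- function(sims, train_ids) {
  lapply(seq_len(nrow(sims)), function(i) {
    order(-sims[i, ], train_ids, method = "radix")
  })
}

#' Sweep the neighborhood size N under stratified cross-validation
#'
#' One stratified fold assignment is drawn from `config$seed`; for every
#' fold and every N on the grid, each test patient receives a personalized
#' prediction from the N most similar training patients, and the pooled
#' test-fold predictions yield one AUROC and one AUPRC per fold. Neighbor
#' orderings are computed once per (index patient, fold) and shared across
#' the entire grid.
#'
#' @param cohort A `cohort`.
#' @param config A [sweep_config()].
#' @return An object of class `sweep_result`: list with `config`, `folds`
#'   (the `fold_assignment`), and `table`, a data frame with one row per
#'   (metric, N): `metric`, `n_similar`, `mean`, `ci_low`, `ci_high`,
#'   `fold_1 .. fold_k`.
#' @export
run_sweep <- function(cohort, config) {
  stopifnot(inherits(cohort, "cohort"), inherits(config, "sweep_config"))
  y <- outcomes(cohort)
  folds <- stratified_folds(y, config$k_folds, config$seed)
  min_train <- min(vapply(seq_len(config$k_folds), function(f) {
    sum(folds$fold != f)
  }, integer(1)))
  if (max(config$n_grid) > min_train) {
    abort("largest N (%d) exceeds the smallest training fold (%d patients)",
          max(config$n_grid), min_train)
  }
  global_scaler <- if (config$normalization_mode == "global") {
    suppressWarnings(fit_scaler(cohort))
  } else NULL

  grid <- config$n_grid
  fold_auroc <- matrix(NA_real_, nrow = length(grid), ncol = config$k_folds)
  fold_auprc <- matrix(NA_real_, nrow = length(grid), ncol = config$k_folds)

  for (f in seq_len(config$k_folds)) {
    train <- cohort_subset(cohort, folds$fold != f)
    test <- cohort_subset(cohort, folds$fold == f)
    y_test <- outcomes(test)

    if (config$model_kind == "death_count") {
      scaler <- global_scaler %||% suppressWarnings(fit_scaler(train))
      tr_vec <- cohort_vectors(train, scaler)
      te_vec <- cohort_vectors(test, scaler, levels = tr_vec$levels)
      sims <- psm_cross(te_vec, tr_vec)
      y_train <- outcomes(train)
      n_max <- max(grid)
      # cumulative deaths over each index patient's ordered neighbors:
      # risks for the entire grid in one pass
      risks_grid <- matrix(NA_real_, nrow = nrow(sims), ncol = length(grid))
      for (i in seq_len(nrow(sims))) {
        ord <- order(-sims[i, ], tr_vec$ids, method = "radix")[seq_len(n_max)]
        risks_grid[i, ] <- cumsum(y_train[ord])[grid] / grid
      }
      for (g in seq_along(grid)) {
        fold_auroc[g, f] <- auroc(risks_grid[, g], y_test)
        fold_auprc[g, f] <- auprc(risks_grid[, g], y_test)
      }
    } else {
      for (g in seq_along(grid)) {
        preds <- predict_fold(train, test, config$model_kind, grid[g],
                              scaler = global_scaler,
                              fit_fallback = config$fit_fallback)
        fold_auroc[g, f] <- auroc(preds$risk, y_test)
        fold_auprc[g, f] <- auprc(preds$risk, y_test)
      }
    }
  }

  tab <- rbind(
    sweep_rows("AUROC", grid, fold_auroc),
    sweep_rows("AUPRC", grid, fold_auprc)
  )
  structure(list(config = config, folds = folds, table = tab),
            class = "sweep_result")
}

sweep_rows <- function(metric, grid, fold_mat) {
  k <- ncol(fold_mat)
  rows <- lapply(seq_along(grid), function(g) {
    s <- mean_ci(fold_mat[g, ], metric_name = metric)
    cbind(data.frame(metric = metric, n_similar = grid[g], mean = s$mean,
                     ci_low = s$ci_low, ci_high = s$ci_high,
                     stringsAsFactors = FALSE),
          stats::setNames(as.data.frame(t(fold_mat[g, ])),
                          paste0("fold_", seq_len(k))))
  })
  do.call(rbind, rows)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("neighborhood sweep: model %s, %d values of N, %d folds\n",
              x$config$model_kind, length(x$config$n_grid),
              x$config$k_folds))
  for (m in unique(x$table$metric)) {
    pk <- find_peak(x, m)
    cat(sprintf("  peak %s %.3f [%.3f, %.3f] at N = %d\n", m, pk$summary$mean,
                pk$summary$ci_low, pk$summary$ci_high, pk$n_star))
  }
  invisible(x)
}

#' Locate the peak of a sweep
#'
#' @param result A `sweep_result`.
#' @param metric_name `"AUROC"` or `"AUPRC"`.
#' @return List with `n_star` (the N with the largest fold-mean; ties go
#'   to the smallest N) and `summary` (its `metric_summary`).
#' @export
find_peak <- function(result, metric_name = "AUROC") {
  stopifnot(inherits(result, "sweep_result"))
  rows <- result$table[result$table$metric == metric_name, , drop = FALSE]
  if (nrow(rows) == 0L) abort("no rows for metric '%s'", metric_name)
  best <- which(rows$mean == max(rows$mean))[1]  # grid is increasing
  list(n_star = rows$n_similar[best],
       summary = row_summary(rows[best, ], metric_name))
}

row_summary <- function(row, metric_name) {
  fold_cols <- grep("^fold_", names(row))
  mean_ci(as.numeric(row[1, fold_cols]), metric_name = metric_name)
}

#' Evaluate customized severity-score benchmarks on shared folds
#'
#' For every score column: on each training fold the score is customized
#' (univariable logistic refit on all training data), the customized model
#' predicts the test fold, and AUROC/AUPRC are recorded per fold - the
#' same partitions the sweep uses, so fold-level comparisons are valid.
#'
#' @param cohort A `cohort` with at least one score column.
#' @param folds A `fold_assignment` over the same patients.
#' @return Named list (one element per score column) of lists with
#'   `AUROC` and `AUPRC` `metric_summary` objects.
#' @export
run_benchmarks <- function(cohort, folds) {
  stopifnot(inherits(cohort, "cohort"), inherits(folds, "fold_assignment"))
  scores <- cohort$schema$score_columns
  if (length(scores) == 0L) abort("cohort declares no score columns")
  if (length(folds$fold) != n_patients(cohort)) {
    abort("fold assignment does not cover this cohort")
  }
  y <- outcomes(cohort)
  out <- list()
  for (s in scores) {
    v <- cohort$data[[s]]
    au_roc <- au_prc <- numeric(folds$k)
    for (f in seq_len(folds$k)) {
      tr <- folds$fold != f
      model <- customize_soi(v[tr], y[tr])
      risk <- predict(model, v[!tr])
      au_roc[f] <- auroc(risk, y[!tr])
      au_prc[f] <- auprc(risk, y[!tr])
    }
    out[[s]] <- list(AUROC = mean_ci(au_roc, "AUROC"),
                     AUPRC = mean_ci(au_prc, "AUPRC"))
  }
  out
}

#' Compare the sweep's peak against its endpoints and benchmarks
#'
#' Two-sided two-sample t-tests (alpha = 0.05) on fold-level metric
#' values: the peak N against the largest N on the grid, and the peak
#' against each customized severity-score benchmark, for both AUROC and
#' AUPRC.
#'
#' @param result A `sweep_result`.
#' @param benchmark_folds Optional output of [run_benchmarks()] computed
#'   on the same fold assignment.
#' @param alpha Significance level for the `significant` flag.
#' @return A data frame: `comparison`, `metric`, `n_star`, `p_value`,
#'   `significant`.
#' @export
compare_conditions <- function(result, benchmark_folds = NULL, alpha = 0.05) {
  stopifnot(inherits(result, "sweep_result"))
  k <- result$config$k_folds
  rows <- list()
  for (m in c("AUROC", "AUPRC")) {
    peak <- find_peak(result, m)
    tabm <- result$table[result$table$metric == m, , drop = FALSE]
    max_row <- tabm[nrow(tabm), , drop = FALSE]
    p <- compare_fold_metrics(peak$summary$fold_values,
                              row_summary(max_row, m)$fold_values)
    rows[[length(rows) + 1L]] <- data.frame(
      comparison = "peak_vs_max_n", metric = m, n_star = peak$n_star,
      p_value = p, significant = p < alpha, stringsAsFactors = FALSE)
    for (b in names(benchmark_folds %||% list())) {
      bf <- benchmark_folds[[b]][[m]]$fold_values
      if (length(bf) != k) {
        abort("benchmark '%s' has %d folds but the sweep has %d", b,
              length(bf), k)
      }
      p <- compare_fold_metrics(peak$summary$fold_values, bf)
      rows[[length(rows) + 1L]] <- data.frame(
        comparison = paste0("peak_vs_", b), metric = m, n_star = peak$n_star,
        p_value = p, significant = p < alpha, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a sweep table as TSV
#'
#' Columns: `metric`, `n_similar`, `mean`, `ci_low`, `ci_high`,
#' `fold_1 .. fold_k`.
#'
#' @param result A `sweep_result`.
#' @param path Output TSV path.
#' @export
write_sweep_table <- function(result, path) {
  utils::write.table(result$table, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
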