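# Evaluation machinery: stratified fold assignment, rank-based AUROC,
# average-precision AUPRC with tie blocks, fold-mean 95% confidence
# intervals, and two-sample t-test comparisons of fold-level metrics.

#' Stratified k-fold assignment
#'
#' Splits patients into `k` cross-validation folds so that the mortality
#' ratio in every fold matches the whole cohort: the expired and the
#' survived are permuted independently (seeded) and each stratum is dealt
#' round-robin into the folds, so per-class fold sizes differ by at most 1.
#'
#' @param outcomes Integer 0/1 vector.
#' @param k Number of folds.
#' @param seed Integer seed for the per-stratum permutations.
#' @return An object of class `fold_assignment`: list with `k`, `seed`,
#'   and `fold`, an integer vector in `1..k` parallel to `outcomes`.
#' @export
stratified_folds <- function(outcomes, k, seed) {
  stopifnot(is_count(k), k >= 2)
  outcomes <- as.integer(outcomes)
  if (!all(outcomes %in% c(0L, 1L))) abort("outcomes must be 0/1")
  for (cls in c(0L, 1L)) {
    if (sum(outcomes == cls) < k) {
      abort("outcome class %d has fewer than k = %d members", cls, k)
    }
  }
  fold <- integer(length(outcomes))
  with_seed(seed, {
    # the round-robin counter continues across the strata, so per-class
    # fold sizes differ by <= 1 AND total fold sizes differ by <= 1
    offset <- 0L
    for (cls in c(1L, 0L)) {
      idx <- which(outcomes == cls)
      perm <- sample(idx)
      fold[perm] <- ((offset + seq_along(perm) - 1L) %% k) + 1L
      offset <- (offset + length(perm)) %% k
    }
  })
  structure(list(k = as.integer(k), seed = as.integer(seed), fold = fold),
            class = "fold_assignment")
}

#' @export
print.fold_assignment <- function(x, ...) {
  cat(sprintf("stratified %d-fold assignment of %d patients (seed %d)\n",
              x$k, length(x$fold), x$seed))
  print(table(fold = x$fold))
  invisible(x)
}

#' Area under the ROC curve (rank-based)
#'
#' The Mann-Whitney form: the probability that a random positive is ranked
#' above a random negative, with ties counting one half. Computed from
#' midranks, which is exactly the mean over all (positive, negative) pairs
#' of 1 / 0.5 / 0 for win / tie / loss.
#'
#' @param risks Numeric predicted risks (any monotone score works).
#' @param labels Integer 0/1 outcomes.
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(risks, labels) {
  labels <- as.integer(labels)
  check_binary_pair(risks, labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    abort("AUROC is undefined with a single outcome class")
  }
  r <- rank(risks, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision, tie blocks)
#'
#' Average precision: patients are sorted by descending risk; each positive
#' contributes the precision at its rank, and the sum is divided by the
#' number of positives. Tied risk values are processed as one block whose
#' end-of-block precision is assigned to every positive in the block. No
#' interpolation is performed between points (precision-recall areas,
#' unlike ROC areas, cannot be linearly interpolated). Under this
#' convention a constant classifier scores exactly the prevalence — not
#' 0.5, which random guessing only attains on balanced data.
#'
#' @inheritParams auroc
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(risks, labels) {
  labels <- as.integer(labels)
  check_binary_pair(risks, labels)
  pos <- sum(labels == 1L)
  if (pos == 0L) abort("AUPRC is undefined with no positive labels")
  ord <- order(-risks)
  y <- labels[ord]
  v <- risks[ord]
  block_end <- cumsum(rle(v)$lengths)       # last index of each tie block
  cum_tp <- cumsum(y)
  tp_end <- cum_tp[block_end]
  prec_end <- tp_end / block_end
  tp_in_block <- diff(c(0L, tp_end))
  sum(tp_in_block * prec_end) / pos
}

check_binary_pair <- function(risks, labels) {
  if (length(risks) != length(labels)) abort("length mismatch")
  if (length(risks) == 0L) abort("empty input")
  if (anyNA(risks) || anyNA(labels)) abort("missing values in metric input")
  if (!all(labels %in% c(0L, 1L))) abort("labels must be 0/1")
  invisible(TRUE)
}

#' Fold-mean with a 95% confidence interval
#'
#' Summarizes k fold-level metric values as mean +/- t(k-1, 0.975) * se,
#' the t-based interval over cross-validation folds.
#'
#' @param fold_values Numeric vector of per-fold metric values (k >= 2).
#' @param metric_name Label, e.g. `"AUROC"`.
#' @param level Confidence level (default 0.95).
#' @return An object of class `metric_summary`: list with `metric_name`,
#'   `fold_values`, `mean`, `ci_low`, `ci_high`.
#' @export
mean_ci <- function(fold_values, metric_name = "metric", level = 0.95) {
  k <- length(fold_values)
  if (k < 2L) abort("at least two fold values are required")
  if (anyNA(fold_values)) abort("missing fold values")
  m <- mean(fold_values)
  half <- stats::qt(1 - (1 - level) / 2, df = k - 1) *
    stats::sd(fold_values) / sqrt(k)
  structure(list(metric_name = metric_name, fold_values = fold_values,
                 mean = m, ci_low = m - half, ci_high = m + half),
            class = "metric_summary")
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("%s: %.3f [%.3f, %.3f] over %d folds\n", x$metric_name,
              x$mean, x$ci_low, x$ci_high, length(x$fold_values)))
  invisible(x)
}

#' Two-sample t-test on fold-level metrics
#'
#' Two-sided two-sample t-test between two sets of fold-level metric
#' values; Welch's unequal-variance form by default, the pooled-variance
#' form with `var_equal = TRUE`. When both samples are constant the
#' p-value is 1 if the means agree and 0 otherwise.
#'
#' @param values_a,values_b Numeric vectors (each of length >= 2).
#' @param var_equal Use the pooled-variance test.
#' @return The two-sided p-value.
#' @export
compare_fold_metrics <- function(values_a, values_b, var_equal = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L) {
    abort("both samples need at least two values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    return(if (isTRUE(all.equal(mean(values_a), mean(values_b)))) 1 else 0)
  }
  stats::t.test(values_a, values_b, var.equal = var_equal)$p.value
}
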