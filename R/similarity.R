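# Patient similarity metric (PSM).
#
# Every patient is a vector in the feature space: continuous predictors
# rescaled to [-1, 1] so each contributes on the same footing, categorical
# predictors compared all-or-none. The PSM is the cosine of the angle
# between two such vectors:
#
#   PSM(P1, P2) = (P1 . P2) / (||P1|| ||P2||)
#
# where a categorical dimension contributes +1 to the dot product when the
# two categories match, -1 when they differ, and exactly 1 to each vector's
# squared magnitude. Under that convention a lone categorical match gives
# PSM = 1 and a lone mismatch -1, consistent with the +/-1 numerator. The
# result is clamped to [-1, 1] to absorb floating-point drift.

#' Fit a min-max feature scaler on a cohort
#'
#' Records, for every continuous feature, the minimum and maximum observed
#' in `cohort`. [normalize_continuous()] then maps a raw value x linearly
#' to `2 * (x - min) / (max - min) - 1`, i.e. onto \[-1, 1\]. Features that
#' are constant in the fitting cohort are flagged and later mapped to 0
#' (they carry no similarity information).
#'
#' @param cohort A `cohort`.
#' @return An object of class `feature_scaler`.
#' @export
fit_scaler <- function(cohort) {
  stopifnot(inherits(cohort, "cohort"))
  if (n_patients(cohort) == 0L) abort("cannot fit a scaler on an empty cohort")
  feats <- continuous_features(cohort$schema)
  mins <- vapply(feats, function(f) min(cohort$data[[f]]), numeric(1))
  maxs <- vapply(feats, function(f) max(cohort$data[[f]]), numeric(1))
  constant <- maxs == mins
  if (any(constant)) {
    warn("constant continuous feature(s) map to 0: %s",
         paste(feats[constant], collapse = ", "))
  }
  structure(
    list(features = feats, fitted_min = mins, fitted_max = maxs,
         constant = constant, fitted_on = sprintf("cohort[n=%d]",
                                                  n_patients(cohort))),
    class = "feature_scaler"
  )
}

#' @export
print.feature_scaler <- function(x, ...) {
  cat(sprintf("feature scaler: %d continuous features (%d constant), %s\n",
              length(x$features), sum(x$constant), x$fitted_on))
  invisible(x)
}

#' Rescale raw continuous values onto \[-1, 1\]
#'
#' @param scaler A [fit_scaler()] result.
#' @param raw A named numeric vector, or a data frame / matrix with one
#'   column per fitted feature.
#' @param clip Clip values outside the fitted range to +/-1 (default) rather
#'   than extrapolating.
#' @return A numeric matrix (rows = patients) with values in \[-1, 1\].
#' @export
normalize_continuous <- function(scaler, raw, clip = TRUE) {
  stopifnot(inherits(scaler, "feature_scaler"))
  if (is.null(dim(raw))) raw <- t(as.matrix(raw))
  raw <- as.matrix(raw)
  missing_f <- setdiff(scaler$features, colnames(raw))
  if (length(missing_f)) {
    abort("feature(s) absent from input: %s", paste(missing_f, collapse = ", "))
  }
  raw <- raw[, scaler$features, drop = FALSE]
  rng <- scaler$fitted_max - scaler$fitted_min
  rng[scaler$constant] <- 1  # avoid 0/0; constant features forced to 0 below
  out <- sweep(sweep(raw, 2, scaler$fitted_min, `-`), 2, rng, `/`) * 2 - 1
  if (any(scaler$constant)) out[, scaler$constant] <- 0
  if (clip) out <- pmin(pmax(out, -1), 1)
  out
}

#' Build a normalized patient vector
#'
#' @param continuous Named numeric values already on \[-1, 1\] (e.g. one row
#'   of [normalize_continuous()]).
#' @param categorical Named character values (category labels).
#' @param id Patient id.
#' @return An object of class `patient_vector`.
#' @export
patient_vector <- function(continuous = numeric(), categorical = character(),
                           id = NA_character_) {
  structure(list(continuous = as.numeric(continuous),
                 categorical = as.character(categorical),
                 id = as.character(id)),
            class = "patient_vector")
}

#' Cosine patient similarity between two patient vectors
#'
#' Returns the cosine of the angle between `p1` and `p2`: identical vectors
#' give 1, exactly opposite continuous vectors give -1. Categorical
#' dimensions enter the dot product as +1 (same category) or -1 (different),
#' all-or-none, and add 1 to each squared magnitude.
#'
#' @param p1,p2 [patient_vector()] objects over the same features in the
#'   same order.
#' @return A number in \[-1, 1\].
#' @examples
#' a <- patient_vector(c(0.6, 0.8), "MICU", id = "a")
#' b <- patient_vector(c(0.6, 0.8), "SICU", id = "b")
#' psm(a, b)  # 0.36 + 0.64 - 1 = 0 over magnitude sqrt(2)*sqrt(2)
#' @export
psm <- function(p1, p2) {
  stopifnot(inherits(p1, "patient_vector"), inherits(p2, "patient_vector"))
  if (length(p1$continuous) != length(p2$continuous) ||
      length(p1$categorical) != length(p2$categorical)) {
    abort("patient vectors do not share a schema (dimension mismatch)")
  }
  q <- length(p1$categorical)
  num <- sum(p1$continuous * p2$continuous) +
    (if (q) sum(ifelse(p1$categorical == p2$categorical, 1, -1)) else 0)
  m1 <- sqrt(sum(p1$continuous^2) + q)
  m2 <- sqrt(sum(p2$continuous^2) + q)
  if (m1 == 0 || m2 == 0) {
    abort("PSM undefined: a patient vector has zero magnitude")
  }
  min(1, max(-1, num / (m1 * m2)))
}

# ---- vectorized form used by the cross-validation sweep --------------------

#' Normalized feature vectors for every patient in a cohort
#'
#' Applies the scaler to the continuous features and integer-codes the
#' categorical features (codes are only compared for equality, so the
#' coding is arbitrary but shared across cohorts via `levels`).
#'
#' @param cohort A `cohort`.
#' @param scaler A `feature_scaler` (typically fitted on the training fold).
#' @param levels Optional named list of category level sets to code
#'   against; unseen labels get fresh codes. Defaults to the cohort's own.
#' @return An object of class `patient_vectors`: list with `X` (numeric
#'   matrix, n x p_continuous, in \[-1, 1\]), `C` (integer matrix,
#'   n x p_categorical), `ids`, and `levels`.
#' @export
cohort_vectors <- function(cohort, scaler, levels = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  cont <- continuous_features(cohort$schema)
  cats <- categorical_features(cohort$schema)
  X <- normalize_continuous(
    scaler, as.matrix(cohort$data[, cont, drop = FALSE])
  )
  C <- matrix(0L, nrow = n_patients(cohort), ncol = length(cats),
              dimnames = list(NULL, cats))
  lv <- levels %||% list()
  for (f in cats) {
    vals <- cohort$data[[f]]
    lv[[f]] <- union(lv[[f]] %||% character(), sort(unique(vals)))
    C[, f] <- match(vals, lv[[f]])
  }
  structure(list(X = X, C = C, ids = patient_ids(cohort), levels = lv),
            class = "patient_vectors")
}

# n1 x n2 matrix of PSM values between two patient_vectors objects.
# BLAS matrix product for the continuous part; per-dimension outer equality
# for the categorical part. Clamped to [-1, 1].
psm_cross <- function(v1, v2) {
  stopifnot(inherits(v1, "patient_vectors"), inherits(v2, "patient_vectors"))
  if (ncol(v1$X) != ncol(v2$X) || ncol(v1$C) != ncol(v2$C)) {
    abort("patient vectors do not share a schema (dimension mismatch)")
  }
  q <- ncol(v1$C)
  num <- v1$X %*% t(v2$X)
  if (q > 0) {
    for (j in seq_len(q)) {
      num <- num + (2 * outer(v1$C[, j], v2$C[, j], `==`) - 1)
    }
  }
  m1 <- sqrt(rowSums(v1$X^2) + q)
  m2 <- sqrt(rowSums(v2$X^2) + q)
  if (any(m1 == 0) || any(m2 == 0)) {
    abort("PSM undefined: a patient vector has zero magnitude")
  }
  out <- num / (m1 %o% m2)
  out[out > 1] <- 1
  out[out < -1] <- -1
  dimnames(out) <- list(v1$ids, v2$ids)
  out
}

# extract patient i of a patient_vectors object as a patient_vector
vector_at <- function(v, i) {
  patient_vector(v$X[i, ], {
    q <- ncol(v$C)
    if (q) vapply(seq_len(q), function(j) {
      v$levels[[colnames(v$C)[j]]][v$C[i, j]]
    }, character(1)) else character()
  }, id = v$ids[i])
}

#' Rank candidate patients by similarity to an index patient
#'
#' Computes the PSM between the index patient and every candidate and
#' returns the candidates sorted by descending PSM; ties are broken by
#' ascending candidate id so the ranking is deterministic.
#'
#' @param index A [patient_vector()] (not among the candidates).
#' @param candidates A `patient_vectors` object ([cohort_vectors()]) or a
#'   list of `patient_vector`s sharing the index patient's schema.
#' @return An object of class `similarity_ranking`: list with `index_id`
#'   and a data frame `entries` (`candidate_id`, `psm`), ordered.
#' @export
rank_neighbors <- function(index, candidates) {
  stopifnot(inherits(index, "patient_vector"))
  if (is.list(candidates) && !inherits(candidates, "patient_vectors")) {
    if (!length(candidates) ||
        !all(vapply(candidates, inherits, logical(1), "patient_vector"))) {
      abort("'candidates' must be a patient_vectors object or a non-empty list of patient_vector")
    }
    ids <- vapply(candidates, `[[`, character(1), "id")
    if (index$id %in% ids) {
      abort("index patient '%s' must not appear among the candidates", index$id)
    }
    vals <- vapply(candidates, function(p) psm(index, p), numeric(1))
    return(make_ranking(index$id, ids, vals))
  }
  cand <- candidates
  if (length(cand$ids) == 0L) abort("candidate pool is empty")
  if (index$id %in% cand$ids) {
    abort("index patient '%s' must not appear among the candidates", index$id)
  }
  # code the index's categories against the candidates' coding; an unseen
  # label gets code -1 and therefore matches no candidate
  q <- ncol(cand$C)
  codes <- integer(q)
  for (j in seq_len(q)) {
    f <- colnames(cand$C)[j]
    m <- match(index$categorical[j], cand$levels[[f]])
    codes[j] <- if (is.na(m)) -1L else m
  }
  iv <- structure(
    list(X = matrix(index$continuous, nrow = 1),
         C = matrix(codes, nrow = 1, ncol = q), ids = index$id,
         levels = cand$levels),
    class = "patient_vectors"
  )
  vals <- drop(psm_cross(iv, cand))
  make_ranking(index$id, cand$ids, vals)
}

make_ranking <- function(index_id, ids, vals) {
  ord <- order(-vals, ids, method = "radix")
  structure(
    list(index_id = index_id,
         entries = data.frame(candidate_id = ids[ord], psm = vals[ord],
                              stringsAsFactors = FALSE)),
    class = "similarity_ranking"
  )
}

#' @export
print.similarity_ranking <- function(x, ...) {
  cat(sprintf("similarity ranking for index '%s': %d candidates\n",
              x$index_id, nrow(x$entries)))
  print(utils::head(x$entries, 5))
  if (nrow(x$entries) > 5) cat("  ...\n")
  invisible(x)
}

#' Dump a similarity ranking as TSV (debugging aid)
#'
#' @param ranking A `similarity_ranking`.
#' @param path Output TSV path.
#' @export
write_ranking <- function(ranking, path) {
  df <- data.frame(index_id = ranking$index_id,
                   candidate_id = ranking$entries$candidate_id,
                   rank = seq_len(nrow(ranking$entries)),
                   psm = ranking$entries$psm)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
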