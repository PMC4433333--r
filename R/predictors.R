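# Per-index-patient risk models.
#
# Three model families, each trained on the N most similar patients only:
#   * death counting  - the observed mortality rate among the N neighbors;
#   * logistic regression - maximum likelihood on all schema features, with
#     an optional (default, tiny) L2 ridge that stabilizes near-separated
#     local subsets without measurably moving coefficients;
#   * classification tree - CART with Gini impurity via rpart, leaf risks
#     Laplace-smoothed so no patient ever receives risk exactly 0 or 1.
# Severity-of-illness scores are benchmarked after "logit customization":
# a univariable logistic refit of the outcome on the raw score.

default_minimum_n <- function(model_kind) {
  switch(model_kind, death_count = 10L, logistic = 5000L, tree = 2000L,
         abort("unknown model kind '%s'", model_kind))
}

#' Death counting: neighborhood mortality rate as the risk
#'
#' The simplest personalized predictor: the fraction of deaths among the
#' index patient's `n` most similar patients.
#'
#' @param ranking A `similarity_ranking` for the index patient.
#' @param outcomes Named (by patient id) integer 0/1 vector covering every
#'   ranked candidate.
#' @param n Neighborhood size; must not exceed the ranking length.
#' @return A one-row data frame of class `risk_prediction` with columns
#'   `patient_id`, `risk`, `model_kind`, `n_similar_used`.
#' @export
death_count_risk <- function(ranking, outcomes, n) {
  stopifnot(inherits(ranking, "similarity_ranking"), is_count(n))
  if (n > nrow(ranking$entries)) {
    abort("n = %d exceeds the %d ranked candidates", n, nrow(ranking$entries))
  }
  top <- ranking$entries$candidate_id[seq_len(n)]
  y <- outcomes[top]
  if (anyNA(y)) abort("outcomes missing for some ranked candidates")
  risk_prediction(ranking$index_id, mean(y), "death_count", n)
}

risk_prediction <- function(patient_id, risk, model_kind, n_similar_used) {
  structure(
    data.frame(patient_id = patient_id, risk = risk, model_kind = model_kind,
               n_similar_used = as.integer(n_similar_used),
               stringsAsFactors = FALSE),
    class = c("risk_prediction", "data.frame")
  )
}

# ---- design matrix ---------------------------------------------------------

# Dummy-code a cohort's features against the first sorted level of each
# categorical (treatment coding). `levels` pins the level sets (e.g. the
# full cohort's) so that levels absent from a local subset still define the
# coding; a label unseen at prediction time falls back to the reference
# level with a warning.
build_design <- function(cohort, levels = NULL, warn_unseen = FALSE) {
  schema <- cohort$schema
  cont <- continuous_features(schema)
  cats <- categorical_features(schema)
  n <- n_patients(cohort)
  lv <- levels %||% lapply(cohort$data[cats], function(v) sort(unique(v)))
  names(lv) <- cats
  blocks <- list(`(Intercept)` = matrix(1, n, 1))
  if (length(cont)) {
    blocks$cont <- as.matrix(cohort$data[, cont, drop = FALSE])
  }
  for (f in cats) {
    lev <- lv[[f]]
    vals <- cohort$data[[f]]
    unseen <- !(vals %in% lev)
    if (any(unseen)) {
      if (warn_unseen) {
        warn("feature '%s': %d value(s) outside the training levels mapped to reference '%s'",
             f, sum(unseen), lev[1])
      }
      vals[unseen] <- lev[1]
    }
    if (length(lev) > 1L) {
      d <- matrix(0, n, length(lev) - 1L,
                  dimnames = list(NULL, paste0(f, "=", lev[-1])))
      m <- match(vals, lev)
      hit <- which(m > 1L)
      d[cbind(hit, m[hit] - 1L)] <- 1
      blocks[[f]] <- d
    }
  }
  X <- do.call(cbind, blocks)
  colnames(X)[1] <- "(Intercept)"
  list(X = X, levels = lv)
}

# Iteratively reweighted least squares for binomial logistic regression
# with an optional L2 penalty on the non-intercept coefficients. Row order
# independent up to floating point; callers sort subsets by id first so
# repeated fits on the same subset are bitwise identical.
irls_logistic <- function(X, y, ridge = 0, max_iter = 100L, tol = 1e-10) {
  p <- ncol(X)
  pen <- rep(ridge, p)
  pen[colnames(X) == "(Intercept)"] <- 0
  beta <- numeric(p)
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtwx <- crossprod(X, X * w)
    diag(xtwx) <- diag(xtwx) + pen
    beta_new <- tryCatch(
      drop(solve(xtwx, crossprod(X, w * z))),
      error = function(e) abort(
        "logistic fit failed (singular system): %s; consider the ridge-stabilized mode",
        conditionMessage(e))
    )
    done <- max(abs(beta_new - beta)) < tol
    beta <- beta_new
    if (done) break
  }
  names(beta) <- colnames(X)
  list(coefficients = beta, iterations = it, converged = done)
}

#' Fit a local logistic risk model on a neighborhood subset
#'
#' Maximum-likelihood logistic regression of the outcome on every schema
#' feature, with categoricals dummy-coded against a fixed reference level
#' (the first level in sorted order). Intended for the N-most-similar
#' subset of an index patient. A tiny default ridge (1e-6) keeps fits on
#' small, nearly separated local subsets finite; `ridge = 0` gives the
#' strict unpenalized fit. Categorical levels known globally (via
#' `full_levels`) but absent from the subset get an implicit coefficient
#' of 0 (a warning is emitted; in `strict = TRUE` mode this is an error,
#' the rationale for the minimum neighborhood size).
#'
#' @param subset A `cohort` (the neighborhood).
#' @param ridge Non-negative L2 penalty on non-intercept coefficients.
#' @param full_levels Optional named list of full categorical level sets.
#' @param strict Error (rather than warn) when `full_levels` contains
#'   levels unobserved in the subset.
#' @return An object of class `local_logistic`.
#' @export
fit_local_logistic <- function(subset, ridge = 1e-6, full_levels = NULL,
                               strict = FALSE) {
  stopifnot(inherits(subset, "cohort"))
  y <- outcomes(subset)
  if (length(unique(y)) < 2L) {
    abort("neighborhood has a single outcome class; enlarge N or fall back to death counting")
  }
  # deterministic fit regardless of neighbor ordering
  subset <- cohort_subset(subset, order(patient_ids(subset), method = "radix"))
  y <- outcomes(subset)
  lv <- NULL
  if (!is.null(full_levels)) {
    cats <- categorical_features(subset$schema)
    lv <- full_levels[cats]
    for (f in cats) {
      absent <- setdiff(lv[[f]], unique(subset$data[[f]]))
      if (length(absent)) {
        msg <- sprintf("feature '%s': level(s) %s absent from the neighborhood (coefficient 0)",
                       f, paste(absent, collapse = ", "))
        if (strict) abort("%s", msg) else warn("%s", msg)
      }
    }
  }
  des <- build_design(subset, levels = lv)
  fit <- irls_logistic(des$X, y, ridge = ridge)
  structure(
    list(coefficients = fit$coefficients, levels = des$levels,
         schema = subset$schema, ridge = ridge, n = n_patients(subset),
         converged = fit$converged),
    class = "local_logistic"
  )
}

#' @export
print.local_logistic <- function(x, ...) {
  cat(sprintf("local logistic model: %d coefficients, n = %d, ridge = %g\n",
              length(x$coefficients), x$n, x$ridge))
  invisible(x)
}

#' Fit a local classification tree on a neighborhood subset
#'
#' CART binary classification tree (Gini impurity, via \pkg{rpart}) on all
#' schema features. Leaf risks are Laplace-smoothed:
#' `(deaths + 1) / (leaf size + 2)`, so no leaf reports exactly 0 or 1;
#' `laplace = FALSE` gives raw leaf proportions. No surrogate splits are
#' used; a patient with an unseen categorical value is routed down the
#' majority child.
#'
#' @param subset A `cohort` (the neighborhood).
#' @param min_leaf Minimum patients per leaf (default 20).
#' @param max_depth Maximum tree depth (default 8).
#' @param laplace Laplace-smooth leaf risks (default `TRUE`).
#' @return An object of class `local_tree`.
#' @export
fit_local_tree <- function(subset, min_leaf = 20L, max_depth = 8L,
                           laplace = TRUE) {
  stopifnot(inherits(subset, "cohort"))
  y <- outcomes(subset)
  if (length(unique(y)) < 2L) {
    abort("neighborhood has a single outcome class; enlarge N")
  }
  subset <- cohort_subset(subset, order(patient_ids(subset), method = "radix"))
  df <- tree_frame(subset)
  fit <- rpart::rpart(
    .outcome ~ ., data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      minsplit = 2L * min_leaf, minbucket = min_leaf, maxdepth = max_depth,
      cp = 0, xval = 0, maxsurrogate = 0, maxcompete = 0, usesurrogate = 2
    )
  )
  structure(
    list(rpart = fit, levels = lapply(df[setdiff(names(df), ".outcome")],
                                      levels),
         schema = subset$schema, laplace = laplace, n = n_patients(subset)),
    class = "local_tree"
  )
}

# model frame for rpart: factors with the subset's observed levels
tree_frame <- function(cohort, levels = NULL) {
  schema <- cohort$schema
  df <- cohort$data[, names(schema$features), drop = FALSE]
  for (f in categorical_features(schema)) {
    lev <- levels[[f]] %||% sort(unique(df[[f]]))
    v <- df[[f]]
    v[!(v %in% lev)] <- NA  # unseen level -> NA -> majority routing
    df[[f]] <- factor(v, levels = lev)
  }
  if (schema$outcome_column %in% names(cohort$data)) {
    df$.outcome <- factor(outcomes(cohort), levels = c(0L, 1L))
  }
  df
}

#' @export
print.local_tree <- function(x, ...) {
  nleaf <- sum(x$rpart$frame$var == "<leaf>")
  cat(sprintf("local classification tree: %d leaves, n = %d, %s leaf risks\n",
              nleaf, x$n,
              if (x$laplace) "Laplace-smoothed" else "raw"))
  invisible(x)
}

#' Logit customization of a severity-of-illness score
#'
#' Refits the relationship between an existing severity score (e.g. SAPS
#' or SOFA) and the outcome with a univariable logistic model,
#' `logit(risk) = alpha + beta * score`, on the entire training fold. Being
#' a monotone transform when `beta > 0`, customization changes calibration
#' but not ranking-based metrics.
#'
#' @param scores Numeric score per patient.
#' @param outcomes Integer 0/1 outcome per patient.
#' @return An object of class `soi_model` with `alpha` and `beta`.
#' @export
customize_soi <- function(scores, outcomes) {
  if (length(scores) != length(outcomes)) abort("length mismatch")
  if (length(unique(outcomes)) < 2L) {
    abort("both outcome classes are required to customize a score")
  }
  if (stats::sd(scores) == 0) abort("score column is constant; cannot customize")
  fit <- stats::glm(outcomes ~ scores, family = stats::binomial())
  co <- stats::coef(fit)
  structure(list(alpha = unname(co[1]), beta = unname(co[2]),
                 n = length(scores)),
            class = "soi_model")
}

#' @export
print.soi_model <- function(x, ...) {
  cat(sprintf("customized severity score: logit(risk) = %.4f + %.4f * score (n = %d)\n",
              x$alpha, x$beta, x$n))
  invisible(x)
}

# ---- prediction ------------------------------------------------------------

#' Predict mortality risk for new patients
#'
#' @param model A fitted `local_logistic`, `local_tree`, or `soi_model`.
#' @param newdata A `cohort` (or, for `soi_model`, a numeric score vector).
#' @param ... Unused.
#' @return Numeric risks in \[0, 1\], one per patient.
#' @name predict_risk
NULL

#' @rdname predict_risk
#' @export
predict.local_logistic <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cohort"))
  des <- build_design(newdata, levels = object$levels, warn_unseen = TRUE)
  keep <- intersect(colnames(des$X), names(object$coefficients))
  eta <- drop(des$X[, keep, drop = FALSE] %*% object$coefficients[keep])
  stats::plogis(eta)
}

#' @rdname predict_risk
#' @export
predict.local_tree <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "cohort"))
  df <- tree_frame(newdata, levels = object$levels)
  df <- df[, setdiff(names(df), ".outcome"), drop = FALSE]
  one_row <- nrow(df) == 1L
  if (one_row) df <- rbind(df, df)  # rpart cannot route a lone NA row
  m <- stats::predict(object$rpart, newdata = df, type = "matrix")
  if (one_row) m <- m[1, , drop = FALSE]
  dead <- unname(m[, 3])
  alive <- unname(m[, 2])
  if (object$laplace) (dead + 1) / (alive + dead + 2) else dead / (alive + dead)
}

#' @rdname predict_risk
#' @export
predict.soi_model <- function(object, newdata, ...) {
  scores <- if (is.numeric(newdata)) newdata else {
    abort("predict.soi_model expects a numeric score vector")
  }
  stats::plogis(object$alpha + object$beta * scores)
}

# ---- serialization (inspection only, not a stable interchange format) -----

#' Serialize a fitted local model to JSON
#'
#' @param model A `local_logistic`, `local_tree`, or `soi_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  doc <- if (inherits(model, "local_logistic")) {
    list(kind = "logistic", coefficients = as.list(model$coefficients),
         ridge = model$ridge, n = model$n)
  } else if (inherits(model, "local_tree")) {
    fr <- model$rpart$frame
    list(kind = "tree", n = model$n, laplace = model$laplace,
         nodes = data.frame(node = as.integer(rownames(fr)), var = fr$var,
                            n = fr$n, stringsAsFactors = FALSE))
  } else if (inherits(model, "soi_model")) {
    list(kind = "soi", alpha = model$alpha, beta = model$beta, n = model$n)
  } else {
    abort("unsupported model class")
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
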