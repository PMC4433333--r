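# Shared fixtures and independent oracles for the test suite.
# Oracles are deliberately naive (explicit loops, direct enumeration) and
# share no code with the implementation they check.

toy_schema <- function(score_columns = character()) {
  cohort_schema(
    c(age = "continuous", hr_min = "continuous", hr_max = "continuous",
      service = "categorical", vasopressor = "categorical"),
    outcome_column = "died30", score_columns = score_columns,
    id_column = "patient_id"
  )
}

# deterministic hand-rolled toy cohort; ids deliberately unsorted on input
toy_table <- function() {
  data.frame(
    patient_id = c("p03", "p01", "p05", "p02", "p04"),
    age = c(71, 64, 55, 80, 47),
    hr_min = c(60, 72, 55, 88, 64),
    hr_max = c(95, 110, 80, 132, 99),
    service = c("MICU", "SICU", "MICU", "CCU", "MICU"),
    vasopressor = c("yes", "no", "no", "yes", "no"),
    died30 = c(1, 0, 0, 1, 0),
    stringsAsFactors = FALSE
  )
}

toy_cohort <- function() new_cohort(toy_table(), toy_schema())

# random mixed-type cohort with a weak signal, for property tests
random_cohort <- function(n, seed = 1, score = FALSE) {
  with_seed_test(seed, {
    tab <- data.frame(
      patient_id = sprintf("r%04d", seq_len(n)),
      age = runif(n, 20, 90),
      hr_min = rnorm(n, 70, 10),
      hr_max = rnorm(n, 100, 15),
      service = sample(c("MICU", "SICU", "CCU", "CSRU"), n, TRUE),
      vasopressor = sample(c("yes", "no"), n, TRUE),
      stringsAsFactors = FALSE
    )
    risk <- plogis(-2 + 0.02 * (tab$age - 55) + (tab$vasopressor == "yes"))
    tab$died30 <- rbinom(n, 1, risk)
    if (score) tab$sofa <- 5 + 8 * risk + rnorm(n, 0, 2)
    new_cohort(tab, toy_schema(if (score) "sofa" else character()))
  })
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# ---- independent oracles ---------------------------------------------------

# cosine PSM by explicit summation loops
oracle_psm <- function(cont1, cat1, cont2, cat2) {
  num <- 0
  for (j in seq_along(cont1)) num <- num + cont1[j] * cont2[j]
  for (j in seq_along(cat1)) num <- num + if (cat1[j] == cat2[j]) 1 else -1
  m1 <- sqrt(sum(cont1^2) + length(cat1))
  m2 <- sqrt(sum(cont2^2) + length(cat2))
  max(-1, min(1, num / (m1 * m2)))
}

# AUROC by brute force over all (positive, negative) pairs
oracle_auroc <- function(risks, labels) {
  pos <- risks[labels == 1]
  neg <- risks[labels == 0]
  total <- 0
  for (a in pos) for (b in neg) {
    total <- total + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# average precision by per-positive enumeration with tie blocks: each
# positive contributes the precision at the end of its tie block
oracle_auprc <- function(risks, labels) {
  contrib <- 0
  for (i in which(labels == 1)) {
    in_or_above_block <- risks >= risks[i]
    prec <- sum(labels[in_or_above_block] == 1) / sum(in_or_above_block)
    contrib <- contrib + prec
  }
  contrib / sum(labels == 1)
}

# cohort from a known two-feature logistic model (coefficient recovery)
two_feature_cohort <- function(n, beta = c(1, -0.5), intercept = -1,
                               seed = 1) {
  with_seed_test(seed, {
    x1 <- rnorm(n)
    x2 <- rnorm(n)
    y <- rbinom(n, 1, plogis(intercept + beta[1] * x1 + beta[2] * x2))
    new_cohort(
      data.frame(patient_id = sprintf("q%05d", seq_len(n)), x1 = x1, x2 = x2,
                 died30 = y, stringsAsFactors = FALSE),
      cohort_schema(c(x1 = "continuous", x2 = "continuous"),
                    outcome_column = "died30", id_column = "patient_id")
    )
  })
}

# random normalized mixed patient_vector
random_patient_vector <- function(id, p_cont = 4, cats = c("A", "B", "C")) {
  patient_vector(runif(p_cont, -1, 1),
                 sample(cats, 2, replace = TRUE), id = id)
}
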