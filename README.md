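# simpredict

Personalized prediction of binary clinical outcomes — prototypically
30-day mortality after an ICU stay — by learning from *similar past
patients* instead of from everyone.

Standard severity-of-illness (SOI) scores such as SAPS or SOFA are static,
one-size-fits-all models. `simpredict` implements the instance-based
alternative: for each **index patient**, it ranks all past patients by a
**patient similarity metric (PSM)**, trains a predictive model on only the
*N* most similar ones, and applies that custom model to the index patient.
Because the right *N* balances training-data *homogeneity* against
training-data *size*, the package's central tool is a stratified
cross-validated **sweep over N** that maps this trade-off and compares its
peak against logit-customized SOI-score benchmarks.

The PSM is cosine similarity over mixed-type patient vectors,

```
PSM(P1, P2) = (P1 · P2) / (||P1|| ||P2||)  ∈  [−1, 1],
```

where continuous predictors are min–max rescaled to [−1, 1] so each
contributes equally, and each categorical dimension contributes ±1 to the
dot product (same / different category, all-or-none) and exactly 1 to each
vector's squared magnitude. Local models are **death counting** (the
mortality rate among the N neighbors), **logistic regression**, and a
CART **classification tree**; evaluation uses rank-based AUROC and
tie-blocked average-precision AUPRC (under which a constant classifier
scores the prevalence, the honest baseline for skewed outcomes), fold
means with t-based 95% CIs, and two-sided two-sample t-tests.

Real cohorts enter as a CSV table plus a JSON schema sidecar declaring
each column's role. Because the ICU data this method targets are
access-restricted, the package also ships a fully seeded synthetic cohort
generator with latent patient subgroups and known ground truth, so every
stage of the pipeline is testable offline.

## Worked example

Simulate a clustered cohort, sweep death counting over N, and benchmark
the SAPS-like score on the same folds:

```r
library(simpredict)

gen    <- generate_cohort(generator_config(n_patients = 2000, seed = 42))
config <- sweep_config("death_count", n_grid = seq(10, 200, 10),
                       k_folds = 5, seed = 42)
result <- run_sweep(gen$cohort, config)
result
#> neighborhood sweep: model death_count, 20 values of N, 5 folds
#>   peak AUROC 0.766 [0.735, 0.798] at N = 60
#>   peak AUPRC 0.346 [0.306, 0.387] at N = 90

bench <- run_benchmarks(gen$cohort, result$folds)
bench$saps$AUROC
#> AUROC: 0.661 [0.599, 0.723] over 5 folds

compare_conditions(result, bench)
#>      comparison metric n_star      p_value significant
#> 1 peak_vs_max_n  AUROC     60 0.6062924688       FALSE
#> 2  peak_vs_saps  AUROC     60 0.0057605663        TRUE
#> 3  peak_vs_sofa  AUROC     60 0.0005192094        TRUE
#> 4 peak_vs_max_n  AUPRC     90 0.5733130838       FALSE
#> 5  peak_vs_saps  AUPRC     90 0.0794875952       FALSE
#> 6  peak_vs_sofa  AUPRC     90 0.0048137004        TRUE
```

Reading this: predicting each test patient from their 60 most similar
patients gives a mean cross-validated AUROC of 0.766, significantly better
than the customized SAPS-like (0.661) and SOFA-like benchmarks; on this
2,000-patient cohort the peak is not yet distinguishable from using the
largest N on the grid. (On larger cohorts with a wider grid the
peak-vs-max-N contrast becomes significant too — that is the
homogeneity/sample-size trade-off the sweep exists to expose.)

The same machinery works one patient at a time on a loaded CSV cohort:

```r
csv    <- system.file("extdata", "example_cohort_synthetic.csv", package = "simpredict")
js     <- system.file("extdata", "example_schema.json", package = "simpredict")
cohort <- load_cohort(csv, js)
scaler <- fit_scaler(cohort)

index <- cohort_subset(cohort, patient_ids(cohort) == "P002")
rest  <- cohort_subset(cohort, patient_ids(cohort) != "P002")

z  <- normalize_continuous(scaler,
        as.matrix(index$data[, c("age", "hr_min", "hr_max", "gcs_min")]))
iv <- patient_vector(z[1, ],
        as.character(index$data[, c("service", "vasopressor")]), id = "P002")

ranking <- rank_neighbors(iv, cohort_vectors(rest, scaler))
ranking
#> similarity ranking for index 'P002': 15 candidates
#>      candidate_id         psm
#> P011         P011 0.934784462
#> P005         P005 0.848650298
#> P008         P008 0.182928021
#> P013         P013 0.017656921
#> P015         P015 0.007280156
#>   ...

death_count_risk(ranking, setNames(outcomes(rest), patient_ids(rest)), n = 5)
#>   patient_id risk  model_kind n_similar_used
#> 1       P002  0.6 death_count              5
```

## Command line

A thin launcher over the same functions is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "simpredict.R", package = "simpredict"))')" \
  generate --n 20000 --clusters 6 --effect high --seed 7 \
  --out cohort.csv --schema-out schema.json --truth-out truth.tsv

Rscript .../simpredict.R sweep --cohort cohort.csv --schema schema.json \
  --model death_count --n-grid 10:500:10 --k 10 --seed 7 --out results/
Rscript .../simpredict.R benchmark --cohort cohort.csv --schema schema.json --out results/
Rscript .../simpredict.R report --in results/
```

Every run writes a `run_manifest.json` (version, effective config, seed,
input digests, outputs); `report` renders peak tables and the N-vs-metric
trade-off curves with CI bands.

## Documentation

The methods vignette
(`vignettes/personalized-mortality-prediction.Rmd`) documents the model
and its assumptions, the normalization-leakage choice, minimum-N
rationale, metric conventions, what the synthetic generator does and does
not emulate, and known limitations.
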