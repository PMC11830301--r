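# famliab

Genetic epidemiology of rare psychiatric phenotypes in population
registers: familial aggregation, liability-scale heritability, genetic
correlations (including between mutually exclusive diagnoses), and
case–case polygenic-score associations — validated end to end on a
synthetic register generator with known ground truth.

The motivating phenotype is psychotic major depressive disorder (ICD-10
F32.3/F33.3), a subtype too rare (~0.2% lifetime prevalence) for ordinary
cohort genetics. The package is for biostatisticians and genetic
epidemiologists who analyse registry-shaped data — a person table with
pedigree links, diagnosis and treatment event tables, and per-person
polygenic scores — or who need a calibrated simulator of such data.

## What it computes

**Liability-threshold model.** A binary trait fires when a latent
standard-normal liability exceeds `z = qnorm(1 - K)` for prevalence `K`.
Liability variance decomposes into additive genetic (A), shared (C) and
unique environment (E) shares, with relative pairs correlating
`0.5 a² + c²` (full siblings), `0.25 a² + κ c²` (half siblings) and
`0.125 a²` (first cousins).

**Estimators.**

* `tetrachoric()` — latent correlation from a 2×2 pair table, via an
  in-package bivariate-normal CDF (`pbvn()`), with delta-method SE;
* `fit_ace_wls()` — ACE/AE decomposition by inverse-variance-weighted
  least squares on the full-sib/cousin tetrachoric contrast;
* `fit_rg_ml()` — maximum-likelihood genetic correlation from 3×3
  (mutually exclusive pair: none/psychotic/non-psychotic) or 4×4 pair
  cross tables, with cell probabilities from an exact conditional
  factorization evaluated by Gauss–Hermite quadrature;
* `fit_cluster_logit()` — familial aggregation/coaggregation odds ratios:
  logistic point estimates (≡ GEE with independence working correlation)
  with a family-clustered sandwich SE;
* `fit_prs_models()` — univariate and mutually-adjusted per-SD odds
  ratios of standardized polygenic scores for the psychotic vs
  non-psychotic case contrast;
* `bootstrap_ci()`, `rg_difference_test()`, `meta_fixed()`,
  `compare_models()` — family bootstrap percentile CIs, bootstrap
  equality tests, fixed-effect pooling, and chi-square/LRT model
  comparison.

**Generator.** `simulate_population()` builds three-generation pedigrees
(full sibs, half sibs, cousins) and draws diagnoses from the multivariate
liability model with configurable variance shares, prevalences,
cross-trait genetic correlations and a "psychotic wins" exclusivity rule;
it emits `persons.tsv`, `diagnoses.tsv`, `treatments.tsv`, `prs.tsv` and
`truth.json`. `simulate_pairs()`, `simulate_aggregation_pairs()` and
`simulate_prs_casecase()` are vectorised design-specific generators for
recovery experiments. `run_pipeline()` chains generation → phenotyping
(`classify_mdd()`, main or restrictive definition) → eligibility →
pair extraction → all estimators → meta-analysis, writing every table
plus an md5 manifest, byte-identical under a fixed seed.

## Worked example

Simulate a register of 2,000 extended families with an exclusive
psychotic/non-psychotic MDD pair (heritabilities 35%/40%, genetic
correlation 0.8, prevalences inflated to 6%/15% so a small example has
concordant pairs), then run the three main estimators:

```r
library(famliab)

tr <- list(trait_spec("psychotic_mdd", 0.06, 0.35, wins = TRUE,
                      exclusive_with = "non_psychotic_mdd"),
           trait_spec("non_psychotic_mdd", 0.15, 0.40))
cfg <- registry_config(2000, tr, rg = matrix(c(1, 0.8, 0.8, 1), 2),
                       seed = 42)
pop    <- simulate_population(cfg)
labels <- classify_mdd(pop$persons, pop$diagnoses)
pairs  <- extract_pairs(pop$persons)
table(pairs$kinship)
#>   cousin full_sib half_sib
#>     9307     7474      599

# familial aggregation, full siblings
expo <- data.frame(person_id = labels$person_id,
                   exposed = as.integer(labels$label == "psychotic_mdd"))
fs <- pairs[pairs$kinship == "full_sib", ]
fit_cluster_logit(pair_dataset(fs, expo, persons = pop$persons),
                  label = "full-sib aggregation")
#> full-sib aggregation: OR = 2.287 (95% CI 1.646-3.178), p = 8.22e-07
#>   [n_pairs = 7474, clusters = 2000]

# AE heritability from the full-sib / cousin contrast
cat_of <- function(ids) {
  l <- labels$label[match(ids, labels$person_id)]
  ifelse(l == "psychotic_mdd", 1L,
         ifelse(l == "non_psychotic_mdd", 2L, 0L))
}
tabs <- lapply(c(full_sib = "full_sib", cousin = "cousin"), function(k) {
  pk <- pairs[pairs$kinship == k, ]
  pair_crosstable((cat_of(pk$person_a) == 1) + 0L,
                  (cat_of(pk$person_b) == 1) + 0L, 2)
})
(fit <- fit_ace_wls(tabs, "AE"))
#> AE model (WLS estimator)
#>   a2 = 0.3941  c2 = 0.0000  e2 = 0.6059
#>   fit statistic = 0.1019 (df = 1)
```

The affected proband roughly doubles a sibling's odds, and the AE fit
recovers the generating heritability (0.394 vs 0.35) within the sampling
error of ~7,500 sibling pairs. The 3×3 cross tables of the exclusive pair
feed the ML genetic-correlation fit the same way (`fit_rg_ml()`, here
0.834 vs a generating 0.8); `run_pipeline(cfg, "out/")` performs all of
the above, bootstrap CIs included, and writes the report tables.

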