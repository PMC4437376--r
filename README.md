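# gpfsel — genomic prediction with feature selection and leakage-aware cross-validation

`gpfsel` is an R package for SNP-based prediction of quantitative traits
in structured cohorts, built for methodologists who want to compare
whole-genome regression models and marker-selection strategies — and, in
particular, to *measure* what happens when feature selection is allowed
to peek at test data.

## What it implements

**Prediction models**

* **G-BLUP** — the mixed model `y = Xb + g + e`, `g ~ N(0, G σ²g)`, on a
  VanRaden method-1 genomic relationship matrix
  `G = WWᵀ / 2Σpⱼ(1−pⱼ)`; variance components by REML (one
  eigendecomposition, then 1-D profile likelihood in
  `λ = σ²g/σ²e`); equivalent to ridge regression on centered SNPs.
* **Bayes C** — spike-and-slab whole-genome regression: each SNP effect
  is zero with probability `π` (estimated, Uniform prior), included
  effects share one variance; single-site Gibbs sampler in C++,
  reproducible from a seed.
* **QTL hit-list regression** — joint OLS on a supplied list of markers.

**Association and selection**

* A two-step (GRAMMAR-style) scan: polygenic-model residuals regressed on
  each SNP; ranks are total and deterministic.
* Five feature-selection algorithms: evenly spaced markers from a random
  offset (UFS); GWAS-rank selection (SFS1); rank selection with
  median-marker-interval pruning (SFS2); interval-conditional P-value
  ranking (SFS3); and haplotype-block-conditional P-value ranking (SFS4),
  with blocks from the Gabriel D′ confidence-interval method as Haploview
  applies it.

**Evaluation**

* K-fold cross-validation where the leakage mode is mandatory and
  audited: `mode = "proper"` restricts the scan and the selection to
  training folds; `mode = "leaky"` deliberately reproduces the biased
  protocol in which markers are ranked on the whole data set.
* Replication-cohort prediction with marker panels intersected and
  allele orientation, centering and the GRM frame frozen from training.
* Accuracy = Pearson correlation of predicted and observed phenotype,
  with fold means and 95% t-intervals; a Daetwyler-form theoretical
  expectation `r = sqrt(n h⁴ / (n h² + mₑ))` for comparison.

**Synthetic cohorts** — a simulator with haplotype-block LD (founder
haplotypes on a random mutation genealogy, so within-block |D′| = 1),
Balding–Nichols-calibrated stratification (`Fst` hit exactly via
Dirichlet founder-usage weights), sib families, and three trait
architectures (height-like polygenic h² = 0.8, HDL-like h² = 0.5 with
five moderate loci, BMI-like h² = 0.3), all with returned ground truth.

## Worked example

```r
library(gpfsel)

cfg    <- trait_preset("hdl", n_individuals = 500, n_subpops = 2,
                       n_snps = 2000, seed = 42)
cohort <- simulate_cohort(cfg)
grm    <- compute_grm(cohort$genotypes)
fit    <- fit_gblup(grm, cohort$phenotype)
fit
#> gblup_fit: n_train = 1000, sigma2_g = 0.5507, sigma2_e = 0.4709, h2 = 0.539

plan <- make_folds(cohort$genotypes$sample_ids, K = 10, seed = 42)
run_cv(cohort$genotypes, cohort$phenotype, plan = plan, model = "gblup",
       selection = list(method = "SFS1", density = 200), mode = "proper")
#> cv_report [gblup, SFS1@200, proper mode]: mean accuracy 0.536
#>   (95% CI 0.508..0.565) over 10 folds
run_cv(cohort$genotypes, cohort$phenotype, plan = plan, model = "gblup",
       selection = list(method = "SFS1", density = 200), mode = "leaky")
#> cv_report [gblup, SFS1@200, leaky mode]: mean accuracy 0.727
#>   (95% CI 0.706..0.747) over 10 folds
```

The HDL-like simulated trait has heritability 0.5; REML recovers
`h2 = 0.539`. Proper 10-fold cross-validation of G-BLUP on the top-200
scan-ranked markers estimates accuracy 0.536; letting the scan see the
test folds inflates the same estimate to 0.727 on identical data — the
gap is pure selection leakage, and on a zero-heritability trait the same
comparison gives ≈ 0 (proper) versus ≈ 0.5 (leaky); see
`leakage_null_experiment()`.

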