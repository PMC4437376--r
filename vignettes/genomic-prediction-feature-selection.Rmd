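---
title: "Genomic prediction with feature selection: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Genomic prediction with feature selection: models, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the package does

`gpfsel` implements the experimental machinery of SNP-based genomic
prediction for quantitative traits in structured human-like cohorts: two
whole-genome regression models (G-BLUP and Bayes C) plus a fixed hit-list
regression, a two-step mixed-model association scan, one unsupervised and
four supervised feature-selection algorithms, and a cross-validation
harness in which *feature-selection leakage* — ranking or choosing markers
with data that later serves as test data — is an explicit, audited mode
rather than an accident.  A cohort simulator with known ground truth makes
every stage testable at desk scale.

# The models

## G-BLUP

The mixed model is

$$y = X b + g + e,\qquad g \sim N(0,\, G\,\sigma^2_g),\qquad
  e \sim N(0,\, I\,\sigma^2_e),$$

where $G$ is the genomic relationship matrix (VanRaden method 1):
$G = W W^\top / 2\sum_j p_j(1-p_j)$ with $W$ the genotype matrix centered
at twice the counted-allele frequencies.  Variance components are
estimated by REML.  Numerically, the training block of $G$ is
eigendecomposed once; the restricted likelihood is then a 1-D function of
the variance ratio $\lambda = \sigma^2_g/\sigma^2_e$, maximised by Brent
search on $\log\lambda \in [-14, 14]$ to a tolerance far below $10^{-6}$
on the ratio.  A fit whose optimum sits at the search boundary is flagged
`converged = FALSE`.  BLUPs for any individual — including individuals
never phenotyped — are $\hat g = \sigma^2_g\,G_{\cdot,T}\,V^{-1}(y_T - X_T
\hat b)$, so test individuals are predicted through their genomic
relationships with the training set.  A jitter of $10^{-8}$ is added to
the training diagonal and recorded in the fit; matrices that remain
indefinite beyond tolerance are rejected with a pointer to `ridge_eps`.

With both variances held fixed, the BLUPs coincide with ridge regression
on the centered genotypes at penalty $\lambda_r = 2\sum_j p_j q_j \cdot
\sigma^2_e / \sigma^2_g$; the test suite verifies this equivalence to
$10^{-6}$ against an independently coded ridge solver.

## Bayes C

Bayes C replaces the equal-variance assumption with a spike-and-slab on
SNP effects: each marker is excluded with probability $\pi$, included
effects share one normal variance, and $\pi$ itself carries a
Uniform(0, 1) prior and is estimated from the data.  The sampler is a
single-site Gibbs scheme written in C++ and driven by R's RNG, so chains
are bit-reproducible from `set.seed()`.  The hyperpriors are scaled
inverse-chi-square with $\nu = 4.2$ for both the effect and the residual
variance; their scales are set by method of moments (residual and genetic
variance each anchored at half the phenotypic variance, the per-effect
variance at the value implying that genetic variance if half the markers
were included).  These are package choices — weakly informative, and
surfaced as arguments — since no canonical values exist for this model
family.  Chain defaults are 10,000 iterations, 2,000 burn-in, thinning 10;
the comparative experiments in the tests use shorter chains
(2,500–3,000 iterations) because posterior means of $\pi$, the variances
and the effect sizes stabilise long before full-length chains at these
problem sizes.  Per-draw heritability is computed from the running genetic
values, so no extra matrix products are needed.  Setting `fix_pi = 0`
keeps every marker in the model, which reduces the sampler to
equal-variance ridge; its predictions then correlate > 0.99 with G-BLUP,
another identity the suite checks.

Bayes C is run without ancestry covariates by default: with markers free
to carry individual weights, the sampler absorbs large-scale structure
into SNP effects itself, whereas G-BLUP and the association scan receive
principal components as fixed covariates when the analyst supplies them.

## QTL hit-list regression

`fit_qtl_linear()` is ordinary least squares of the phenotype on all SNPs
of a supplied hit list jointly. Aliased (collinear) columns are dropped
with a warning and recorded; prediction uses the retained coefficients.

# The association scan

`run_gwas()` uses the two-step (GRAMMAR-style) approach: fit the polygenic
mixed model once on the training individuals, take its environmental
residuals, and regress those residuals on each SNP separately, with Wald
P-values on $t_{n-p-1}$.  The known deflation of this two-step scheme is
deliberately left uncorrected: downstream feature selection consumes only
the *ranks*, which are invariant to monotone rescaling of the test
statistic.  The genomic-control inflation factor is exposed via
`gc_lambda()`, and a naive single-marker OLS scan (`run_gwas_naive()`) is
provided as the comparator that shows why the polygenic adjustment is
needed in family-structured samples: on a trait driven purely by a shared
full-sib environment, the naive scan inflates ($\lambda \approx 1.5$ in
the test design) while the two-step scan sits nearer 1 — although, being
conservative, it undershoots rather than overshoots.  Monomorphic markers
receive $P = 1$, the last rank, and a flag.  Ranks are total and
deterministic: ties are broken by chromosome, position, then marker id.

The scan is also the package's leakage gate: it refuses to run when any
training id is flagged as a test member unless `leaky = TRUE` is passed
explicitly, and the provenance string it stamps on its output (and that
every feature subset inherits) records which samples informed it.

# Feature selection

* **UFS** — markers at stride $\lfloor m/\text{density}\rfloor$ along
  genome order from a seed-drawn offset; ten consecutive seeds give the
  conventional ten subsets per density.  Phenotype-free, hence leak-free.
  The default density ladder is
  `ufs_densities` = {100, 500, 1,000, 5,000, 10,000, 50,000, 100,000,
  150,000, 200,000, 250,000}, capped at the panel size.
* **SFS1** — top markers by scan rank, ignoring LD.
* **SFS2** — greedy rank-order pruning: take the best remaining marker,
  remove everything within the median marker interval (base-pair distance
  `msd` on the same chromosome, computed from the complete map, a
  phenotype-independent quantity), iterate until the panel is empty; the
  subset is the selection-order prefix.  `msd = 0` collapses to SFS1.
* **SFS3** — the same greedy pass defines intervals; each interval (hit
  plus neighbours, entered in rank order) is fitted jointly in one linear
  model on the polygenic residuals, and every member receives its
  conditional P-value from that model; the final subset is the
  genome-wide top by *conditional* P, not the greedy order.  Singleton
  intervals keep the marginal scan P verbatim, so isolated markers are
  ranked exactly as in SFS1.
* **SFS4** — as SFS3, but the joint models are per haplotype block.

Two total-order rules the source procedures leave open are fixed here:
collinear members of a joint model receive conditional $P = 1$ and hence
rank last (a deterministic convention; the first-entered, better-ranked
copy keeps the signal), and all final orderings break ties by map
position then marker id.  The median interval is global by default with a
per-chromosome option.  Joint models larger than the training set are
truncated (SFS3) or split at the worst-ranked marker (SFS4), with
warnings.

## Haplotype blocks

`detect_blocks()` implements the Gabriel confidence-interval method as
Haploview applies it by default.  Two-locus haplotype frequencies for
unphased genotype pairs come from an EM that splits only the double
heterozygote cell; the 90% interval on $|D'|$ is obtained by evaluating
the multinomial likelihood of the 3×3 genotype-pair table on a grid of
101 $|D'|$ values (allele frequencies fixed at their MLEs) and taking the
grid points below/above which 5% of the normalised likelihood mass lies —
the likelihood-mass construction Haploview actually uses, which we prefer
to a two-unit support interval precisely because "default Haploview
behaviour" is the specification.  Pairs are "strong LD" when the lower
bound ≥ 0.70 and the upper ≥ 0.98, "strong recombination" when the upper
< 0.90.  A candidate span is a block when informative pairs are ≥ 95%
strong-LD; candidates are accepted greedily, longest (marker count, then
bp span) first, without overlap; everything else becomes singleton
blocks, so the partition is total.  Spans are bounded at 500 kb and 60
markers — the latter a computational cap, far above simulated block
sizes.  Markers monomorphic in the sample carry no LD information and can
only end up as singletons; block-recovery checks therefore score the
polymorphic (MAF ≥ 0.05) span of each simulated block.

# Cross-validation and the leakage experiment

`make_folds()` partitions samples uniformly at random into K = 10 folds
(sizes differing by at most one), or into `round(1/test_fraction)` folds
when a held-out fraction is specified.  `run_cv()` requires `mode` to be
stated:

* **proper** — scan, selection, GRM centering frequencies and model
  training see training folds only;
* **leaky** — scan and selection see *all* samples; training still
  excludes test phenotypes.

Accuracy is the Pearson correlation between predicted and observed
phenotype in the held-out fold, summarised across folds by the mean and a
95% t-interval (the interval construction is a package choice).  Fold
models can be retained and applied unchanged to a replication cohort
(`predict_replication()`), with marker panels intersected and allele
orientation, centering and the GRM frame all frozen from training.

On a null trait the flagship property holds by construction: proper-mode
accuracy is centred at zero, while leaky-mode accuracy is substantially
positive (≈ 0.5 in the default experiment: top-100 markers from a
10,000-SNP panel, n = 1,000, ten folds), and the inflation is essentially
flat across held-out fractions of 1.25–10% — what matters is that the
test samples helped rank the markers at all, not how many of them there
are.  `leakage_null_experiment()` packages this experiment.

The theoretical accuracy expectation is implemented in the Daetwyler
form $r = \sqrt{n h^4 / (n h^2 + m_e)}$ (the phenotype-scale version,
i.e. $h \cdot r_{\hat g}$), with $m_e$ defaulting to the independent
segment count implied by a simulation config (`n_snps / block_length`).
The printed source for this formula is corrupted in the material the
package draws on, so the form itself is a documented package choice.  It
assumes unrelated individuals, independent loci and mass-univariate
information accrual; in that regime (the suite checks an n = 600,
m = 5,000, independent-marker design) simulated G-BLUP accuracy matches
it within ±0.07, while joint shrinkage beats the formula when markers
are fewer than phenotypes — a known limitation of the expectation, not of
the estimator.

# The cohort simulator

`simulate_cohort()` builds what the analyses assume, with every piece
returned as ground truth:

* **LD blocks** — markers are partitioned into blocks (~`block_length`
  SNPs, Poisson-distributed, never crossing a chromosome boundary; one
  chromosome per 1,000 markers at 1 kb spacing so base-pair radii mean
  something).  Each block has a pool of `founder_pool` (default 8)
  founder haplotypes generated on a random mutation genealogy
  (infinite-sites, no within-block recombination), so within-pool marker
  pairs are in complete LD ($|D'| = 1$) — the structure the Gabriel block
  definition detects.  With probability $1 -$ `within_block_corr` a
  marker instead segregates independently of the genealogy, so that
  parameter tunes the strength of within-block LD (0 = no LD).
  Individual haplotypes are per-block mosaics of the pool.
* **Stratification** — all sub-populations share the founder pools;
  differentiation comes from Dirichlet-distributed founder-usage weights
  whose total concentration $\alpha_0 = (1-F_{st})/F_{st}$ makes the
  between-population allele-frequency variance exactly $F_{st}$ times the
  pool heterozygosity (the Balding–Nichols parameter form, applied at the
  haplotype level).  The Weir–Cockerham estimator recovers the configured
  value (0.05 → 0.050 ± 0.002 in the calibration runs); defaults are
  0.005 within the study cohort and 0.01 for replication cohorts —
  placeholder magnitudes for "little differentiation among neighbouring
  isolates", chosen once, since no authoritative values are available.
* **Relatedness** — `n_families` sib-ships per sub-population (default
  10% of individuals in sib pairs) share two unsampled parents; their
  realised genomic relationship averages 0.50 as pedigree theory says.
* **Traits** — `n_qtl` causal SNPs with Gaussian effects, or the
  `few_large_plus_polygenic` mixture in which `n_moderate` = 5 loci carry
  half the genetic variance (an HDL-like architecture).  Phenotype =
  breeding value + Gaussian noise scaled so realised $h^2$ matches the
  configuration (verified to ±0.05 over seeds); phenotypes are
  standardised on output.  `qtl_typed_frac` < 1 removes part of the
  causal loci from the marker panel while keeping them in the trait —
  the array situation in which genome-wide similarity, not direct QTL
  genotypes, carries part of the signal.
* **Replication cohorts** — `simulate_replication()` offers three
  separations: same population (`related = TRUE`), different ancestry
  with consistent LD (same pools, fresh usage weights — the default,
  and the regime in which transfer reflects marker–QTL LD), and fully
  independent founders (`independent_founders = TRUE`, under which even
  LD signal does not transfer and within-cohort accuracy collapses the
  most).

The trait presets encode the three architectures the experiments
contrast: `height` ($h^2 = 0.8$, 1,000 QTL, half untyped — effectively
infinitesimal), `hdl` ($h^2 = 0.5$, 5 moderate loci + polygenic
background, all typed), `bmi` ($h^2 = 0.3$, 600 small QTL, half untyped).
Under these presets the replication ordering reproduces the expected
pattern: Bayes C ≥ G-BLUP for the HDL-like trait (sparse signal transfers
through LD), G-BLUP ≥ Bayes C for the height-like trait (aggregate
similarity beats selection when no individual locus is detectable).

What the simulator does *not* emulate: LD decay within blocks
(within-block LD is flat, between-block LD zero, rather than
distance-decaying), missing genotypes and genotyping error, imputation
uncertainty, non-Gaussian noise, X-linked loci, and assortative or
admixed mating structures.  Passing tests therefore demonstrate the
algorithms' correctness and their qualitative behaviour under controlled
structure, not performance on any real cohort; in particular real-data
accuracy values cannot be reproduced here, because the cohorts those
values came from are not public.

# Problem sizes used in the checks

The automated checks run at desk scale, chosen to keep the full suite
within tens of minutes on one core while leaving each property
well-resolved statistically: the leakage experiment uses 20 cohorts of
n = 1,000 × m = 10,000; heritability recovery uses n = 2,000 × m = 5,000
(10 seeds per architecture); the architecture-ordering experiment uses
n = 800 training / 400 replication × m = 2,000 with 10 seeds; scan
calibration uses m = 5,000.  The acceptance script
(`scripts/acceptance.R`) re-runs the same experiments at slightly reduced
seed counts and writes the resulting quantities as JSON.

# Known limitations

* REML is exact but $O(n^3)$ in the training size; tens of thousands of
  individuals would need sparse or randomised approaches out of scope
  here.
* The Gibbs sampler is single-site; at biobank marker counts its runtime
  grows linearly in markers × iterations, which is precisely the
  motivation for feature selection in the G-BLUP framework.
* GRAMMAR deflation is uncorrected by design; absolute P-values from
  `run_gwas()` are conservative and should not be compared across
  traits with different heritabilities — only ranks feed selection.
* The D' confidence grid has 0.01 resolution, matching the reference
  implementation; blocks whose evidence sits exactly at a threshold can
  flip with sample size, which is inherent to the method.
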