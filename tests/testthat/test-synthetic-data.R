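test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(h2 = 1.2), "h2")
  expect_error(sim_config(n_qtl = 50, n_snps = 20), "n_qtl")
  expect_error(sim_config(fst = 1), "fst")
  expect_error(sim_config(qtl_typed_frac = 2), "qtl_typed_frac")
  expect_error(sim_config(n_families = 300, n_individuals = 100), "exceeds")
})

test_that("the same seed reproduces the cohort bit for bit", {
  cfg <- sim_config(n_individuals = 60, n_snps = 300, n_qtl = 30, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$truth, b$truth)
})

test_that("marker maps are well formed and genotypes complete", {
  coh <- small_cohort()
  map <- coh$genotypes$map
  expect_false(anyNA(coh$genotypes$values))
  expect_true(all(coh$genotypes$values %in% 0:2))
  for (ch in unique(map$chr)) {
    expect_true(all(diff(map$pos[map$chr == ch]) > 0))
  }
})

test_that("a null-heritability trait carries no genetic signal", {
  coh <- simulate_cohort(sim_config(n_individuals = 1000, n_subpops = 2,
                                    n_snps = 1000, h2 = 0, seed = 11))
  expect_true(all(coh$truth$breeding_values == 0))
  expect_lt(abs(cor(coh$phenotype, coh$truth$genetic_score)), 0.05)
})

test_that("phenotype regressed on breeding values has unit slope", {
  coh <- simulate_cohort(sim_config(n_individuals = 1000, n_subpops = 2,
                                    n_snps = 5000, n_qtl = 500, h2 = 0.8,
                                    seed = 1))
  slope <- coef(lm(coh$phenotype ~ coh$truth$breeding_values))[2]
  expect_lt(abs(slope - 1), 0.1)
})

test_that("realized heritability tracks the configured h2", {
  for (h2 in c(0.3, 0.8)) {
    r <- vapply(1:10, function(s) {
      coh <- simulate_cohort(sim_config(n_individuals = 1000, n_subpops = 2,
                                        n_snps = 1000, n_qtl = 200, h2 = h2,
                                        seed = s))
      var(coh$truth$breeding_values) / var(coh$phenotype)
    }, numeric(1))
    expect_lt(abs(mean(r) - h2), 0.05)
  }
})

test_that("within-block genotype correlation dominates between-block", {
  coh <- simulate_cohort(sim_config(n_individuals = 500, n_subpops = 1,
                                    n_snps = 400, n_families = 0,
                                    within_block_corr = 0.5, seed = 9))
  C <- abs(suppressWarnings(cor(coh$genotypes$values)))
  blk <- coh$internals$blocks
  same <- outer(blk, blk, "==") & upper.tri(C)
  diff_ <- !outer(blk, blk, "==") & upper.tri(C)
  expect_gt(mean(C[same], na.rm = TRUE), 2 * mean(C[diff_], na.rm = TRUE))
})

test_that("untyped causal variants leave the panel but stay in the trait", {
  coh <- simulate_cohort(sim_config(n_individuals = 100, n_snps = 500,
                                    n_qtl = 100, qtl_typed_frac = 0.5,
                                    seed = 3))
  on_panel <- coh$truth$qtl_ids %in% coh$genotypes$map$id
  expect_equal(sum(on_panel), 50)
  expect_equal(nrow(coh$genotypes$map), 450)
  expect_equal(length(coh$truth$qtl_effects), 100)
})

test_that("Fst estimates are calibrated against the simulator", {
  coh0 <- simulate_cohort(sim_config(n_individuals = 1000, n_subpops = 2,
                                     n_snps = 5000, fst = 0,
                                     n_families = 0, seed = 7))
  expect_lt(abs(estimate_fst(coh0$genotypes)$mean), 0.005)

  coh5 <- simulate_cohort(sim_config(n_individuals = 1000, n_subpops = 2,
                                     n_snps = 5000, fst = 0.05,
                                     n_families = 0, seed = 8))
  expect_lt(abs(estimate_fst(coh5$genotypes)$mean - 0.05), 0.01)
})

test_that("Weir-Cockerham theta matches the hand-computed fixture", {
  ## pop1 genotypes (2,2,1,0), pop2 (0,0,1,1) at one SNP: theta = 1/9
  g <- toy_genotypes(matrix(c(2, 2, 1, 0, 0, 0, 1, 1), ncol = 1))
  labels <- rep(c("A", "B"), each = 4)
  est <- estimate_fst(g, labels)
  expect_equal(unname(est$per_snp[1]), 1 / 9, tolerance = 1e-12)
  expect_equal(est$mean, 1 / 9, tolerance = 1e-12)
})

test_that("Fst estimation rejects degenerate label sets", {
  g <- toy_genotypes(matrix(rbinom(20, 2, 0.4), ncol = 2))
  expect_error(estimate_fst(g, rep("A", 10)), "two sub-populations")
  expect_error(estimate_fst(g, c("A", rep("B", 9))), "at least 2")
  expect_error(estimate_fst(g, NULL), "labels")
})

test_that("identical sub-populations show near-zero Fst", {
  set.seed(21)
  vals <- sapply(runif(200, 0.2, 0.8), function(p) rbinom(800, 2, p))
  g <- toy_genotypes(vals)
  est <- estimate_fst(g, rep(c("A", "B"), each = 400))
  expect_lt(abs(est$mean), 0.005)
})

test_that("replication cohorts share panel, QTL and trait scaling", {
  coh <- small_cohort()
  rep_coh <- simulate_replication(coh, n_individuals = 300, seed = 5)
  expect_identical(rep_coh$genotypes$map$id, coh$genotypes$map$id)
  expect_identical(rep_coh$truth$qtl_ids, coh$truth$qtl_ids)
  h2r <- var(rep_coh$truth$breeding_values) / var(rep_coh$phenotype)
  expect_lt(abs(h2r - coh$config$h2), 0.1)
})
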