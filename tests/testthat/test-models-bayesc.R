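test_that("chains are bit-identical given the same seed and data", {
  coh <- simulate_cohort(sim_config(n_individuals = 100, n_snps = 200,
                                    n_qtl = 20, h2 = 0.5, seed = 19))
  ch <- list(n_iter = 600, burn_in = 100, thin = 5, seed = 77)
  a <- fit_bayesc(coh$genotypes, coh$phenotype, chain = ch)
  b <- fit_bayesc(coh$genotypes, coh$phenotype, chain = ch)
  expect_identical(a$pi_samples, b$pi_samples)
  expect_identical(a$effect_means, b$effect_means)
  expect_identical(a$h2_samples, b$h2_samples)
})

test_that("chain metadata is recorded and validated", {
  coh <- simulate_cohort(sim_config(n_individuals = 60, n_snps = 100,
                                    seed = 20))
  expect_error(fit_bayesc(coh$genotypes, coh$phenotype,
                          chain = list(n_iter = 100, burn_in = 200)),
               "burn_in")
  fit <- fit_bayesc(coh$genotypes, coh$phenotype,
                    chain = list(n_iter = 300, burn_in = 100, thin = 2,
                                 seed = 5))
  expect_equal(fit$chain_meta,
               list(n_iter = 300, burn_in = 100, thin = 2, seed = 5))
  expect_true(all(fit$pi_samples >= 0 & fit$pi_samples <= 1))
  expect_true(all(fit$inclusion_probs >= 0 & fit$inclusion_probs <= 1))
})

test_that("a pure-noise phenotype drives the exclusion proportion up", {
  coh <- simulate_cohort(sim_config(n_individuals = 500, n_subpops = 2,
                                    n_snps = 2000, h2 = 0, seed = 31))
  fit <- fit_bayesc(coh$genotypes, coh$phenotype,
                    chain = list(n_iter = 3000, burn_in = 1000, thin = 5,
                                 seed = 1))
  expect_gte(fit$pi_hat, 0.95)
})

test_that("large-effect QTL dominate the inclusion-probability ranking", {
  coh <- simulate_cohort(sim_config(n_individuals = 500, n_subpops = 2,
                                    n_snps = 2000, n_qtl = 10, h2 = 0.5,
                                    seed = 11))
  fit <- fit_bayesc(coh$genotypes, coh$phenotype,
                    chain = list(n_iter = 2000, burn_in = 500, thin = 5,
                                 seed = 3))
  top <- names(sort(fit$inclusion_probs, decreasing = TRUE))[1:30]
  blk <- coh$internals$blocks
  qtl_blocks <- blk[match(coh$truth$qtl_ids, coh$genotypes$map$id)]
  top_blocks <- blk[match(top, coh$genotypes$map$id)]
  ## each QTL, or an LD block-mate, should surface near the top
  expect_gte(sum(qtl_blocks %in% top_blocks), 8)
})

test_that("with exclusion disabled the sampler agrees with G-BLUP", {
  coh <- simulate_cohort(sim_config(n_individuals = 100, n_subpops = 1,
                                    n_snps = 300, n_qtl = 50, h2 = 0.5,
                                    seed = 2))
  fb <- fit_bayesc(coh$genotypes, coh$phenotype,
                   chain = list(n_iter = 3000, burn_in = 1000, thin = 5,
                                seed = 4), fix_pi = 0)
  fg <- fit_gblup(compute_grm(coh$genotypes), coh$phenotype)
  expect_gt(cor(predict(fb, coh$genotypes), fg$blups), 0.99)
  ## every polymorphic marker stays in the model at every draw
  poly <- allele_freqs(coh$genotypes) %in% c(0, 1) == FALSE
  expect_true(all(fb$inclusion_probs[poly] == 1))
})

test_that("posterior-mean heritability agrees with REML on polygenic data", {
  coh <- simulate_cohort(sim_config(n_individuals = 500, n_subpops = 2,
                                    n_snps = 1000, n_qtl = 200, h2 = 0.5,
                                    seed = 23))
  fg <- fit_gblup(compute_grm(coh$genotypes), coh$phenotype)
  fb <- fit_bayesc(coh$genotypes, coh$phenotype,
                   chain = list(n_iter = 2500, burn_in = 500, thin = 5,
                                seed = 6))
  expect_lt(abs(fb$h2_hat - fg$h2_hat), 0.1)
})

test_that("prediction freezes centering at the training frequencies", {
  coh <- small_cohort()
  ids <- coh$genotypes$sample_ids
  train <- ids[1:400]
  test <- ids[401:500]
  fit <- fit_bayesc(coh$genotypes, coh$phenotype, train_ids = train,
                    markers = coh$genotypes$map$id[1:200],
                    chain = list(n_iter = 500, burn_in = 100, thin = 5,
                                 seed = 9))
  expect_equal(fit$allele_freqs,
               allele_freqs(coh$genotypes,
                            ids = train)[coh$genotypes$map$id[1:200]])
  pred <- predict(fit, coh$genotypes, test_ids = test)
  expect_equal(names(pred), test)
  ## markers absent from the prediction panel are an error, with ids listed
  sub <- coh$genotypes
  keep <- coh$genotypes$map$id[5:200]
  sub$values <- sub$values[, keep]
  sub$map <- sub$map[5:200, ]
  expect_error(predict(fit, sub), "missing")
})
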