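test_that("fold plans are balanced, reproducible and validated", {
  ids20 <- sprintf("S%02d", 1:20)
  plan <- make_folds(ids20, K = 10, seed = 1)
  expect_true(all(table(plan$fold) == 2))
  ids21 <- sprintf("S%02d", 1:21)
  plan21 <- make_folds(ids21, K = 10, seed = 1)
  expect_lte(diff(range(table(plan21$fold))), 1)
  expect_identical(make_folds(ids21, K = 10, seed = 9)$fold,
                   make_folds(ids21, K = 10, seed = 9)$fold)
  expect_error(make_folds(ids20, K = 25, seed = 1), "exceed")
  expect_error(make_folds(ids20, K = 1, seed = 1), "at least 2")
  tf <- make_folds(sprintf("S%03d", 1:400), seed = 2, test_fraction = 0.05)
  expect_equal(tf$K, 20)
  expect_true(all(table(tf$fold) == 20))
})

test_that("accuracy is the Pearson correlation with input checks", {
  expect_equal(accuracy(2 * (1:10), 1:10), 1)
  expect_equal(accuracy(-(1:10), 1:10), -1)
  ## hand 4-point set: cor computed once by hand
  pred <- c(1, 2, 3, 5)
  obs <- c(2, 1, 4, 4)
  hand <- 5.75 / sqrt(8.75 * 6.75)
  expect_equal(accuracy(pred, obs), hand, tolerance = 1e-12)
  expect_error(accuracy(c(1, 2), c(1, 2)), "at least 3")
  expect_error(accuracy(rep(1, 5), 1:5), "constant")
  a <- setNames(1:5, paste0("s", 1:5))
  b <- setNames(c(5:1, 9), paste0("s", c(1:5, 9)))
  expect_equal(accuracy(a, b), -1)  # aligned by name, extras dropped
})

test_that("the theoretical accuracy expectation behaves as a Daetwyler
           form should", {
  expect_equal(expected_accuracy(1, 100, 0), 1)
  expect_equal(expected_accuracy(0, 1000, 500), 0)
  h2s <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(sapply(h2s, expected_accuracy,
                              n_train = 500, m_eff = 1000)) > 0))
  ns <- c(100, 500, 2000, 10000)
  expect_true(all(diff(sapply(ns, function(n) {
    expected_accuracy(0.5, n, 1000)
  })) > 0))
  ms <- c(100, 1000, 10000)
  expect_true(all(diff(sapply(ms, function(m) {
    expected_accuracy(0.5, 500, m)
  })) < 0))
  ## n -> infinity limit is sqrt(h2)
  expect_equal(expected_accuracy(0.5, 1e12, 1000), sqrt(0.5),
               tolerance = 1e-6)
})

test_that("the leakage mode must be chosen explicitly", {
  coh <- small_cohort()
  plan <- make_folds(coh$genotypes$sample_ids, K = 5, seed = 1)
  expect_error(run_cv(coh$genotypes, coh$phenotype, plan = plan,
                      model = "gblup", selection = "full"),
               "explicitly")
})

test_that("without a selection step the two modes coincide", {
  coh <- simulate_cohort(sim_config(n_individuals = 100, n_subpops = 2,
                                    n_snps = 400, n_qtl = 50, h2 = 0.5,
                                    seed = 55))
  plan <- make_folds(coh$genotypes$sample_ids, K = 4, seed = 2)
  a <- run_cv(coh$genotypes, coh$phenotype, plan = plan, model = "gblup",
              selection = "full", mode = "proper")
  b <- run_cv(coh$genotypes, coh$phenotype, plan = plan, model = "gblup",
              selection = "full", mode = "leaky")
  expect_equal(a$per_fold$accuracy, b$per_fold$accuracy, tolerance = 1e-12)
})

test_that("cv reports carry their audit fields", {
  coh <- simulate_cohort(sim_config(n_individuals = 100, n_subpops = 2,
                                    n_snps = 400, n_qtl = 50, h2 = 0.5,
                                    seed = 56))
  plan <- make_folds(coh$genotypes$sample_ids, K = 4, seed = 2)
  rep_ <- run_cv(coh$genotypes, coh$phenotype, plan = plan,
                 model = "gblup",
                 selection = list(method = "SFS1", density = 30),
                 mode = "leaky")
  expect_equal(rep_$selection_mode, "leaky")
  expect_match(rep_$selection_provenance, "leaky")
  expect_match(rep_$selection, "SFS1")
  expect_true(nzchar(rep_$config_hash))
  expect_true(all(abs(rep_$per_fold$accuracy) <= 1))
})

test_that("a replication cohort identical to the training cohort scores
           like the training cohort itself", {
  coh <- simulate_cohort(sim_config(n_individuals = 120, n_subpops = 1,
                                    n_snps = 400, n_qtl = 50, h2 = 0.8,
                                    seed = 57))
  plan <- make_folds(coh$genotypes$sample_ids, K = 4, seed = 3)
  rep_ <- run_cv(coh$genotypes, coh$phenotype, plan = plan,
                 model = "gblup", selection = "full", mode = "proper",
                 keep_models = TRUE)
  back <- predict_replication(rep_, coh$genotypes, coh$genotypes,
                              coh$phenotype)
  for (k in seq_along(rep_$models)) {
    manual <- accuracy(rep_$models[[k]]$fit$blups, coh$phenotype)
    expect_equal(back$per_fold$accuracy[k], manual, tolerance = 1e-6)
  }
})

test_that("within-cohort accuracy exceeds replication accuracy for a
           polygenic trait", {
  coh <- simulate_cohort(sim_config(n_individuals = 300, n_subpops = 2,
                                    n_snps = 1000, n_qtl = 300, h2 = 0.8,
                                    seed = 58))
  plan <- make_folds(coh$genotypes$sample_ids, K = 5, seed = 4)
  within <- run_cv(coh$genotypes, coh$phenotype, plan = plan,
                   model = "gblup", selection = "full", mode = "proper",
                   keep_models = TRUE)
  rep_coh <- simulate_replication(coh, n_individuals = 300,
                                  independent_founders = TRUE, seed = 59)
  rep_acc <- predict_replication(within, coh$genotypes, rep_coh$genotypes,
                                 rep_coh$phenotype)
  expect_gt(within$mean, rep_acc$mean)
})

test_that("whole-data selection manufactures accuracy on a null trait", {
  lk <- leakage_null_experiment(seeds = 1:3, n_individuals = 250,
                                n_subpops = 2, n_snps = 2000,
                                density = 50, K = 5)
  prop <- lk$accuracy[lk$mode == "proper"]
  leak <- lk$accuracy[lk$mode == "leaky"]
  expect_gt(mean(leak), mean(prop) + 0.1)
  expect_lt(abs(mean(prop)), 0.15)
})

test_that("the harness runs every model and selection method end to end", {
  coh <- simulate_cohort(sim_config(n_individuals = 120, n_subpops = 2,
                                    n_snps = 500, n_qtl = 20, h2 = 0.6,
                                    seed = 60))
  plan <- make_folds(coh$genotypes$sample_ids, K = 3, seed = 6)
  combos <- list(
    list(model = "gblup", selection = list(method = "UFS", density = 80)),
    list(model = "gblup", selection = list(method = "SFS2", density = 80)),
    list(model = "gblup", selection = list(method = "SFS3", density = 80)),
    list(model = "gblup", selection = list(method = "SFS4", density = 80)),
    list(model = "bayesc", selection = list(method = "SFS1", density = 80)),
    list(model = "qtl_linear",
         selection = list(method = "SFS1", density = 20)))
  blocks <- detect_blocks(coh$genotypes)
  for (cb in combos) {
    ## collinear block-mates in a hit list legitimately warn; not under test
    rep_ <- suppressWarnings(
      run_cv(coh$genotypes, coh$phenotype, plan = plan,
             model = cb$model, selection = cb$selection,
             mode = "proper", blocks = blocks,
             chain = list(n_iter = 400, burn_in = 100, thin = 2,
                          seed = 1)))
    expect_s3_class(rep_, "cv_report")
    expect_true(all(is.finite(rep_$per_fold$accuracy)))
    expect_true(all(abs(rep_$per_fold$accuracy) <= 1))
  }
})
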