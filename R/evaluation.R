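#' Build a cross-validation plan
#'
#' Uniform random partition of the samples into `K` folds of roughly equal
#' size (sizes differ by at most one), reproducible from `seed`.  For the
#' test-fraction experiments, `test_fraction` overrides `K` with
#' `round(1 / test_fraction)` folds so each held-out fold contains
#' approximately that fraction of the samples.
#'
#' @param sample_ids character vector of sample ids.
#' @param K number of folds (default 10).
#' @param seed integer seed.
#' @param test_fraction optional held-out fraction (e.g. 0.0125, 0.025,
#'   0.05, 0.10) overriding `K`.
#' @return An object of class `cv_plan`: `fold` (named integer vector), `K`,
#'   `seed`, `test_fraction`.
#' @export
make_folds <- function(sample_ids, K = 10, seed = 1, test_fraction = NULL) {
  n <- length(sample_ids)
  if (!is.null(test_fraction)) {
    stopifnot(test_fraction > 0, test_fraction < 0.5)
    K <- max(2L, as.integer(round(1 / test_fraction)))
  }
  if (K < 2) stop("K must be at least 2 (or supply test_fraction)")
  if (K > n) stop("K may not exceed the number of samples")
  set.seed(seed)
  fold <- sample(rep(seq_len(K), length.out = n))
  names(fold) <- sample_ids
  structure(list(fold = fold, K = K, seed = seed,
                 test_fraction = test_fraction),
            class = "cv_plan")
}

#' Prediction accuracy (Pearson correlation)
#'
#' @param pred,obs numeric vectors; if both are named they are aligned by
#'   name.  At least 3 pairs, neither constant.
#' @return the Pearson correlation.
#' @export
accuracy <- function(pred, obs) {
  if (!is.null(names(pred)) && !is.null(names(obs))) {
    common <- intersect(names(pred), names(obs))
    pred <- pred[common]
    obs <- obs[common]
  }
  keep <- complete.cases(pred, obs)
  pred <- pred[keep]; obs <- obs[keep]
  if (length(pred) < 3) stop("need at least 3 prediction/observation pairs")
  if (sd(pred) == 0 || sd(obs) == 0) stop("constant input; accuracy undefined")
  cor(pred, obs)
}

## t-interval across fold accuracies
fold_ci <- function(acc, level = 0.95) {
  acc <- acc[is.finite(acc)]
  k <- length(acc)
  m <- mean(acc)
  if (k < 2) return(c(mean = m, lower = NA, upper = NA))
  half <- qt(1 - (1 - level) / 2, k - 1) * sd(acc) / sqrt(k)
  c(mean = m, lower = m - half, upper = m + half)
}

#' Theoretical expectation of prediction accuracy
#'
#' Daetwyler-form expectation for the accuracy of predicting the
#' *phenotype*: `r = h * sqrt(n h2 / (n h2 + m_eff))`, equivalently
#' `sqrt(n h2^2 / (n h2 + m_eff))`, with `m_eff` the number of independent
#' chromosome segments.  Monotone increasing in `h2` and `n`, decreasing in
#' `m_eff`; tends to `sqrt(h2)` as `n` grows and to 1 in the degenerate
#' limit `h2 -> 1`, `m_eff -> 0`.
#'
#' @param h2 heritability in `[0, 1]`.
#' @param n_train training-set size.
#' @param m_eff effective number of independent segments; for simulated
#'   cohorts [m_eff_from_config()] supplies a sensible default.
#' @return expected accuracy (0 when `h2 = 0`).
#' @export
expected_accuracy <- function(h2, n_train, m_eff) {
  stopifnot(h2 >= 0, h2 <= 1, n_train > 0, m_eff >= 0)
  if (h2 == 0) return(0)
  sqrt(n_train * h2^2 / (n_train * h2 + m_eff))
}

#' Effective segment count implied by a simulation config
#'
#' The simulator's LD blocks are (nearly) independent, so the implied number
#' of independent segments is the expected block count,
#' `n_snps / block_length`.
#'
#' @param config a [sim_config()].
#' @return numeric, the implied `m_eff`.
#' @export
m_eff_from_config <- function(config) {
  config$n_snps / config$block_length
}

## polynomial rolling hash of a serialised R object; cheap run-config
## fingerprint (not cryptographic)
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Cross-validated genomic prediction with explicit leakage mode
#'
#' Runs K-fold cross-validation of a prediction model combined with a
#' feature-selection method.  The `mode` argument is mandatory and audited:
#'
#' * `"proper"` -- for each fold, the association scan, the feature
#'   selection, the GRM allele frequencies and the model training all use
#'   the training samples only;
#' * `"leaky"` -- the scan and the selection use *all* samples (train +
#'   test), deliberately reproducing the biased protocol in which features
#'   are chosen on the whole data set; model training still excludes test
#'   phenotypes.
#'
#' With `selection = "full"` there is no selection step and the two modes
#' coincide.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param phenotype named numeric vector.
#' @param covariates optional fixed covariates for G-BLUP and the scan
#'   (e.g. ancestry PCs).
#' @param plan a [make_folds()] plan.
#' @param model `"gblup"`, `"bayesc"` or `"qtl_linear"`.
#' @param selection `"full"`, or a list `list(method =, density =)` with
#'   method one of `"UFS"`, `"SFS1"`, `"SFS2"`, `"SFS3"`, `"SFS4"`.
#' @param mode `"proper"` or `"leaky"`; no default -- leakage must be an
#'   explicit choice.
#' @param msd pruning radius for SFS2/SFS3; default
#'   [median_marker_interval()] of the full map.
#' @param blocks `haplotype_blocks` for SFS4; computed once from the
#'   genotypes (phenotype-free) if not supplied.
#' @param chain Bayes C chain settings (see [fit_bayesc()]).
#' @param bayesc_covariates covariates for Bayes C; `NULL` by default (the
#'   sampler's selected SNPs absorb structure themselves).
#' @param max_folds evaluate only the first `max_folds` folds (a sampling
#'   economy for the many-fold test-fraction plans); default all.
#' @param keep_models retain per-fold fitted models (needed by
#'   [predict_replication()]).
#' @return An object of class `cv_report`: `per_fold` (fold, n_test,
#'   accuracy), `mean`, `ci` (95% t-interval across folds),
#'   `selection_mode`, `model`, `selection`, `config_hash`, and `models`
#'   when requested.
#' @export
run_cv <- function(genotypes, phenotype, covariates = NULL, plan,
                   model = c("gblup", "bayesc", "qtl_linear"),
                   selection = "full", mode, msd = NULL, blocks = NULL,
                   chain = list(n_iter = 3000, burn_in = 1000, thin = 5,
                                seed = 1),
                   bayesc_covariates = NULL, max_folds = NULL,
                   keep_models = FALSE) {
  if (missing(mode)) {
    stop("mode must be given explicitly: \"proper\" or \"leaky\"")
  }
  mode <- match.arg(mode, c("proper", "leaky"))
  model <- match.arg(model)
  stopifnot(inherits(plan, "cv_plan"))
  ids <- names(plan$fold)
  stopifnot(all(ids %in% genotypes$sample_ids),
            all(ids %in% names(phenotype)))
  map <- genotypes$map
  sel_is_list <- is.list(selection)
  method <- if (sel_is_list) selection$method else "full"
  supervised <- method %in% c("SFS1", "SFS2", "SFS3", "SFS4")
  if (supervised || model == "gblup") {
    ## raw cross-product reused for every per-fold GRM (rank-one corrected
    ## to fold-specific centering inside compute_grm)
    xxt <- tcrossprod(genotypes$values[ids, , drop = FALSE])
  }
  if (method %in% c("SFS2", "SFS3") && is.null(msd)) {
    msd <- median_marker_interval(map)
  }
  if (method == "SFS4" && is.null(blocks)) {
    blocks <- detect_blocks(genotypes, train_ids = ids)
  }
  gwas_all <- NULL
  if (supervised && mode == "leaky") {
    grm_all <- compute_grm_ids(genotypes, ids, ids, xxt)
    gwas_all <- run_gwas(genotypes, phenotype, covariates, grm_all,
                         train_ids = ids, test_ids = ids, leaky = TRUE,
                         dataset = "ALL")
  }

  folds <- seq_len(plan$K)
  if (!is.null(max_folds)) folds <- head(folds, max_folds)
  per_fold <- data.frame(fold = folds, n_test = NA_integer_,
                         accuracy = NA_real_)
  models <- if (keep_models) vector("list", length(folds)) else NULL

  for (fi in seq_along(folds)) {
    f <- folds[fi]
    test <- ids[plan$fold == f]
    train <- setdiff(ids, test)
    ## --- feature selection ---
    if (!sel_is_list) {
      markers <- map$id
      sel_prov <- "full"
    } else if (method == "UFS") {
      sub <- select_unsupervised(map, selection$density,
                                 seed = plan$seed * 1000L + f)
      markers <- sub$marker_ids
      sel_prov <- sub$provenance
    } else {
      gw <- if (mode == "leaky") gwas_all else {
        grm_tr <- compute_grm_ids(genotypes, ids, train, xxt)
        run_gwas(genotypes, phenotype, covariates, grm_tr,
                 train_ids = train, test_ids = test, leaky = FALSE,
                 dataset = sprintf("fold%d", f))
      }
      sub <- switch(method,
        SFS1 = select_sfs1(gw, selection$density),
        SFS2 = select_sfs2(gw, selection$density, msd),
        SFS3 = select_sfs3(gw, genotypes, selection$density, msd),
        SFS4 = select_sfs4(gw, genotypes, blocks, selection$density))
      markers <- sub$marker_ids
      sel_prov <- sub$provenance
    }
    ## --- model training (training phenotypes only, training freqs) ---
    tr_freqs <- allele_freqs(genotypes, ids = train)
    fit <- switch(model,
      gblup = {
        grm_sel <- if (!sel_is_list) {
          compute_grm_ids(genotypes, ids, train, xxt)
        } else {
          compute_grm(genotypes, freqs = tr_freqs[markers],
                      markers = markers)
        }
        fit_gblup(grm_sel, phenotype, covariates, train_ids = train)
      },
      bayesc = {
        ch <- chain
        ch$seed <- chain$seed * 1000L + f
        fit_bayesc(genotypes, phenotype, bayesc_covariates,
                   train_ids = train, markers = markers, chain = ch)
      },
      qtl_linear = {
        hits <- markers
        cap <- floor(length(train) / 2)
        if (length(hits) > cap) {
          warning("hit list truncated to ", cap, " markers for OLS")
          hits <- head(hits, cap)
        }
        fit_qtl_linear(genotypes, phenotype, hits, covariates,
                       train_ids = train)
      })
    pred <- switch(model,
      gblup = predict(fit, test_ids = test),
      bayesc = predict(fit, genotypes, test_ids = test),
      qtl_linear = predict(fit, genotypes, test_ids = test))
    per_fold$n_test[fi] <- length(test)
    per_fold$accuracy[fi] <- accuracy(pred, phenotype[test])
    if (keep_models) {
      models[[fi]] <- list(fold = f, model = model, fit = fit,
                           markers = markers, freqs = tr_freqs[markers],
                           train_ids = train)
    }
  }
  ci <- fold_ci(per_fold$accuracy)
  structure(
    list(per_fold = per_fold, mean = unname(ci["mean"]),
         ci = ci[c("lower", "upper")], selection_mode = mode,
         model = model,
         selection = if (sel_is_list) {
           sprintf("%s@%d", method, selection$density)
         } else "full",
         selection_provenance = if (exists("sel_prov")) sel_prov else NA,
         plan = plan,
         config_hash = config_hash(list(plan$seed, plan$K, model, selection,
                                        mode, msd)),
         models = models),
    class = "cv_report"
  )
}

## full-panel GRM for a training subset, centered/scaled at that subset's
## frequencies, but covering all `ids` rows (so test rows are projected
## into the training frame)
compute_grm_ids <- function(genotypes, ids, train, xxt) {
  freqs <- allele_freqs(genotypes, ids = train)
  sub <- list(values = genotypes$values[ids, , drop = FALSE],
              map = genotypes$map, sample_ids = ids, subpop = NULL)
  class(sub) <- "gp_genotypes"
  compute_grm(sub, freqs = freqs, xxt = xxt)
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf(
    "cv_report [%s, %s, %s mode]: mean accuracy %.3f (95%% CI %.3f..%.3f) over %d folds\n",
    x$model, x$selection, x$selection_mode, x$mean, x$ci[1], x$ci[2],
    nrow(x$per_fold)))
  invisible(x)
}

#' Score cross-validation fold models on a replication cohort
#'
#' Applies every fold-trained model from a [run_cv()] report (run with
#' `keep_models = TRUE`) to an independent replication cohort and reports
#' per-fold and mean accuracy there.  Marker panels are intersected (and
#' the loss logged); allele orientation, centering frequencies and the GRM
#' frame are all frozen from the training folds.
#'
#' @param report a `cv_report` with retained models.
#' @param genotypes the training-cohort genotypes (needed for G-BLUP
#'   cross-relationships).
#' @param rep_genotypes,rep_phenotype the replication cohort.
#' @return list with `per_fold` (fold, n_markers, accuracy), `mean`, `ci`.
#' @export
predict_replication <- function(report, genotypes, rep_genotypes,
                                rep_phenotype) {
  stopifnot(inherits(report, "cv_report"))
  if (is.null(report$models)) {
    stop("run_cv must be called with keep_models = TRUE")
  }
  res <- data.frame(fold = vapply(report$models, `[[`, numeric(1), "fold"),
                    n_markers = NA_integer_, accuracy = NA_real_)
  for (k in seq_along(report$models)) {
    mk <- report$models[[k]]
    common <- intersect(mk$markers, rep_genotypes$map$id)
    if (length(common) == 0) stop("no markers shared with the replication ",
                                  "cohort")
    if (length(common) < length(mk$markers)) {
      message(length(mk$markers) - length(common),
              " training markers absent from the replication panel")
    }
    pred <- switch(mk$model,
      gblup = {
        K <- grm_cross(rep_genotypes, genotypes, freqs = mk$freqs,
                       markers = common, ids_ref = mk$fit$train_ids)
        predict(mk$fit, grm_cross = K)
      },
      bayesc = {
        W <- center_genotypes(rep_genotypes, mk$fit$allele_freqs,
                              markers = intersect(mk$fit$marker_ids, common))
        setNames(drop(W %*% mk$fit$effect_means[colnames(W)]),
                 rep_genotypes$sample_ids)
      },
      qtl_linear = {
        keep <- intersect(mk$fit$snp_ids, common)
        Xs <- rep_genotypes$values[, keep, drop = FALSE]
        setNames(mk$fit$intercept +
                   drop(Xs %*% mk$fit$coefficients[keep]),
                 rep_genotypes$sample_ids)
      })
    res$n_markers[k] <- length(common)
    res$accuracy[k] <- accuracy(pred, rep_phenotype)
  }
  ci <- fold_ci(res$accuracy)
  list(per_fold = res, mean = unname(ci["mean"]),
       ci = ci[c("lower", "upper")])
}

#' The selection-leakage experiment on a null trait
#'
#' The package's flagship regression experiment: simulate cohorts with zero
#' heritability, run K-fold cross-validated G-BLUP on a supervised feature
#' subset twice per cohort -- once with selection restricted to the training
#' folds ("proper") and once with selection computed on all samples
#' ("leaky") -- and return the mean accuracy of each run.  With no genetic
#' signal, proper selection must average to zero accuracy while whole-data
#' selection manufactures apparent accuracy.
#'
#' @param seeds simulation seeds (one cohort per seed).
#' @param n_individuals,n_subpops,n_snps cohort dimensions (defaults
#'   500 x 2 subpopulations, 10,000 SNPs).
#' @param density selected-subset size (default 100).
#' @param K folds (default 10).
#' @param test_fraction optional held-out fraction instead of `K`.
#' @param max_folds evaluate only this many folds per cohort.
#' @param cohorts optional pre-simulated cohorts to reuse (must match
#'   `seeds` in length); a convenience when comparing several
#'   `test_fraction` settings on identical data.
#' @param modes which modes to run (default both).
#' @return data frame with columns `seed`, `mode`, `accuracy` (mean over
#'   folds).
#' @export
leakage_null_experiment <- function(seeds = 1:20, n_individuals = 500,
                                    n_subpops = 2, n_snps = 10000,
                                    density = 100, K = 10,
                                    test_fraction = NULL, max_folds = NULL,
                                    cohorts = NULL,
                                    modes = c("proper", "leaky")) {
  out <- list()
  for (k in seq_along(seeds)) {
    coh <- if (!is.null(cohorts)) cohorts[[k]] else {
      simulate_cohort(sim_config(n_individuals = n_individuals,
                                 n_subpops = n_subpops, n_snps = n_snps,
                                 h2 = 0, n_qtl = 100, seed = seeds[k]))
    }
    plan <- make_folds(coh$genotypes$sample_ids, K = K, seed = seeds[k],
                       test_fraction = test_fraction)
    for (mode in modes) {
      rep_ <- run_cv(coh$genotypes, coh$phenotype, plan = plan,
                     model = "gblup",
                     selection = list(method = "SFS1", density = density),
                     mode = mode, max_folds = max_folds)
      out[[length(out) + 1]] <- data.frame(seed = seeds[k], mode = mode,
                                           accuracy = rep_$mean)
    }
  }
  do.call(rbind, out)
}
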