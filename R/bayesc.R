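#' Fit Bayes C by Gibbs sampling
#'
#' Whole-genome regression `y = X b + sum_j w_j a_j d_j + e` in which each
#' SNP effect is excluded (`d_j = 0`) with probability `pi`, included effects
#' share a common variance `sigma2_b` with a scaled-inverse-chi-square prior,
#' `pi` has a Uniform(0, 1) prior and is estimated from the data, and the
#' residual variance has a scaled-inverse-chi-square prior.  Genotypes are
#' column-centered internally at the training allele frequencies; the chain
#' is reproducible from `chain$seed`.
#'
#' Hyperparameters default to weakly informative `nu = 4.2` scaled-inverse-
#' chi-square priors whose prior means are set by method of moments: the
#' residual and genetic variances are each anchored at half the phenotypic
#' variance, and the per-effect variance at the value that would produce that
#' genetic variance if half the markers were included.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param phenotype named numeric vector.
#' @param covariates optional fixed covariates (row names = sample ids); an
#'   intercept is always fitted.
#' @param train_ids individuals used for fitting; default: all with
#'   non-missing phenotype.
#' @param markers optional marker subset (e.g. a selected feature panel).
#' @param chain list with `n_iter`, `burn_in`, `thin`, `seed` (defaults
#'   10000 / 2000 / 10 / 1); `n_iter > burn_in` required.
#' @param fix_pi optional fixed exclusion proportion; `fix_pi = 0` keeps
#'   every marker in the model, which turns the sampler into equal-variance
#'   ridge and should agree with G-BLUP.
#' @param nu_b,nu_e prior degrees of freedom (default 4.2).
#' @return An object of class `bayesc_fit`: posterior draws of `pi` and the
#'   variances, per-draw heritability, per-SNP posterior mean effects
#'   (`effect_means`, i.e. `E[a_j d_j]`) and inclusion probabilities, fixed
#'   effect posterior means, `h2_hat`, `pi_hat`, the allele frequencies used
#'   for centering, and the full `chain_meta`.
#' @export
fit_bayesc <- function(genotypes, phenotype, covariates = NULL,
                       train_ids = NULL, markers = NULL,
                       chain = list(n_iter = 10000, burn_in = 2000,
                                    thin = 10, seed = 1),
                       fix_pi = NULL, nu_b = 4.2, nu_e = 4.2) {
  defaults <- list(n_iter = 10000, burn_in = 2000, thin = 10, seed = 1)
  defaults[names(chain)] <- chain
  chain <- defaults
  if (chain$n_iter <= chain$burn_in) stop("n_iter must exceed burn_in")
  if (is.null(train_ids)) {
    train_ids <- intersect(genotypes$sample_ids,
                           names(phenotype)[!is.na(phenotype)])
  }
  y <- phenotype[train_ids]
  if (sd(y) == 0) stop("phenotype is constant in the training set")
  if (is.null(markers)) markers <- genotypes$map$id
  freqs <- allele_freqs(genotypes, ids = train_ids)[markers]
  W <- center_genotypes(genotypes, freqs, ids = train_ids, markers = markers)
  X <- build_design(covariates, train_ids)
  m <- ncol(W)

  ## method-of-moments prior scales (scaled-inv-chi2 mean = nu s2 / (nu - 2))
  vy <- var(y)
  var_e0 <- 0.5 * vy
  sum2pq <- 2 * sum(freqs * (1 - freqs))
  var_b0 <- if (sum2pq > 0) (0.5 * vy) / (0.5 * sum2pq) else 0.5 * vy
  s2_e <- var_e0 * (nu_e - 2) / nu_e
  s2_b <- var_b0 * (nu_b - 2) / nu_b

  pi_fixed <- if (is.null(fix_pi)) -1 else fix_pi
  set.seed(chain$seed)
  out <- bayesc_gibbs(W, unname(y), X,
                      as.integer(chain$n_iter), as.integer(chain$burn_in),
                      as.integer(chain$thin), nu_b, s2_b, nu_e, s2_e,
                      pi_fixed, var_b0, var_e0)
  names(out$effect_means) <- names(out$inclusion_probs) <- markers
  names(out$fixed_effect_means) <- colnames(X)

  structure(
    list(pi_samples = out$pi_samples,
         sigma2_b_samples = out$sigma2_b_samples,
         sigma2_e_samples = out$sigma2_e_samples,
         h2_samples = out$h2_samples,
         effect_means = out$effect_means,
         inclusion_probs = out$inclusion_probs,
         fixed_effect_means = out$fixed_effect_means,
         h2_hat = mean(out$h2_samples),
         pi_hat = mean(out$pi_samples),
         allele_freqs = freqs, marker_ids = markers,
         train_ids = train_ids,
         chain_meta = chain),
    class = "bayesc_fit"
  )
}

#' @export
print.bayesc_fit <- function(x, ...) {
  cat(sprintf(
    "bayesc_fit: %d markers, n_train = %d, pi_hat = %.3f, h2_hat = %.3f\n",
    length(x$marker_ids), length(x$train_ids), x$pi_hat, x$h2_hat))
  cat(sprintf("  chain: %d iterations, burn-in %d, thin %d, seed %s\n",
              x$chain_meta$n_iter, x$chain_meta$burn_in, x$chain_meta$thin,
              format(x$chain_meta$seed)))
  invisible(x)
}

#' Predict genetic values from a Bayes C fit
#'
#' `sum_j w_j E[a_j d_j]` with genotypes centered at the training allele
#' frequencies stored in the fit (orientation and centering frozen from
#' training).  Fixed-covariate contributions are excluded.
#'
#' @param object a `bayesc_fit`.
#' @param genotypes genotypes containing the individuals to predict.
#' @param test_ids ids to predict; default: all individuals in `genotypes`.
#' @param ... unused.
#' @return named numeric vector of predicted genetic values.
#' @export
predict.bayesc_fit <- function(object, genotypes, test_ids = NULL, ...) {
  if (is.null(test_ids)) test_ids <- genotypes$sample_ids
  miss <- setdiff(object$marker_ids, genotypes$map$id)
  if (length(miss) > 0) {
    stop("markers missing from prediction genotypes: ",
         paste(head(miss, 5), collapse = ", "),
         if (length(miss) > 5) sprintf(" (+%d more)", length(miss) - 5))
  }
  W <- center_genotypes(genotypes, object$allele_freqs, ids = test_ids,
                        markers = object$marker_ids)
  setNames(drop(W %*% object$effect_means), test_ids)
}
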