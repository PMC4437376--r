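#' GRAMMAR two-step association scan
#'
#' Step 1 fits the polygenic mixed model (intercept + covariates + GRM
#' random effect, via [fit_gblup()]) on the training individuals and
#' extracts its environmental residuals; step 2 regresses those residuals on
#' each SNP separately (genotypes centered at training frequencies) and
#' reports Wald P-values from the t distribution with `n - p - 1` degrees of
#' freedom (`p` = number of fixed-effect columns).  Because feature selection
#' consumes only the ranks, GRAMMAR's well-known test-statistic deflation is
#' left uncorrected: rank order is invariant to monotone rescaling.
#'
#' The operation enforces the leakage contract that supervised feature
#' selection depends on: if any supplied `train_ids` also appear in
#' `test_ids`, the scan refuses to run unless `leaky = TRUE` is passed
#' explicitly, and the provenance recorded in the result says so.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param phenotype named numeric vector.
#' @param covariates optional fixed covariates (ancestry PCs etc.).
#' @param grm a `gp_grm` covering the training individuals.
#' @param train_ids individuals whose data informs the scan.
#' @param test_ids individuals reserved for testing; used only to audit the
#'   contract above.
#' @param leaky explicit override allowing test individuals into the scan
#'   (the biased protocol the evaluation module reproduces on purpose).
#' @param dataset optional label recorded in the result's provenance.
#' @return An object of class `gwas_result`: a data frame with columns
#'   `snp`, `chr`, `bp`, `beta`, `se`, `p`, `rank`, `monomorphic`, plus
#'   attributes `provenance` (dataset identity -- critical for the leakage
#'   audit), `covariates`, `h2_hat` (step-1 polygenic heritability),
#'   `residuals` and `freqs` (consumed by the conditional-model selection
#'   scenarios), and `df`.
#' @export
run_gwas <- function(genotypes, phenotype, covariates = NULL, grm,
                     train_ids, test_ids = NULL, leaky = FALSE,
                     dataset = NULL) {
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap) > 0 && !leaky) {
    stop("run_gwas: ", length(overlap), " individual(s) flagged as test ",
         "members are in train_ids; pass leaky = TRUE only if this ",
         "leakage is intentional")
  }
  pg <- fit_gblup(grm, phenotype, covariates = covariates,
                  train_ids = train_ids)
  X <- build_design(covariates, train_ids)
  r <- phenotype[train_ids] - drop(X %*% pg$fixed_effects) -
    pg$blups[train_ids]
  freqs <- allele_freqs(genotypes, ids = train_ids)
  W <- center_genotypes(genotypes, freqs, ids = train_ids)
  n <- length(train_ids)
  df <- n - ncol(X) - 1
  wtw <- colSums(W^2)
  wtr <- drop(crossprod(W, r))
  mono <- wtw <= 0
  beta <- ifelse(mono, 0, wtr / wtw)
  rss <- sum(r^2) - beta^2 * wtw
  se <- ifelse(mono, NA_real_, sqrt(pmax(rss, 0) / (df * wtw)))
  tstat <- beta / se
  p <- ifelse(mono, 1, 2 * pt(-abs(tstat), df))
  map <- genotypes$map
  ord <- order(p, map$chr, map$pos, map$id)
  rank <- integer(length(p))
  rank[ord] <- seq_along(p)
  res <- data.frame(snp = map$id, chr = map$chr, bp = map$pos,
                    beta = beta, se = se, p = p, rank = rank,
                    monomorphic = mono, stringsAsFactors = FALSE,
                    row.names = map$id)
  prov <- sprintf("%s;n=%d;%s",
                  if (is.null(dataset)) "dataset" else dataset,
                  n, if (leaky) "leaky" else "proper")
  structure(res, class = c("gwas_result", "data.frame"),
            provenance = prov,
            covariates = colnames(X),
            h2_hat = pg$h2_hat,
            residuals = setNames(as.numeric(r), train_ids),
            freqs = freqs, df_marginal = df)
}

#' Genomic-control inflation factor
#'
#' `lambda = median(chi2) / qchisq(0.5, 1)` over the scan's P-values; close
#' to 1 for a well-calibrated scan on a null trait, inflated when family
#' structure is not accounted for.
#'
#' @param p a vector of P-values or a `gwas_result`.
#' @return the inflation factor lambda.
#' @export
gc_lambda <- function(p) {
  if (inherits(p, "gwas_result")) p <- p$p
  p <- p[is.finite(p) & p > 0 & p <= 1]
  median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)
}

#' Naive single-marker OLS scan
#'
#' Plain regression of the phenotype on each SNP with optional covariates,
#' without any polygenic adjustment.  Provided as the comparator that shows
#' why the two-step mixed-model scan is needed in structured samples.
#'
#' @inheritParams run_gwas
#' @return data frame with `snp`, `beta`, `se`, `p`.
#' @export
run_gwas_naive <- function(genotypes, phenotype, covariates = NULL,
                           train_ids) {
  y <- phenotype[train_ids]
  X <- build_design(covariates, train_ids)
  ## project out covariates once; per-SNP slope on the residualised scale
  qx <- qr(X)
  r <- qr.resid(qx, y)
  freqs <- allele_freqs(genotypes, ids = train_ids)
  W <- center_genotypes(genotypes, freqs, ids = train_ids)
  W <- qr.resid(qx, W)
  df <- length(y) - ncol(X) - 1
  wtw <- colSums(W^2)
  mono <- wtw <= 0
  beta <- ifelse(mono, 0, drop(crossprod(W, r)) / wtw)
  rss <- sum(r^2) - beta^2 * wtw
  se <- ifelse(mono, NA_real_, sqrt(pmax(rss, 0) / (df * wtw)))
  p <- ifelse(mono, 1, 2 * pt(-abs(beta / se), df))
  data.frame(snp = genotypes$map$id, beta = beta, se = se, p = p,
             stringsAsFactors = FALSE)
}
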