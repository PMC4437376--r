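#' Fit a fixed hit-list QTL linear model
#'
#' Ordinary least squares of the phenotype on all SNPs of a supplied hit
#' list jointly (plus intercept and optional covariates).  Aliased columns
#' (duplicated or otherwise collinear SNPs) are dropped with a warning and
#' recorded in the fit.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param phenotype named numeric vector.
#' @param hit_list marker ids to fit simultaneously; must number fewer than
#'   the training individuals.
#' @param covariates optional fixed covariates (row names = sample ids).
#' @param train_ids individuals used for fitting.
#' @return An object of class `qtl_fit`: `snp_ids` (markers retained),
#'   `coefficients` (per retained SNP), `intercept`, `covariate_effects`,
#'   `dropped` (aliased markers), `se`, `p` (per-SNP t-test).
#' @export
fit_qtl_linear <- function(genotypes, phenotype, hit_list,
                           covariates = NULL, train_ids = NULL) {
  if (is.null(train_ids)) {
    train_ids <- intersect(genotypes$sample_ids,
                           names(phenotype)[!is.na(phenotype)])
  }
  y <- phenotype[train_ids]
  hit_list <- as.character(hit_list)
  if (length(hit_list) >= length(train_ids)) {
    stop("hit list must be smaller than the training set")
  }
  miss <- setdiff(hit_list, genotypes$map$id)
  if (length(miss) > 0) stop("hit list markers not in genotypes: ",
                             paste(head(miss, 5), collapse = ", "))
  X <- build_design(covariates, train_ids)
  p0 <- ncol(X)
  if (length(hit_list) > 0) {
    Xs <- genotypes$values[train_ids, hit_list, drop = FALSE]
    X <- cbind(X, Xs)
  }
  qr_fit <- lm.fit(X, y)
  coefs <- qr_fit$coefficients
  aliased <- names(coefs)[is.na(coefs)]
  dropped <- intersect(aliased, hit_list)
  if (length(dropped) > 0) {
    warning("dropping aliased SNP(s): ", paste(dropped, collapse = ", "))
  }
  kept <- setdiff(hit_list, dropped)
  ## standard errors from the reduced (full-rank) model
  keep_cols <- setdiff(colnames(X), aliased)
  Xr <- X[, keep_cols, drop = FALSE]
  fit <- lm.fit(Xr, y)
  df <- length(y) - ncol(Xr)
  rss <- sum(fit$residuals^2)
  XtXinv <- chol2inv(qr.R(fit$qr))
  se_all <- sqrt(diag(XtXinv) * rss / df)
  names(se_all) <- keep_cols
  tt <- fit$coefficients / se_all
  pv <- 2 * pt(-abs(tt), df)
  structure(
    list(snp_ids = kept,
         coefficients = fit$coefficients[kept],
         intercept = unname(fit$coefficients["(Intercept)"]),
         covariate_effects = fit$coefficients[setdiff(keep_cols,
                                                      c(kept))],
         dropped = dropped,
         se = se_all[kept], p = pv[kept],
         train_ids = train_ids),
    class = "qtl_fit"
  )
}

#' @export
print.qtl_fit <- function(x, ...) {
  cat(sprintf("qtl_fit: %d SNP(s) fitted jointly, %d dropped as aliased\n",
              length(x$snp_ids), length(x$dropped)))
  invisible(x)
}

#' Predict genetic values from a QTL hit-list model
#'
#' Intercept plus the fitted SNP coefficients applied to the raw additive
#' dosages; covariate contributions are excluded.  Marker orientation must
#' match the training data (freeze it with
#' `read_plink_text(counted_alleles = ...)` when reading external cohorts).
#'
#' @param object a `qtl_fit`.
#' @param genotypes genotypes for the individuals to predict.
#' @param test_ids ids to predict; default all.
#' @param ... unused.
#' @return named numeric vector.
#' @export
predict.qtl_fit <- function(object, genotypes, test_ids = NULL, ...) {
  if (is.null(test_ids)) test_ids <- genotypes$sample_ids
  miss <- setdiff(object$snp_ids, genotypes$map$id)
  if (length(miss) > 0) stop("markers missing from prediction genotypes: ",
                             paste(head(miss, 5), collapse = ", "))
  if (length(object$snp_ids) == 0) {
    return(setNames(rep(object$intercept, length(test_ids)), test_ids))
  }
  Xs <- genotypes$values[test_ids, object$snp_ids, drop = FALSE]
  setNames(object$intercept + drop(Xs %*% object$coefficients), test_ids)
}
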