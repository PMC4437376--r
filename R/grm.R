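#' Genomic relationship matrix (VanRaden method 1)
#'
#' `G = W W' / (2 * sum(p_j (1 - p_j)))` with `W` the genotype matrix
#' column-centered at `2 p_j`.  When `freqs` is supplied (typically
#' training-fold frequencies) it is used for both centering and scaling, so
#' test individuals are placed in the training frame without contributing to
#' it -- the centering analogue of freezing allele orientation.
#'
#' @param genotypes a [genotype_matrix()] object (no missing entries).
#' @param freqs optional named per-SNP counted-allele frequencies; defaults
#'   to frequencies computed over all individuals in `genotypes`.
#' @param markers optional marker ids to restrict to.
#' @param xxt optional precomputed `tcrossprod(X)` over the raw 0/1/2 matrix
#'   (all individuals, all requested markers), a performance aid for repeated
#'   per-fold GRMs: the centered cross-product is recovered from it by a
#'   rank-one correction instead of a full matrix product.
#' @return An object of class `gp_grm`: list with `matrix` (n x n, dimnames =
#'   sample ids), `sample_ids`, `allele_freqs`, `denom` (the VanRaden
#'   scaling constant `2 sum p q`).
#' @export
compute_grm <- function(genotypes, freqs = NULL, markers = NULL, xxt = NULL) {
  X <- genotypes$values
  if (!is.null(markers)) X <- X[, markers, drop = FALSE]
  if (nrow(X) < 2) stop("need at least two individuals")
  if (anyNA(X)) stop("GRM requires complete genotypes")
  if (is.null(freqs)) {
    freqs <- colMeans(X) / 2
  } else {
    freqs <- freqs[colnames(X)]
    if (anyNA(freqs)) stop("freqs missing for some markers")
  }
  denom <- 2 * sum(freqs * (1 - freqs))
  if (denom <= 0) stop("all markers are monomorphic at the supplied ",
                       "frequencies; GRM undefined")
  cc <- 2 * freqs
  if (is.null(xxt)) {
    W <- sweep(X, 2L, cc, "-")
    G <- tcrossprod(W) / denom
  } else {
    xc <- drop(X %*% cc)
    G <- (xxt - outer(xc, rep(1, nrow(X))) - outer(rep(1, nrow(X)), xc) +
            sum(cc^2)) / denom
  }
  dimnames(G) <- list(rownames(X), rownames(X))
  structure(list(matrix = G, sample_ids = rownames(X),
                 allele_freqs = freqs, denom = denom),
            class = "gp_grm")
}

#' Cross-block genomic relationships between new and reference individuals
#'
#' Relationship rows for individuals absent from the training GRM (e.g. a
#' replication cohort), computed in the training frame: both sides are
#' centered at the supplied (training) frequencies and scaled by the same
#' VanRaden constant.
#'
#' @param genotypes_new,genotypes_ref `gp_genotypes` for the new and the
#'   reference individuals (may be the same object with different `ids`).
#' @param freqs named training allele frequencies.
#' @param markers marker ids to use (must be present on both sides).
#' @param ids_new,ids_ref optional sample subsets.
#' @return matrix of relationships, new individuals in rows.
#' @export
grm_cross <- function(genotypes_new, genotypes_ref, freqs, markers = NULL,
                      ids_new = NULL, ids_ref = NULL) {
  if (is.null(markers)) markers <- names(freqs)
  Wn <- center_genotypes(genotypes_new, freqs, ids = ids_new,
                         markers = markers)
  Wr <- center_genotypes(genotypes_ref, freqs, ids = ids_ref,
                         markers = markers)
  f <- freqs[markers]
  denom <- 2 * sum(f * (1 - f))
  if (denom <= 0) stop("all markers monomorphic at the supplied frequencies")
  tcrossprod(Wn, Wr) / denom
}

#' @export
print.gp_grm <- function(x, ...) {
  cat("gp_grm:", length(x$sample_ids), "individuals, mean diagonal",
      round(mean(diag(x$matrix)), 3), "\n")
  invisible(x)
}

#' Ancestry principal components from a GRM
#'
#' Top-k eigendecomposition of the genomic relationship matrix; component
#' scores are eigenvectors scaled by the square root of their eigenvalues.
#' The default of 24 components mirrors the adjustment used in the package's
#' stratification-aware analyses (20 cline components plus 4 for recent
#' admixture); any `k < n` may be requested.
#'
#' @param grm a `gp_grm`.
#' @param k number of components, `k < n`.
#' @return An object of class `pc_set`: list with `scores` (n x k),
#'   `eigenvalues` (length k, non-increasing), `k`.
#' @export
compute_pcs <- function(grm, k = 24) {
  n <- length(grm$sample_ids)
  if (k >= n) stop("k must be smaller than the number of individuals")
  e <- eigen(grm$matrix, symmetric = TRUE)
  val <- e$values[seq_len(k)]
  sc <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(val, 0)), k)
  dimnames(sc) <- list(grm$sample_ids, paste0("PC", seq_len(k)))
  structure(list(scores = sc, eigenvalues = val, k = k), class = "pc_set")
}
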