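## fixtures shared across test files, built once per run

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = fixture_cache)) {
    assign(key, force(expr), envir = fixture_cache)
  }
  get(key, envir = fixture_cache)
}

## small structured cohort: 2 sub-populations, families, real trait
small_cohort <- function() cached("small", simulate_cohort(
  sim_config(n_individuals = 250, n_subpops = 2, n_snps = 1000,
             n_qtl = 50, h2 = 0.5, seed = 101)))

## hand-built genotype container on one chromosome (1 kb spacing)
toy_genotypes <- function(values, pos = NULL, chr = NULL) {
  values <- as.matrix(values)
  m <- ncol(values)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chr)) chr <- rep(1L, m)
  map <- data.frame(chr = chr, pos = pos,
                    id = sprintf("m%03d", seq_len(m)),
                    a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("I%04d", seq_len(nrow(values)))
  }
  genotype_matrix(values, map)
}

## random biallelic genotypes, independent markers
random_genotypes <- function(n, m, seed = 1, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  vals <- sapply(maf, function(p) rbinom(n, 2, p))
  toy_genotypes(vals)
}

## fabricated association scan carrying everything the supervised
## selection scenarios consume (ranks, residuals, centering frequencies)
fake_gwas <- function(p, genotypes, residuals = NULL) {
  map <- genotypes$map
  ord <- order(p, map$chr, map$pos, map$id)
  rank <- integer(length(p))
  rank[ord] <- seq_along(p)
  res <- data.frame(snp = map$id, chr = map$chr, bp = map$pos,
                    beta = 0, se = 1, p = p, rank = rank,
                    monomorphic = FALSE, stringsAsFactors = FALSE,
                    row.names = map$id)
  ids <- if (!is.null(residuals)) names(residuals) else NULL
  structure(res, class = c("gwas_result", "data.frame"),
            provenance = "fixture;n=0;proper",
            covariates = "(Intercept)",
            residuals = residuals,
            freqs = allele_freqs(genotypes, ids = ids),
            df_marginal = if (!is.null(residuals)) {
              length(residuals) - 2
            } else NA_integer_)
}
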