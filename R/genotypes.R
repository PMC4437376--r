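#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs matrix of additive allele counts (0/1/2,
#' counting the `a1` allele of each marker) with its marker map and sample
#' identifiers.  This is the container every other function in the package
#' consumes.
#'
#' @param values numeric matrix, individuals in rows, SNPs in columns, entries
#'   in `{0, 1, 2}` (`NA` allowed only for data read from disk; simulated
#'   cohorts are complete).
#' @param map data frame with one row per SNP and columns `chr`, `pos`, `id`,
#'   `a1`, `a2`.  `a1` is the counted allele.  Positions are 1-based and must
#'   be strictly increasing within a chromosome.
#' @param sample_ids character vector of unique individual identifiers;
#'   defaults to `rownames(values)`.
#' @param subpop optional character/factor of sub-population labels, one per
#'   individual.
#'
#' @return An object of class `gp_genotypes`: a list with elements `values`,
#'   `map`, `sample_ids` and `subpop`.
#' @export
genotype_matrix <- function(values, map, sample_ids = rownames(values),
                            subpop = NULL) {
  values <- as.matrix(values)
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("I%05d", seq_len(nrow(values)))
  }
  stopifnot(
    nrow(map) == ncol(values),
    all(c("chr", "pos", "id", "a1", "a2") %in% names(map)),
    length(sample_ids) == nrow(values),
    !anyDuplicated(sample_ids),
    !anyDuplicated(map$id)
  )
  bad <- !(values %in% c(0, 1, 2) | is.na(values))
  if (any(bad)) {
    stop("genotype values must be additive allele counts in {0, 1, 2}")
  }
  for (ch in unique(map$chr)) {
    p <- map$pos[map$chr == ch]
    if (length(p) > 1L && any(diff(p) <= 0)) {
      stop("marker positions must be strictly increasing within chromosome ",
           ch)
    }
  }
  dimnames(values) <- list(sample_ids, map$id)
  if (!is.null(subpop)) {
    stopifnot(length(subpop) == length(sample_ids))
    subpop <- as.character(subpop)
  }
  structure(
    list(values = values, map = as.data.frame(map, stringsAsFactors = FALSE),
         sample_ids = sample_ids, subpop = subpop),
    class = "gp_genotypes"
  )
}

#' @export
print.gp_genotypes <- function(x, ...) {
  cat("gp_genotypes:", length(x$sample_ids), "individuals x",
      nrow(x$map), "SNPs on", length(unique(x$map$chr)), "chromosome(s)\n")
  if (!is.null(x$subpop)) {
    cat("  sub-populations:", paste(names(table(x$subpop)),
                                    table(x$subpop), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.gp_genotypes <- function(x) dim(x$values)

#' Allele frequencies of the counted allele
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param ids optional sample ids over which to compute frequencies (e.g. a
#'   training fold, so that the same orientation/centering can later be applied
#'   to test individuals).
#' @return named numeric vector of counted-allele frequencies, one per SNP.
#' @export
allele_freqs <- function(genotypes, ids = NULL) {
  X <- genotypes$values
  if (!is.null(ids)) X <- X[ids, , drop = FALSE]
  colMeans(X, na.rm = TRUE) / 2
}

## Column-centered genotype matrix W = X - 2p, the workhorse of the GRM,
## GRAMMAR step 2, and Bayes C.  Frequencies may come from a different
## (training) subset than `ids`.
center_genotypes <- function(genotypes, freqs, ids = NULL, markers = NULL) {
  X <- genotypes$values
  if (!is.null(ids)) X <- X[ids, , drop = FALSE]
  if (!is.null(markers)) {
    X <- X[, markers, drop = FALSE]
    freqs <- freqs[markers]
  }
  sweep(X, 2L, 2 * freqs, "-")
}

subset_markers <- function(genotypes, markers) {
  keep <- match(markers, genotypes$map$id)
  stopifnot(!anyNA(keep))
  genotype_matrix(genotypes$values[, keep, drop = FALSE],
                  genotypes$map[keep, , drop = FALSE],
                  genotypes$sample_ids, genotypes$subpop)
}
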