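#' Read PLINK text genotypes (.ped/.map)
#'
#' Parses a PLINK pedigree/map text pair into a [genotype_matrix()].  The
#' additive coding counts the minor allele as computed over the file (ties at
#' frequency 0.5 broken alphabetically), unless an explicit orientation is
#' supplied via `counted_alleles` -- the mechanism by which a training-set
#' allele orientation is frozen and applied to test data.
#'
#' @param ped_path,map_path paths to the `.ped` and `.map` files.
#' @param counted_alleles optional named character vector (names = marker
#'   ids) giving the allele to count for each marker, overriding the
#'   minor-allele rule.
#' @return A `gp_genotypes` object.  Missing genotypes (allele code `0`)
#'   become `NA`.
#' @export
read_plink_text <- function(ped_path, map_path, counted_alleles = NULL) {
  map_raw <- read.table(map_path, header = FALSE,
                        stringsAsFactors = FALSE)
  if (ncol(map_raw) < 4) stop(".map file must have 4 columns (CHR SNP CM BP)")
  map <- data.frame(chr = map_raw[[1]], pos = as.integer(map_raw[[4]]),
                    id = as.character(map_raw[[2]]),
                    a1 = NA_character_, a2 = NA_character_,
                    stringsAsFactors = FALSE)
  m <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  A1 <- matrix(NA_character_, n, m)
  A2 <- matrix(NA_character_, n, m)
  ids <- character(n)
  valid <- c("A", "C", "G", "T", "0")
  for (i in seq_len(n)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6 + 2 * m) {
      stop(sprintf(".ped line %d: expected %d fields, found %d",
                   i, 6 + 2 * m, length(f)))
    }
    al <- f[-(1:6)]
    bad <- setdiff(unique(al), valid)
    if (length(bad) > 0) {
      stop(sprintf(".ped line %d: invalid allele code(s): %s",
                   i, paste(bad, collapse = ", ")))
    }
    ids[i] <- f[2]
    A1[i, ] <- al[seq(1, 2 * m, by = 2)]
    A2[i, ] <- al[seq(2, 2 * m, by = 2)]
  }
  values <- matrix(NA_real_, n, m)
  for (j in seq_len(m)) {
    obs <- c(A1[, j], A2[, j])
    obs <- obs[obs != "0"]
    al <- sort(unique(obs))
    if (length(al) > 2) {
      stop(sprintf("marker %s: more than two alleles observed", map$id[j]))
    }
    if (!is.null(counted_alleles) && map$id[j] %in% names(counted_alleles)) {
      counted <- counted_alleles[[map$id[j]]]
    } else if (length(al) == 0) {
      counted <- NA_character_
    } else if (length(al) == 1) {
      ## monomorphic: the minor allele is absent, so the dosage is 0
      counted <- "0"
    } else {
      cnt <- table(factor(obs, levels = al))
      counted <- if (cnt[1] != cnt[2]) al[which.min(cnt)] else al[1]
    }
    other <- setdiff(al, counted)
    map$a1[j] <- if (is.na(counted)) "0" else counted
    map$a2[j] <- if (length(other) > 0) other[1] else "0"
    miss <- A1[, j] == "0" | A2[, j] == "0"
    values[, j] <- (A1[, j] == counted) + (A2[, j] == counted)
    values[miss, j] <- NA_real_
  }
  genotype_matrix(values, map, sample_ids = ids)
}

#' Write PLINK text genotypes (.ped/.map)
#'
#' Before writing, the coding is normalised so that the counted allele is the
#' minor allele (frequency ties broken alphabetically), which makes
#' write-then-read a round trip.
#'
#' @param genotypes a `gp_genotypes` object (no missing entries).
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @param phenotype optional named numeric placed in the 6th .ped column
#'   (default `-9`).
#' @return Invisibly, the two file paths.
#' @export
write_plink_text <- function(genotypes, prefix, phenotype = NULL) {
  X <- genotypes$values
  if (anyNA(X)) stop("cannot write missing genotypes to .ped")
  map <- genotypes$map
  n <- nrow(X); m <- ncol(X)
  ## normalise orientation: count the minor allele, ties alphabetical
  freq <- colMeans(X) / 2
  flip <- freq > 0.5 | (freq == 0.5 & !is.na(map$a2) & map$a2 != "0" &
                          map$a2 < map$a1)
  flip[is.na(flip)] <- FALSE
  if (any(flip)) {
    X[, flip] <- 2 - X[, flip]
    tmp <- map$a1[flip]; map$a1[flip] <- map$a2[flip]; map$a2[flip] <- tmp
  }
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  write.table(data.frame(map$chr, map$id, 0, map$pos),
              map_path, quote = FALSE, row.names = FALSE, col.names = FALSE,
              sep = "\t")
  ph <- if (is.null(phenotype)) rep(-9, n)
        else phenotype[genotypes$sample_ids]
  al <- matrix("", n, 2 * m)
  for (j in seq_len(m)) {
    a1 <- map$a1[j]; a2 <- map$a2[j]
    g <- X[, j]
    al[, 2 * j - 1] <- ifelse(g >= 1, a1, a2)
    al[, 2 * j] <- ifelse(g == 2, a1, a2)
  }
  ped <- cbind(genotypes$sample_ids, genotypes$sample_ids, "0", "0", "0",
               format(ph, trim = TRUE), al)
  writeLines(apply(ped, 1, paste, collapse = " "), ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

#' Write a GWAS result table
#'
#' Tab-separated with fixed column order `SNP CHR BP BETA SE P RANK`; P is
#' written in scientific notation.  Rows with `NaN` P-values are rejected
#' (monomorphic markers carry P = 1, never `NaN`).
#'
#' @param results a `gwas_result` from [run_gwas()] (or a data frame with the
#'   same lower-case columns).
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gwas_table <- function(results, path) {
  df <- as.data.frame(results)
  need <- c("snp", "chr", "bp", "beta", "se", "p", "rank")
  stopifnot(all(need %in% names(df)))
  if (any(is.nan(df$p))) stop("NaN P-values cannot be written")
  out <- data.frame(SNP = df$snp, CHR = df$chr, BP = df$bp,
                    BETA = df$beta, SE = df$se,
                    P = sprintf("%.6e", df$p), RANK = df$rank)
  write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' Read a GWAS result table written by [write_gwas_table()]
#' @param path input path.
#' @return data frame with columns `snp chr bp beta se p rank`.
#' @export
read_gwas_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  df
}

#' Write/read a phenotype (or covariate) table
#'
#' Tab-separated `FID IID <trait...>` layout.
#'
#' @param phenotype named numeric vector, or a data frame of traits with row
#'   names = sample ids.
#' @param path file path.
#' @return `write_phenotype_table`: invisibly `path`;
#'   `read_phenotype_table`: a data frame of traits with sample-id row names.
#' @export
write_phenotype_table <- function(phenotype, path) {
  if (is.vector(phenotype)) {
    phenotype <- data.frame(value = phenotype,
                            row.names = names(phenotype))
  }
  out <- cbind(FID = rownames(phenotype), IID = rownames(phenotype),
               phenotype)
  write.table(out, path, quote = FALSE, row.names = FALSE, sep = "\t")
  invisible(path)
}

#' @rdname write_phenotype_table
#' @export
read_phenotype_table <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$IID)) stop("duplicate sample ids in phenotype table")
  rownames(df) <- df$IID
  df[, setdiff(names(df), c("FID", "IID")), drop = FALSE]
}

#' Persist a GRM as lower-triangle text
#'
#' GCTA-like dialect: comment header lines carrying the sample ids, then one
#' line per lower-triangle element (row index, column index, value, both
#' 1-based, diagonal included).
#'
#' @param grm a `gp_grm` from [compute_grm()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_grm_text <- function(grm, path) {
  G <- grm$matrix
  n <- nrow(G)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste("# n", n),
               paste("# ids", paste(grm$sample_ids, collapse = " "))), con)
  idx <- which(lower.tri(G, diag = TRUE), arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  writeLines(sprintf("%d %d %.10g", idx[, 1], idx[, 2],
                     G[idx]), con)
  invisible(path)
}

#' @rdname write_grm_text
#' @export
read_grm_text <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  ids <- strsplit(sub("^# ids ", "", hdr[startsWith(hdr, "# ids")]),
                  " ")[[1]]
  body <- read.table(text = lines[!startsWith(lines, "#")])
  n <- length(ids)
  G <- matrix(0, n, n, dimnames = list(ids, ids))
  G[cbind(body[[1]], body[[2]])] <- body[[3]]
  G[cbind(body[[2]], body[[1]])] <- body[[3]]
  structure(list(matrix = G, sample_ids = ids, allele_freqs = NULL),
            class = "gp_grm")
}

#' Write a feature subset as a PLINK `--extract` style marker list
#'
#' One marker id per line, preceded by comment lines recording the method,
#' density and provenance (the leakage audit trail).
#'
#' @param subset a `feature_subset`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_feature_subset <- function(subset, path) {
  writeLines(c(sprintf("# method %s", subset$method),
               sprintf("# density %d", subset$density),
               sprintf("# provenance %s", subset$provenance),
               subset$marker_ids), path)
  invisible(path)
}

#' Read a simulation config from YAML
#'
#' @param path YAML file whose keys are [sim_config()] arguments.
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}

#' Write haplotype blocks as a .blocks-style text file
#'
#' One line per block: chromosome, start bp, end bp, then the marker ids.
#'
#' @param blocks a `haplotype_blocks` from [detect_blocks()].
#' @param path output path.
#' @param multi_only drop singleton blocks (default TRUE, matching the
#'   usual .blocks convention).
#' @return Invisibly, `path`.
#' @export
write_blocks <- function(blocks, path, multi_only = TRUE) {
  stopifnot(inherits(blocks, "haplotype_blocks"))
  map <- blocks$map
  lines <- vapply(blocks$blocks, function(b) {
    if (multi_only && length(b$marker_ids) < 2) return(NA_character_)
    paste(b$chr, map$pos[b$start], map$pos[b$end],
          paste(b$marker_ids, collapse = ","))
  }, character(1))
  writeLines(lines[!is.na(lines)], path)
  invisible(path)
}
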