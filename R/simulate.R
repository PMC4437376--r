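#' Simulation configuration
#'
#' Parameters of the synthetic cohort generator.  The generator emulates the
#' structure the downstream analyses assume: a small number of modestly
#' differentiated sub-populations (Balding-Nichols-calibrated
#' founder-usage weights over a shared founder pool), haplotype-block
#' linkage disequilibrium produced by a blockwise mosaic of that pool,
#' sib-family relatedness, and quantitative traits built from planted QTL
#' plus Gaussian noise.
#'
#' @param n_individuals individuals per sub-population.
#' @param n_subpops number of sub-populations.
#' @param fst differentiation between sub-populations, in `[0, 1)`.  The
#'   default 0.005 reflects the very low differentiation typical of
#'   neighbouring isolate cohorts.
#' @param n_snps total marker count.  Markers are laid out at 1 kb spacing,
#'   one chromosome per 1,000 SNPs, so that base-pair pruning radii have a
#'   meaningful scale.
#' @param block_length mean SNPs per LD block.
#' @param within_block_corr strength of within-block LD, in `[0, 1)`: the
#'   probability that a marker arises on the block's founder genealogy
#'   (such markers are in complete pairwise LD across the founder pool);
#'   the remainder segregate independently.  0 gives mutually
#'   uncorrelated markers.
#' @param n_families full-sib families per sub-population; each contributes
#'   `sibs_per_family` sibs sharing two simulated parents (and therefore an
#'   expected genomic relationship of 0.5).  Default: 10 percent of
#'   `n_individuals`, i.e. one fifth of each sub-population sits in a sib
#'   pair.
#' @param sibs_per_family sibs per family (default 2).
#' @param founder_pool founder haplotypes per block, shared by all
#'   sub-populations; individual haplotypes are per-block mosaics of this
#'   pool, which is what creates block-level LD and haplotype sharing.
#' @param n_qtl number of causal SNPs.
#' @param qtl_typed_frac fraction of causal SNPs present on the marker
#'   panel (default 1).  Untyped causal variants stay in the trait and in
#'   the returned ground truth but are removed from the genotype matrix, so
#'   markers tag them only through LD -- the situation of real arrays,
#'   where genome-wide similarity rather than direct QTL genotypes carries
#'   part of the signal.
#' @param h2 narrow-sense heritability in `[0, 1]`.
#' @param effect_model `"gaussian"` (all QTL effects drawn N(0,1) and
#'   rescaled) or `"few_large_plus_polygenic"` (`n_moderate` loci jointly
#'   explain `moderate_var_frac` of the genetic variance, the remaining QTL
#'   the rest -- an HDL-like architecture).
#' @param n_moderate,moderate_var_frac mixture parameters for
#'   `"few_large_plus_polygenic"`; defaults 5 loci, half of the genetic variance.
#' @param seed integer seed; the whole cohort is reproducible from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_individuals = 500, n_subpops = 2, fst = 0.005,
                       n_snps = 5000, block_length = 10,
                       within_block_corr = 0.7, n_families = NULL,
                       sibs_per_family = 2, founder_pool = 8,
                       n_qtl = 100, qtl_typed_frac = 1, h2 = 0.5,
                       effect_model = c("gaussian",
                                        "few_large_plus_polygenic"),
                       n_moderate = 5, moderate_var_frac = 0.5,
                       seed = 1) {
  effect_model <- match.arg(effect_model)
  if (is.null(n_families)) {
    n_families <- floor(0.1 * n_individuals)
  }
  if (h2 < 0 || h2 > 1) stop("h2 must lie in [0, 1]")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0, 1)")
  if (within_block_corr < 0 || within_block_corr >= 1) {
    stop("within_block_corr must lie in [0, 1)")
  }
  counts <- c(n_individuals = n_individuals, n_subpops = n_subpops,
              n_snps = n_snps, block_length = block_length,
              founder_pool = founder_pool, n_qtl = n_qtl)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (n_qtl > n_snps) stop("n_qtl must not exceed n_snps")
  if (qtl_typed_frac < 0 || qtl_typed_frac > 1) {
    stop("qtl_typed_frac must lie in [0, 1]")
  }
  if (n_families * sibs_per_family > n_individuals) {
    stop("n_families * sibs_per_family exceeds n_individuals")
  }
  structure(
    list(n_individuals = n_individuals, n_subpops = n_subpops, fst = fst,
         n_snps = n_snps, block_length = block_length,
         within_block_corr = within_block_corr, n_families = n_families,
         sibs_per_family = sibs_per_family, founder_pool = founder_pool,
         n_qtl = n_qtl, qtl_typed_frac = qtl_typed_frac, h2 = h2,
         effect_model = effect_model,
         n_moderate = n_moderate, moderate_var_frac = moderate_var_frac,
         seed = seed),
    class = "sim_config")
}

## Marker map: 1 chromosome per 1,000 SNPs, 1 kb inter-marker spacing.
make_map <- function(n_snps) {
  snps_per_chr <- 1000L
  j <- seq_len(n_snps) - 1L
  chr <- j %/% snps_per_chr + 1L
  pos <- (j %% snps_per_chr) * 1000L + 1L
  bases <- c("A", "C", "G", "T")
  a <- matrix(NA_character_, n_snps, 2)
  for (i in seq_len(n_snps)) a[i, ] <- sample(bases, 2)
  data.frame(chr = chr, pos = pos,
             id = sprintf("snp%06d", seq_len(n_snps)),
             a1 = a[, 1], a2 = a[, 2], stringsAsFactors = FALSE)
}

## Partition markers into LD blocks of ~block_length SNPs, never crossing a
## chromosome boundary.  Returns an integer block index per SNP.
make_blocks <- function(map, block_length) {
  blk <- integer(nrow(map))
  nxt <- 1L
  for (ch in unique(map$chr)) {
    idx <- which(map$chr == ch)
    i <- 1L
    while (i <= length(idx)) {
      len <- if (block_length > 1) max(1L, rpois(1, block_length - 1) + 1L)
             else 1L
      len <- min(len, length(idx) - i + 1L)
      blk[idx[i:(i + len - 1L)]] <- nxt
      nxt <- nxt + 1L
      i <- i + len
    }
  }
  blk
}

## Founder haplotypes for one block, generated on a random mutation
## genealogy (infinite-sites, no within-block recombination): each block
## SNP arises from a single mutation on a random clade of the founder
## genealogy, so any two such SNPs show at most three of the four two-locus
## haplotypes and are in complete LD (|D'| = 1) across the pool -- the
## structure the Gabriel block definition is built around.  With
## probability 1 - rho a SNP instead segregates independently of the
## genealogy (a block-discordant marker), so `rho` tunes the strength of
## within-block LD; rho = 0 gives mutually uncorrelated markers.
draw_founders <- function(n_hap, p, rho) {
  L <- length(p)
  H <- matrix(0L, n_hap, L)
  ## random genealogy: recursive random bipartitions; proper clades only
  clades <- list()
  split_set <- function(members) {
    if (length(members) < 2) return(invisible(NULL))
    repeat {
      g <- runif(length(members)) < 0.5
      if (any(g) && !all(g)) break
    }
    a <- members[g]
    b <- members[!g]
    clades[[length(clades) + 1]] <<- a
    clades[[length(clades) + 1]] <<- b
    split_set(a)
    split_set(b)
    invisible(NULL)
  }
  if (n_hap > 1) split_set(seq_len(n_hap))
  tree_snp <- runif(L) < rho & length(clades) > 0
  for (j in seq_len(L)) {
    if (tree_snp[j]) {
      cl <- clades[[sample.int(length(clades), 1)]]
      al <- integer(n_hap)
      al[cl] <- 1L
      ## orient the mutation so the counted-allele frequency tracks p[j]
      if (abs(1 - length(cl) / n_hap - p[j]) <
          abs(length(cl) / n_hap - p[j])) {
        al <- 1L - al
      }
      H[, j] <- al
    } else {
      H[, j] <- rbinom(n_hap, 1, p[j])
    }
  }
  H
}

## Sub-population founder-usage weights.  All sub-populations share one
## founder pool per block; differentiation comes from Dirichlet-distributed
## usage weights.  For a symmetric Dirichlet with total concentration
## alpha0, the across-subpopulation variance of the implied allele
## frequency is Var_pool(f) / (alpha0 + 1), so Fst = 1 / (alpha0 + 1);
## alpha0 = (1 - fst) / fst therefore hits the target exactly (the
## Balding-Nichols parameter form).  fst = 0 gives uniform weights and
## hence zero differentiation beyond sampling noise.
draw_weights <- function(n_founders, fst) {
  if (fst <= 0) return(rep(1 / n_founders, n_founders))
  alpha0 <- (1 - fst) / fst
  g <- stats::rgamma(n_founders, shape = alpha0 / n_founders)
  if (sum(g) <= 0) g <- rep(1, n_founders)
  g / sum(g)
}

## Assemble haplotypes for one sub-population as a per-block mosaic of the
## shared founder pool, sampled with that sub-population's usage weights.
## Unrelated individuals draw two haplotypes per block; sibs draw from the
## four haplotypes of their two (unsampled) parents.
assemble_subpop <- function(pool, blocks_idx, weights, n_ind, n_families,
                            sibs_per_family) {
  n_snps <- sum(lengths(blocks_idx))
  X <- matrix(0L, n_ind, n_snps)
  n_sib <- n_families * sibs_per_family
  n_unrel <- n_ind - n_sib
  fam_of <- if (n_sib > 0) rep(seq_len(n_families), each = sibs_per_family)
            else integer(0)
  for (b in seq_along(blocks_idx)) {
    Fb <- pool[[b]]
    np <- nrow(Fb)
    w <- weights[[b]]
    cols <- blocks_idx[[b]]
    if (n_unrel > 0) {
      h1 <- sample.int(np, n_unrel, replace = TRUE, prob = w)
      h2 <- sample.int(np, n_unrel, replace = TRUE, prob = w)
      X[seq_len(n_unrel), cols] <- Fb[h1, , drop = FALSE] +
        Fb[h2, , drop = FALSE]
    }
    if (n_sib > 0) {
      ## 4 parental haplotypes per family for this block
      par_hap <- matrix(sample.int(np, 4 * n_families, replace = TRUE,
                                   prob = w),
                        n_families, 4)
      mat <- ifelse(runif(n_sib) < 0.5, par_hap[fam_of, 1], par_hap[fam_of, 2])
      pat <- ifelse(runif(n_sib) < 0.5, par_hap[fam_of, 3], par_hap[fam_of, 4])
      X[n_unrel + seq_len(n_sib), cols] <- Fb[mat, , drop = FALSE] +
        Fb[pat, , drop = FALSE]
    }
  }
  list(X = X, family = c(rep(NA_integer_, n_unrel), fam_of))
}

#' Simulate a genotyped cohort with a quantitative trait
#'
#' Generates genotypes (Balding-Nichols sub-population frequencies, blockwise
#' founder-mosaic LD, sib families), plants `n_qtl` causal SNPs, and builds a
#' phenotype as breeding value plus Gaussian noise scaled so the realised
#' narrow-sense heritability matches `config$h2`.  Phenotypes are standardised
#' to zero mean and unit variance on output.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `gp_cohort`: list with `genotypes`
#'   ([genotype_matrix()]), `phenotype` (named, standardised), `truth` (list
#'   with `breeding_values` on the phenotype scale, `genetic_score` (the
#'   unit-variance genetic value, defined even when `h2 = 0`), `qtl_ids`,
#'   `qtl_effects`), `config`, and `internals` used by
#'   [simulate_replication()].
#' @examples
#' coh <- simulate_cohort(sim_config(n_individuals = 100, n_snps = 200,
#'                                   n_families = 10, n_qtl = 20, seed = 42))
#' var(coh$truth$breeding_values) / var(coh$phenotype)  # ~ h2
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  map <- make_map(config$n_snps)
  blk <- make_blocks(map, config$block_length)
  blocks_idx <- split(seq_len(config$n_snps), blk)
  p0 <- runif(config$n_snps, 0.1, 0.9)

  ## one founder pool per block, shared by all sub-populations
  pool <- lapply(blocks_idx, function(cols) {
    draw_founders(config$founder_pool, p0[cols], config$within_block_corr)
  })
  weights <- vector("list", config$n_subpops)
  Xs <- vector("list", config$n_subpops)
  fam <- vector("list", config$n_subpops)
  for (s in seq_len(config$n_subpops)) {
    weights[[s]] <- lapply(blocks_idx, function(cols) {
      draw_weights(config$founder_pool, config$fst)
    })
    asm <- assemble_subpop(pool, blocks_idx, weights[[s]],
                           config$n_individuals,
                           config$n_families, config$sibs_per_family)
    Xs[[s]] <- asm$X
    fam[[s]] <- asm$family
  }
  X <- do.call(rbind, Xs)
  n <- nrow(X)
  ids <- sprintf("P%d_I%04d", rep(seq_len(config$n_subpops),
                                  each = config$n_individuals),
                 sequence(rep(config$n_individuals, config$n_subpops)))
  subpop <- sprintf("P%d", rep(seq_len(config$n_subpops),
                               each = config$n_individuals))
  dimnames(X) <- list(ids, map$id)

  trait <- build_trait(X, config)
  ## untyped causal variants: on the trait, off the panel
  untyped <- character(0)
  if (config$qtl_typed_frac < 1) {
    qtl_ids <- trait$truth$qtl_ids
    n_untyped <- round((1 - config$qtl_typed_frac) * length(qtl_ids))
    untyped <- sample(qtl_ids, n_untyped)
  }
  panel <- setdiff(map$id, untyped)
  keep <- match(panel, map$id)
  genotypes <- genotype_matrix(X[, keep, drop = FALSE],
                               map[keep, , drop = FALSE], ids, subpop)

  structure(
    list(genotypes = genotypes, phenotype = trait$phenotype,
         truth = trait$truth, config = config,
         internals = list(p0 = p0, blocks = blk, blocks_idx = blocks_idx,
                          pool = pool, weights = weights,
                          map = map, family = unlist(fam), untyped = untyped,
                          raw_effects = trait$raw_effects)),
    class = "gp_cohort"
  )
}

## Shared by simulate_cohort and simulate_replication: plant QTL effects
## (or reuse supplied raw effects) and scale noise to the target h2.
build_trait <- function(X, config, qtl = NULL, raw_effects = NULL) {
  n <- nrow(X)
  if (is.null(qtl)) qtl <- sort(sample.int(ncol(X), config$n_qtl))
  if (is.null(raw_effects)) {
    a <- rnorm(config$n_qtl)
    moderate <- integer(0)
    if (config$effect_model == "few_large_plus_polygenic") {
      k <- min(config$n_moderate, config$n_qtl)
      moderate <- sample.int(config$n_qtl, k)
    }
    raw_effects <- list(a = a, moderate = moderate)
  }
  Xq <- X[, qtl, drop = FALSE]
  a <- raw_effects$a
  moderate <- raw_effects$moderate
  if (length(moderate) > 0) {
    g_big <- Xq[, moderate, drop = FALSE] %*% a[moderate]
    g_small <- Xq[, -moderate, drop = FALSE] %*% a[-moderate]
    f <- config$moderate_var_frac
    s_big <- if (sd(g_big) > 0) sqrt(f) / sd(g_big) else 0
    s_small <- if (sd(g_small) > 0) sqrt(1 - f) / sd(g_small) else 0
    a[moderate] <- a[moderate] * s_big
    a[-moderate] <- a[-moderate] * s_small
  }
  g <- drop(Xq %*% a)
  sdg <- sd(g)
  if (sdg > 0) {
    gs <- (g - mean(g)) / sdg
    a <- a / sdg
  } else {
    gs <- g * 0
  }
  h2 <- config$h2
  y0 <- sqrt(h2) * gs + sqrt(1 - h2) * rnorm(n)
  sdy <- sd(y0)
  y <- (y0 - mean(y0)) / sdy
  bv <- sqrt(h2) * gs / sdy
  eff <- a * sqrt(h2) / sdy
  ids <- rownames(X)
  names(y) <- names(bv) <- names(gs) <- ids
  list(
    phenotype = y,
    truth = list(breeding_values = bv, genetic_score = gs,
                 qtl_ids = colnames(X)[qtl], qtl_effects = setNames(
                   eff, colnames(X)[qtl])),
    raw_effects = raw_effects
  )
}

#' Simulate a replication cohort sharing the marker panel and QTL
#'
#' Draws a new cohort on the same marker map and with the same causal loci
#' and (raw) allele-substitution effects as `cohort`.  Three degrees of
#' separation from the training cohort are available:
#'
#' * `related = TRUE` -- same founder pool *and* same usage weights as the
#'   training cohort's first sub-population: essentially more samples of
#'   the same population, maximally sharing haplotypes;
#' * `related = FALSE` (default) -- same founder pool, but fresh
#'   founder-usage weights at divergence `fst`: a population of different
#'   ancestry whose LD structure is consistent with training (the signal
#'   that transfers is marker-QTL LD, not recent relatedness);
#' * `independent_founders = TRUE` -- an entirely fresh founder pool: no
#'   haplotype is shared and within-block LD patterns are re-drawn, so even
#'   LD-based signal does not transfer and prediction relies on typed
#'   causal markers alone.
#'
#' @param cohort a `gp_cohort` from [simulate_cohort()].
#' @param n_individuals replication cohort size.
#' @param fst divergence of the replication population (default 0.01, i.e.
#'   modestly more differentiated than the within-study sub-populations).
#' @param related share the training population's founder-usage weights.
#' @param independent_founders draw a completely new founder pool.
#' @param seed integer seed.
#' @return A `gp_cohort` for the replication population (single
#'   sub-population, no families), on the same marker panel as `cohort`
#'   (untyped causal variants removed identically).
#' @export
simulate_replication <- function(cohort, n_individuals = 500, fst = 0.01,
                                 related = FALSE,
                                 independent_founders = FALSE, seed = 1) {
  stopifnot(inherits(cohort, "gp_cohort"))
  set.seed(seed)
  cfg <- cohort$config
  int <- cohort$internals
  if (independent_founders) {
    pool <- lapply(int$blocks_idx, function(cols) {
      draw_founders(cfg$founder_pool, int$p0[cols], cfg$within_block_corr)
    })
  } else {
    pool <- int$pool
  }
  if (related && !independent_founders) {
    weights <- int$weights[[1]]
  } else {
    weights <- lapply(int$blocks_idx, function(cols) {
      draw_weights(cfg$founder_pool, fst)
    })
  }
  asm <- assemble_subpop(pool, int$blocks_idx, weights, n_individuals,
                         0L, 0L)
  X <- asm$X
  dimnames(X) <- list(sprintf("R_I%04d", seq_len(n_individuals)),
                      int$map$id)
  qtl <- match(cohort$truth$qtl_ids, int$map$id)
  trait <- build_trait(X, cfg, qtl = qtl, raw_effects = int$raw_effects)
  panel <- setdiff(int$map$id, int$untyped)
  keep <- match(panel, int$map$id)
  genotypes <- genotype_matrix(X[, keep, drop = FALSE],
                               int$map[keep, , drop = FALSE], rownames(X),
                               rep("REP", n_individuals))
  structure(
    list(genotypes = genotypes, phenotype = trait$phenotype,
         truth = trait$truth, config = cfg,
         internals = list(map = int$map)),
    class = "gp_cohort"
  )
}

#' Trait-architecture presets
#'
#' Convenience wrapper around [sim_config()] for the three architectures the
#' package's experiments contrast: a height-like highly polygenic trait
#' (h2 = 0.8), an HDL-like trait (h2 = 0.5 with a few moderate-effect loci),
#' and a BMI-like weakly polygenic trait (h2 = 0.3).
#'
#' @param trait one of `"height"`, `"hdl"`, `"bmi"`.
#' @param ... overrides passed on to [sim_config()].
#' @return A `sim_config`.
#' @export
trait_preset <- function(trait = c("height", "hdl", "bmi"), ...) {
  trait <- match.arg(trait)
  base <- switch(trait,
    height = list(h2 = 0.8, n_qtl = 1000, effect_model = "gaussian",
                  qtl_typed_frac = 0.5),
    hdl = list(h2 = 0.5, n_qtl = 100,
               effect_model = "few_large_plus_polygenic",
               n_moderate = 5, moderate_var_frac = 0.5),
    bmi = list(h2 = 0.3, n_qtl = 600, effect_model = "gaussian",
               qtl_typed_frac = 0.5)
  )
  dots <- list(...)
  base[names(dots)] <- dots
  do.call(sim_config, base)
}

#' Weir-Cockerham Fst
#'
#' Per-SNP and multi-locus Weir & Cockerham (1984) theta-hat from additive
#' genotypes and sub-population labels.  The multi-locus estimate is the
#' ratio-of-sums combination of the per-SNP variance components, the standard
#' way of averaging this estimator over loci.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param labels sub-population labels, one per individual; defaults to the
#'   labels stored in `genotypes`.
#' @return list with `per_snp` (named vector; `NaN` where undefined, e.g.
#'   monomorphic across all populations) and `mean` (ratio-of-sums estimate).
#' @export
estimate_fst <- function(genotypes, labels = genotypes$subpop) {
  if (is.null(labels)) stop("sub-population labels are required")
  labels <- as.character(labels)
  tab <- table(labels)
  if (length(tab) < 2) stop("need at least two sub-populations")
  if (any(tab < 2)) stop("each sub-population needs at least 2 individuals")
  X <- genotypes$values
  r <- length(tab)
  pops <- names(tab)
  n_i <- as.numeric(tab)
  p_i <- matrix(0, r, ncol(X))
  h_i <- matrix(0, r, ncol(X))
  for (k in seq_len(r)) {
    Xi <- X[labels == pops[k], , drop = FALSE]
    p_i[k, ] <- colMeans(Xi) / 2
    h_i[k, ] <- colMeans(Xi == 1)
  }
  nbar <- mean(n_i)
  nc <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  pbar <- colSums(n_i * p_i) / (r * nbar)
  s2 <- colSums(n_i * (p_i - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(n_i * h_i) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  per_snp <- a / (a + b + cc)
  names(per_snp) <- colnames(X)
  ok <- is.finite(a) & is.finite(b) & is.finite(cc) & (a + b + cc) != 0
  list(per_snp = per_snp,
       mean = sum(a[ok]) / sum((a + b + cc)[ok]))
}
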