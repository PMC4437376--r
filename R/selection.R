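new_feature_subset <- function(marker_ids, density, method, provenance,
                               seed = NULL) {
  stopifnot(!anyDuplicated(marker_ids), nzchar(provenance))
  structure(list(marker_ids = marker_ids, density = as.integer(density),
                 method = method, provenance = provenance, seed = seed),
            class = "feature_subset")
}

#' @export
print.feature_subset <- function(x, ...) {
  cat(sprintf("feature_subset [%s]: %d of %d requested markers (%s)\n",
              x$method, length(x$marker_ids), x$density, x$provenance))
  invisible(x)
}

#' The default density ladder for unsupervised subsets
#' @export
ufs_densities <- c(100, 500, 1000, 5000, 10000, 50000, 100000, 150000,
                   200000, 250000)

#' Unsupervised feature selection: evenly spaced markers
#'
#' Takes markers at stride `floor(m / density)` along genome order, starting
#' from a random offset in `[0, stride)` drawn from `seed`.  Repeating with
#' ten consecutive seeds yields the conventional ten subsets per density;
#' above `m / 2` markers the subsets necessarily overlap.  Selection uses the
#' map only -- no phenotype is touched, so there is nothing to leak.
#'
#' @param map a marker map (or a `gp_genotypes`, whose map is used) ordered
#'   by chromosome and position.
#' @param density requested marker count; if it exceeds the number of
#'   markers, all markers are returned with a warning.
#' @param seed integer seed for the starting offset.
#' @param offset optional explicit 0-based offset (overrides `seed`).
#' @return A `feature_subset` with method `"UFS"`.
#' @export
select_unsupervised <- function(map, density, seed = 1, offset = NULL) {
  if (inherits(map, "gp_genotypes")) map <- map$map
  stopifnot(density >= 1)
  map <- map[order(map$chr, map$pos), , drop = FALSE]
  m <- nrow(map)
  if (density > m) {
    warning("density ", density, " exceeds ", m, " markers; returning all")
    return(new_feature_subset(map$id, density, "UFS", "map-only", seed))
  }
  stride <- max(1L, floor(m / density))
  if (is.null(offset)) {
    set.seed(seed)
    offset <- sample.int(stride, 1) - 1L
  }
  stopifnot(offset >= 0, offset < stride)
  idx <- offset + 1L + stride * (seq_len(density) - 1L)
  new_feature_subset(map$id[idx], density, "UFS", "map-only", seed)
}

#' Supervised selection scenario 1: GWAS P-value rank
#'
#' The top `density` markers by association rank in the supplied scan,
#' ignoring marker dependencies (LD).
#'
#' @param gwas a `gwas_result` (its provenance is propagated into the
#'   subset, preserving the leakage audit trail).
#' @param density requested marker count.
#' @return A `feature_subset` with method `"SFS1"`.
#' @export
select_sfs1 <- function(gwas, density) {
  stopifnot(density >= 1)
  ord <- order(gwas$rank)
  take <- head(ord, density)
  new_feature_subset(gwas$snp[take], density, "SFS1",
                     attr(gwas, "provenance"))
}

#' Median marker interval
#'
#' Median of the base-pair gaps between adjacent markers within
#' chromosomes, computed on the complete genotype map (marker positions are
#' phenotype-independent, so this does not leak test information).  The
#' usual pruning radius for the interval-based selection scenarios.
#'
#' @param map marker map or `gp_genotypes`.
#' @param per_chromosome return a per-chromosome median instead of the
#'   global one.
#' @return median gap in base pairs (named vector if `per_chromosome`).
#' @export
median_marker_interval <- function(map, per_chromosome = FALSE) {
  if (inherits(map, "gp_genotypes")) map <- map$map
  map <- map[order(map$chr, map$pos), , drop = FALSE]
  gaps <- lapply(split(map$pos, map$chr), diff)
  if (all(lengths(gaps) == 0)) {
    stop("no chromosome has more than one marker; interval undefined")
  }
  if (per_chromosome) {
    vapply(gaps, function(g) if (length(g)) median(g) else NA_real_,
           numeric(1))
  } else {
    median(unlist(gaps))
  }
}

## Greedy rank-order pruning: repeatedly take the best-ranked remaining
## marker and remove it together with every remaining marker within +/- msd
## base pairs on its chromosome.  Returns the selection in rank order and,
## optionally (collect_intervals), each hit's pruning interval.
greedy_prune <- function(gwas, msd, collect_intervals = FALSE,
                         stop_after = Inf) {
  ord <- order(gwas$rank)
  m <- nrow(gwas)
  avail <- rep(TRUE, m)
  chr <- gwas$chr
  bp <- gwas$bp
  selected <- integer(0)
  intervals <- if (collect_intervals) vector("list", 0) else NULL
  for (s in ord) {
    if (!avail[s]) next
    near <- which(avail & chr == chr[s] & abs(bp - bp[s]) <= msd)
    selected <- c(selected, s)
    if (collect_intervals) intervals[[length(selected)]] <- near
    avail[near] <- FALSE
    avail[s] <- FALSE
    if (!collect_intervals && length(selected) >= stop_after) break
  }
  list(selected = selected, intervals = intervals)
}

#' Supervised selection scenario 2: rank with median-interval pruning
#'
#' Greedy loop: take the best-ranked remaining marker, then remove it and
#' every marker within `msd` base pairs on its chromosome from the selection
#' panel; iterate until the panel is empty.  The subset is the first
#' `density` markers in selection order.  With `msd = 0` (and unique
#' positions) no neighbour is ever pruned and the result equals scenario 1.
#'
#' @param gwas a `gwas_result`.
#' @param density requested marker count.
#' @param msd pruning radius in base pairs, typically
#'   [median_marker_interval()]; must be `>= 0`.
#' @return A `feature_subset` with method `"SFS2"`.  If pruning leaves fewer
#'   than `density` survivors, all survivors are returned with a warning.
#' @export
select_sfs2 <- function(gwas, density, msd) {
  stopifnot(density >= 1, msd >= 0)
  sel <- greedy_prune(gwas, msd, stop_after = density)$selected
  if (length(sel) < density) {
    ## the early exit above never triggers in this branch: the loop ran dry
    warning("only ", length(sel), " markers survived pruning ",
            "(density ", density, " requested)")
  }
  new_feature_subset(gwas$snp[head(sel, density)], density, "SFS2",
                     attr(gwas, "provenance"))
}

## Conditional P-values from one joint OLS of the polygenic residuals on a
## set of centered marker columns, entered in the given order.  Aliased
## (collinear) columns receive P = 1.  df matches the marginal scan when the
## model contains a single marker.
joint_conditional_p <- function(W, r, df_extra) {
  q <- ncol(W)
  n <- nrow(W)
  fit <- lm.fit(W, r)
  coefs <- fit$coefficients
  aliased <- is.na(coefs)
  rk <- fit$rank
  df <- n - df_extra - rk
  if (df <= 0 || rk == 0) return(rep(1, q))
  rss <- sum(fit$residuals^2)
  R <- qr.R(fit$qr)[seq_len(rk), seq_len(rk), drop = FALSE]
  cols <- fit$qr$pivot[seq_len(rk)]
  XtXinv <- chol2inv(R)
  se <- sqrt(diag(XtXinv) * rss / df)
  p <- rep(1, q)
  tt <- coefs[cols] / se
  p[cols] <- 2 * pt(-abs(tt), df)
  p[aliased] <- 1
  p
}

#' Supervised selection scenario 3: interval-conditional P-values
#'
#' The greedy pruning pass of scenario 2 defines intervals: at each step the
#' best-ranked remaining marker and its within-`msd` neighbours are fitted
#' jointly (entry order by GWAS rank) in one linear model on the polygenic
#' residuals carried by the scan, and every member's conditional P-value is
#' extracted from its t-test in that joint model; the interval is then
#' removed from the panel.  After the loop every marker carries a
#' conditional P-value and the subset is the `density` markers with the
#' smallest conditional P (ties by map position), not the greedy selection
#' order.  Collinear members are assigned P = 1 and hence rank last.
#'
#' @param gwas a `gwas_result` carrying the training residuals.
#' @param genotypes the genotypes the scan was computed from.
#' @param density requested marker count.
#' @param msd interval radius in base pairs.
#' @return A `feature_subset` with method `"SFS3"`; the conditional
#'   P-values are attached as attribute `conditional_p`.
#' @export
select_sfs3 <- function(gwas, genotypes, density, msd) {
  stopifnot(density >= 1, msd >= 0)
  r <- attr(gwas, "residuals")
  freqs <- attr(gwas, "freqs")
  if (is.null(r)) stop("gwas result does not carry residuals")
  train_ids <- names(r)
  df_extra <- length(attr(gwas, "covariates"))
  pr <- greedy_prune(gwas, msd, collect_intervals = TRUE)
  cond_p <- rep(NA_real_, nrow(gwas))
  max_q <- max(2L, floor(length(train_ids) / 2))
  for (iv in pr$intervals) {
    iv <- iv[order(gwas$rank[iv])]
    if (length(iv) == 1) {
      ## a singleton interval's joint model is the marginal scan model;
      ## reuse the scan P-value verbatim
      cond_p[iv] <- gwas$p[iv]
      next
    }
    if (length(iv) >= length(train_ids) - df_extra) {
      warning("interval with ", length(iv), " markers truncated to ",
              max_q, " best-ranked for the joint model")
      kept <- iv[seq_len(max_q)]
      cond_p[setdiff(iv, kept)] <- 1
      iv <- kept
    }
    W <- center_genotypes(genotypes, freqs, ids = train_ids,
                          markers = gwas$snp[iv])
    cond_p[iv] <- joint_conditional_p(W, r, df_extra)
  }
  ord <- order(cond_p, gwas$chr, gwas$bp, gwas$snp)
  take <- head(ord, density)
  out <- new_feature_subset(gwas$snp[take], density, "SFS3",
                            attr(gwas, "provenance"))
  attr(out, "conditional_p") <- setNames(cond_p, gwas$snp)
  out
}

#' Supervised selection scenario 4: haplotype-block conditional P-values
#'
#' For every multi-marker haplotype block, one joint linear model of the
#' polygenic residuals on all intra-block SNPs (entry order by GWAS rank)
#' yields each SNP's conditional P-value; singleton blocks keep their
#' marginal scan P-value.  The subset is the `density` markers genome-wide
#' with the smallest conditional P, ties by position.  Collinear SNPs get
#' P = 1 (last rank); a block too large for the training sample is split at
#' its worst-ranked marker, with a warning.
#'
#' @param gwas a `gwas_result` carrying the training residuals.
#' @param genotypes the genotypes the scan was computed from.
#' @param blocks a `haplotype_blocks` object from [detect_blocks()] covering
#'   every marker in `gwas`.
#' @param density requested marker count.
#' @return A `feature_subset` with method `"SFS4"`; conditional P-values
#'   attached as attribute `conditional_p`.
#' @export
select_sfs4 <- function(gwas, genotypes, blocks, density) {
  stopifnot(density >= 1, inherits(blocks, "haplotype_blocks"))
  r <- attr(gwas, "residuals")
  freqs <- attr(gwas, "freqs")
  if (is.null(r)) stop("gwas result does not carry residuals")
  train_ids <- names(r)
  df_extra <- length(attr(gwas, "covariates"))
  covered <- unlist(lapply(blocks$blocks, `[[`, "marker_ids"))
  if (!all(gwas$snp %in% covered)) {
    stop("every marker must appear in exactly one block")
  }
  cond_p <- setNames(gwas$p, gwas$snp)  # singletons keep marginal P
  n_train <- length(train_ids)
  rank_of <- setNames(gwas$rank, gwas$snp)
  idx_of <- setNames(seq_len(nrow(gwas)), gwas$snp)

  fit_block <- function(ids) {
    if (length(ids) < 2) return(invisible(NULL))
    if (length(ids) >= n_train - df_extra) {
      warning("block of ", length(ids), " markers split at its ",
              "worst-ranked marker (training set too small)")
      worst <- ids[which.max(rank_of[ids])]
      cut <- match(worst, ids)
      fit_block(ids[seq_len(cut - 1)])
      fit_block(ids[cut:length(ids)])
      return(invisible(NULL))
    }
    ord_ids <- ids[order(rank_of[ids])]
    W <- center_genotypes(genotypes, freqs, ids = train_ids,
                          markers = ord_ids)
    cond_p[ord_ids] <<- joint_conditional_p(W, r, df_extra)
    invisible(NULL)
  }
  for (b in blocks$blocks) fit_block(b$marker_ids)

  pv <- cond_p[gwas$snp]
  ord <- order(pv, gwas$chr, gwas$bp, gwas$snp)
  take <- head(ord, density)
  out <- new_feature_subset(gwas$snp[take], density, "SFS4",
                            attr(gwas, "provenance"))
  attr(out, "conditional_p") <- cond_p
  out
}
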