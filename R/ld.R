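## Pairwise two-locus statistics for unphased genotypes: EM haplotype
## frequencies, D', and a Haploview-style likelihood-based D' confidence
## interval, vectorised across marker pairs.

## 3x3 genotype-pair counts for a list of index pairs within one chromosome.
pair_counts <- function(X, i, j) {
  ind <- lapply(0:2, function(g) (X == g) + 0)
  cnt <- list()
  for (a in 0:2) for (b in 0:2) {
    C <- crossprod(ind[[a + 1]], ind[[b + 1]])
    cnt[[paste0("n", a, b)]] <- C[cbind(i, j)]
  }
  cnt
}

## EM for two-locus haplotype frequencies (alleles coded 1 = counted allele).
## Cells with one or zero double-hets are phase-unambiguous; the (1,1) cell
## is split according to the current phase probability.
em_hap_freqs <- function(cnt, iter = 64) {
  N2 <- 2 * Reduce(`+`, cnt)
  c11_0 <- 2 * cnt$n22 + cnt$n21 + cnt$n12
  c10_0 <- 2 * cnt$n20 + cnt$n21 + cnt$n10
  c01_0 <- 2 * cnt$n02 + cnt$n12 + cnt$n01
  c00_0 <- 2 * cnt$n00 + cnt$n01 + cnt$n10
  dh <- cnt$n11
  x <- rep(0.5, length(dh))
  for (k in seq_len(iter)) {
    p11 <- (c11_0 + x * dh) / N2
    p10 <- (c10_0 + (1 - x) * dh) / N2
    p01 <- (c01_0 + (1 - x) * dh) / N2
    p00 <- (c00_0 + x * dh) / N2
    num <- p11 * p00
    den <- num + p10 * p01
    x <- ifelse(den > 0, num / den, 0.5)
  }
  list(p11 = p11, p10 = p10, p01 = p01, p00 = p00)
}

## D' and its likelihood-based 90% interval (Haploview's approach): with
## allele frequencies fixed at their MLEs, the likelihood of the observed
## genotype-pair table is evaluated on a grid of |D'| values in [0, 1]; the
## bounds are the grid points below/above which 5% of the normalised
## likelihood mass lies.
dprime_ci <- function(cnt, em_iter = 64) {
  hf <- em_hap_freqs(cnt, em_iter)
  pA <- hf$p11 + hf$p10
  pB <- hf$p11 + hf$p01
  D <- hf$p11 - pA * pB
  pos <- D >= 0
  dmax <- ifelse(pos, pmin(pA * (1 - pB), (1 - pA) * pB),
                 pmin(pA * pB, (1 - pA) * (1 - pB)))
  ok <- dmax > 1e-12
  dprime <- ifelse(ok, abs(D) / dmax, NA_real_)
  npair <- length(pA)
  grid <- seq(0, 1, by = 0.01)
  ll <- matrix(-Inf, npair, length(grid))
  sgn <- ifelse(pos, 1, -1)
  eps <- 1e-10
  for (k in seq_along(grid)) {
    Dk <- sgn * grid[k] * dmax
    p11 <- pmax(pA * pB + Dk, eps)
    p10 <- pmax(pA * (1 - pB) - Dk, eps)
    p01 <- pmax((1 - pA) * pB - Dk, eps)
    p00 <- pmax((1 - pA) * (1 - pB) + Dk, eps)
    ll[, k] <-
      cnt$n00 * log(p00^2) + cnt$n01 * log(2 * p00 * p01) +
      cnt$n02 * log(p01^2) + cnt$n10 * log(2 * p00 * p10) +
      cnt$n11 * log(2 * (p11 * p00 + p10 * p01)) +
      cnt$n12 * log(2 * p01 * p11) + cnt$n20 * log(p10^2) +
      cnt$n21 * log(2 * p10 * p11) + cnt$n22 * log(p11^2)
  }
  rel <- exp(ll - apply(ll, 1, max))
  tot <- rowSums(rel)
  cum <- t(apply(rel, 1, cumsum))
  lo <- hi <- rep(NA_real_, npair)
  for (q in seq_len(npair)) {
    if (!ok[q] || !is.finite(tot[q])) next
    lo[q] <- grid[min(which(cum[q, ] >= 0.05 * tot[q]))]
    hi[q] <- grid[max(which(tot[q] - cum[q, ] + rel[q, ] >= 0.05 * tot[q]))]
  }
  list(dprime = dprime, ci_low = lo, ci_high = hi)
}

#' Pairwise D' confidence intervals
#'
#' EM-phased two-locus haplotype frequencies and Haploview-style
#' likelihood-based 90% confidence intervals on |D'| for marker pairs of a
#' genotype matrix.  Exposed mainly for inspection; [detect_blocks()] drives
#' it internally.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param pairs two-column integer matrix of marker indices (same
#'   chromosome); default: all within-chromosome pairs.
#' @param ids optional sample subset.
#' @return data frame with marker indices/ids, `dprime`, `ci_low`,
#'   `ci_high`.
#' @export
ld_dprime <- function(genotypes, pairs = NULL, ids = NULL) {
  map <- genotypes$map
  X <- genotypes$values
  if (!is.null(ids)) X <- X[ids, , drop = FALSE]
  if (is.null(pairs)) {
    pairs <- do.call(rbind, lapply(split(seq_len(nrow(map)), map$chr),
                                   function(ix) {
      if (length(ix) < 2) return(NULL)
      t(utils::combn(ix, 2))
    }))
  }
  stopifnot(all(map$chr[pairs[, 1]] == map$chr[pairs[, 2]]))
  cnt <- pair_counts(X, pairs[, 1], pairs[, 2])
  ci <- dprime_ci(cnt)
  data.frame(i = pairs[, 1], j = pairs[, 2],
             snp_i = map$id[pairs[, 1]], snp_j = map$id[pairs[, 2]],
             dprime = ci$dprime, ci_low = ci$ci_low, ci_high = ci$ci_high,
             stringsAsFactors = FALSE)
}

#' Detect haplotype blocks (Gabriel confidence-interval method)
#'
#' Haploview's default procedure: for every within-chromosome marker pair
#' (up to `max_kb` apart and `max_block_markers` apart in index), the 90%
#' confidence interval of |D'| classifies the pair as "strong LD" (lower
#' bound >= 0.70 and upper bound >= 0.98), "strong recombination" (upper
#' bound < 0.90), or uninformative.  A candidate region is a block when its
#' informative pairs are at least 95% strong-LD; candidates are accepted
#' greedily, longest first, without overlap.  Markers in no accepted block
#' become singleton blocks, so every marker lies in exactly one block.
#'
#' @param genotypes a [genotype_matrix()] object.
#' @param train_ids optional sample subset used to estimate LD.
#' @param max_kb maximum block span in kilobases (default 500).
#' @param max_block_markers maximum markers per block considered (default
#'   60; a computational bound, generous relative to typical block sizes).
#' @param strong_low,strong_high,recomb_high the Gabriel thresholds.
#' @param inf_frac required fraction of informative pairs in strong LD.
#' @return An object of class `haplotype_blocks`: `blocks` is a list of
#'   `list(chr, start, end, marker_ids)` (indices into the map, singletons
#'   included), `assignment` maps each marker id to its block number.
#' @export
detect_blocks <- function(genotypes, train_ids = NULL, max_kb = 500,
                          max_block_markers = 60, strong_low = 0.70,
                          strong_high = 0.98, recomb_high = 0.90,
                          inf_frac = 0.95) {
  map <- genotypes$map
  m <- nrow(map)
  accepted <- list()
  for (ch in unique(map$chr)) {
    ix <- which(map$chr == ch)
    mc <- length(ix)
    if (mc < 2) next
    pos <- map$pos[ix]
    ## all pairs within the window
    pi_ <- pj_ <- integer(0)
    for (a in seq_len(mc - 1)) {
      b <- seq(a + 1, min(mc, a + max_block_markers - 1))
      b <- b[pos[b] - pos[a] <= max_kb * 1000]
      if (length(b) > 0) {
        pi_ <- c(pi_, rep(a, length(b)))
        pj_ <- c(pj_, b)
      }
    }
    if (length(pi_) == 0) next
    X <- genotypes$values[, ix, drop = FALSE]
    if (!is.null(train_ids)) X <- X[train_ids, , drop = FALSE]
    cnt <- pair_counts(X, pi_, pj_)
    ci <- dprime_ci(cnt)
    cls <- integer(length(pi_))  # 1 strong LD, 2 strong recombination
    informative <- !is.na(ci$ci_low)
    cls[informative & ci$ci_low >= strong_low &
          ci$ci_high >= strong_high] <- 1L
    cls[informative & ci$ci_high < recomb_high] <- 2L
    CLS <- matrix(0L, mc, mc)
    CLS[cbind(pi_, pj_)] <- cls
    ## enumerate candidate spans, counting classes incrementally
    cand <- list()
    for (a in seq_len(mc - 1)) {
      nSL <- 0L; nSR <- 0L
      bmax <- min(mc, a + max_block_markers - 1)
      for (b in seq(a + 1, bmax)) {
        if (pos[b] - pos[a] > max_kb * 1000) break
        newc <- CLS[a:(b - 1), b]
        nSL <- nSL + sum(newc == 1L)
        nSR <- nSR + sum(newc == 2L)
        if (nSL + nSR > 0 && nSL / (nSL + nSR) >= inf_frac && nSL > 0) {
          cand[[length(cand) + 1]] <- c(a, b)
        }
      }
    }
    if (length(cand) == 0) next
    cand <- do.call(rbind, cand)
    span_m <- cand[, 2] - cand[, 1] + 1
    span_bp <- pos[cand[, 2]] - pos[cand[, 1]]
    ord <- order(-span_m, -span_bp, cand[, 1])
    covered <- rep(FALSE, mc)
    for (k in ord) {
      a <- cand[k, 1]; b <- cand[k, 2]
      if (any(covered[a:b])) next
      covered[a:b] <- TRUE
      accepted[[length(accepted) + 1]] <-
        list(chr = ch, start = ix[a], end = ix[b],
             marker_ids = map$id[ix[a:b]])
    }
  }
  ## order accepted blocks along the genome, then add singletons
  if (length(accepted) > 0) {
    accepted <- accepted[order(vapply(accepted, `[[`, numeric(1), "start"))]
  }
  in_block <- unlist(lapply(accepted, `[[`, "marker_ids"))
  singles <- setdiff(map$id, in_block)
  blocks <- accepted
  for (s in singles) {
    k <- match(s, map$id)
    blocks[[length(blocks) + 1]] <- list(chr = map$chr[k], start = k,
                                         end = k, marker_ids = s)
  }
  blocks <- blocks[order(vapply(blocks, `[[`, numeric(1), "start"))]
  assignment <- integer(m)
  names(assignment) <- map$id
  for (k in seq_along(blocks)) assignment[blocks[[k]]$marker_ids] <- k
  structure(list(blocks = blocks, assignment = assignment, map = map),
            class = "haplotype_blocks")
}

#' @export
print.haplotype_blocks <- function(x, ...) {
  sizes <- lengths(lapply(x$blocks, `[[`, "marker_ids"))
  cat(sprintf(
    "haplotype_blocks: %d blocks over %d markers (%d multi-marker, max %d)\n",
    length(x$blocks), length(x$assignment), sum(sizes > 1), max(sizes)))
  invisible(x)
}

#' All-singleton block partition
#'
#' Every marker its own block -- the degenerate partition under which the
#' block-conditional selection scenario reduces to plain rank selection.
#'
#' @param map marker map or `gp_genotypes`.
#' @return A `haplotype_blocks` object.
#' @export
singleton_blocks <- function(map) {
  if (inherits(map, "gp_genotypes")) map <- map$map
  blocks <- lapply(seq_len(nrow(map)), function(k) {
    list(chr = map$chr[k], start = k, end = k, marker_ids = map$id[k])
  })
  assignment <- setNames(seq_len(nrow(map)), map$id)
  structure(list(blocks = blocks, assignment = assignment, map = map),
            class = "haplotype_blocks")
}
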