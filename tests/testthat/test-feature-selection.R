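test_that("unsupervised stride selection follows the offset arithmetic", {
  g <- random_genotypes(5, 10, seed = 30)
  sub <- select_unsupervised(g$map, 5, offset = 0)
  expect_equal(sub$marker_ids, g$map$id[c(1, 3, 5, 7, 9)])
  full1 <- select_unsupervised(g$map, 10, seed = 1)
  full2 <- select_unsupervised(g$map, 10, seed = 99)
  expect_equal(full1$marker_ids, g$map$id)
  expect_equal(full2$marker_ids, g$map$id)
  expect_warning(all_m <- select_unsupervised(g$map, 20, seed = 1),
                 "returning all")
  expect_equal(all_m$marker_ids, g$map$id)
})

test_that("stride subsets match exhaustive offset enumeration at m = 20", {
  g <- random_genotypes(5, 20, seed = 31)
  density <- 10
  stride <- floor(20 / density)
  enumerated <- lapply(seq_len(stride) - 1, function(o) {
    g$map$id[o + 1 + stride * (seq_len(density) - 1)]
  })
  for (o in seq_len(stride) - 1) {
    expect_equal(select_unsupervised(g$map, density, offset = o)$marker_ids,
                 enumerated[[o + 1]])
  }
  ## seed-drawn subsets can only ever be one of the enumerated ones, and
  ## pairwise overlaps match the brute-force overlap multiset {0, density}
  drawn <- lapply(1:10, function(s) {
    select_unsupervised(g$map, density, seed = s)$marker_ids
  })
  expect_true(all(vapply(drawn, function(d) {
    any(vapply(enumerated, identical, logical(1), d))
  }, logical(1))))
  ov <- outer(seq_along(drawn), seq_along(drawn), Vectorize(function(i, j) {
    length(intersect(drawn[[i]], drawn[[j]]))
  }))
  expect_true(all(ov[upper.tri(ov)] %in% c(0, density)))
  expect_gte(length(unique(unlist(drawn))), density)
})

test_that("rank selection returns the top of the scan", {
  g <- random_genotypes(20, 10, seed = 32)
  p <- c(0.5, 0.01, 0.9, 0.3, 0.02, 0.8, 0.15, 0.6, 0.05, 0.4)
  gw <- fake_gwas(p, g)
  expect_equal(select_sfs1(gw, 1)$marker_ids, g$map$id[2])
  expect_equal(select_sfs1(gw, 10)$marker_ids,
               g$map$id[order(p)])
  ## hand-ordered: 0.01 < 0.02 < 0.05 < 0.15
  expect_equal(select_sfs1(gw, 4)$marker_ids, g$map$id[c(2, 5, 9, 7)])
  expect_equal(select_sfs1(gw, 4)$provenance, "fixture;n=0;proper")
})

test_that("the median marker interval follows the textbook conventions", {
  mk_map <- function(chr, pos) {
    data.frame(chr = chr, pos = pos,
               id = sprintf("s%02d", seq_along(pos)),
               a1 = "A", a2 = "G", stringsAsFactors = FALSE)
  }
  expect_equal(median_marker_interval(mk_map(rep(1, 4), c(1, 3, 7, 13))), 4)
  expect_equal(median_marker_interval(
    mk_map(c(1, 1, 2, 2), c(1, 2, 1, 10))), 5)
  grid <- mk_map(rep(1, 50), seq(1, by = 1000, length.out = 50))
  expect_equal(median_marker_interval(grid), 1000)
  expect_error(median_marker_interval(mk_map(1:3, c(5, 5, 5))),
               "interval undefined")
  per_chr <- median_marker_interval(mk_map(c(1, 1, 2, 2), c(1, 2, 1, 10)),
                                    per_chromosome = TRUE)
  expect_equal(unname(per_chr), c(1, 9))
})

test_that("interval pruning follows the greedy rank-order rule", {
  g <- random_genotypes(10, 5, seed = 33)
  g$map$pos <- c(1L, 2L, 3L, 100L, 101L)
  p <- c(0.01, 0.30, 0.40, 0.20, 0.50)  # ranks 1, 3, 4, 2, 5
  gw <- fake_gwas(p, g)
  sub <- select_sfs2(gw, 2, msd = 2)
  expect_equal(sub$marker_ids, g$map$id[c(1, 4)])
  ## asking for more than the pruning leaves warns and returns survivors
  expect_warning(sub2 <- select_sfs2(gw, 5, msd = 2), "survived")
  expect_equal(sub2$marker_ids, g$map$id[c(1, 4)])
})

test_that("interval pruning limits collapse as specified", {
  g <- random_genotypes(20, 12, seed = 34)
  p <- runif(12)
  gw <- fake_gwas(p, g)
  expect_equal(select_sfs2(gw, 12, msd = 0)$marker_ids,
               select_sfs1(gw, 12)$marker_ids)
  ## everything mutually within msd on one chromosome: lone survivor
  expect_warning(one <- select_sfs2(gw, 5, msd = 1e9), "survived")
  expect_equal(one$marker_ids, g$map$id[which.min(p)])
})

test_that("interval-conditional P-values equal an independent OLS oracle", {
  set.seed(35)
  g <- random_genotypes(120, 6, seed = 35)
  g$map$pos <- c(1000L, 2000L, 3000L, 50000L, 90000L, 130000L)
  r <- rnorm(120)
  r <- setNames(r - mean(r), g$sample_ids)
  p <- c(0.01, 0.2, 0.3, 0.05, 0.5, 0.6)
  gw <- fake_gwas(p, g, residuals = r)
  sub <- select_sfs3(gw, g, density = 6, msd = 2500)
  cond <- attr(sub, "conditional_p")
  ## interval 1 = markers 1..3 jointly; oracle: plain lm on centered dosages
  W <- scale(g$values[, 1:3], scale = FALSE)
  oracle <- summary(lm(r ~ W))$coefficients[-1, 4]
  expect_equal(unname(cond[1:3]), unname(oracle), tolerance = 1e-8)
  ## singleton intervals keep their marginal scan P verbatim
  expect_equal(unname(cond[4:6]), p[4:6])
})

test_that("interval-conditional selection collapses to rank selection for
           singleton intervals", {
  coh <- small_cohort()
  ids <- coh$genotypes$sample_ids
  gw <- run_gwas(coh$genotypes, coh$phenotype,
                 grm = compute_grm(coh$genotypes), train_ids = ids)
  s1 <- select_sfs1(gw, 40)
  s3 <- select_sfs3(gw, coh$genotypes, 40, msd = 0)
  expect_equal(s3$marker_ids, s1$marker_ids)
})

test_that("collinear interval members get conditional P = 1, ranked last", {
  g <- random_genotypes(100, 4, seed = 36)
  g$values[, 2] <- g$values[, 1]  # duplicate inside the interval
  set.seed(37)
  r <- drop(scale(0.6 * g$values[, 1] + rnorm(100)))
  r <- setNames(r, g$sample_ids)
  p <- c(0.001, 0.002, 0.5, 0.6)
  gw <- fake_gwas(p, g, residuals = r)
  sub <- select_sfs3(gw, g, density = 4, msd = 2500)
  cond <- attr(sub, "conditional_p")
  expect_lt(cond[[1]], 0.01)       # first-entered keeps the signal
  expect_equal(cond[[2]], 1)       # aliased duplicate
  expect_equal(sub$marker_ids[4], g$map$id[2])
})

test_that("block-conditional P-values equal a joint OLS oracle", {
  set.seed(38)
  g <- random_genotypes(150, 7, seed = 38)
  r <- rnorm(150)
  r <- setNames(r - mean(r), g$sample_ids)
  p <- runif(7)
  gw <- fake_gwas(p, g, residuals = r)
  blocks <- structure(list(
    blocks = list(
      list(chr = 1L, start = 1L, end = 4L, marker_ids = g$map$id[1:4]),
      list(chr = 1L, start = 5L, end = 5L, marker_ids = g$map$id[5]),
      list(chr = 1L, start = 6L, end = 7L, marker_ids = g$map$id[6:7])),
    assignment = setNames(c(1L, 1L, 1L, 1L, 2L, 3L, 3L), g$map$id),
    map = g$map), class = "haplotype_blocks")
  sub <- select_sfs4(gw, g, blocks, density = 7)
  cond <- attr(sub, "conditional_p")
  W <- scale(g$values[, 1:4], scale = FALSE)
  oracle <- summary(lm(r ~ W))$coefficients[-1, 4]
  expect_equal(unname(cond[g$map$id[1:4]]), unname(oracle),
               tolerance = 1e-8)
  ## singleton block keeps the marginal scan P
  expect_equal(cond[[g$map$id[5]]], p[5])
})

test_that("block-conditional selection with all singletons equals rank
           selection, and duplicates follow the collinearity rule", {
  coh <- small_cohort()
  ids <- coh$genotypes$sample_ids
  gw <- run_gwas(coh$genotypes, coh$phenotype,
                 grm = compute_grm(coh$genotypes), train_ids = ids)
  s1 <- select_sfs1(gw, 40)
  s4 <- select_sfs4(gw, coh$genotypes,
                    singleton_blocks(coh$genotypes), 40)
  expect_equal(s4$marker_ids, s1$marker_ids)

  g <- random_genotypes(100, 3, seed = 39)
  g$values[, 2] <- g$values[, 1]
  set.seed(40)
  r <- setNames(drop(scale(0.7 * g$values[, 1] + rnorm(100))),
                g$sample_ids)
  gw2 <- fake_gwas(c(0.001, 0.002, 0.9), g, residuals = r)
  blocks <- structure(list(
    blocks = list(list(chr = 1L, start = 1L, end = 2L,
                       marker_ids = g$map$id[1:2]),
                  list(chr = 1L, start = 3L, end = 3L,
                       marker_ids = g$map$id[3])),
    assignment = setNames(c(1L, 1L, 2L), g$map$id),
    map = g$map), class = "haplotype_blocks")
  sub <- select_sfs4(gw2, g, blocks, density = 3)
  cond <- attr(sub, "conditional_p")
  expect_lt(cond[[1]], 0.01)
  expect_equal(cond[[2]], 1)
})

test_that("subsets never exceed availability and never duplicate", {
  coh <- small_cohort()
  ids <- coh$genotypes$sample_ids
  gw <- run_gwas(coh$genotypes, coh$phenotype,
                 grm = compute_grm(coh$genotypes), train_ids = ids)
  for (d in c(1, 37, 1000)) {
    sub <- select_sfs1(gw, d)
    expect_equal(length(sub$marker_ids), min(d, 1000))
    expect_false(anyDuplicated(sub$marker_ids) > 0)
    expect_true(nzchar(sub$provenance))
  }
})
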