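test_that("Weir-Cockerham F_ST hits its analytic anchors", {
  # single SNP fixed 1 vs 0, n = 50 per population
  d <- rbind(matrix(2L, 50, 1), matrix(0L, 50, 1))
  p <- tiny_panel(d, c(rep("A", 50), rep("B", 50)))
  expect_gte(pairwise_fst(p, "A", "B")$fst, 0.97)

  # two copies of the same sample set are undifferentiated (the unbiased
  # estimator can go slightly negative here, which is fine)
  set.seed(1)
  g <- matrix(rbinom(40 * 1000, 2, runif(1000, 0.1, 0.9)[rep(1:1000, each = 40)]),
              nrow = 40)
  p2 <- tiny_panel(rbind(g, g), c(rep("A", 40), rep("B", 40)))
  expect_lte(pairwise_fst(p2, "A", "B")$fst, 0.005)
  expect_gt(pairwise_fst(p2, "A", "B")$fst, -0.02)
})

test_that("F_ST recovers the Balding-Nichols drift scale", {
  # Monte-Carlo oracle (frozen): two branches of F = 0.005 each give a
  # Weir-Cockerham estimate of ~0.005 at this design
  p <- bn_pair(0.005, n_samples = 100, n_snps = 20000, seed = 21)
  est <- pairwise_fst(p, "A", "B")$fst
  expect_equal(est, 0.005, tolerance = 0.2)
})

test_that("F_ST is symmetric, allele-flip invariant and drift-monotonic", {
  p <- bn_pair(0.02, n_samples = 30, n_snps = 2000, seed = 4)
  f1 <- pairwise_fst(p, "A", "B")$fst
  expect_identical(f1, pairwise_fst(p, "B", "A")$fst)

  flip <- sample(c(TRUE, FALSE), n_snps(p), replace = TRUE)
  d2 <- p$dosages
  d2[, flip] <- 2L - d2[, flip]
  p2 <- genotype_panel(d2, p$snps, p$pop_of)
  expect_equal(pairwise_fst(p2, "A", "B")$fst, f1)

  fs <- vapply(c(0.002, 0.005, 0.01, 0.02), function(F) {
    pairwise_fst(bn_pair(F, n_samples = 50, n_snps = 5000, seed = 11),
                 "A", "B")$fst
  }, numeric(1))
  expect_true(all(diff(fs) > 0))
})

test_that("fst_matrix is consistent with pairwise calls and drift ordering", {
  m <- divergence_model(c(A = 0.005, B = 0.02, C = 0.06), n_samples = 40,
                        n_snps = 4000)
  p <- simulate_divergence(m, seed = 8)
  fm <- fst_matrix(p)
  expect_true(isSymmetric(fm$values))
  expect_equal(unname(diag(fm$values)), rep(0, 3))
  expect_equal(fm$values["A", "B"], pairwise_fst(p, "A", "B")$fst)
  # star tree: pair F_ST ordering follows summed branch drifts
  expect_lt(fm$values["A", "B"], fm$values["A", "C"])
  expect_lt(fm$values["A", "C"], fm$values["B", "C"] + fm$values["A", "C"]) # sanity
  expect_lt(fm$values["A", "B"], fm$values["B", "C"])
})

test_that("allele sharing distance matches hand arithmetic and its bounds", {
  g <- rbind(c(0L, 1L, 2L, 2L), c(2L, 1L, 0L, 2L))
  p <- tiny_panel(g, c("X", "Y"))
  expect_equal(asd_matrix(p)$values[1, 2], 0.5)

  same <- tiny_panel(rbind(c(0L, 1L, 2L), c(0L, 1L, 2L)), "P")
  expect_equal(asd_matrix(same)$values[1, 2], 0)
  extreme <- tiny_panel(rbind(rep(0L, 7), rep(2L, 7)), "P")
  expect_equal(asd_matrix(extreme)$values[1, 2], 1)
})

test_that("ASD is a metric on complete data and respects missingness", {
  set.seed(13)
  d <- matrix(rbinom(12 * 200, 2, 0.4), nrow = 12)
  v <- asd_matrix(tiny_panel(d, "P"))$values
  for (i in 1:10) {
    ijk <- sample(12, 3)
    expect_lte(v[ijk[1], ijk[3]],
               v[ijk[1], ijk[2]] + v[ijk[2], ijk[3]] + 1e-12)
  }
  # pairwise-complete exclusion: a missing cell only affects that pair's SNPs
  d2 <- d
  d2[1, 1:50] <- NA
  v2 <- asd_matrix(tiny_panel(d2, "P"))$values
  expect_equal(v2[2, 3], v[2, 3])
  expect_false(identical(v2[1, 2], v[1, 2]))
})

test_that("neighbor joining reconstructs additive trees exactly", {
  # tree ((A:1,B:2):1,(C:3,D:4)) -> additive distances
  dm <- matrix(c(0, 3, 5, 6,
                 3, 0, 6, 7,
                 5, 6, 0, 7,
                 6, 7, 7, 0), 4, 4,
               dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  tr <- nj_tree(dm)
  # exact additivity: tree path lengths reproduce the input matrix
  ct <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(ct, dm, tolerance = 1e-10)
  # AB vs CD split present
  expect_true(ape::is.monophyletic(ape::unroot(tr), c("A", "B")))

  # three taxa: three-point formulas
  d3 <- matrix(c(0, 2, 3, 2, 0, 3, 3, 3, 0), 3, 3,
               dimnames = list(c("x", "y", "z"), c("x", "y", "z")))
  t3 <- nj_tree(d3)
  expect_equal(sort(ape::cophenetic.phylo(t3)[lower.tri(d3)]), c(2, 3, 3))

  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("NJ on simulated pairs separates the populations", {
  hits <- 0
  for (s in 1:20) {
    p <- bn_pair(0.05, n_samples = 8, n_snps = 1500, seed = 100 + s)
    tr <- nj_tree(asd_matrix(p))
    mid <- phangorn::midpoint(tr)
    if (ape::is.monophyletic(mid, samples_of(p, "A")) &&
        ape::is.monophyletic(mid, samples_of(p, "B"))) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("negative NJ branch lengths are clamped to zero", {
  set.seed(7)
  for (i in 1:5) {
    m <- matrix(runif(36, 0.5, 1), 6, 6)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    dimnames(m) <- list(letters[1:6], letters[1:6])
    expect_true(all(nj_tree(m)$edge.length >= 0))
  }
})

test_that("PCA separates differentiated populations and reports both variance conventions", {
  p <- bn_pair(0.05, n_samples = 40, n_snps = 3000, seed = 14)
  pc <- pca_panel(p)
  s1 <- pc$coordinates[p$pop_of == "A", 1]
  s2 <- pc$coordinates[p$pop_of == "B", 1]
  expect_true(min(s1) > max(s2) || min(s2) > max(s1))  # zero overlap on PC1
  expect_true(all(diff(pc$eigenvalues) <= 1e-8))
  expect_equal(sum(pc$var_frac_top10[1:10]), 1)
  expect_equal(pc$var_frac_total,
               pc$eigenvalues / sum(pc$eigenvalues))
})

test_that("PCA scores are invariant to SNP order and duplicate samples coincide", {
  p <- bn_pair(0.03, n_samples = 15, n_snps = 500, seed = 15)
  pc <- pca_panel(p, n_components = 3)
  perm <- sample(n_snps(p))
  pp <- genotype_panel(p$dosages[, perm], p$snps[perm, ], p$pop_of)
  pc2 <- pca_panel(pp, n_components = 3)
  for (k in 1:3) {
    expect_equal(abs(pc$coordinates[, k]), abs(pc2$coordinates[, k]),
                 tolerance = 1e-6)
  }

  dup <- rbind(p$dosages, dup1 = p$dosages[1, ])
  pd <- genotype_panel(dup, p$snps,
                       c(p$pop_of, dup1 = unname(p$pop_of[1])))
  pcd <- pca_panel(pd, n_components = 2)
  expect_equal(pcd$coordinates["dup1", ], pcd$coordinates[1, ],
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("kmeans on top PCs clusters separated groups and tabulates fractions", {
  p <- bn_pair(0.08, n_samples = 30, n_snps = 2000, seed = 16)
  pc <- pca_panel(p)
  km <- kmeans_on_pcs(pc, K = 2, seed = 1)
  expect_equal(sort(unname(km$fractions["A", ])), c(0, 1))
  expect_equal(sort(unname(km$fractions["B", ])), c(0, 1))
  expect_equal(unname(rowSums(km$fractions)), c(1, 1))

  km1 <- kmeans_on_pcs(pc, K = 1, seed = 1)
  expect_true(all(km1$assignments == 1))
  expect_error(kmeans_on_pcs(pc, K = 1000), "exceed")
})

test_that("with two close populations and one distant, K = 2 merges the close pair", {
  m <- divergence_model(c(A = 0.005, B = 0.005, C = 0.15), n_samples = 25,
                        n_snps = 3000)
  p <- simulate_divergence(m, seed = 17)
  km <- kmeans_on_pcs(pca_panel(p), K = 2, seed = 2)
  clA <- which.max(km$fractions["A", ])
  expect_equal(which.max(km$fractions["B", ]), clA)
  expect_false(which.max(km$fractions["C", ]) == clA)
})
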