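test_that("D statistic matches hand arithmetic and boundary cases", {
  # two SNPs (w,x,y,z) = (.6,.1,.8,.2) and (.3,.7,.4,.9): D = 0.50/0.7308
  w <- c(.6, .3); x <- c(.1, .7); y <- c(.8, .4); z <- c(.2, .9)
  # replicate to satisfy the minimum block count; identical SNP pairs
  f <- freq_table(W = rep(w, 10), X = rep(x, 10), Y = rep(y, 10),
                  Z = rep(z, 10))
  r <- d_stat(f, "W", "X", "Y", "Z", n_blocks = 10)
  expect_equal(r$value, 0.5 / (0.3944 + 0.3364), tolerance = 1e-10)
  expect_equal(r$value, 0.6842, tolerance = 1e-4)

  # y = z everywhere -> D = 0 exactly
  f0 <- freq_table(W = runif(50), X = runif(50), Y = seq(0.1, 0.9, length.out = 50),
                   Z = seq(0.1, 0.9, length.out = 50))
  expect_equal(d_stat(f0, "W", "X", "Y", "Z", n_blocks = 10)$value, 0)

  # single fixed SNP pattern: Num = Den = 1
  f1 <- freq_table(W = rep(1, 20), X = rep(0, 20), Y = rep(1, 20),
                   Z = rep(0, 20))
  expect_equal(d_stat(f1, "W", "X", "Y", "Z", n_blocks = 10)$value, 1)
})

test_that("D is antisymmetric in its target pair and bounded", {
  set.seed(31)
  f <- freq_table(W = runif(600), X = runif(600), Y = runif(600),
                  Z = runif(600))
  r1 <- d_stat(f, "W", "X", "Y", "Z", n_blocks = 30)
  r2 <- d_stat(f, "W", "X", "Z", "Y", n_blocks = 30)
  expect_equal(r1$value, -r2$value)
  expect_equal(r1$jackknife_se, r2$jackknife_se)
  expect_lte(abs(r1$value), 1)
})

test_that("f2, f3, f4 match their closed forms", {
  # f2 single-value: (0.9 - 0.1)^2 = 0.64
  f <- freq_table(A = rep(0.9, 20), B = rep(0.1, 20))
  expect_equal(f2_stat(f, "A", "B", n_blocks = 10)$value, 0.64)
  # f2(A, A) = 0
  expect_equal(f2_stat(f, "A", "A", n_blocks = 10)$value, 0)

  # f3(C; A, B) = (0.5-0.2)(0.5-0.9) = -0.12
  f3t <- freq_table(C = rep(0.5, 20), A = rep(0.2, 20), B = rep(0.9, 20))
  expect_equal(f3_stat(f3t, "C", "A", "B", n_blocks = 10)$value, -0.12)
  # c = a everywhere -> 0
  v <- runif(20)
  expect_equal(f3_stat(freq_table(C = v, A = v, B = runif(20)),
                       "C", "A", "B", n_blocks = 10)$value, 0)

  # f4 = (0.9-0.1)(0.8-0.2) = 0.48; A = B -> 0
  f4t <- freq_table(A = rep(.9, 20), B = rep(.1, 20), C = rep(.8, 20),
                    D = rep(.2, 20))
  expect_equal(f4_stat(f4t, "A", "B", "C", "D", n_blocks = 10)$value, 0.48)
  expect_equal(f4_stat(f4t, "A", "A", "C", "D", n_blocks = 10)$value, 0)
})

test_that("f4 is additive over the third slot and antisymmetric", {
  set.seed(33)
  f <- freq_table(A = runif(300), B = runif(300), C = runif(300),
                  D = runif(300), E = runif(300))
  abcd <- f4_stat(f, "A", "B", "C", "D", n_blocks = 15)$value
  abce <- f4_stat(f, "A", "B", "C", "E", n_blocks = 15)$value
  abed <- f4_stat(f, "A", "B", "E", "D", n_blocks = 15)$value
  expect_equal(abcd, abce + abed, tolerance = 1e-12)
  expect_equal(f4_stat(f, "B", "A", "C", "D", n_blocks = 15)$value, -abcd)
})

test_that("D and f-statistics are invariant to ref/alt recoding", {
  set.seed(34)
  f <- freq_table(W = runif(400), X = runif(400), Y = runif(400),
                  Z = runif(400))
  flip <- sample(c(TRUE, FALSE), 400, replace = TRUE)
  ff <- f
  ff$freq[, flip] <- 1 - ff$freq[, flip]
  expect_equal(d_stat(ff, "W", "X", "Y", "Z", n_blocks = 20)$value,
               d_stat(f, "W", "X", "Y", "Z", n_blocks = 20)$value)
  expect_equal(f2_stat(ff, "W", "X", n_blocks = 20)$value,
               f2_stat(f, "W", "X", n_blocks = 20)$value)
  expect_equal(f3_stat(ff, "W", "X", "Y", n_blocks = 20)$value,
               f3_stat(f, "W", "X", "Y", n_blocks = 20)$value)
  expect_equal(f4_stat(ff, "W", "X", "Y", "Z", n_blocks = 20)$value,
               f4_stat(f, "W", "X", "Y", "Z", n_blocks = 20)$value)
})

test_that("f2 grows with Balding-Nichols branch drift (fixed seeds)", {
  vals <- vapply(c(0.005, 0.01, 0.02, 0.05), function(F) {
    p <- bn_pair(F, n_samples = 50, n_snps = 4000, seed = 19)
    f2_stat(allele_frequencies(p), "A", "B", n_blocks = 40)$value
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("an admixed target shows significantly negative f3", {
  src <- bn_pair(0.06, n_samples = 60, n_snps = 30000, seed = 41)
  tg <- simulate_admixed_targets(src, "A", "B", c(0.5), n_samples = 60,
                                 seed = 42)
  fr <- allele_frequencies(combine_panels(src, tg))
  r <- f3_stat(fr, "mix1", "A", "B", n_blocks = 100)
  expect_lt(r$value, 0)
  expect_lt(r$Z, -2.58)
  # an unadmixed tip is not significantly negative
  r2 <- f3_stat(fr, "A", "B", "mix1", n_blocks = 100)
  expect_gt(r2$Z, -2.58)
})

test_that("block jackknife reproduces the analytic SE of a mean", {
  set.seed(35)
  ratios <- replicate(100, {
    x <- rnorm(2000, mean = 0.3, sd = 1)
    jk <- block_jackknife(x, n_blocks = 50)
    jk$se / (sd(x) / sqrt(2000))
  })
  expect_equal(mean(ratios), 1, tolerance = 0.15)

  # constant blocks -> SE 0
  jk0 <- block_jackknife(rep(2, 500), n_blocks = 10)
  expect_equal(jk0$se, 0)
  expect_equal(jk0$estimate, 2)

  # SE is stable when the block count doubles on homogeneous data
  set.seed(36)
  x <- rnorm(5000)
  s1 <- block_jackknife(x, n_blocks = 50)$se
  s2 <- block_jackknife(x, n_blocks = 100)$se
  expect_lt(abs(s2 - s1) / s1, 0.2)

  expect_error(block_jackknife(rnorm(30), n_blocks = 50), "smaller")
  expect_error(block_jackknife(rnorm(30), n_blocks = 5), ">= 10")
})

test_that("F4 regression recovers exact line geometry on noiseless mixtures", {
  # targets whose frequencies are exact mixtures of the donors give points
  # that lie exactly on y = l - (l/m) x; alphas are recovered to precision
  set.seed(37)
  L <- 1000
  da <- runif(L, -0.2, 0.2); db <- runif(L, -0.2, 0.2)
  alphas <- c(0.2, 0.5, 0.8)
  tg <- lapply(alphas, function(a) 0.5 + a * da + (1 - a) * db)
  names(tg) <- paste0("t", 1:3)
  f <- do.call(freq_table,
               c(list(O = rep(0.5, L), A = 0.5 + da, B = 0.5 + db), tg))
  # lm warns about the essentially perfect fit; that is the point here
  reg <- suppressWarnings(
    f4_ratio_regression(f, "O", "A", "B", names(tg), n_blocks = 50))
  expect_equal(unname(reg$alphas), alphas, tolerance = 1e-10)
  expect_equal(reg$intercept_l, mean(da * (da - db)), tolerance = 1e-10)
  expect_equal(reg$m_edge, mean(db * (db - da)), tolerance = 1e-10)
  expect_equal(reg$r_squared, 1, tolerance = 1e-10)
  expect_lt(max(reg$alpha_se), 1e-8)
})

test_that("F4 regression recovers simulated admixture proportions within 0.05", {
  m <- divergence_model(c(O = 0.15, A = 0.05, B = 0.05), n_samples = 60,
                        n_snps = 30000)
  src <- simulate_divergence(m, seed = 51)
  alphas <- c(0.2, 0.5, 0.8)
  tg <- simulate_admixed_targets(src, "A", "B", alphas, n_samples = 60,
                                 seed = 52)
  fr <- allele_frequencies(combine_panels(src, tg))
  reg <- f4_ratio_regression(fr, "O", "A", "B", paste0("mix", 1:3),
                             n_blocks = 100)
  expect_lt(max(abs(reg$alphas - alphas)), 0.05)
  expect_lt(reg$slope, 0)
  expect_gt(reg$intercept_l, 0)
  expect_gt(reg$r_squared, 0.9)
  expect_true(all(reg$alpha_se > 0))

  # a target equal to donor A sits near x = 0 with alpha ~ 1
  tg2 <- simulate_admixed_targets(src, "A", "B", c(pure = 1, half = 0.5,
                                                   none = 0),
                                  n_samples = 60, seed = 53)
  fr2 <- allele_frequencies(combine_panels(src, tg2))
  reg2 <- f4_ratio_regression(fr2, "O", "A", "B", c("pure", "half", "none"),
                              n_blocks = 100)
  expect_equal(unname(reg2$alphas["pure"]), 1, tolerance = 0.05)
  expect_lt(abs(reg2$points$x[1]), 0.002)
})

test_that("three-way contributions renormalize pairwise regressions", {
  mk_reg <- function(donors, alphas, targets) {
    structure(list(donors = donors, targets = targets,
                   alphas = setNames(alphas, targets)),
              class = "admixture_regression")
  }
  t <- c("X1", "X2")
  ab <- mk_reg(c("A", "B"), c(0.6, 0.5), t)
  ac <- mk_reg(c("A", "C"), c(0.6, 0.5), t)
  bc <- mk_reg(c("B", "C"), c(0.5, 0.5), t)
  out <- three_way_contributions(ab, ac, bc)
  expect_equal(unname(rowSums(out)), c(1, 1))
  expect_true(all(out >= 0 & out <= 1))
  # symmetric inputs give symmetric shares for X2
  expect_equal(unname(out["X2", ]), rep(1 / 3, 3), tolerance = 1e-12)
})
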