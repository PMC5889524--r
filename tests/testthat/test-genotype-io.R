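test_that("read_vcf parses GT fields, drops non-autosomes and unknown samples", {
  samples <- c("s1", "s2", "s3")
  recs <- c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t0|1\t1|1\t0|0",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1\t1|1",
    "2\t150\trs3\tG\tA\t.\tPASS\t.\tGT\t1|0\t0|0\t0|1",
    "X\t300\trs4\tT\tC\t.\tPASS\t.\tGT\t0|0\t1|1\t0|1"
  )
  vcf <- write_vcf_lines(recs, samples, phased = TRUE)
  pops <- write_pop_tsv(samples, c("P1", "P1", "P2"))
  p <- read_vcf(vcf, pops)

  expect_equal(n_snps(p), 3)             # chrX record dropped
  expect_false("rs4" %in% p$snps$id)
  expect_true(p$phased)
  expect_equal(unname(p$dosages[, "rs1"]), c(1L, 2L, 0L))
  expect_equal(unname(p$haplotypes[1:2, "rs1"]), c(0L, 1L))  # s1 = 0|1

  # a sample missing from the pop table is dropped with a message
  pops2 <- write_pop_tsv(c("s1", "s2"), c("P1", "P1"))
  expect_message(p2 <- read_vcf(vcf, pops2), "dropped")
  expect_equal(n_samples(p2), 2)
})

test_that("missing genotypes reduce n_hap and flag undefined frequencies", {
  samples <- c("s1", "s2", "s3")
  recs <- c(
    "1\t100\trs1\tA\tG\t.\tPASS\t.\tGT\t./.\t0/1\t1/1",
    "1\t200\trs2\tC\tT\t.\tPASS\t.\tGT\t./.\t./.\t./."
  )
  vcf <- write_vcf_lines(recs, samples)
  p <- read_vcf(vcf, write_pop_tsv(samples, "P1"))
  expect_false(p$phased)
  expect_true(is.na(p$dosages["s1", "rs1"]))
  fr <- allele_frequencies(p)
  expect_equal(unname(fr$n_hap["P1", ]), c(4L, 0L))   # one missing sample = -2 chromosomes
  expect_equal(unname(fr$freq["P1", "rs1"]), 3 / 4)
  expect_true(is.na(fr$freq["P1", "rs2"]))
})

test_that("panels round-trip through VCF, phased and unphased", {
  p <- bn_pair(0.02, n_samples = 10, n_snps = 80, seed = 5)
  p$dosages[1, 3] <- NA  # inject a missing call
  p <- genotype_panel(p$dosages, p$snps, p$pop_of)
  vf <- tempfile(fileext = ".vcf"); pf <- tempfile(fileext = ".tsv")
  write_vcf(p, vf, pf)
  p2 <- read_vcf(vf, pf)
  expect_identical(unname(p$dosages), unname(p2$dosages))
  expect_identical(p$snps$pos_bp, p2$snps$pos_bp)
  expect_identical(unname(p$pop_of), unname(p2$pop_of))

  w <- simulate_wright_fisher_haplotypes(
    wf_config(50, n_generations = 50L, chrom_length_cM = 2, n_loci = 30,
              sample_haplotypes = 20L), seed = 2)
  write_vcf(w, vf, pf)
  w2 <- read_vcf(vf, pf)
  expect_true(w2$phased)
  expect_identical(unname(w$haplotypes), unname(w2$haplotypes))
})

test_that("qc_missingness applies a strict less-than threshold", {
  d <- matrix(0L, nrow = 20, ncol = 3)
  d[1, 1] <- NA               # SNP 1: missing rate exactly 0.05
  d[1:2, 2] <- NA             # SNP 2: 0.10
  d[, 3] <- 1L                # SNP 3: complete
  p <- tiny_panel(d, "P1")
  q <- qc_missingness(p, max_missing = 0.05)
  expect_equal(q$snps$id, "m003")    # 0.05 is removed (strict <)
  expect_equal(n_samples(q), 20)

  full <- tiny_panel(matrix(1L, 5, 4), "P1")
  expect_equal(n_snps(qc_missingness(full, 0.05)), 4)     # identity on complete data
  expect_equal(n_snps(qc_missingness(p, 0)), 0)           # nothing survives max_missing = 0
})

test_that("thin_by_distance keeps the greedy >gap subset per chromosome", {
  p <- tiny_panel(matrix(1L, 2, 4), "P1", pos_bp = c(1e5, 4e5, 7e5, 1.3e6))
  t1 <- thin_by_distance(p, 5e5)
  expect_equal(t1$snps$pos_bp, c(1e5, 7e5, 1.3e6))
  expect_equal(n_snps(thin_by_distance(p, 0)), 4)
  single <- tiny_panel(matrix(1L, 2, 1), "P1")
  expect_equal(n_snps(thin_by_distance(single, 5e5)), 1)
  # property: all surviving same-chromosome gaps exceed the threshold
  q <- bn_pair(0.01, n_samples = 5, n_snps = 400, seed = 2, spacing_bp = 200000)
  th <- thin_by_distance(q, 500000)
  gaps <- unlist(tapply(th$snps$pos_bp, th$snps$chrom, diff))
  expect_true(all(gaps > 500000))
})

test_that("ld_prune removes duplicates but keeps independent SNPs", {
  set.seed(42)
  d <- matrix(rbinom(50 * 20, 2, 0.4), nrow = 50)
  dup <- cbind(d, d[, 3])     # perfect copy of SNP 3
  p <- tiny_panel(dup, "P1")
  pruned <- ld_prune(p, r2_threshold = 0.8, window_snps = 30, step_snps = 5)
  expect_equal(n_snps(pruned), 20)   # exactly one of the duplicate pair dropped

  # independent simulated SNPs survive
  p2 <- tiny_panel(d, "P1")
  expect_equal(n_snps(ld_prune(p2, 0.8, 30, 5)), 20)
  # threshold 1.0 removes only perfect duplicates
  expect_equal(n_snps(ld_prune(p, 1.0, 30, 5)), 20)
  expect_equal(n_snps(ld_prune(p2, 1.0, 30, 5)), 20)
})

test_that("allele_frequencies match hand counts and pool by n_hap weighting", {
  d <- rbind(c(0L, 2L), c(1L, 2L), c(2L, 2L))
  p <- tiny_panel(d, "P1")
  fr <- allele_frequencies(p)
  expect_equal(unname(fr$freq["P1", 1]), 0.5)
  expect_equal(unname(fr$n_hap["P1", 1]), 6L)

  d2 <- rbind(c(1L), c(0L), c(0L), c(0L), c(0L))
  fr2 <- allele_frequencies(tiny_panel(d2, "P1"))
  expect_equal(unname(fr2$freq["P1", 1]), 0.1)
  expect_equal(unname(fr2$n_hap["P1", 1]), 10L)

  expect_error(allele_frequencies(p, "nope"), "unknown population")

  # pooled frequency = n_hap-weighted mean of subpopulation frequencies
  q <- bn_pair(0.05, n_samples = c(12, 30), n_snps = 200, seed = 3)
  fr3 <- allele_frequencies(q)
  pooled <- q
  pooled$pop_of[] <- "ALL"
  frp <- allele_frequencies(pooled)
  wmean <- (fr3$freq["A", ] * fr3$n_hap["A", ] + fr3$freq["B", ] * fr3$n_hap["B", ]) /
    (fr3$n_hap["A", ] + fr3$n_hap["B", ])
  expect_equal(unname(frp$freq["ALL", ]), unname(wmean))
})

test_that("genetic map attachment interpolates and defaults to 1 cM/Mb", {
  p <- tiny_panel(matrix(1L, 2, 3), "P1", pos_bp = c(1e6, 2e6, 3e6))
  expect_equal(genetic_positions(p), c(1, 2, 3))
  map <- data.frame(chrom = "1", pos_bp = c(1e6, 3e6), cM = c(0, 4))
  pm <- attach_genetic_map(p, map)
  expect_equal(pm$snps$pos_cM, c(0, 2, 4))
})
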