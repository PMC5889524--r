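#' Weir-Cockerham variance components for one population pair
#'
#' Per-SNP between-population (`a`) and total (`a + b + c`) variance
#' components of the Weir & Cockerham (1984) unbiased F_ST estimator,
#' computed from dosages with per-SNP non-missing sample sizes. SNPs
#' monomorphic across the pooled pair, or with fewer than two genotyped
#' samples in either population, are returned as `NA` and skipped by the
#' aggregators.
#'
#' @param panel a `genotype_panel`.
#' @param popA,popB population names.
#' @return list with numeric vectors `a` and `abc` (one entry per SNP).
#' @keywords internal
wc_components <- function(panel, popA, popB) {
  dA <- panel$dosages[panel$pop_of == popA, , drop = FALSE]
  dB <- panel$dosages[panel$pop_of == popB, , drop = FALSE]
  n1 <- colSums(!is.na(dA)); n2 <- colSums(!is.na(dB))
  p1 <- colSums(dA, na.rm = TRUE) / (2 * n1)
  p2 <- colSums(dB, na.rm = TRUE) / (2 * n2)
  h1 <- colMeans(dA == 1L, na.rm = TRUE)
  h2 <- colMeans(dB == 1L, na.rm = TRUE)

  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)

  a <- nbar / nc *
    (s2 - 1 / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2

  usable <- n1 >= 2 & n2 >= 2 & pbar > 0 & pbar < 1
  a[!usable] <- NA_real_
  abc <- a + b + cc
  abc[!usable] <- NA_real_
  list(a = a, abc = abc)
}

#' Unbiased pairwise F_ST (Weir-Cockerham 1984)
#'
#' Ratio-of-sums aggregation over SNPs: `F_ST = sum(a) / sum(a + b + c)`,
#' the standard multi-locus form of the unbiased estimator (slightly
#' negative values are possible on weakly differentiated pairs). With
#' `per_snp_mean = TRUE` the mean of per-SNP ratios is returned instead, for
#' sensitivity analysis.
#'
#' @param panel a `genotype_panel`.
#' @param popA,popB population names (each with >= 2 samples).
#' @param per_snp_mean use mean of per-SNP ratios instead of ratio of sums.
#' @return list with `fst` and `n_snps` (informative SNPs used).
#' @export
pairwise_fst <- function(panel, popA, popB, per_snp_mean = FALSE) {
  if (sum(panel$pop_of == popA) < 2 || sum(panel$pop_of == popB) < 2) {
    stop("both populations need >= 2 samples")
  }
  comp <- wc_components(panel, popA, popB)
  use <- !is.na(comp$a)
  if (!any(use)) stop("no usable (polymorphic) SNPs for pair ", popA, "-", popB)
  fst <- if (per_snp_mean) mean(comp$a[use] / comp$abc[use])
         else sum(comp$a[use]) / sum(comp$abc[use])
  list(fst = fst, n_snps = sum(use))
}

#' Per-SNP pairwise F_ST (for marker ranking)
#'
#' @inheritParams pairwise_fst
#' @return numeric vector of per-SNP `a / (a + b + c)`; `NA` where
#'   uninformative.
#' @export
per_snp_fst <- function(panel, popA, popB) {
  comp <- wc_components(panel, popA, popB)
  comp$a / comp$abc
}

#' Pairwise F_ST matrix over all populations
#'
#' @param panel a `genotype_panel`.
#' @return an `fst_matrix`: list with `populations`, symmetric `values`
#'   matrix (diagonal 0) and `n_snps` matrix of per-pair SNP counts.
#' @export
fst_matrix <- function(panel) {
  pops <- populations(panel)
  k <- length(pops)
  vals <- matrix(0, k, k, dimnames = list(pops, pops))
  cnts <- matrix(NA_integer_, k, k, dimnames = list(pops, pops))
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      r <- pairwise_fst(panel, pops[i], pops[j])
      vals[i, j] <- vals[j, i] <- r$fst
      cnts[i, j] <- cnts[j, i] <- r$n_snps
    }
  }
  structure(list(populations = pops, values = vals, n_snps = cnts),
            class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  cat("Pairwise F_ST (Weir-Cockerham, ratio of sums):\n")
  print(round(x$values, 4))
  invisible(x)
}
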