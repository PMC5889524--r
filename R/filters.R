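#' Remove SNPs by missing-call rate
#'
#' Keeps only SNPs whose missing fraction across all samples is strictly
#' below `max_missing` (a SNP missing in exactly 5% of samples is removed at
#' the default threshold). Samples are never removed.
#'
#' @param panel a `genotype_panel`.
#' @param max_missing maximum tolerated missing fraction, in `[0, 1]`.
#' @return the filtered panel.
#' @export
qc_missingness <- function(panel, max_missing = 0.05) {
  stopifnot(max_missing >= 0, max_missing <= 1)
  miss <- colMeans(is.na(panel$dosages))
  subset_panel(panel, snp_idx = which(miss < max_missing))
}

#' Thin SNPs to a minimum physical spacing
#'
#' Greedy left-to-right scan per chromosome: a SNP is kept iff its distance
#' to the previously kept SNP exceeds `min_gap_bp`; the first SNP of each
#' chromosome is always kept.
#'
#' @param panel a `genotype_panel` (SNPs are stored position-sorted).
#' @param min_gap_bp minimum inter-marker distance in base pairs.
#' @return the thinned panel.
#' @export
thin_by_distance <- function(panel, min_gap_bp = 500000) {
  keep <- logical(n_snps(panel))
  for (chr in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == chr)
    last <- -Inf
    for (i in idx) {
      if (panel$snps$pos_bp[i] - last > min_gap_bp) {
        keep[i] <- TRUE
        last <- panel$snps$pos_bp[i]
      }
    }
  }
  subset_panel(panel, snp_idx = which(keep))
}

#' Prune SNPs in high linkage disequilibrium
#'
#' Sliding-window genotype-correlation pruning. Within each window of
#' `window_snps` SNPs (advanced by `step_snps`), while any surviving pair has
#' squared dosage correlation above `r2_threshold`, the member of the worst
#' pair with the higher missing rate is dropped (tie: the later position).
#' Deterministic for a given panel.
#'
#' @param panel a `genotype_panel`.
#' @param r2_threshold r-squared above which one of a pair is removed, `(0, 1]`.
#' @param window_snps window width in SNPs.
#' @param step_snps window advance in SNPs.
#' @return the pruned panel.
#' @export
ld_prune <- function(panel, r2_threshold = 0.8, window_snps = 50, step_snps = 5) {
  stopifnot(r2_threshold > 0, r2_threshold <= 1,
            window_snps >= step_snps, step_snps >= 1)
  keep <- rep(TRUE, n_snps(panel))
  miss <- colMeans(is.na(panel$dosages))
  for (chr in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == chr)
    start <- 1L
    repeat {
      win <- idx[start:min(start + window_snps - 1L, length(idx))]
      live <- win[keep[win]]
      if (length(live) >= 2L) {
        cm <- suppressWarnings(
          stats::cor(panel$dosages[, live, drop = FALSE],
                     use = "pairwise.complete.obs")
        )
        r2 <- cm^2
        diag(r2) <- 0
        r2[is.na(r2)] <- 0
        # inclusive threshold (with float slack) so threshold 1 still
        # removes perfect duplicates
        while (max(r2) >= r2_threshold - 1e-9) {
          w <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
          pair <- live[c(w[1L], w[2L])]
          drop <- if (miss[pair[1L]] > miss[pair[2L]]) pair[1L]
                  else if (miss[pair[2L]] > miss[pair[1L]]) pair[2L]
                  else max(pair)  # tie: later position
          keep[drop] <- FALSE
          di <- which(live == drop)
          r2[di, ] <- 0
          r2[, di] <- 0
        }
      }
      if (start + window_snps - 1L >= length(idx)) break
      start <- start + step_snps
    }
  }
  subset_panel(panel, snp_idx = which(keep))
}
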