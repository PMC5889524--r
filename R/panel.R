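#' Construct a genotype panel
#'
#' The central container of the package: a diploid alt-allele dosage matrix
#' (samples x SNPs, entries 0/1/2 or `NA` for missing) together with SNP
#' metadata, a sample-to-population mapping and, for phased data, the
#' underlying haplotypes. All downstream statistics (F_ST, ASD, PCA, AIMs,
#' LD, D/f-statistics) consume this object.
#'
#' @param dosages integer matrix, samples in rows, SNPs in columns; entries
#'   in `{0, 1, 2, NA}`.
#' @param snps data frame with columns `id`, `chrom`, `pos_bp`, `ref`, `alt`
#'   and optionally `pos_cM`; one row per dosage column, ordered by
#'   (chrom, pos_bp).
#' @param pop_of named character vector mapping each sample id (names) to a
#'   population label.
#' @param haplotypes optional binary matrix with `2 * nrow(dosages)` rows
#'   (two consecutive rows per sample, in sample order); per-sample sums must
#'   reproduce `dosages` at non-missing cells. Supplying it marks the panel
#'   phased.
#' @return An object of class `genotype_panel`.
#' @export
genotype_panel <- function(dosages, snps, pop_of, haplotypes = NULL) {
  if (is.null(rownames(dosages))) stop("dosages must have sample ids as rownames")
  sample_ids <- rownames(dosages)
  if (anyDuplicated(sample_ids)) stop("duplicate sample id")
  if (!all(sample_ids %in% names(pop_of))) {
    stop("every sample must be mapped to a population")
  }
  pop_of <- pop_of[sample_ids]
  if (!is.data.frame(snps)) stop("snps must be a data frame")
  needed <- c("id", "chrom", "pos_bp", "ref", "alt")
  if (!all(needed %in% names(snps))) {
    stop("snps must have columns ", paste(needed, collapse = ", "))
  }
  if (nrow(snps) != ncol(dosages)) stop("snps rows must match dosage columns")
  if (is.null(snps$pos_cM)) snps$pos_cM <- NA_real_
  mode(dosages) <- "integer"
  bad <- !(dosages %in% c(0L, 1L, 2L, NA))
  if (any(bad)) stop("dosages must be 0, 1, 2 or NA")
  colnames(dosages) <- snps$id
  ord <- order(snps$chrom, snps$pos_bp)
  if (!identical(ord, seq_len(nrow(snps)))) {
    snps <- snps[ord, , drop = FALSE]
    rownames(snps) <- NULL
    dosages <- dosages[, ord, drop = FALSE]
    if (!is.null(haplotypes)) haplotypes <- haplotypes[, ord, drop = FALSE]
  }
  phased <- !is.null(haplotypes)
  if (phased) {
    if (nrow(haplotypes) != 2L * nrow(dosages)) {
      stop("haplotypes must have two rows per sample")
    }
    mode(haplotypes) <- "integer"
    hap_sum <- haplotypes[seq(1L, nrow(haplotypes), by = 2L), , drop = FALSE] +
      haplotypes[seq(2L, nrow(haplotypes), by = 2L), , drop = FALSE]
    ok <- is.na(dosages) | (hap_sum == dosages)
    if (!all(ok, na.rm = TRUE)) stop("haplotype pair sums must equal dosages")
    rownames(haplotypes) <- paste0(rep(sample_ids, each = 2L), c("_1", "_2"))
    colnames(haplotypes) <- snps$id
  }
  structure(
    list(
      sample_ids = sample_ids,
      pop_of = pop_of,
      snps = snps,
      dosages = dosages,
      phased = phased,
      haplotypes = haplotypes
    ),
    class = "genotype_panel"
  )
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf(
    "genotype_panel: %d samples x %d SNPs (%s), %d population(s)\n",
    n_samples(x), n_snps(x), if (x$phased) "phased" else "unphased",
    length(unique(x$pop_of))
  ))
  tab <- table(x$pop_of)
  cat("  ", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Number of samples / SNPs in a panel
#' @param panel a `genotype_panel`.
#' @return integer count.
#' @export
n_samples <- function(panel) length(panel$sample_ids)

#' @rdname n_samples
#' @export
n_snps <- function(panel) nrow(panel$snps)

#' Population labels present in a panel
#' @param panel a `genotype_panel`.
#' @return character vector of unique population names.
#' @export
populations <- function(panel) unique(unname(panel$pop_of))

#' Samples belonging to a population
#' @param panel a `genotype_panel`.
#' @param pop population name.
#' @return character vector of sample ids.
#' @export
samples_of <- function(panel, pop) {
  if (!pop %in% panel$pop_of) stop("unknown population: ", pop)
  panel$sample_ids[panel$pop_of == pop]
}

#' Subset a panel by SNPs and/or samples
#'
#' @param panel a `genotype_panel`.
#' @param snp_idx integer or logical index into the SNP columns (optional).
#' @param sample_ids character vector of samples to keep (optional).
#' @return the subset `genotype_panel`.
#' @export
subset_panel <- function(panel, snp_idx = NULL, sample_ids = NULL) {
  dos <- panel$dosages
  snps <- panel$snps
  hap <- panel$haplotypes
  if (!is.null(snp_idx)) {
    dos <- dos[, snp_idx, drop = FALSE]
    snps <- snps[snp_idx, , drop = FALSE]
    rownames(snps) <- NULL
    if (!is.null(hap)) hap <- hap[, snp_idx, drop = FALSE]
  }
  if (!is.null(sample_ids)) {
    keep <- match(sample_ids, rownames(dos))
    if (anyNA(keep)) stop("unknown sample id(s)")
    dos <- dos[keep, , drop = FALSE]
    if (!is.null(hap)) {
      hrows <- as.vector(rbind(2L * keep - 1L, 2L * keep))
      hap <- hap[hrows, , drop = FALSE]
    }
  }
  genotype_panel(dos, snps, panel$pop_of, haplotypes = hap)
}

#' Haplotype rows for one population
#'
#' @param panel a phased `genotype_panel`.
#' @param pop population name.
#' @return binary matrix of haplotypes (2 per sample) for that population.
#' @export
haplotypes_of <- function(panel, pop) {
  if (!panel$phased) stop("panel is not phased")
  idx <- which(panel$pop_of == pop)
  if (!length(idx)) stop("unknown population: ", pop)
  hrows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  panel$haplotypes[hrows, , drop = FALSE]
}

#' Attach genetic-map positions to a panel
#'
#' Interpolates centimorgan positions from a genetic map; SNPs outside the
#' map range are extrapolated linearly from the nearest map interval. When
#' `map` is `NULL` a uniform 1 cM/Mb map is assumed (`pos_cM = pos_bp * 1e-6`),
#' the conventional genome-wide average rate.
#'
#' @param panel a `genotype_panel`.
#' @param map data frame with columns `chrom`, `pos_bp`, `cM`, or `NULL`.
#' @return the panel with `snps$pos_cM` filled in.
#' @export
attach_genetic_map <- function(panel, map = NULL) {
  if (is.null(map)) {
    panel$snps$pos_cM <- panel$snps$pos_bp * 1e-6
    return(panel)
  }
  if (!all(c("chrom", "pos_bp", "cM") %in% names(map))) {
    stop("map needs columns chrom, pos_bp, cM")
  }
  map$chrom <- norm_chrom(map$chrom)
  cm <- rep(NA_real_, n_snps(panel))
  for (chr in unique(panel$snps$chrom)) {
    idx <- which(panel$snps$chrom == chr)
    m <- map[map$chrom == chr, , drop = FALSE]
    if (nrow(m) < 2L) stop("genetic map needs >= 2 points on chromosome ", chr)
    m <- m[order(m$pos_bp), , drop = FALSE]
    if (is.unsorted(m$cM)) stop("map cM must be non-decreasing on chromosome ", chr)
    cm[idx] <- stats::approx(m$pos_bp, m$cM, xout = panel$snps$pos_bp[idx],
                             rule = 2)$y
    # linear extrapolation beyond map ends at the terminal interval's rate
    lo <- panel$snps$pos_bp[idx] < m$pos_bp[1L]
    hi <- panel$snps$pos_bp[idx] > m$pos_bp[nrow(m)]
    if (any(lo)) {
      rate <- (m$cM[2L] - m$cM[1L]) / (m$pos_bp[2L] - m$pos_bp[1L])
      cm[idx][lo] <- m$cM[1L] + (panel$snps$pos_bp[idx][lo] - m$pos_bp[1L]) * rate
    }
    if (any(hi)) {
      k <- nrow(m)
      rate <- (m$cM[k] - m$cM[k - 1L]) / (m$pos_bp[k] - m$pos_bp[k - 1L])
      cm[idx][hi] <- m$cM[k] + (panel$snps$pos_bp[idx][hi] - m$pos_bp[k]) * rate
    }
  }
  panel$snps$pos_cM <- cm
  panel
}

#' Genetic positions of a panel, filling in the default map if absent
#' @param panel a `genotype_panel`.
#' @return numeric vector of cM positions.
#' @export
genetic_positions <- function(panel) {
  cm <- panel$snps$pos_cM
  if (anyNA(cm)) cm <- panel$snps$pos_bp * 1e-6
  cm
}

norm_chrom <- function(x) sub("^chr", "", as.character(x), ignore.case = TRUE)

AUTOSOMES <- as.character(1:22)
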