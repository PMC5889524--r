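#' Read a VCF into a genotype panel
#'
#' Parses GT fields into alt-allele dosages; if every genotype call is phased
#' (`|` separator) the haplotypes are retained and the panel is marked
#' phased. Non-autosomal records are dropped, as are samples absent from the
#' population table (with a message giving the count). Chromosome labels are
#' normalized by stripping a leading "chr".
#'
#' @param path path to a VCF file (plain or gzipped).
#' @param pop_table_path TSV with two columns, `sample_id` and `population`
#'   (header optional).
#' @param map optional genetic map data frame (`chrom`, `pos_bp`, `cM`)
#'   passed to [attach_genetic_map()].
#' @return a `genotype_panel`.
#' @export
read_vcf <- function(path, pop_table_path, map = NULL) {
  pop_of <- read_pop_table(pop_table_path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(rownames(gt), colnames(gt)))
  samples <- colnames(gt)
  if (anyDuplicated(samples)) stop("duplicate sample id in VCF")
  known <- samples %in% names(pop_of)
  if (!all(known)) {
    message(sum(!known), " sample(s) absent from population table dropped")
    gt <- gt[, known, drop = FALSE]
    samples <- samples[known]
  }
  if (!length(samples)) stop("no samples remain after matching population table")

  chrom <- norm_chrom(fix[, "CHROM"])
  auto <- chrom %in% AUTOSOMES
  fix <- fix[auto, , drop = FALSE]
  gt <- gt[auto, , drop = FALSE]
  chrom <- chrom[auto]
  if (!nrow(fix)) stop("no autosomal records in VCF")

  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0(chrom, ":", fix[, "POS"])[is.na(ids) | ids == "."]
  snps <- data.frame(
    id = make.unique(ids),
    chrom = chrom,
    pos_bp = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    stringsAsFactors = FALSE
  )

  gt[gt %in% c(".", "./.", ".|.")] <- NA
  phased <- all(grepl("|", gt[!is.na(gt)], fixed = TRUE)) && any(!is.na(gt))
  a1 <- suppressWarnings(as.integer(substr(gt, 1L, 1L)))
  a2 <- suppressWarnings(as.integer(substr(gt, 3L, 3L)))
  if (any((is.na(a1) | is.na(a2)) & !is.na(gt))) {
    bad <- which((is.na(a1) | is.na(a2)) & !is.na(gt))[1L]
    stop("malformed GT at record ", ((bad - 1L) %% nrow(gt)) + 1L, ": ", gt[bad])
  }
  dos <- matrix(a1 + a2, nrow = nrow(gt))
  dosages <- t(dos)
  rownames(dosages) <- samples

  haplotypes <- NULL
  if (phased) {
    h1 <- matrix(a1, nrow = nrow(gt))
    h2 <- matrix(a2, nrow = nrow(gt))
    haplotypes <- matrix(0L, nrow = 2L * length(samples), ncol = nrow(snps))
    haplotypes[seq(1L, nrow(haplotypes), 2L), ] <- t(h1)
    haplotypes[seq(2L, nrow(haplotypes), 2L), ] <- t(h2)
  }
  panel <- genotype_panel(dosages, snps, pop_of, haplotypes = haplotypes)
  attach_genetic_map(panel, map)
}

#' Read a sample-to-population TSV
#'
#' @param path two-column TSV `sample_id<TAB>population`; a header line
#'   (`sample_id`, `population`) is detected and skipped.
#' @return named character vector (names = sample ids).
#' @export
read_pop_table <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 2L) stop("population table needs two columns")
  if (tolower(tab[1L, 1L]) %in% c("sample_id", "sample")) tab <- tab[-1L, , drop = FALSE]
  if (anyDuplicated(tab[[1L]])) stop("duplicate sample id in population table")
  stats::setNames(tab[[2L]], tab[[1L]])
}

#' Read a genetic map TSV
#' @param path TSV with columns `chrom`, `pos_bp`, `cM` (header required).
#' @return data frame usable by [attach_genetic_map()].
#' @export
read_genetic_map <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  names(m)[1:3] <- c("chrom", "pos_bp", "cM")
  m
}

#' Write a genotype panel to VCF (with a companion population TSV)
#'
#' Emits a minimal VCFv4.2 with GT-only genotypes; phased panels use the
#' `|` separator so phasing survives a round trip.
#'
#' @param panel a `genotype_panel`.
#' @param path output VCF path.
#' @param pop_path optional path for the sample-to-population TSV.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(panel, path, pop_path = NULL) {
  n <- n_samples(panel)
  L <- n_snps(panel)
  if (panel$phased) {
    h1 <- panel$haplotypes[seq(1L, 2L * n, 2L), , drop = FALSE]
    h2 <- panel$haplotypes[seq(2L, 2L * n, 2L), , drop = FALSE]
    gt <- matrix(paste0(h1, "|", h2), nrow = n)
    gt[is.na(panel$dosages)] <- ".|."
  } else {
    gt <- matrix("", nrow = n, ncol = L)
    gt[panel$dosages == 0L] <- "0/0"
    gt[panel$dosages == 1L] <- "0/1"
    gt[panel$dosages == 2L] <- "1/1"
    gt[is.na(panel$dosages)] <- "./."
  }
  body <- cbind(
    panel$snps$chrom, panel$snps$pos_bp, panel$snps$id,
    panel$snps$ref, panel$snps$alt, ".", "PASS", ".", "GT",
    t(gt)
  )
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=popdrift",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", panel$sample_ids), collapse = "\t"),
    apply(body, 1L, paste, collapse = "\t")
  )
  writeLines(lines, path)
  if (!is.null(pop_path)) {
    utils::write.table(
      data.frame(sample_id = panel$sample_ids, population = unname(panel$pop_of)),
      pop_path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
    )
  }
  invisible(path)
}

#' Write an allele-frequency table to TSV
#' @param freqs an `allele_freq_table` (see [allele_frequencies()]).
#' @param path output path; columns `snp_id`, `pop`, `freq`, `n_hap`.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(freqs, path) {
  long <- do.call(rbind, lapply(freqs$populations, function(p) {
    data.frame(
      snp_id = colnames(freqs$freq),
      pop = p,
      freq = freqs$freq[p, ],
      n_hap = freqs$n_hap[p, ],
      stringsAsFactors = FALSE
    )
  }))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
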