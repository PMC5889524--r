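# build a tiny panel from a literal dosage matrix (one chromosome,
# positions 1e5 apart unless given)
tiny_panel <- function(dosages, pops, pos_bp = NULL, chrom = NULL,
                       haplotypes = NULL) {
  n <- nrow(dosages)
  L <- ncol(dosages)
  ids <- sprintf("s%02d", seq_len(n))
  rownames(dosages) <- ids
  if (is.null(pos_bp)) pos_bp <- seq_len(L) * 100000L
  if (is.null(chrom)) chrom <- rep("1", L)
  snps <- data.frame(id = sprintf("m%03d", seq_len(L)), chrom = chrom,
                     pos_bp = as.integer(pos_bp), ref = "A", alt = "G",
                     stringsAsFactors = FALSE)
  genotype_panel(dosages, snps, stats::setNames(rep_len(pops, n), ids),
                 haplotypes = haplotypes)
}

# two-population Balding-Nichols panel
bn_pair <- function(F, n_samples = 50, n_snps = 5000, seed = 1, ...) {
  simulate_divergence(
    divergence_model(c(A = F, B = F), n_samples = n_samples, n_snps = n_snps,
                     ...),
    seed = seed
  )
}

# write a VCF text fixture and return its path
write_vcf_lines <- function(records, samples, phased = FALSE) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records
  ), path)
  path
}

# frequency table built directly from per-population frequency vectors
freq_table <- function(...) {
  mats <- list(...)
  pops <- names(mats)
  freq <- do.call(rbind, mats)
  rownames(freq) <- pops
  L <- ncol(freq)
  colnames(freq) <- sprintf("m%04d", seq_len(L))
  structure(list(populations = pops, freq = freq,
                 n_hap = matrix(100L, length(pops), L,
                                dimnames = dimnames(freq)),
                 snps = NULL),
            class = "allele_freq_table")
}

write_pop_tsv <- function(samples, pops) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(samples, rep_len(pops, length(samples)), sep = "\t"), path)
  path
}
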