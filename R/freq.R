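#' Per-population sample allele frequencies
#'
#' For each requested population and SNP: `freq` is the alt-allele sample
#' frequency (sum of non-missing dosages over `n_hap`) and `n_hap` is the
#' number of non-missing chromosomes (2 x non-missing samples). A SNP with
#' no data in a population has `n_hap = 0` and `freq = NA`. These are the
#' sample frequencies that the D and f2/f3/f4 statistics consume.
#'
#' @param panel a `genotype_panel`.
#' @param populations population names; defaults to all in the panel.
#' @return an `allele_freq_table`: list with `populations`, `freq`
#'   (pop x SNP matrix), `n_hap` (pop x SNP matrix), and `snps` metadata.
#' @export
allele_frequencies <- function(panel, populations = NULL) {
  if (is.null(populations)) populations <- unique(unname(panel$pop_of))
  unknown <- setdiff(populations, panel$pop_of)
  if (length(unknown)) stop("unknown population(s): ", paste(unknown, collapse = ", "))
  L <- n_snps(panel)
  freq <- matrix(NA_real_, nrow = length(populations), ncol = L,
                 dimnames = list(populations, panel$snps$id))
  n_hap <- matrix(0L, nrow = length(populations), ncol = L,
                  dimnames = list(populations, panel$snps$id))
  for (p in populations) {
    d <- panel$dosages[panel$pop_of == p, , drop = FALSE]
    nh <- 2L * colSums(!is.na(d))
    s <- colSums(d, na.rm = TRUE)
    freq[p, ] <- ifelse(nh > 0L, s / nh, NA_real_)
    n_hap[p, ] <- nh
  }
  structure(
    list(populations = populations, freq = freq, n_hap = n_hap,
         snps = panel$snps),
    class = "allele_freq_table"
  )
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d populations x %d SNPs\n",
              length(x$populations), ncol(x$freq)))
  invisible(x)
}
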