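#' Pairwise haplotype r-squared
#'
#' `r^2 = D^2 / (p_i (1-p_i) p_j (1-p_j))` with
#' `D = freq(1,1 haplotype) - p_i p_j`, computed on haplotypes non-missing
#' at both sites.
#'
#' @param haplotypes binary matrix (haplotypes x loci), `NA` allowed.
#' @param i,j locus column indices.
#' @return r-squared, or `NA` if either locus is monomorphic among the
#'   jointly observed haplotypes.
#' @export
pairwise_r2 <- function(haplotypes, i, j) {
  hi <- haplotypes[, i]; hj <- haplotypes[, j]
  ok <- !is.na(hi) & !is.na(hj)
  hi <- hi[ok]; hj <- hj[ok]
  pi_ <- mean(hi); pj <- mean(hj)
  if (pi_ <= 0 || pi_ >= 1 || pj <= 0 || pj >= 1) return(NA_real_)
  D <- mean(hi == 1 & hj == 1) - pi_ * pj
  D^2 / (pi_ * (1 - pi_) * pj * (1 - pj))
}

# all-pairs r2 for a complete (no-NA) haplotype matrix, vectorized
r2_all_pairs <- function(hap) {
  n <- nrow(hap)
  p <- colMeans(hap)
  P11 <- crossprod(hap) / n
  D <- P11 - outer(p, p)
  pq <- p * (1 - p)
  r2 <- D^2 / outer(pq, pq)
  r2[, pq == 0] <- NA
  r2[pq == 0, ] <- NA
  r2
}

#' Bin pairwise r-squared by genetic distance
#'
#' All same-chromosome SNP pairs in one population's haplotypes whose
#' genetic distance lies in `[c_min_cM, c_max_cM)` are assigned to half-open
#' distance classes of width `width_cM` (the default grid is 2500 classes
#' from 0.001 to 2.5 cM). Each class reports the mean r-squared adjusted for
#' sample size, `mean(r^2) - 1/n`, where `n` is the number of chromosomes
#' used.
#'
#' @param panel a phased `genotype_panel`.
#' @param population population whose haplotypes to use.
#' @param c_min_cM,c_max_cM,width_cM distance-class grid, in centimorgans.
#' @return data frame of class `ld_bins` with columns `c_lo`, `c_hi`,
#'   `c_mid` (Morgans), `n_pairs`, `mean_r2_adj`, plus attributes `n_hap`
#'   and `population`.
#' @export
bin_r2 <- function(panel, population, c_min_cM = 0.001, c_max_cM = 2.5,
                   width_cM = 0.001) {
  if (!panel$phased) stop("panel must be phased for LD operations")
  hap <- haplotypes_of(panel, population)
  n <- nrow(hap)
  cm <- genetic_positions(panel)
  chrom <- panel$snps$chrom

  n_bins <- as.integer(round((c_max_cM - c_min_cM) / width_cM))
  edges_cM <- c_min_cM + width_cM * (0:n_bins)
  sum_r2 <- numeric(n_bins)
  n_pairs <- integer(n_bins)

  for (chr in unique(chrom)) {
    idx <- which(chrom == chr)
    if (length(idx) < 2) next
    h <- hap[, idx, drop = FALSE]
    if (anyNA(h)) h[is.na(h)] <- 0L  # defensive; simulated haplotypes are complete
    r2 <- r2_all_pairs(h)
    d <- abs(outer(cm[idx], cm[idx], "-"))
    ut <- upper.tri(d)
    dv <- d[ut]; rv <- r2[ut]
    keep <- dv >= c_min_cM & dv < c_max_cM & !is.na(rv)
    if (!any(keep)) next
    bin <- pmin(floor((dv[keep] - c_min_cM) / width_cM) + 1L, n_bins)
    sum_r2 <- sum_r2 + as.numeric(tapply(rv[keep], factor(bin, levels = 1:n_bins),
                                         sum, default = 0))
    n_pairs <- n_pairs + as.integer(tapply(rep(1L, sum(keep)),
                                           factor(bin, levels = 1:n_bins),
                                           sum, default = 0L))
  }
  mean_r2_adj <- ifelse(n_pairs > 0, sum_r2 / n_pairs - 1 / n, NA_real_)
  out <- data.frame(
    c_lo = edges_cM[-length(edges_cM)] / 100,
    c_hi = edges_cM[-1] / 100,
    c_mid = (edges_cM[-length(edges_cM)] + width_cM / 2) / 100,
    n_pairs = n_pairs,
    mean_r2_adj = mean_r2_adj
  )
  attr(out, "n_hap") <- n
  attr(out, "population") <- population
  class(out) <- c("ld_bins", "data.frame")
  out
}

#' Effective-population-size trajectory from binned LD
#'
#' Each distance class at genetic distance `c` Morgans reflects the
#' effective size about `t = 1/(2c)` generations ago, estimated as
#' `N_e = ((1 / mean_r2_adj) - 2) / (4c)`. Classes with fewer than
#' `min_pairs` SNP pairs or non-positive adjusted r-squared are emitted
#' with `Ne = NA`.
#'
#' @param bins an `ld_bins` data frame from [bin_r2()].
#' @param population label to record (defaults to the bins' population).
#' @param min_pairs minimum pairs per class for a usable estimate.
#' @return data frame of class `ne_trajectory` with columns `c_mid`,
#'   `t_generations`, `mean_r2_adj`, `n_pairs`, `Ne`, `population`.
#' @export
ne_trajectory <- function(bins, population = attr(bins, "population"),
                          min_pairs = 10) {
  ne <- ifelse(
    bins$n_pairs >= min_pairs & !is.na(bins$mean_r2_adj) & bins$mean_r2_adj > 0,
    ((1 / bins$mean_r2_adj) - 2) / (4 * bins$c_mid),
    NA_real_
  )
  ne[!is.na(ne) & ne < 0] <- NA_real_
  out <- data.frame(
    c_mid = bins$c_mid,
    t_generations = 1 / (2 * bins$c_mid),
    mean_r2_adj = bins$mean_r2_adj,
    n_pairs = bins$n_pairs,
    Ne = ne,
    population = if (is.null(population)) NA_character_ else population,
    stringsAsFactors = FALSE
  )
  attr(out, "n_hap") <- attr(bins, "n_hap")
  class(out) <- c("ne_trajectory", "data.frame")
  out
}

#' Inter-population effective size over a distance range
#'
#' The harmonic mean of each population's per-class `N_e` over the classes
#' whose midpoint falls in `c_range` (default 0.01-0.25 cM, i.e. 200-5000
#' generations ago), then the arithmetic mean of the two harmonic means.
#' With `pooled = TRUE` the classes of both populations are pooled into a
#' single harmonic mean instead (alternative reading, for sensitivity).
#'
#' @param trajA,trajB `ne_trajectory` data frames.
#' @param c_range length-2 numeric, class-midpoint range in centimorgans.
#' @param pooled pool both populations' classes into one harmonic mean.
#' @return scalar inter-population `N_e`.
#' @export
interpop_ne <- function(trajA, trajB, c_range = c(0.01, 0.25), pooled = FALSE) {
  pick <- function(tr) {
    cm <- tr$c_mid * 100  # Morgans -> cM
    v <- tr$Ne[cm >= c_range[1] & cm <= c_range[2]]
    bad <- sum(!is.na(v) & v <= 0)
    if (bad) message(bad, " class(es) with non-positive Ne excluded")
    v <- v[!is.na(v) & v > 0]
    if (!length(v)) stop("no usable Ne classes in range for one population")
    v
  }
  a <- pick(trajA); b <- pick(trajB)
  hm <- function(v) length(v) / sum(1 / v)
  if (pooled) hm(c(a, b)) else (hm(a) + hm(b)) / 2
}

#' Date a population divergence from F_ST and effective size
#'
#' `T_F = 2 N_e F_ST` generations, converted to years with
#' `years_per_generation` (default 25). Negative F_ST estimates are clamped
#' to zero with a warning.
#'
#' @param pair character vector of the two population names.
#' @param fst pairwise F_ST for the pair.
#' @param Ne_interpop inter-population effective size (see [interpop_ne()]).
#' @param years_per_generation years per generation.
#' @return a `divergence_estimate` list: `pair`, `fst`, `Ne_interpop`,
#'   `T_F_generations`, `T_F_years`.
#' @export
divergence_time <- function(pair, fst, Ne_interpop, years_per_generation = 25) {
  if (fst < 0) {
    warning("negative F_ST clamped to 0")
    fst <- 0
  }
  tf <- 2 * Ne_interpop * fst
  structure(
    list(pair = sort(pair), fst = fst, Ne_interpop = Ne_interpop,
         T_F_generations = tf,
         T_F_years = tf * years_per_generation),
    class = "divergence_estimate"
  )
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("%s-%s: T_F = %.0f generations (%.0f years) [Fst=%.4f, Ne=%.0f]\n",
              x$pair[1], x$pair[2], x$T_F_generations, x$T_F_years,
              x$fst, x$Ne_interpop))
  invisible(x)
}
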