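#' Specify a Balding-Nichols divergence model
#'
#' Each SNP draws an ancestral frequency `p` from Uniform(`freq_lo`,
#' `freq_hi`); each population then draws its own frequency from
#' Beta(`p(1-F)/F`, `(1-p)(1-F)/F`) where `F` is that population's drift
#' parameter (`F = 0` means the frequency is exactly `p`), so
#' `Var(pop freq | p) = F p (1-p)`. Genotypes are Binomial(2, pop freq).
#' Two populations with per-branch drifts F1 and F2 are differentiated by
#' roughly F1 + F2 on the F_ST scale, which makes the model a convenient
#' stand-in for panels of closely related populations.
#'
#' @param pops named numeric vector of per-population drift values `F`
#'   (each in `[0, 1)`).
#' @param n_samples integer, samples per population (recycled).
#' @param n_snps number of SNPs.
#' @param freq_lo,freq_hi ancestral-frequency range; the default
#'   Uniform(0.05, 0.95) avoids near-monomorphic SNPs.
#' @param spacing_bp physical spacing between consecutive SNPs (one
#'   autosome per 100,000 SNPs).
#' @return a `divergence_model` list.
#' @export
divergence_model <- function(pops, n_samples = 50, n_snps = 10000,
                             freq_lo = 0.05, freq_hi = 0.95,
                             spacing_bp = 5000) {
  stopifnot(all(pops >= 0), all(pops < 1), n_snps >= 1)
  n_samples <- rep_len(n_samples, length(pops))
  structure(list(pops = pops, n_samples = n_samples, n_snps = n_snps,
                 freq_lo = freq_lo, freq_hi = freq_hi,
                 spacing_bp = spacing_bp),
            class = "divergence_model")
}

snp_grid <- function(n_snps, spacing_bp, per_chrom = NULL) {
  if (is.null(per_chrom)) {
    # keep positions well inside integer range (~2e9 bp per chromosome)
    per_chrom <- min(100000L, as.integer(2e9 %/% spacing_bp))
  }
  chrom_i <- ((seq_len(n_snps) - 1L) %/% per_chrom) + 1L
  if (max(chrom_i) > 22L) {
    stop("SNP grid exceeds 22 autosomes; reduce n_snps or spacing_bp")
  }
  pos <- ((seq_len(n_snps) - 1L) %% per_chrom + 1L) * spacing_bp
  data.frame(
    id = sprintf("snp%06d", seq_len(n_snps)),
    chrom = as.character(chrom_i),
    pos_bp = as.integer(pos),
    ref = "A", alt = "G",
    pos_cM = pos * 1e-6,
    stringsAsFactors = FALSE
  )
}

#' Simulate a multi-population panel under Balding-Nichols drift
#'
#' @param model a [divergence_model()].
#' @param seed integer seed; fixes all randomness.
#' @return an unphased `genotype_panel` with the model's population labels,
#'   and the per-SNP true population frequencies in
#'   `attr(panel, "true_freqs")`.
#' @export
simulate_divergence <- function(model, seed = 1) {
  set.seed(seed)
  L <- model$n_snps
  p_anc <- stats::runif(L, model$freq_lo, model$freq_hi)
  pops <- names(model$pops)
  true_freqs <- matrix(NA_real_, nrow = length(pops), ncol = L,
                       dimnames = list(pops, NULL))
  dos_list <- vector("list", length(pops))
  sample_ids <- character(0)
  pop_of <- character(0)
  for (k in seq_along(pops)) {
    F <- model$pops[[k]]
    pf <- if (F == 0) p_anc else
      stats::rbeta(L, p_anc * (1 - F) / F, (1 - p_anc) * (1 - F) / F)
    true_freqs[k, ] <- pf
    n <- model$n_samples[k]
    d <- matrix(stats::rbinom(n * L, 2L, rep(pf, each = n)), nrow = n)
    ids <- sprintf("%s_%03d", pops[k], seq_len(n))
    rownames(d) <- ids
    dos_list[[k]] <- d
    sample_ids <- c(sample_ids, ids)
    pop_of <- c(pop_of, stats::setNames(rep(pops[k], n), ids))
  }
  panel <- genotype_panel(do.call(rbind, dos_list),
                          snp_grid(L, model$spacing_bp), pop_of)
  attr(panel, "true_freqs") <- true_freqs
  panel
}

#' Simulate admixed target populations from two source populations
#'
#' Each target individual's alleles are drawn, independently per chromosome
#' copy and SNP, from source A's sample allele frequency with probability
#' `alpha` and from source B's otherwise, so the target's expected frequency
#' at each SNP is `alpha * p_A + (1 - alpha) * p_B`. The true mixing
#' proportions are recorded in `attr(panel, "true_alphas")`.
#'
#' @param source_panel a `genotype_panel` containing both sources.
#' @param source_a,source_b population names of the two donors.
#' @param alphas numeric vector in `[0, 1]`; one target population per entry,
#'   named `mix1`, `mix2`, ... (or `names(alphas)` if set).
#' @param n_samples samples per target population.
#' @param seed integer seed.
#' @return a `genotype_panel` of the target individuals only (combine with
#'   the sources via [combine_panels()]).
#' @export
simulate_admixed_targets <- function(source_panel, source_a, source_b,
                                     alphas, n_samples = 50, seed = 1) {
  if (any(alphas < 0 | alphas > 1)) stop("alpha must be in [0, 1]")
  set.seed(seed)
  fr <- allele_frequencies(source_panel, c(source_a, source_b))
  pA <- fr$freq[source_a, ]
  pB <- fr$freq[source_b, ]
  if (anyNA(pA) || anyNA(pB)) stop("sources must have data at every SNP")
  L <- n_snps(source_panel)
  targets <- if (is.null(names(alphas))) paste0("mix", seq_along(alphas))
             else names(alphas)
  dos_list <- vector("list", length(alphas))
  pop_of <- character(0)
  for (k in seq_along(alphas)) {
    a <- alphas[[k]]
    n2 <- 2L * n_samples
    from_a <- matrix(stats::runif(n2 * L) < a, nrow = n2)
    p_mat <- matrix(rep(pB, each = n2), nrow = n2)
    p_mat[from_a] <- matrix(rep(pA, each = n2), nrow = n2)[from_a]
    hap <- matrix(stats::rbinom(n2 * L, 1L, p_mat), nrow = n2)
    d <- hap[seq(1L, n2, 2L), , drop = FALSE] + hap[seq(2L, n2, 2L), , drop = FALSE]
    ids <- sprintf("%s_%03d", targets[k], seq_len(n_samples))
    rownames(d) <- ids
    dos_list[[k]] <- d
    pop_of <- c(pop_of, stats::setNames(rep(targets[k], n_samples), ids))
  }
  panel <- genotype_panel(do.call(rbind, dos_list), source_panel$snps, pop_of)
  attr(panel, "true_alphas") <- stats::setNames(as.numeric(alphas), targets)
  panel
}

#' Combine panels that share a SNP set
#' @param ... `genotype_panel` objects with identical SNP tables.
#' @return one `genotype_panel` holding all samples.
#' @export
combine_panels <- function(...) {
  panels <- list(...)
  snps <- panels[[1L]]$snps
  for (p in panels[-1L]) {
    if (!identical(p$snps$id, snps$id)) stop("panels must share the SNP set")
  }
  dos <- do.call(rbind, lapply(panels, `[[`, "dosages"))
  pop_of <- do.call(c, lapply(panels, `[[`, "pop_of"))
  phased <- all(vapply(panels, `[[`, logical(1), "phased"))
  hap <- if (phased) do.call(rbind, lapply(panels, `[[`, "haplotypes")) else NULL
  genotype_panel(dos, snps, pop_of, haplotypes = hap)
}

#' Specify a forward Wright-Fisher haplotype simulation
#'
#' A single chromosome of `n_loci` equally spaced biallelic loci evolves in a
#' constant-size population of `2 * N_e` haplotypes. Each generation every
#' offspring haplotype recombines two uniformly chosen parental haplotypes
#' with a Poisson number of crossovers (mean = map length in Morgans,
#' positions uniform). The initial state is linkage equilibrium with locus
#' frequencies drawn from Uniform(`freq_lo`, `freq_hi`).
#'
#' @param N_e diploid effective size (>= 2).
#' @param n_generations generations to run; the default `4 * N_e` reaches
#'   drift-recombination equilibrium.
#' @param chrom_length_cM map length of the simulated chromosome.
#' @param n_loci number of loci (>= 2), equally spaced.
#' @param sample_haplotypes haplotypes to sample at the end (even, <= 2 N_e).
#' @param freq_lo,freq_hi initial-frequency range.
#' @return a `wf_config` list.
#' @export
wf_config <- function(N_e, n_generations = 4L * N_e, chrom_length_cM = 10,
                      n_loci = 100, sample_haplotypes = 200,
                      freq_lo = 0.05, freq_hi = 0.95) {
  stopifnot(N_e >= 2, n_loci >= 2, chrom_length_cM > 0,
            sample_haplotypes %% 2 == 0)
  if (sample_haplotypes > 2 * N_e) stop("cannot sample more than 2 N_e haplotypes")
  structure(list(N_e = as.integer(N_e), n_generations = as.integer(n_generations),
                 chrom_length_cM = chrom_length_cM, n_loci = as.integer(n_loci),
                 sample_haplotypes = as.integer(sample_haplotypes),
                 freq_lo = freq_lo, freq_hi = freq_hi),
            class = "wf_config")
}

#' Simulate phased haplotypes with LD decay governed by a known N_e
#'
#' Runs the forward Wright-Fisher model of [wf_config()] and samples
#' haplotypes without replacement into a phased `genotype_panel` (consecutive
#' haplotype pairs form diploid samples). At drift-recombination equilibrium
#' the sample-size-adjusted r-squared between loci at genetic distance `c`
#' Morgans is approximately `1 / (2 + 4 N_e c)`, the relation the N_e
#' trajectory machinery inverts.
#'
#' @param config a [wf_config()].
#' @param seed integer seed.
#' @param pop population label for the sampled individuals.
#' @return a phased `genotype_panel`.
#' @export
simulate_wright_fisher_haplotypes <- function(config, seed = 1, pop = "WF") {
  set.seed(seed)
  twoN <- 2L * config$N_e
  L <- config$n_loci
  pos_cM <- seq(0, config$chrom_length_cM, length.out = L)
  p0 <- stats::runif(L, config$freq_lo, config$freq_hi)
  init <- matrix(stats::rbinom(L * twoN, 1L, p0), nrow = L)  # loci x haplotypes
  H <- wf_sim_core(init, pos_cM / 100, config$n_generations)
  pick <- sample.int(twoN, config$sample_haplotypes)
  hap <- t(H[, pick, drop = FALSE])
  n <- config$sample_haplotypes %/% 2L
  dos <- hap[seq(1L, 2L * n, 2L), , drop = FALSE] + hap[seq(2L, 2L * n, 2L), , drop = FALSE]
  ids <- sprintf("%s_%03d", pop, seq_len(n))
  rownames(dos) <- ids
  snps <- data.frame(
    id = sprintf("wf%05d", seq_len(L)),
    chrom = "1",
    pos_bp = as.integer(round(pos_cM * 1e6)) + 1L,
    ref = "A", alt = "G",
    pos_cM = pos_cM,
    stringsAsFactors = FALSE
  )
  genotype_panel(dos, snps, stats::setNames(rep(pop, n), ids), haplotypes = hap)
}
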